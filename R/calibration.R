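#' Predicted LDH along a trajectory
#'
#' Serum LDH is modeled as directly proportional to the total tumor burden
#' plus a basal contribution from normal tissue: `basal + S(t) + R(t)`
#' (proportionality constant 1, so burdens are carried in LDH-equivalent
#' U/L).
#'
#' @param traj A `tumor_trajectory`.
#' @param basal Basal LDH, U/L.
#' @param times Months at which to evaluate; defaults to the trajectory's
#'   own sample times. Requests outside the span are an error.
#' @return Numeric LDH values, U/L.
#' @export
ldh_model <- function(traj, basal = 100, times = NULL) {
  if (is.null(times)) return(basal + traj$S + traj$R)
  st <- trajectory_at(traj, times)
  basal + st$S + st$R
}

param_names <- function(model_kind) {
  switch(model_kind,
         lv = c("S0", "K", "delta", "rR", "C"),
         sw = c("S0", "K", "delta", "rR", "alpha"),
         stop_invalid("model_kind must be 'lv' or 'sw'"))
}

# Build a model params object from a calibration theta. rS and beta are
# multiplied by zero throughout on-treatment fitting, so they are set to 0
# here; therapy simulations assign them later as multiples of rR.
theta_to_params <- function(theta, model_kind, rs_mult = 0, beta_mult = 0) {
  if (model_kind == "lv") {
    lv_params(rS = rs_mult * theta[["rR"]], rR = theta[["rR"]],
              K = theta[["K"]], delta = theta[["delta"]], C = theta[["C"]])
  } else {
    sw_params(rS = rs_mult * theta[["rR"]], rR = theta[["rR"]],
              K = theta[["K"]], delta = theta[["delta"]],
              alpha = theta[["alpha"]], beta = beta_mult * theta[["rR"]])
  }
}

#' Least-squares calibration objective
#'
#' Euclidean (L2) norm of the difference between modeled LDH
#' (`basal + S + R`) and the measured series, with the model run under
#' continuous therapy (all patient data were collected on uninterrupted
#' dosing). The initial resistant burden is tied to the data:
#' `R0 = LDH0 - basal - S0`.
#'
#' Integration failures return a large penalty value (with a warning)
#' rather than an error, so a derivative-free optimizer can keep going.
#'
#' @param theta Named parameter vector: `S0, K, delta, rR, C` for the LV
#'   model, `S0, K, delta, rR, alpha` for the switching model.
#' @param series A [patient_series()].
#' @param model_kind `"lv"` or `"sw"`.
#' @param basal Basal LDH; defaults to the series' own value. Set 0 to tie
#'   R0 to total LDH0 instead of tumor-attributable LDH.
#' @param rtol Solver tolerance used during fitting.
#' @return Non-negative scalar.
#' @export
fit_objective <- function(theta, series, model_kind = c("lv", "sw"),
                          basal = NULL, rtol = 1e-6) {
  model_kind <- match.arg(model_kind)
  basal <- basal %||% series$basal
  pn <- param_names(model_kind)
  if (!all(pn %in% names(theta))) {
    stop_invalid("theta must have entries ", paste(pn, collapse = ", "))
  }
  R0 <- series$ldh[1] - basal - theta[["S0"]]
  if (R0 < 0) return(1e8 + abs(R0))
  pred <- tryCatch({
    params <- theta_to_params(theta, model_kind)
    # integrate directly at the observation times; no dense grid needed.
    # maxsteps is kept small so pathological parameter regions fail fast
    # into the penalty instead of grinding the solver.
    suppressWarnings(
      out <- run_lsoda(c(theta[["S0"]], R0), series$times, params,
                       on = TRUE, rtol = rtol, atol = 1e-8 * params$K,
                       maxsteps = 500))
    basal + out[, 2] + out[, 3]
  }, error = function(e) {
    warning(structure(
      class = c("adaptherapy_penalty_warning", "warning", "condition"),
      list(message = paste0("penalized integration failure during fitting: ",
                            conditionMessage(e)),
           call = sys.call(-1))))
    NULL
  })
  if (is.null(pred) || anyNA(pred) || any(!is.finite(pred))) return(1e8)
  sqrt(sum((pred - series$ldh)^2))
}

#' Default calibration bounds for a patient series
#'
#' `S0` spans (0, LDH0 - basal); `K` spans max observed LDH to 20 times
#' that; rate constants span (0, 10] per month (alpha (0, 5]); `C` spans
#' `[0.5, 3]`, bracketing the plausible competitive asymmetries.
#'
#' @param series A [patient_series()].
#' @param model_kind `"lv"` or `"sw"`.
#' @param basal Basal LDH.
#' @return List with named vectors `lower`, `upper` and character `scale`
#'   (`"log"` / `"linear"` per parameter, used for start sampling).
#' @export
default_fit_bounds <- function(series, model_kind = c("lv", "sw"),
                               basal = NULL) {
  model_kind <- match.arg(model_kind)
  basal <- basal %||% series$basal
  tumor0 <- series$ldh[1] - basal
  Lmax <- max(series$ldh)
  lower <- c(S0 = 1e-3 * tumor0, K = Lmax, delta = 1e-3, rR = 1e-3)
  upper <- c(S0 = (1 - 1e-6) * tumor0, K = 20 * Lmax, delta = 10, rR = 10)
  scale <- c(S0 = "linear", K = "log", delta = "log", rR = "log")
  if (model_kind == "lv") {
    lower <- c(lower, C = 0.5); upper <- c(upper, C = 3)
    scale <- c(scale, C = "linear")
  } else {
    lower <- c(lower, alpha = 1e-3); upper <- c(upper, alpha = 5)
    scale <- c(scale, alpha = "log")
  }
  list(lower = lower, upper = upper, scale = scale)
}

#' Multistart calibration of one patient series
#'
#' Runs [implicit_filtering()] from `n_starts` Latin-hypercube start points
#' (log-spaced for rate-like parameters, linear for `S0` and `C`) and
#' returns the fits ranked by objective value. Entries named in `fixed`
#' are held at the given values and excluded from the search, which is how
#' partial refits (for example re-estimating only `rR` and `delta`) are
#' expressed.
#'
#' @param series A [patient_series()].
#' @param model_kind `"lv"` or `"sw"`.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param budget Objective evaluations per start.
#' @param bounds Optional bounds list as from [default_fit_bounds()].
#' @param fixed Optional named numeric of parameters to hold fixed.
#' @param seed Integer seed for start sampling.
#' @param basal Basal LDH.
#' @param rtol Solver tolerance during fitting.
#' @param polish Number of top-ranked stencil-stage fits to refine with a
#'   bounded quasi-Newton local search (`stats::optim` L-BFGS-B on the
#'   same log-scaled coordinates); 0 disables. The global stage is
#'   derivative-free; the polish exploits the smoothness of the objective
#'   near a basin.
#' @return A `ranked_fits` object: list of fits, each with `theta`,
#'   `fixed_mask`, `objective`, `R0`, `start_index`, `seed`, `evals`;
#'   sorted by increasing objective (ties broken by earlier start).
#' @export
multistart_fit <- function(series, model_kind = c("lv", "sw"),
                           n_starts = 20, budget = 1000, bounds = NULL,
                           fixed = NULL, seed = 1, basal = NULL,
                           rtol = 1e-6, polish = 3) {
  model_kind <- match.arg(model_kind)
  if (n_starts < 1) stop_invalid("n_starts must be >= 1")
  basal <- basal %||% series$basal
  bounds <- bounds %||% default_fit_bounds(series, model_kind, basal)
  pn <- param_names(model_kind)
  fixed <- fixed %||% numeric(0)
  if (length(fixed) && !all(names(fixed) %in% pn)) {
    stop_invalid("fixed names must be among ", paste(pn, collapse = ", "))
  }
  free <- setdiff(pn, names(fixed))
  if (!length(free)) stop_invalid("at least one parameter must be free")
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  sc <- bounds$scale[free]

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(n_starts, length(free))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  starts <- matrix(NA_real_, n_starts, length(free),
                   dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    starts[, j] <- if (sc[j] == "log") {
      exp(log(lo[j]) + U[, j] * (log(hi[j]) - log(lo[j])))
    } else {
      lo[j] + U[, j] * (hi[j] - lo[j])
    }
  }

  full_theta <- function(x) {
    th <- c(x, fixed)
    th[pn]
  }
  # search rate-like parameters in log-space, matching the start sampling,
  # so the stencil resolves slow and fast kinetics equally well
  is_log <- sc == "log"
  fwd <- function(x) { x[is_log] <- log(x[is_log]); x }
  bwd <- function(z) { z[is_log] <- exp(z[is_log]); z }
  obj <- function(z) {
    x <- bwd(z)
    names(x) <- free
    fit_objective(full_theta(x), series, model_kind, basal, rtol)
  }

  fits <- vector("list", n_starts)
  failures <- character(0)
  n_penalized <- 0L
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      withCallingHandlers(
        implicit_filtering(obj, fwd(lo), fwd(hi), fwd(starts[i, ]),
                           budget = budget),
        adaptherapy_penalty_warning = function(w) {
          n_penalized <<- n_penalized + 1L
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("start %d: %s", i, conditionMessage(res)))
      next
    }
    th <- bwd(res$par); names(th) <- free
    theta <- full_theta(th)
    mask <- stats::setNames(pn %in% names(fixed), pn)
    fits[[i]] <- list(model_kind = model_kind, theta = theta,
                      fixed_mask = mask, objective = res$value,
                      R0 = series$ldh[1] - basal - theta[["S0"]],
                      start_index = i, seed = seed, evals = res$evals,
                      patient_id = series$patient_id, basal = basal)
  }
  # local quasi-Newton polish of the best stencil-stage fits
  n_polish <- min(polish, length(fits) - sum(vapply(fits, is.null, logical(1))))
  if (n_polish > 0) {
    ord0 <- order(vapply(fits[!vapply(fits, is.null, logical(1))],
                         `[[`, numeric(1), "objective"))
    live <- which(!vapply(fits, is.null, logical(1)))[ord0]
    for (j in live[seq_len(min(n_polish, length(live)))]) {
      z0 <- fwd(fits[[j]]$theta[free])
      r <- tryCatch(suppressWarnings(withCallingHandlers(
        stats::optim(z0, obj, method = "L-BFGS-B",
                     lower = fwd(lo), upper = fwd(hi),
                     control = list(maxit = 200)),
        adaptherapy_penalty_warning = function(w) {
          n_penalized <<- n_penalized + 1L
          invokeRestart("muffleWarning")
        })), error = function(e) NULL)
      if (!is.null(r) && r$value < fits[[j]]$objective) {
        th <- bwd(r$par); names(th) <- free
        fits[[j]]$theta <- full_theta(th)
        fits[[j]]$objective <- r$value
        fits[[j]]$R0 <- series$ldh[1] - basal - fits[[j]]$theta[["S0"]]
      }
    }
  }
  if (n_penalized > 0) {
    message(sprintf("patient %s: %d objective evaluation(s) hit the integration-failure penalty",
                    series$patient_id, n_penalized))
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) {
    stop("all optimizer starts failed:\n", paste(failures, collapse = "\n"))
  }
  ord <- order(vapply(fits, `[[`, numeric(1), "objective"),
               vapply(fits, `[[`, numeric(1), "start_index"))
  structure(fits[ord], class = "ranked_fits",
            series_id = series$patient_id, model_kind = model_kind,
            basal = basal, seed = seed, bounds = bounds, fixed = fixed)
}

#' @export
print.ranked_fits <- function(x, ...) {
  cat(sprintf("<%d ranked %s fits for patient %s; best objective %.4g>\n",
              length(x), attr(x, "model_kind"), attr(x, "series_id"),
              x[[1]]$objective))
  invisible(x)
}

#' Build a virtual cohort from ranked fits
#'
#' Takes the `top_k` best fits per patient (after removing duplicate optima
#' whose parameter vectors agree within `dedup_tol`) and stacks them into a
#' cohort table. The free parameters `rS` (both models) and `beta`
#' (switching model) stay unassigned (`NA`) until a sweep or paired
#' simulation assigns them as multiples of the fitted `rR`.
#'
#' @param fits_per_patient Named list: patient id -> `ranked_fits`.
#' @param top_k Fits retained per patient.
#' @param dedup_tol Maximum absolute parameter difference treated as a
#'   duplicate.
#' @return A `virtual_cohort` data frame: one row per virtual patient with
#'   the fitted parameters, `R0`, objective and rank.
#' @export
build_virtual_cohort <- function(fits_per_patient, top_k = 50,
                                 dedup_tol = 1e-10) {
  if (!length(fits_per_patient)) stop_invalid("no fits supplied")
  rows <- list()
  for (pid in names(fits_per_patient)) {
    fits <- fits_per_patient[[pid]]
    kept <- list()
    n_dup <- 0L
    for (f in fits) {
      dup <- any(vapply(kept, function(k) {
        max(abs(k$theta - f$theta)) <= dedup_tol
      }, logical(1)))
      if (dup) { n_dup <- n_dup + 1L; next }
      kept[[length(kept) + 1]] <- f
      if (length(kept) == top_k) break
    }
    if (n_dup > 0) {
      message(sprintf("patient %s: dropped %d duplicate fit(s)", pid, n_dup))
    }
    if (length(kept) < top_k) {
      stop(sprintf("patient %s has only %d distinct fits (need %d)",
                   pid, length(kept), top_k))
    }
    for (r in seq_along(kept)) {
      f <- kept[[r]]
      rows[[length(rows) + 1]] <- data.frame(
        patient = pid, model_kind = f$model_kind, rank = r,
        as.list(f$theta), R0 = f$R0, objective = f$objective,
        start_index = f$start_index, basal = f$basal,
        rs_mult = NA_real_, beta_mult = NA_real_)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  structure(cohort, class = c("virtual_cohort", "data.frame"))
}

#' Assemble a virtual cohort directly from known ground truths
#'
#' Convenience for in-silico experiments on synthetic cohorts where the
#' generating parameters are known and no calibration is wanted.
#'
#' @param truths List of ground-truth objects from [sample_ground_truth()]
#'   or [generate_cohort()].
#' @return A `virtual_cohort` data frame.
#' @export
cohort_from_ground_truths <- function(truths) {
  rows <- lapply(seq_along(truths), function(i) {
    gt <- truths[[i]]
    p <- gt$params
    base <- data.frame(patient = gt$patient_id %||% sprintf("GT%d", i),
                       model_kind = model_kind(p), rank = 1L,
                       S0 = gt$S0, K = p$K, delta = p$delta, rR = p$rR)
    if (inherits(p, "lv_params")) {
      base$C <- p$C
    } else {
      base$alpha <- p$alpha
    }
    base$R0 <- gt$R0
    base$objective <- 0
    base$start_index <- 1L
    base$basal <- gt$basal
    base$rs_mult <- if (p$rR > 0) p$rS / p$rR else NA_real_
    base$beta_mult <- if (inherits(p, "sw_params") && p$rR > 0) {
      p$beta / p$rR
    } else {
      NA_real_
    }
    base
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  structure(cohort, class = c("virtual_cohort", "data.frame"))
}

#' Assign free parameters to a virtual cohort
#'
#' The sensitive growth rate and (switching model) the re-sensitization
#' rate cannot be identified from continuous-therapy data, so they are
#' assigned after calibration as multiples of the fitted `rR`. The
#' conventional defaults are `rS = rR` and `beta = 0.45 rR`.
#'
#' @param cohort A `virtual_cohort` data frame.
#' @param rs_mult `rS / rR` multiple, in `[0.05, 2]`.
#' @param beta_mult `beta / rR` multiple, in `[0.05, 0.95]` (SW rows only).
#' @return The cohort with `rs_mult` / `beta_mult` columns filled in.
#' @export
assign_free_params <- function(cohort, rs_mult = 1, beta_mult = 0.45) {
  cohort$rs_mult <- rs_mult
  cohort$beta_mult <- ifelse(cohort$model_kind == "sw", beta_mult, NA_real_)
  cohort
}

# Model params for one cohort row with assigned free-parameter multiples.
row_params <- function(row, rs_mult = NULL, beta_mult = NULL) {
  rs_mult <- rs_mult %||% row$rs_mult
  if (is.na(rs_mult)) stop_invalid("rs_mult unassigned for this virtual patient")
  if (row$model_kind == "lv") {
    lv_params(rS = rs_mult * row$rR, rR = row$rR, K = row$K,
              delta = row$delta, C = row$C)
  } else {
    beta_mult <- beta_mult %||% row$beta_mult
    if (is.na(beta_mult)) stop_invalid("beta_mult unassigned for this virtual patient")
    sw_params(rS = rs_mult * row$rR, rR = row$rR, K = row$K,
              delta = row$delta, alpha = row$alpha,
              beta = beta_mult * row$rR)
  }
}

#' Perturbation robustness of a fit
#'
#' Multiplies every parameter of the fitted vector by independent factors
#' drawn uniformly from `[1 - fraction, 1 + fraction]` and re-evaluates the
#' calibration objective for each perturbed vector.
#'
#' @param fit One fit from a `ranked_fits` list.
#' @param series The [patient_series()] it was fitted to.
#' @param fraction Relative perturbation half-width (default 0.1).
#' @param n Number of perturbed vectors.
#' @param seed Integer seed.
#' @return Data frame with the perturbed parameters and their `objective`.
#' @export
perturb_and_predict <- function(fit, series, fraction = 0.1, n = 100,
                                seed = 1) {
  if (n < 1) stop_invalid("n must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  d <- length(fit$theta)
  factors <- matrix(stats::runif(n * d, 1 - fraction, 1 + fraction), n, d)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    th <- fit$theta * factors[i, ]
    obj <- fit_objective(th, series, fit$model_kind, fit$basal)
    out[[i]] <- data.frame(as.list(th), objective = obj)
  }
  do.call(rbind, out)
}

#' Pooled goodness of fit and parameter variability
#'
#' Pools predicted-versus-observed LDH over all supplied (fit, series)
#' pairs and reports the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, plus the interquartile range of each
#' fitted parameter across fits.
#'
#' @param fits List of fit objects (each carrying `theta`, `model_kind`,
#'   `basal` and `patient_id`).
#' @param series_set Named list of [patient_series()], keyed by patient id.
#' @return List with `r_squared`, `n_points`, `param_iqr`, and the pooled
#'   `observed` / `predicted` vectors. `r_squared` is `NA` when the
#'   observations have no variance.
#' @export
fit_quality <- function(fits, series_set) {
  obs <- pred <- numeric(0)
  thetas <- list()
  for (f in fits) {
    s <- series_set[[f$patient_id]]
    if (is.null(s)) stop_invalid("no series for patient ", f$patient_id)
    R0 <- s$ldh[1] - f$basal - f$theta[["S0"]]
    params <- theta_to_params(f$theta, f$model_kind)
    traj <- simulate_model(params, S0 = f$theta[["S0"]], R0 = max(R0, 0),
                           t_end = max(s$times) + 1e-9, treatment_on = TRUE)
    obs <- c(obs, s$ldh)
    pred <- c(pred, ldh_model(traj, f$basal, s$times))
    thetas[[length(thetas) + 1]] <- f$theta
  }
  if (length(obs) < 2) stop_invalid("need at least 2 pooled observations")
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot <= 0) NA_real_ else 1 - sum((obs - pred)^2) / ss_tot
  theta_mat <- do.call(rbind, thetas)
  iqr <- apply(theta_mat, 2, stats::IQR)
  list(r_squared = r2, n_points = length(obs), param_iqr = iqr,
       observed = obs, predicted = pred)
}
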