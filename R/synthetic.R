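#' Define a virtual-patient archetype
#'
#' An archetype pins down the clinical phenotype a generated patient must
#' exhibit under continuous therapy: the range the baseline LDH may take
#' and the window its progression time must fall into. Fast progressors
#' relapse within 6 months of starting therapy; slow progressors take
#' longer. Parameter draws that violate the window are rejected and
#' redrawn.
#'
#' The prior ranges are package choices intended to produce realistic
#' melanoma-like LDH kinetics; they are documented here and in the methods
#' vignette, and every one can be overridden.
#'
#' @param label `"slow_progressor"` or `"fast_progressor"`.
#' @param model_kind `"lv"` or `"sw"`.
#' @param ldh0_range Baseline LDH range, U/L.
#' @param ttp_window Continuous-therapy progression window, months.
#'   Defaults: `(0, 6]` for fast, `(6, 40]` for slow progressors.
#' @param s_frac_range Range of the initial sensitive fraction
#'   `S0 / (S0 + R0)`. Defaults: `[0.5, 0.995]` slow, `[0.05, 0.6]` fast.
#' @param rR_range,delta_range,alpha_range Log-uniform prior ranges, per
#'   month.
#' @param K_mult_range Log-uniform range of carrying capacity as a multiple
#'   of the initial tumor-attributable LDH.
#' @param C_range Uniform prior range of the LV competition coefficient.
#' @param rs_mult,beta_mult Free-parameter defaults carried by the ground
#'   truth: `rS = rs_mult * rR` and (SW) `beta = beta_mult * rR`.
#' @return A `patient_archetype` object.
#' @export
patient_archetype <- function(label = c("slow_progressor", "fast_progressor"),
                              model_kind = c("lv", "sw"),
                              ldh0_range = c(300, 1500),
                              ttp_window = NULL,
                              s_frac_range = NULL,
                              rR_range = c(0.1, 1.5),
                              delta_range = c(0.3, 3),
                              K_mult_range = c(1.5, 10),
                              C_range = c(1.0, 1.6),
                              alpha_range = c(0.01, 0.5),
                              rs_mult = 1, beta_mult = 0.45) {
  label <- match.arg(label)
  model_kind <- match.arg(model_kind)
  ttp_window <- ttp_window %||%
    if (label == "fast_progressor") c(0, 6) else c(6, 40)
  s_frac_range <- s_frac_range %||%
    if (label == "fast_progressor") c(0.05, 0.6) else c(0.5, 0.995)
  for (r in list(ldh0_range, ttp_window, s_frac_range, rR_range, delta_range,
                 K_mult_range, C_range, alpha_range)) {
    if (length(r) != 2 || any(!is.finite(r)) || r[2] <= r[1] || any(r < 0)) {
      stop_invalid("archetype ranges must be positive, non-empty intervals")
    }
  }
  structure(list(label = label, model_kind = model_kind,
                 ldh0_range = ldh0_range, ttp_window = ttp_window,
                 s_frac_range = s_frac_range, rR_range = rR_range,
                 delta_range = delta_range, K_mult_range = K_mult_range,
                 C_range = C_range, alpha_range = alpha_range,
                 rs_mult = rs_mult, beta_mult = beta_mult),
            class = "patient_archetype")
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Sample one ground-truth virtual patient
#'
#' Draws model parameters and an initial state from the archetype's priors
#' and accepts the draw only if the simulated continuous-therapy course
#' progresses inside the archetype's window (rejection sampling, capped).
#'
#' @param archetype A [patient_archetype()].
#' @param seed Integer seed; a fixed seed reproduces the draw exactly.
#' @param basal Basal LDH, U/L.
#' @param max_draws Rejection cap; exceeding it raises an error naming the
#'   constraint.
#' @return A `ground_truth` list: `params`, `S0`, `R0`, `basal`, `ldh0`,
#'   `ttp_continuous`, `archetype`, `seed`, `n_draws`.
#' @export
sample_ground_truth <- function(archetype, seed = 1, basal = 100,
                                max_draws = 1000) {
  if (!inherits(archetype, "patient_archetype")) {
    stop_invalid("archetype must be a patient_archetype")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  pol <- therapy_policy("continuous", horizon = archetype$ttp_window[2] + 1)
  for (i in seq_len(max_draws)) {
    ldh0 <- stats::runif(1, archetype$ldh0_range[1], archetype$ldh0_range[2])
    tumor0 <- ldh0 - basal
    if (tumor0 <= 0) next
    s_frac <- stats::runif(1, archetype$s_frac_range[1], archetype$s_frac_range[2])
    S0 <- s_frac * tumor0
    R0 <- tumor0 - S0
    rR <- runif_log(1, archetype$rR_range)
    delta <- runif_log(1, archetype$delta_range)
    K <- runif_log(1, archetype$K_mult_range) * tumor0
    params <- if (archetype$model_kind == "lv") {
      C <- stats::runif(1, archetype$C_range[1], archetype$C_range[2])
      lv_params(rS = archetype$rs_mult * rR, rR = rR, K = K,
                delta = delta, C = C)
    } else {
      alpha <- runif_log(1, archetype$alpha_range)
      sw_params(rS = archetype$rs_mult * rR, rR = rR, K = K, delta = delta,
                alpha = alpha, beta = archetype$beta_mult * rR)
    }
    sim <- tryCatch(run_policy(params, S0, R0, pol, basal = basal),
                    error = function(e) NULL)
    if (is.null(sim) || sim$censored) next
    ttp <- sim$ttp_months
    if (ttp > archetype$ttp_window[1] && ttp <= archetype$ttp_window[2]) {
      return(structure(list(params = params, S0 = S0, R0 = R0, basal = basal,
                            ldh0 = ldh0, ttp_continuous = ttp,
                            archetype = archetype$label, seed = seed,
                            n_draws = i),
                       class = "ground_truth"))
    }
  }
  stop(sprintf(
    "archetype '%s' infeasible: no draw progressed within (%g, %g] months in %d attempts",
    archetype$label, archetype$ttp_window[1], archetype$ttp_window[2],
    max_draws))
}

#' Generate a noisy LDH series from a ground truth
#'
#' Samples the noiseless continuous-therapy LDH curve at clinic-like visit
#' times (every `sampling_interval` months with uniform +/-20% jitter,
#' first visit at t = 0) running to just past the progression time, then
#' applies independent multiplicative lognormal noise with coefficient of
#' variation `noise_cv`, mean-corrected so the expected factor is 1.
#'
#' @param ground_truth A `ground_truth` from [sample_ground_truth()].
#' @param sampling_interval Months between draws; `NULL` draws one
#'   uniformly from `[0.5, 1]` (2-4 weeks).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param jitter_frac Visit-time jitter as a fraction of the interval.
#' @param patient_id Label for the emitted series.
#' @return A [patient_series()] carrying the ground truth as attribute
#'   `ground_truth` and the noiseless curve as attribute `ldh_noiseless`.
#' @export
generate_patient_series <- function(ground_truth, sampling_interval = NULL,
                                    noise_cv = 0.1, seed = 1,
                                    jitter_frac = 0.2, patient_id = "P1") {
  if (noise_cv < 0) stop_invalid("noise_cv must be >= 0")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  interval <- sampling_interval %||% stats::runif(1, 0.5, 1.0)
  if (interval <= 0) stop_invalid("sampling_interval must be > 0")
  t_end <- max(ground_truth$ttp_continuous, 3.2 * interval)
  times <- 0
  repeat {
    nxt <- times[length(times)] +
      interval * (1 + stats::runif(1, -jitter_frac, jitter_frac))
    if (nxt > t_end + interval && length(times) >= 4) break
    times <- c(times, nxt)
    if (length(times) > 200) break
  }
  traj <- simulate_model(ground_truth$params, ground_truth$S0,
                         ground_truth$R0, t_end = max(times) + 1e-6,
                         treatment_on = TRUE)
  noiseless <- ldh_model(traj, ground_truth$basal, times)
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    factors <- exp(stats::rnorm(length(times)) * sigma - sigma^2 / 2)
  } else {
    factors <- rep(1, length(times))
  }
  s <- patient_series(patient_id, times, noiseless * factors,
                      basal = ground_truth$basal)
  attr(s, "ground_truth") <- ground_truth
  attr(s, "ldh_noiseless") <- noiseless
  s
}

#' Generate a synthetic cohort with retained ground truths
#'
#' Emulates an LDH-monitored melanoma cohort under continuous therapy:
#' a mix of slow and fast progressors (by default 5:3 in 8 patients),
#' baseline LDH 300-1500 U/L, visits every 2-4 weeks, decline-then-rebound
#' dynamics. Every series carries its generating parameters so recovery
#' error can be computed directly.
#'
#' @param n_patients Cohort size.
#' @param archetype_mix Named fractions over archetype labels; must sum
#'   to 1.
#' @param model_kind `"lv"` or `"sw"`.
#' @param noise_cv Measurement noise CV.
#' @param seed Master seed; per-patient seeds are derived from it.
#' @param basal Basal LDH.
#' @param archetypes Optional named list of [patient_archetype()] objects
#'   to use instead of the defaults (names must cover `archetype_mix`).
#' @param sampling_interval Passed to [generate_patient_series()].
#' @return A `synthetic_cohort`: list with `series` (named list of
#'   [patient_series()]) and `truths` (parallel list of ground truths).
#' @export
generate_cohort <- function(n_patients = 8,
                            archetype_mix = c(slow_progressor = 5 / 8,
                                              fast_progressor = 3 / 8),
                            model_kind = c("lv", "sw"), noise_cv = 0.1,
                            seed = 1, basal = 100, archetypes = NULL,
                            sampling_interval = NULL) {
  model_kind <- match.arg(model_kind)
  if (n_patients < 1) stop_invalid("n_patients must be >= 1")
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop_invalid("archetype_mix fractions must sum to 1 (got ",
                 sum(archetype_mix), ")")
  }
  labels <- names(archetype_mix)
  if (is.null(labels)) stop_invalid("archetype_mix must be named")
  # largest-remainder apportionment of patients to archetypes
  raw <- archetype_mix * n_patients
  counts <- floor(raw)
  rem <- n_patients - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  assign_labels <- rep(labels, counts)
  if (is.null(archetypes)) {
    archetypes <- lapply(stats::setNames(labels, labels), function(l) {
      patient_archetype(l, model_kind = model_kind)
    })
  }
  seeds <- derive_seeds(seed, 2L * n_patients)
  series <- list(); truths <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%d", i)
    gt <- sample_ground_truth(archetypes[[assign_labels[i]]],
                              seed = seeds[2 * i - 1], basal = basal)
    gt$patient_id <- pid
    s <- generate_patient_series(gt, sampling_interval = sampling_interval,
                                 noise_cv = noise_cv, seed = seeds[2 * i],
                                 patient_id = pid)
    series[[pid]] <- s
    truths[[pid]] <- gt
  }
  structure(list(series = series, truths = truths, seed = seed,
                 model_kind = model_kind),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$truths, `[[`, character(1), "archetype")
  cat(sprintf("<synthetic cohort: %d patients (%s), %s model, seed %d>\n",
              length(x$series),
              paste(sprintf("%d %s", table(labs), names(table(labs))),
                    collapse = ", "),
              x$model_kind, x$seed))
  invisible(x)
}

#' Write ground truths to CSV
#'
#' One row per patient with every generating parameter and the seed, so a
#' recovery analysis needs no access to R objects.
#'
#' @param truths List of `ground_truth` objects (as in
#'   `generate_cohort()$truths`).
#' @param file Output path.
#' @export
write_ground_truth_csv <- function(truths, file) {
  rows <- lapply(truths, function(gt) {
    p <- gt$params
    df <- data.frame(patient_id = gt$patient_id %||% NA_character_,
                     model_kind = model_kind(p), archetype = gt$archetype,
                     S0 = gt$S0, R0 = gt$R0, basal = gt$basal,
                     ldh0 = gt$ldh0, ttp_continuous = gt$ttp_continuous,
                     rS = p$rS, rR = p$rR, K = p$K, delta = p$delta,
                     C = if (inherits(p, "lv_params")) p$C else NA_real_,
                     alpha = if (inherits(p, "sw_params")) p$alpha else NA_real_,
                     beta = if (inherits(p, "sw_params")) p$beta else NA_real_,
                     seed = gt$seed)
    df
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
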