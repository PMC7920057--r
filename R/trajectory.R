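#' Integrate a tumor-dynamics model over an on/off treatment schedule
#'
#' Solves the piecewise-smooth ODE obtained by substituting the gated
#' parameters segment by segment. State is handed across segment boundaries,
#' so trajectories are continuous while treatment status switches as a step
#' function.
#'
#' @param params An [lv_params()] or [sw_params()] object.
#' @param S0,R0 Initial sensitive and resistant burden, U/L (>= 0).
#' @param schedule Data frame with columns `start`, `end`, `on` (logical);
#'   rows must partition the requested span contiguously. Defaults to a
#'   single on-treatment segment of `t_end` months.
#' @param t_end Span in months when `schedule` is not given.
#' @param treatment_on Mode of the default single-segment schedule.
#' @param rtol,atol Solver tolerances. `atol` defaults to `1e-10 * K`.
#' @param dt_out Output grid spacing, months. The stored grid is dense
#'   enough that cubic interpolation by [trajectory_at()] reproduces the
#'   solution to about 1e-6 relative error.
#' @return A `tumor_trajectory`: a data frame with columns `t`, `S`, `R`,
#'   `treatment_on`, carrying the parameters and segment table as
#'   attributes. Tiny negative solver undershoot is clamped to zero in the
#'   output.
#' @export
#' @examples
#' p <- lv_params(rS = 0.3, rR = 0.3, K = 2000, delta = 1, C = 1.4)
#' tr <- simulate_model(p, S0 = 400, R0 = 40, t_end = 6)
#' tail(tr, 2)
simulate_model <- function(params, S0, R0, schedule = NULL, t_end = NULL,
                           treatment_on = TRUE,
                           rtol = 1e-8, atol = NULL, dt_out = 0.02) {
  check_finite(c(S0, R0), "initial state")
  if (S0 < 0 || R0 < 0) stop_invalid("S0 and R0 must be >= 0")
  if (is.null(schedule)) {
    if (is.null(t_end)) stop_invalid("provide schedule or t_end")
    schedule <- data.frame(start = 0, end = t_end, on = isTRUE(treatment_on))
  }
  if (!all(c("start", "end", "on") %in% names(schedule))) {
    stop_invalid("schedule needs columns start, end, on")
  }
  if (any(schedule$end <= schedule$start)) stop_invalid("empty schedule segment")
  if (nrow(schedule) > 1 &&
      max(abs(schedule$start[-1] - schedule$end[-nrow(schedule)])) > 1e-9) {
    stop_invalid("schedule segments must partition the span contiguously")
  }
  atol <- atol %||% (1e-10 * params$K)

  y <- c(S0, R0)
  pieces <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    seg <- schedule[i, ]
    times <- seg_times(seg$start, seg$end, dt_out)
    out <- run_lsoda(y, times, params, seg$on, rtol, atol)
    y <- c(out[nrow(out), 2], out[nrow(out), 3])
    pieces[[i]] <- data.frame(t = out[, 1],
                              S = clamp0(out[, 2], atol),
                              R = clamp0(out[, 3], atol),
                              treatment_on = seg$on)
  }
  traj <- do.call(rbind, pieces)
  rownames(traj) <- NULL
  structure(traj,
            params = params, schedule = schedule, atol = atol, rtol = rtol,
            class = c("tumor_trajectory", "data.frame"))
}

seg_times <- function(start, end, dt_out) {
  n <- max(2L, ceiling((end - start) / dt_out) + 1L)
  seq(start, end, length.out = n)
}

# Gated parameter vector for the compiled derivative functions.
gated_parms <- function(params, on) {
  if (inherits(params, "lv_params")) {
    c(if (on) 0 else params$rS, if (on) params$delta else 0,
      params$rR, params$K, params$C)
  } else {
    c(if (on) 0 else params$rS, if (on) params$delta else 0,
      if (on) params$alpha else 0, if (on) 0 else params$beta,
      params$rR, params$K)
  }
}

run_lsoda <- function(y, times, params, on, rtol, atol, maxsteps = 5000) {
  kind <- model_kind(params)
  out <- deSolve::lsoda(y = y, times = times,
                        func = paste0(kind, "_derivs"),
                        parms = gated_parms(params, on),
                        dllname = "adaptherapy",
                        initfunc = paste0(kind, "_init"),
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop(sprintf(
      "integration failed (istate = %d) on segment [%g, %g] for %s model",
      diag[1], times[1], times[length(times)], model_kind(params)))
  }
  unclass(out)
}

# Output-only clamp of floating-point undershoot; the solver state itself is
# never altered.
clamp0 <- function(x, atol) {
  x[x < 0 & abs(x) < 10 * atol] <- 0
  pmax(x, 0)
}

#' Evaluate a trajectory at arbitrary times
#'
#' Cubic-spline interpolation within each treatment segment (the solution is
#' smooth inside a segment but only continuous across mode switches).
#'
#' @param traj A `tumor_trajectory` from [simulate_model()] or
#'   [run_policy()].
#' @param t Times in months, within the trajectory span.
#' @return Data frame with columns `t`, `S`, `R`.
#' @export
trajectory_at <- function(traj, t) {
  check_finite(t, "t")
  span <- range(traj$t)
  if (any(t < span[1] - 1e-9 | t > span[2] + 1e-9)) {
    stop_invalid("requested times outside trajectory span [",
                 span[1], ", ", span[2], "]")
  }
  t <- pmin(pmax(t, span[1]), span[2])
  schedule <- attr(traj, "schedule")
  # assign each query time to a segment (boundary times go to the earlier one)
  idx <- pmin(findInterval(t, schedule$end + 1e-12) + 1L, nrow(schedule))
  S <- R <- numeric(length(t))
  for (i in seq_len(nrow(schedule))) {
    seg <- schedule[i, ]
    sel <- idx == i
    if (!any(sel)) next
    rows <- traj$t >= seg$start - 1e-12 & traj$t <= seg$end + 1e-12
    tt <- traj$t[rows]
    keep <- !duplicated(tt)
    S[sel] <- stats::spline(tt[keep], traj$S[rows][keep], xout = t[sel],
                            method = "natural")$y
    R[sel] <- stats::spline(tt[keep], traj$R[rows][keep], xout = t[sel],
                            method = "natural")$y
  }
  data.frame(t = t, S = pmax(S, 0), R = pmax(R, 0))
}

#' Export a trajectory as CSV
#'
#' Writes columns `t_months`, `S`, `R`, `ldh_model` (basal + S + R) and
#' `treatment_on` (0/1).
#'
#' @param traj A `tumor_trajectory`.
#' @param file Output path.
#' @param basal Basal (normal-tissue) LDH, U/L.
#' @export
write_trajectory_csv <- function(traj, file, basal = 100) {
  df <- data.frame(t_months = traj$t, S = traj$S, R = traj$R,
                   ldh_model = basal + traj$S + traj$R,
                   treatment_on = as.integer(traj$treatment_on))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<tumor trajectory: %s model, %d samples over [%g, %g] months>\n",
              model_kind(p), nrow(x), min(x$t), max(x$t)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
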