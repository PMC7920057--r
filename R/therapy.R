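#' Specify a dosing policy
#'
#' Three clinically motivated schedules are supported. `"continuous"` is
#' uninterrupted dosing (the standard-of-care comparator). `"adaptive"`
#' stops treatment when the monitored burden has fallen to `f_stop` times
#' its initial value, resumes when it regrows to `f_resume` times the
#' initial value (default: the initial value itself), and declares
#' progression at `f_prog` times the initial value. `"intermittent"`
#' alternates fixed `on_months` / `off_months` blocks.
#'
#' The monitored burden is total modeled LDH (basal + S + R) by default;
#' set `threshold_on = "tumor"` to gate on tumor-attributable burden
#' (S + R) instead.
#'
#' @param kind One of `"continuous"`, `"adaptive"`, `"intermittent"`.
#' @param f_stop Stop fraction (adaptive). The trial-style 50% rule is
#'   `f_stop = 0.5`; the milder 20%-reduction rule is `f_stop = 0.8`.
#' @param f_resume Resume fraction (adaptive), default 1.
#' @param f_prog Progression fraction, default 1.5.
#' @param on_months,off_months Cycle lengths (intermittent).
#' @param horizon Simulation horizon in months.
#' @param monitor_interval Optional check interval in months; when set,
#'   thresholds are evaluated only at blood-draw-like check times instead
#'   of by continuous event detection.
#' @param threshold_on `"total"` or `"tumor"`.
#' @return A `therapy_policy` object.
#' @export
therapy_policy <- function(kind = c("continuous", "adaptive", "intermittent"),
                           f_stop = 0.5, f_resume = 1.0, f_prog = 1.5,
                           on_months = NULL, off_months = NULL,
                           horizon = 60, monitor_interval = NULL,
                           threshold_on = c("total", "tumor")) {
  kind <- match.arg(kind)
  threshold_on <- match.arg(threshold_on)
  check_finite(c(f_stop, f_resume, f_prog, horizon), "policy fractions")
  if (horizon <= 0) stop_invalid("horizon must be > 0")
  if (kind == "adaptive") {
    if (!(0 < f_stop && f_stop < f_resume && f_resume <= f_prog)) {
      stop_invalid("need 0 < f_stop < f_resume <= f_prog")
    }
  }
  if (kind == "intermittent") {
    if (is.null(on_months) || is.null(off_months) ||
        on_months <= 0 || off_months <= 0) {
      stop_invalid("intermittent policy needs positive on_months and off_months")
    }
  }
  if (!is.null(monitor_interval) && monitor_interval <= 0) {
    stop_invalid("monitor_interval must be > 0")
  }
  structure(list(kind = kind, f_stop = f_stop, f_resume = f_resume,
                 f_prog = f_prog, on_months = on_months,
                 off_months = off_months, horizon = horizon,
                 monitor_interval = monitor_interval,
                 threshold_on = threshold_on),
            class = "therapy_policy")
}

# One treatment segment with threshold roots. Returns the solver output,
# the time and index of the root that terminated the segment (or NULL when
# the segment ran to t1).
segment_with_roots <- function(params, on, y0, t0, t1, thresholds,
                               basal_term, rtol, atol, dt_out) {
  f <- rhs_closure(params, on)
  times <- seg_times(t0, t1, dt_out)
  if (length(thresholds)) {
    root <- function(t, y, parms) basal_term + y[1] + y[2] - thresholds
    out <- deSolve::lsodar(y = y0, times = times, func = f, parms = NULL,
                           rtol = rtol, atol = atol, rootfunc = root)
  } else {
    out <- deSolve::lsoda(y = y0, times = times, func = f, parms = NULL,
                          rtol = rtol, atol = atol)
  }
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1] < 0 && diag[1] != 3) {
    stop(sprintf("integration failed (istate = %d) on [%g, %g], %s model, %s",
                 diag[1], t0, t1, model_kind(params),
                 if (on) "treatment on" else "treatment off"))
  }
  troot <- attr(out, "troot")
  iroot <- attr(out, "indroot")
  list(out = unclass(out),
       troot = if (length(troot)) troot[1] else NULL,
       iroot = if (length(iroot)) iroot[1] else NULL)
}

#' Simulate a dosing policy for one (virtual) patient
#'
#' Treatment starts on at t = 0. For adaptive policies, mode switches are
#' located by ODE root finding on the monitored burden, so stop/resume
#' events sit on their thresholds to solver precision. The run terminates
#' at the first progression crossing (monitored burden reaching
#' `f_prog` times its initial value) or at the horizon (censored).
#'
#' @param params An [lv_params()] or [sw_params()] object.
#' @param S0,R0 Initial burdens, U/L; their sum must be positive.
#' @param policy A [therapy_policy()].
#' @param basal Basal (normal-tissue) LDH, U/L.
#' @param rtol,atol,dt_out Solver controls as in [simulate_model()].
#' @param max_segments Safety cap on on/off segments.
#' @return A `therapy_sim` object: list with `trajectory`, `on_intervals`
#'   (data frame `start`/`end`), `events` (data frame `t`/`type`),
#'   `LDH0`, `ttp_months`, `censored`, `dose_rate`, plus the inputs.
#' @export
run_policy <- function(params, S0, R0, policy, basal = 100,
                       rtol = 1e-8, atol = NULL, dt_out = 0.02,
                       max_segments = 10000) {
  if (!inherits(policy, "therapy_policy")) stop_invalid("policy must be a therapy_policy")
  check_finite(c(S0, R0, basal), "initial state")
  if (S0 < 0 || R0 < 0 || S0 + R0 <= 0) {
    stop_invalid("need S0, R0 >= 0 and S0 + R0 > 0")
  }
  atol <- atol %||% (1e-10 * params$K)
  basal_term <- if (policy$threshold_on == "total") basal else 0
  v0 <- basal_term + S0 + R0
  ldh0 <- basal + S0 + R0
  horizon <- policy$horizon

  if (!is.null(policy$monitor_interval) && policy$kind == "adaptive") {
    return(run_adaptive_monitored(params, S0, R0, policy, basal, basal_term,
                                  v0, ldh0, rtol, atol, dt_out))
  }

  y <- c(S0, R0)
  t <- 0
  on <- TRUE
  intermittent_next <- policy$on_months
  pieces <- list()
  sched <- list()
  events <- list()
  ttp <- NA_real_
  n_seg <- 0L

  while (t < horizon - 1e-12) {
    n_seg <- n_seg + 1L
    if (n_seg > max_segments) {
      stop("policy simulation exceeded max_segments; dynamics may be degenerate")
    }
    t1 <- horizon
    thresholds <- policy$f_prog * v0
    thr_names <- "progression"
    if (policy$kind == "adaptive") {
      if (on) {
        thresholds <- c(policy$f_stop * v0, thresholds)
        thr_names <- c("stop", thr_names)
      } else {
        thresholds <- c(policy$f_resume * v0, thresholds)
        thr_names <- c("resume", thr_names)
      }
    } else if (policy$kind == "intermittent") {
      t1 <- min(horizon, t + intermittent_next)
    }
    seg <- segment_with_roots(params, on, y, t, t1, thresholds,
                              basal_term, rtol, atol, dt_out)
    out <- seg$out
    t_end <- out[nrow(out), 1]
    y <- c(out[nrow(out), 2], out[nrow(out), 3])
    pieces[[n_seg]] <- data.frame(t = out[, 1],
                                  S = clamp0(out[, 2], atol),
                                  R = clamp0(out[, 3], atol),
                                  treatment_on = on)
    sched[[n_seg]] <- data.frame(start = t, end = t_end, on = on)

    if (!is.null(seg$troot)) {
      v_end <- basal_term + sum(y)
      # identify which threshold fired (lsodar reports the index, but guard
      # against simultaneous roots by distance)
      which_thr <- if (!is.null(seg$iroot)) seg$iroot
                   else which.min(abs(thresholds - v_end))
      type <- thr_names[which_thr]
      events[[length(events) + 1]] <- data.frame(t = seg$troot, type = type)
      if (type == "progression") {
        ttp <- seg$troot
        t <- t_end
        break
      } else if (type == "stop") {
        on <- FALSE
      } else if (type == "resume") {
        on <- TRUE
      }
      t <- t_end
    } else {
      t <- t_end
      if (policy$kind == "intermittent" && t < horizon - 1e-12) {
        on <- !on
        intermittent_next <- if (on) policy$on_months else policy$off_months
        events[[length(events) + 1]] <-
          data.frame(t = t, type = if (on) "resume" else "stop")
      }
    }
  }

  finish_sim(pieces, sched, events, params, policy, S0, R0, basal,
             ldh0, ttp, horizon, rtol, atol)
}

# Discrete monitoring variant: thresholds are only evaluated at check times.
run_adaptive_monitored <- function(params, S0, R0, policy, basal, basal_term,
                                   v0, ldh0, rtol, atol, dt_out) {
  dt_m <- policy$monitor_interval
  horizon <- policy$horizon
  y <- c(S0, R0); t <- 0; on <- TRUE
  pieces <- list(); sched <- list(); events <- list()
  ttp <- NA_real_; i <- 0L
  while (t < horizon - 1e-12) {
    i <- i + 1L
    t1 <- min(t + dt_m, horizon)
    seg <- segment_with_roots(params, on, y, t, t1, numeric(0),
                              basal_term, rtol, atol, dt_out)
    out <- seg$out
    y <- c(out[nrow(out), 2], out[nrow(out), 3])
    pieces[[i]] <- data.frame(t = out[, 1], S = clamp0(out[, 2], atol),
                              R = clamp0(out[, 3], atol), treatment_on = on)
    sched[[i]] <- data.frame(start = t, end = t1, on = on)
    t <- t1
    v <- basal_term + sum(y)
    if (v >= policy$f_prog * v0) {
      events[[length(events) + 1]] <- data.frame(t = t, type = "progression")
      ttp <- t
      break
    }
    if (on && v <= policy$f_stop * v0) {
      on <- FALSE
      events[[length(events) + 1]] <- data.frame(t = t, type = "stop")
    } else if (!on && v >= policy$f_resume * v0) {
      on <- TRUE
      events[[length(events) + 1]] <- data.frame(t = t, type = "resume")
    }
  }
  finish_sim(pieces, sched, events, params, policy, S0, R0, basal,
             ldh0, ttp, horizon, rtol, atol)
}

finish_sim <- function(pieces, sched, events, params, policy, S0, R0, basal,
                       ldh0, ttp, horizon, rtol, atol) {
  traj <- do.call(rbind, pieces)
  rownames(traj) <- NULL
  schedule <- do.call(rbind, sched)
  traj <- structure(traj, params = params, schedule = schedule,
                    atol = atol, rtol = rtol,
                    class = c("tumor_trajectory", "data.frame"))
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(t = numeric(0), type = character(0))
  censored <- is.na(ttp)
  t_elapsed <- if (censored) horizon else ttp
  on_rows <- schedule[schedule$on & schedule$start < t_elapsed, , drop = FALSE]
  on_intervals <- data.frame(start = on_rows$start,
                             end = pmin(on_rows$end, t_elapsed))
  # merge contiguous on-intervals (monitored runs keep the mode across checks)
  if (nrow(on_intervals) > 1) {
    keep <- c(TRUE, on_intervals$start[-1] - on_intervals$end[-nrow(on_intervals)] > 1e-9)
    grp <- cumsum(keep)
    on_intervals <- data.frame(
      start = tapply(on_intervals$start, grp, min),
      end = tapply(on_intervals$end, grp, max), row.names = NULL)
  }
  dose_rate <- sum(on_intervals$end - on_intervals$start) / t_elapsed
  structure(list(trajectory = traj, on_intervals = on_intervals,
                 events = events, LDH0 = ldh0,
                 ttp_months = if (censored) horizon else ttp,
                 censored = censored, dose_rate = dose_rate,
                 policy = policy, params = params, S0 = S0, R0 = R0,
                 basal = basal),
            class = "therapy_sim")
}

#' @export
print.therapy_sim <- function(x, ...) {
  cat(sprintf("<therapy simulation: %s policy, %s model>\n",
              x$policy$kind, model_kind(x$params)))
  cat(sprintf("  initial LDH %.1f U/L; %s at %.3f months; dose rate %.1f%%\n",
              x$LDH0, if (x$censored) "censored" else "progression",
              x$ttp_months, 100 * x$dose_rate))
  invisible(x)
}

#' Time to progression of a simulated treatment course
#'
#' First time at which the monitored burden reaches `f_prog` times its
#' initial value, located by linear interpolation on the stored trajectory;
#' censored at the horizon when no crossing occurs.
#'
#' @param sim A `therapy_sim` (or any list with `trajectory`, `LDH0`,
#'   `basal` and `policy` fields).
#' @return Numeric months, with attribute `censored` (logical).
#' @export
time_to_progression <- function(sim) {
  pol <- sim$policy
  basal_term <- if ((pol$threshold_on %||% "total") == "total") sim$basal else 0
  tr <- sim$trajectory
  v <- basal_term + tr$S + tr$R
  v0 <- if ((pol$threshold_on %||% "total") == "total") sim$LDH0
        else sim$LDH0 - sim$basal
  thr <- pol$f_prog * v0
  idx <- which(v >= thr - 1e-9 * v0)
  if (!length(idx)) {
    return(structure(pol$horizon, censored = TRUE))
  }
  i <- idx[1]
  t_cross <- if (i == 1 || v[i] <= thr) tr$t[i] else {
    tr$t[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (tr$t[i] - tr$t[i - 1])
  }
  structure(t_cross, censored = FALSE)
}

#' Cumulative dose rate
#'
#' Fraction of the elapsed treatment course (time until progression or
#' censoring) spent on drug; continuous therapy scores exactly 1.
#'
#' @param sim A `therapy_sim`.
#' @return Fraction in `[0, 1]`.
#' @export
cumulative_dose_rate <- function(sim) {
  elapsed <- min(sim$ttp_months, sim$policy$horizon)
  if (!is.finite(elapsed) || elapsed <= 0) {
    stop_invalid("elapsed time must be positive")
  }
  sum(sim$on_intervals$end - sim$on_intervals$start) / elapsed
}

#' Time gained by adaptive over continuous therapy
#'
#' Difference in time to progression between two simulations of the same
#' virtual patient (identical model parameters and initial state). When
#' either arm is censored at the horizon the value is interval-censored;
#' the returned number then bounds the true gain and carries
#' `attr(, "censored") = TRUE`.
#'
#' @param adaptive,continuous `therapy_sim` objects for the two arms.
#' @return Numeric months with attribute `censored`.
#' @export
time_gained <- function(adaptive, continuous) {
  same <- isTRUE(all.equal(unlist(adaptive$params), unlist(continuous$params),
                           tolerance = 1e-12)) &&
    isTRUE(all.equal(c(adaptive$S0, adaptive$R0, adaptive$basal),
                     c(continuous$S0, continuous$R0, continuous$basal),
                     tolerance = 1e-12))
  if (!same) stop_invalid("arms were not simulated from the same patient state")
  gain <- adaptive$ttp_months - continuous$ttp_months
  structure(gain, censored = adaptive$censored || continuous$censored)
}
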