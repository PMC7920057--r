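#' Paired adaptive/continuous simulation of one virtual patient
#'
#' Runs the adaptive policy and its continuous comparator from the same
#' parameters and initial state, enforcing the paired-run discipline that
#' every time-gained value requires.
#'
#' @param row One row of a `virtual_cohort` data frame.
#' @param policy An adaptive (or intermittent) [therapy_policy()].
#' @param rs_mult,beta_mult Free-parameter assignment as multiples of the
#'   fitted `rR`; default to the row's stored values.
#' @param continuous_sim Optional precomputed continuous-arm result (the
#'   continuous arm does not depend on `rs_mult`/`beta_mult`, which only
#'   act off-treatment, so it can be shared across a sweep).
#' @return List with `gain`, `censored`, `dose_rate`, `ttp_adaptive`,
#'   `ttp_continuous`, and the two `therapy_sim` objects.
#' @export
paired_run <- function(row, policy, rs_mult = NULL, beta_mult = NULL,
                       continuous_sim = NULL) {
  params <- row_params(row, rs_mult, beta_mult)
  cont_pol <- therapy_policy("continuous", f_prog = policy$f_prog,
                             horizon = policy$horizon,
                             threshold_on = policy$threshold_on)
  cont <- continuous_sim %||%
    run_policy(params, row$S0, row$R0, cont_pol, basal = row$basal)
  adap <- run_policy(params, row$S0, row$R0, policy, basal = row$basal)
  # pairing guard: the cached continuous arm must match this patient state
  if (!isTRUE(all.equal(c(cont$S0, cont$R0, cont$basal),
                        c(row$S0, row$R0, row$basal), tolerance = 1e-12))) {
    stop_invalid("cached continuous arm does not match the virtual patient")
  }
  gain <- adap$ttp_months - cont$ttp_months
  list(gain = gain, censored = adap$censored || cont$censored,
       dose_rate = adap$dose_rate, ttp_adaptive = adap$ttp_months,
       ttp_continuous = cont$ttp_months, adaptive = adap, continuous = cont)
}

continuous_arm <- function(row, policy) {
  params <- row_params(row, rs_mult = 0,
                       beta_mult = if (row$model_kind == "sw") 0 else NULL)
  pol <- therapy_policy("continuous", f_prog = policy$f_prog,
                        horizon = policy$horizon,
                        threshold_on = policy$threshold_on)
  run_policy(params, row$S0, row$R0, pol, basal = row$basal)
}

#' Sweep the free parameters of a virtual cohort
#'
#' For every grid point (a multiple of the fitted `rR` for `rS`, and for
#' the switching model a multiple for `beta`) and every virtual patient,
#' runs paired adaptive/continuous simulations and aggregates mean time
#' gained and mean cumulative dose rate per grid cell. Pairs censored at
#' the horizon are excluded from cell means and counted separately.
#'
#' @param cohort A `virtual_cohort` data frame.
#' @param policy An adaptive [therapy_policy()].
#' @param rs_grid Multiples of `rR` for the sensitive growth rate
#'   (clinical sweep range 0.05-2).
#' @param beta_grid Multiples of `rR` for the re-sensitization rate
#'   (switching model; range 0.05-0.95). Ignored for LV cohorts.
#' @return A `time_gained_map` data frame: `rs_mult`, `beta_mult`,
#'   `mean_gain_months`, `mean_dose_rate`, `n`, `n_censored`.
#' @export
sweep_free_params <- function(cohort, policy = therapy_policy("adaptive"),
                              rs_grid = seq(0.05, 2, length.out = 20),
                              beta_grid = NULL) {
  if (!nrow(cohort)) stop_invalid("empty cohort")
  is_sw <- cohort$model_kind[1] == "sw"
  if (is_sw) {
    beta_grid <- beta_grid %||% seq(0.05, 0.95, length.out = 19)
  } else {
    beta_grid <- NA_real_
  }
  grid <- expand.grid(rs_mult = rs_grid, beta_mult = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cont <- lapply(seq_len(nrow(cohort)),
                 function(i) continuous_arm(cohort[i, ], policy))
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    gains <- doses <- numeric(0)
    n_cens <- 0L
    for (i in seq_len(nrow(cohort))) {
      pr <- paired_run(cohort[i, ], policy, rs_mult = grid$rs_mult[g],
                       beta_mult = if (is_sw) grid$beta_mult[g] else NULL,
                       continuous_sim = cont[[i]])
      if (pr$censored) {
        n_cens <- n_cens + 1L
      } else {
        gains <- c(gains, pr$gain)
        doses <- c(doses, pr$dose_rate)
      }
    }
    out[[g]] <- data.frame(
      rs_mult = grid$rs_mult[g], beta_mult = grid$beta_mult[g],
      mean_gain_months = if (length(gains)) mean(gains) else NA_real_,
      mean_dose_rate = if (length(doses)) mean(doses) else NA_real_,
      n = length(gains), n_censored = n_cens)
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  structure(map, class = c("time_gained_map", "data.frame"),
            policy = policy)
}

#' Per-fit time gained versus fitted tumor properties
#'
#' For an LV cohort, averages the time gained over a grid of sensitive
#' growth-rate multiples separately for every fitted parameter set and
#' returns it against the fit's initial sensitive proportion `S0/K` and
#' competition coefficient `C` (one point per virtual patient).
#'
#' @param cohort An LV `virtual_cohort`.
#' @param policy An adaptive [therapy_policy()].
#' @param rs_grid Multiples of `rR` averaged over.
#' @return Data frame: `patient`, `rank`, `s0_over_k`, `C`,
#'   `mean_gain_months`, `mean_dose_rate`, `n_censored`.
#' @export
scatter_by_fit_properties <- function(cohort,
                                      policy = therapy_policy("adaptive"),
                                      rs_grid = seq(0.05, 2, length.out = 20)) {
  if (!nrow(cohort)) stop_invalid("empty cohort")
  if (any(cohort$model_kind != "lv")) {
    stop_invalid("scatter_by_fit_properties expects an LV cohort")
  }
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    cont <- continuous_arm(row, policy)
    gains <- doses <- numeric(0)
    n_cens <- 0L
    for (m in rs_grid) {
      pr <- paired_run(row, policy, rs_mult = m, continuous_sim = cont)
      if (pr$censored) n_cens <- n_cens + 1L
      else { gains <- c(gains, pr$gain); doses <- c(doses, pr$dose_rate) }
    }
    out[[i]] <- data.frame(
      patient = row$patient, rank = row$rank,
      s0_over_k = row$S0 / row$K, C = row$C,
      mean_gain_months = if (length(gains)) mean(gains) else NA_real_,
      mean_dose_rate = if (length(doses)) mean(doses) else NA_real_,
      n_censored = n_cens)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare adaptive stopping thresholds on one cohort
#'
#' Re-runs the free-parameter sweep with identical virtual patients for a
#' list of stop fractions. `f_stop = 0.5` is the 50%-drop rule used in the
#' prostate adaptive-therapy trial; `f_stop = 0.8` stops after only a 20%
#' drop from baseline.
#'
#' @param cohort A `virtual_cohort`.
#' @param f_stop_list Stop fractions to compare (>= 2).
#' @param policy Template adaptive [therapy_policy()]; its `f_stop` is
#'   replaced per threshold.
#' @param rs_grid,beta_grid Passed to [sweep_free_params()].
#' @return Named list of `time_gained_map`s, one per threshold.
#' @export
compare_thresholds <- function(cohort, f_stop_list = c(0.5, 0.8),
                               policy = therapy_policy("adaptive"),
                               rs_grid = seq(0.05, 2, length.out = 20),
                               beta_grid = NULL) {
  if (length(f_stop_list) < 2) stop_invalid("need at least 2 thresholds")
  if (any(f_stop_list <= 0 | f_stop_list >= policy$f_prog)) {
    stop_invalid("thresholds must lie in (0, f_prog)")
  }
  maps <- lapply(f_stop_list, function(fs) {
    pol <- therapy_policy("adaptive", f_stop = fs,
                          f_resume = max(policy$f_resume, fs + 1e-9),
                          f_prog = policy$f_prog, horizon = policy$horizon,
                          threshold_on = policy$threshold_on)
    sweep_free_params(cohort, pol, rs_grid, beta_grid)
  })
  names(maps) <- sprintf("f_stop_%g", f_stop_list)
  maps
}

#' Rank correlation of progression time with fitted parameters
#'
#' Spearman rank correlation (midranks for ties) of time to progression
#' against each parameter column.
#'
#' @param fits Data frame of parameters, one row per fit (e.g. a
#'   `virtual_cohort` restricted to its parameter columns).
#' @param ttp Numeric progression times, one per row.
#' @return Named numeric of correlation coefficients; `NA` for constant
#'   columns.
#' @export
correlate_ttp_with_params <- function(fits, ttp) {
  fits <- as.data.frame(fits)
  num <- vapply(fits, is.numeric, logical(1))
  fits <- fits[, num, drop = FALSE]
  if (nrow(fits) != length(ttp)) stop_invalid("ttp length must match fits rows")
  if (length(ttp) < 3) stop_invalid("need at least 3 paired observations")
  vapply(fits, function(col) {
    if (stats::sd(col) == 0 || stats::sd(ttp) == 0) return(NA_real_)
    stats::cor(col, ttp, method = "spearman")
  }, numeric(1))
}

#' Progression-free survival records for an in-silico trial
#'
#' Simulates every virtual patient in the cohort under each named policy
#' arm and returns one survival record per patient and arm (progression
#' event or censoring at the horizon).
#'
#' @param cohort A `virtual_cohort` with assigned `rs_mult` (and
#'   `beta_mult` for SW rows).
#' @param arms Named list of [therapy_policy()] objects, e.g.
#'   `list(continuous = ..., adaptive_50 = ..., adaptive_20 = ...)`.
#' @return Data frame with columns `time` (months), `event` (1 =
#'   progression, 0 = censored), `arm`, `patient`, `rank`.
#' @export
survival_records <- function(cohort, arms) {
  if (is.null(names(arms)) || any(names(arms) == "")) {
    stop_invalid("arms must be a named list of policies")
  }
  rows <- list()
  for (arm in names(arms)) {
    pol <- arms[[arm]]
    for (i in seq_len(nrow(cohort))) {
      row <- cohort[i, ]
      sim <- run_policy(row_params(row), row$S0, row$R0, pol,
                        basal = row$basal)
      rows[[length(rows) + 1]] <- data.frame(
        time = sim$ttp_months, event = as.integer(!sim$censored),
        arm = arm, patient = row$patient, rank = row$rank)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier estimate of progression-free survival
#'
#' Product-limit estimator for one arm; right-censored records reduce the
#' risk set without producing a step.
#'
#' @param records Data frame with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @return Data frame with `time`, `n_risk`, `n_event`, `surv`, plus
#'   attribute `median` (median PFS, `NA` if never reached).
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) stop_invalid("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(out, median = med, class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard unstratified two-sample log-rank chi-square with one degree of
#' freedom.
#'
#' @param records Data frame with columns `time`, `event`, `arm` containing
#'   exactly two arms.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
logrank_test <- function(records) {
  arms <- unique(records$arm)
  if (length(arms) != 2) stop_invalid("need exactly two arms, got ",
                                      length(arms))
  if (any(!table(records$arm))) stop_invalid("both arms must be non-empty")
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = records)
  chisq <- sd$chisq
  list(statistic = unname(chisq),
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE), df = 1)
}
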