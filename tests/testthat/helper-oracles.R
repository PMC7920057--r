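# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own integration and survival code paths.

# Fixed-step classical RK4 reference integrator on the gated models.
rk4_reference <- function(params, S0, R0, treatment_on, t_end, dt = 1e-4) {
  f <- function(y) unname(adaptherapy::lv_rhs(y, params, treatment_on))
  if (inherits(params, "sw_params")) {
    f <- function(y) unname(adaptherapy::sw_rhs(y, params, treatment_on))
  }
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  y <- c(S0, R0)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

logistic_closed_form <- function(S0, r, K, t) {
  K / (1 + (K - S0) / S0 * exp(-r * t))
}

# Inverse of the logistic growth curve: time at which it reaches `target`.
logistic_crossing_time <- function(S0, r, K, target) {
  -log((K - target) * S0 / (target * (K - S0))) / r
}

# Hand product-limit tabulation (no survival package).
km_by_hand <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    tt <- ev_times[i]
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, surv = surv)
}

# Hand log-rank chi-square via the 2x2-per-event-time tabulation.
logrank_by_hand <- function(time, event, group) {
  groups <- sort(unique(group))
  stopifnot(length(groups) == 2)
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == groups[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == groups[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Spearman via explicit midranks.
spearman_by_hand <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small favorable-regime LV cohort used by several experiment tests:
# large initial sensitive fraction and strong competition, the conditions
# under which adaptive scheduling is expected to help.
favorable_lv_archetype <- function() {
  patient_archetype("slow_progressor", model_kind = "lv",
                    ttp_window = c(2, 20),
                    s_frac_range = c(0.85, 0.99),
                    K_mult_range = c(1.5, 2.2),
                    C_range = c(1.4, 1.6))
}

make_truth_cohort <- function(n, archetype, seed) {
  seeds <- adaptherapy:::derive_seeds(seed, n)
  truths <- lapply(seq_len(n), function(i) {
    gt <- sample_ground_truth(archetype, seed = seeds[i])
    gt$patient_id <- sprintf("VP%d", i)
    gt
  })
  cohort_from_ground_truths(truths)
}
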