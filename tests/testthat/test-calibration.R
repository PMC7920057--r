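# static tumor: all rates zero, so modeled LDH is constant at its baseline
static_theta <- function() {
  c(S0 = 100, K = 5000, delta = 0, rR = 0, C = 1)
}

static_series <- function(residuals) {
  n <- length(residuals)
  patient_series("S", seq(0, by = 1, length.out = n), 400 + residuals)
}

test_that("modeled LDH is basal plus total burden", {
  p <- lv_params(rS = 0, rR = 0, K = 5000, delta = 0, C = 1)
  tr <- simulate_model(p, 200, 100, t_end = 2, treatment_on = TRUE)
  expect_equal(ldh_model(tr, basal = 100, times = 1.3), 400)
  tr0 <- simulate_model(p, 0, 0, t_end = 2, treatment_on = TRUE)
  expect_equal(ldh_model(tr0, basal = 100, times = 0.5), 100)
  expect_error(ldh_model(tr, 100, times = 5), "span")
})

test_that("objective is the Euclidean norm of the LDH residuals", {
  # residual vector (0, 3, 4, 0): norm 5
  s <- static_series(c(0, 3, 4, 0))
  expect_equal(fit_objective(static_theta(), s, "lv"), 5)
  # perfect predictions
  s0 <- static_series(c(0, 0, 0, 0))
  expect_lt(fit_objective(static_theta(), s0, "lv"), 1e-8)
})

test_that("objective at the generating truth of a noiseless series is ~0", {
  arch <- patient_archetype("slow_progressor")
  gt <- sample_ground_truth(arch, seed = 5)
  s <- generate_patient_series(gt, noise_cv = 0, seed = 6)
  theta <- c(S0 = gt$S0, K = gt$params$K, delta = gt$params$delta,
             rR = gt$params$rR, C = gt$params$C)
  expect_lt(fit_objective(theta, s, "lv"), 1e-6 * sqrt(sum(s$ldh^2)))
  # and the generator's noiseless curve round-trips through ldh_model
  tr <- simulate_model(gt$params, gt$S0, gt$R0,
                       t_end = max(s$times) + 1e-6, treatment_on = TRUE)
  expect_equal(ldh_model(tr, gt$basal, s$times),
               attr(s, "ldh_noiseless"), tolerance = 1e-8)
})

test_that("implicit filtering solves standard bound-constrained problems", {
  q <- implicit_filtering(function(x) (x - 2)^2, 0, 5, start = 4.5,
                          budget = 200)
  expect_lt(abs(q$par - 2), 1e-4)

  rb <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  out <- implicit_filtering(rb, c(-2, -2), c(2, 2), c(-1.2, 1),
                            budget = 5000)
  expect_lt(out$value, 1e-3)

  expect_true(all(diff(out$best_trace) <= 0))
  expect_error(implicit_filtering(function(x) x, 1, 0, 0.5), "bounds")
  expect_error(implicit_filtering(function(x) x, 0, 1, 2), "within")
})

test_that("the therapy death rate is identifiable from decay data alone", {
  delta_true <- 0.9
  p <- lv_params(rS = 0, rR = 0, K = 5000, delta = delta_true, C = 1)
  times <- seq(0, 3, by = 0.25)
  s <- patient_series("D", times, 100 + 400 * exp(-delta_true * times) + 1e-9)
  obj <- function(d) {
    fit_objective(c(S0 = 400 - 1e-9, K = 5000, delta = d, rR = 0, C = 1),
                  s, "lv")
  }
  out <- implicit_filtering(obj, 0.01, 5, start = 2, budget = 300)
  expect_lt(abs(out$par - delta_true) / delta_true, 1e-3)
})

test_that("multistart fits are ranked, reproducible and honor fixed masks", {
  arch <- patient_archetype("slow_progressor")
  gt <- sample_ground_truth(arch, seed = 15)
  s <- generate_patient_series(gt, noise_cv = 0.05, seed = 16)

  f1 <- suppressMessages(
    multistart_fit(s, "lv", n_starts = 3, budget = 300, seed = 9,
                   polish = 1))
  objs <- vapply(f1, `[[`, numeric(1), "objective")
  expect_true(all(diff(objs) >= 0))

  f2 <- suppressMessages(
    multistart_fit(s, "lv", n_starts = 3, budget = 300, seed = 9,
                   polish = 1))
  expect_identical(lapply(f1, `[[`, "theta"), lapply(f2, `[[`, "theta"))
  expect_identical(objs, vapply(f2, `[[`, numeric(1), "objective"))

  fixed <- c(S0 = gt$S0, K = gt$params$K, C = gt$params$C)
  f3 <- suppressMessages(
    multistart_fit(s, "lv", n_starts = 2, budget = 300, seed = 9,
                   fixed = fixed, polish = 1))
  for (f in f3) {
    expect_equal(f$theta[names(fixed)], fixed)
    expect_equal(unname(f$fixed_mask[c("S0", "K", "C")]), rep(TRUE, 3))
    expect_equal(unname(f$fixed_mask[c("delta", "rR")]), rep(FALSE, 2))
  }
  expect_error(multistart_fit(s, "lv", fixed = c(bogus = 1)), "fixed")
})

test_that("virtual cohort takes top-k per patient and deduplicates optima", {
  fake_fit <- function(obj, theta_shift = 0, idx = 1) {
    list(model_kind = "lv",
         theta = c(S0 = 100 + theta_shift, K = 2000, delta = 1, rR = 0.3,
                   C = 1.2),
         fixed_mask = setNames(rep(FALSE, 5), c("S0", "K", "delta", "rR", "C")),
         objective = obj, R0 = 50, start_index = idx, seed = 1, basal = 100,
         patient_id = "X")
  }
  fits <- list(
    A = list(fake_fit(1, 0, 1), fake_fit(2, 5, 2), fake_fit(3, 9, 3)),
    B = list(fake_fit(1.5, 0, 1), fake_fit(2.5, 4, 2), fake_fit(9, 8, 3))
  )
  co <- build_virtual_cohort(fits, top_k = 2)
  expect_equal(nrow(co), 4)
  expect_equal(co$rank, c(1L, 2L, 1L, 2L))

  # 8 patients x top 50 distinct fits: the full-size cohort bookkeeping
  big <- setNames(lapply(1:8, function(p) {
    lapply(1:60, function(k) fake_fit(k, k, k))
  }), paste0("P", 1:8))
  expect_equal(nrow(build_virtual_cohort(big, top_k = 50)), 400)
  expect_equal(nrow(build_virtual_cohort(big, top_k = 1)), 8)

  # exact duplicates are dropped (with a note) and may starve top_k
  dup <- list(A = list(fake_fit(1, 0, 1), fake_fit(1, 0, 2),
                       fake_fit(2, 3, 3)))
  expect_message(co2 <- build_virtual_cohort(dup, top_k = 2), "duplicate")
  expect_equal(nrow(co2), 2)
  expect_error(suppressMessages(build_virtual_cohort(dup, top_k = 3)), "A")
})

test_that("parameter perturbation is seeded and detects local optimality", {
  arch <- patient_archetype("slow_progressor")
  gt <- sample_ground_truth(arch, seed = 25)
  s <- generate_patient_series(gt, noise_cv = 0, seed = 26)
  fit <- list(model_kind = "lv",
              theta = c(S0 = gt$S0, K = gt$params$K, delta = gt$params$delta,
                        rR = gt$params$rR, C = gt$params$C),
              basal = gt$basal, patient_id = s$patient_id)
  base_obj <- fit_objective(fit$theta, s, "lv")

  p0 <- perturb_and_predict(fit, s, fraction = 0, n = 5, seed = 3)
  expect_equal(p0$objective, rep(base_obj, 5))

  pa <- perturb_and_predict(fit, s, fraction = 0.1, n = 20, seed = 3)
  pb <- perturb_and_predict(fit, s, fraction = 0.1, n = 20, seed = 3)
  expect_identical(pa, pb)
  expect_gt(median(pa$objective), base_obj)
})

test_that("objective at truth undercuts >= 20% parameter perturbations", {
  arch <- patient_archetype("slow_progressor")
  gt <- sample_ground_truth(arch, seed = 33)
  s <- generate_patient_series(gt, noise_cv = 0, seed = 34)
  theta <- c(S0 = gt$S0, K = gt$params$K, delta = gt$params$delta,
             rR = gt$params$rR, C = gt$params$C)
  f0 <- fit_objective(theta, s, "lv")
  set.seed(44)
  for (k in 1:10) {
    signs <- sample(c(-1, 1), 5, replace = TRUE)
    th <- theta * (1 + 0.2 * signs)
    expect_gt(fit_objective(th, s, "lv"), f0)
  }
})

test_that("fit quality pools predictions and matches hand arithmetic", {
  # static fits give constant predictions = baseline LDH
  fitA <- list(model_kind = "lv", theta = static_theta(), basal = 100,
               patient_id = "S")
  s <- static_series(c(0, 6, -6, 0))      # observed 400, 406, 394, 400
  q <- fit_quality(list(fitA), list(S = s))
  # hand: predictions all 400; SS_res = 72, SS_tot = 72 => R2 = 0
  expect_equal(q$r_squared, 0, tolerance = 1e-12)

  # perfect predictions on varying data: truth fit of a noiseless series
  arch <- patient_archetype("slow_progressor")
  gt <- sample_ground_truth(arch, seed = 55)
  sv <- generate_patient_series(gt, noise_cv = 0, seed = 56)
  fitT <- list(model_kind = "lv",
               theta = c(S0 = gt$S0, K = gt$params$K, delta = gt$params$delta,
                         rR = gt$params$rR, C = gt$params$C),
               basal = gt$basal, patient_id = sv$patient_id)
  q2 <- fit_quality(list(fitT), setNames(list(sv), sv$patient_id))
  expect_equal(q2$r_squared, 1, tolerance = 1e-6)

  # pooled hand example: the static model predicts its own baseline, which
  # is tied to the first observation (R0 = LDH0 - basal - S0), here 401
  s3 <- static_series(c(1, -1, 2, -2))
  q3 <- fit_quality(list(fitA, fitA), list(S = s3))
  obs <- rep(400 + c(1, -1, 2, -2), 2)
  r2_hand <- 1 - sum((obs - 401)^2) / sum((obs - mean(obs))^2)
  expect_equal(q3$r_squared, r2_hand, tolerance = 1e-12)
  expect_named(q3$param_iqr, c("S0", "K", "delta", "rR", "C"))

  # degenerate variance: constant observations give the undefined marker
  s4 <- static_series(c(0, 0, 0, 0))
  q4 <- fit_quality(list(fitA), list(S = s4))
  expect_true(is.na(q4$r_squared))

  expect_error(fit_quality(list(fitA), list(Z = s)), "patient")
})

test_that("default bounds adapt to the series and contain truth-scale values", {
  s <- static_series(c(0, 30, 60, 100))
  b <- default_fit_bounds(s, "lv")
  expect_lt(b$upper["S0"], 400 - 100 + 1e-9)
  expect_equal(unname(b$lower["K"]), 500)
  expect_equal(unname(b$upper["K"]), 10000)
  bsw <- default_fit_bounds(s, "sw")
  expect_true("alpha" %in% names(bsw$lower))
})
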