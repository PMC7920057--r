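test_that("LV right-hand side matches direct substitution and gating", {
  # carrying-capacity equilibrium off treatment
  p_eq <- lv_params(rS = 1, rR = 1, K = 100, delta = 0, C = 1)
  expect_equal(unname(lv_rhs(c(S = 50, R = 50), p_eq, FALSE)), c(0, 0))

  # on-treatment: rS forced to zero, only death acts on S
  p_on <- lv_params(rS = 3, rR = 2, K = 100, delta = 0.5, C = 1)
  expect_equal(unname(lv_rhs(c(S = 10, R = 0), p_on, TRUE)), c(-5, 0))

  # asymmetric competition: C scales only S's effect on R
  p <- lv_params(rS = 1, rR = 0.5, K = 100, delta = 0, C = 1.4)
  expect_equal(unname(lv_rhs(c(S = 40, R = 10), p, FALSE)), c(20, 1.7))

  expect_error(lv_rhs(c(S = NaN, R = 1), p, FALSE), "finite")
  expect_error(lv_rhs(c(S = -1, R = 1), p, FALSE), "non-negative")
  expect_error(lv_params(rS = 1, rR = 1, K = -5, delta = 0, C = 1), "K")
})

test_that("SW right-hand side matches direct substitution and gating", {
  p_off <- sw_params(rS = 1, rR = 1, K = 100, delta = 0, alpha = 0,
                     beta = 0.45)
  expect_equal(unname(sw_rhs(c(S = 20, R = 30), p_off, FALSE)), c(23.5, 1.5))

  p_on <- sw_params(rS = 1, rR = 1, K = 100, delta = 0.2, alpha = 0.1,
                    beta = 0.45)
  expect_equal(unname(sw_rhs(c(S = 50, R = 10), p_on, TRUE)), c(-15, 9))

  # extinction fixed point under any gating
  expect_equal(unname(sw_rhs(c(S = 0, R = 0), p_on, TRUE)), c(0, 0))
  expect_equal(unname(sw_rhs(c(S = 0, R = 0), p_off, FALSE)), c(0, 0))
})

test_that("integrator reproduces closed-form solutions to 1e-6 relative", {
  # on-treatment LV: pure exponential decay of S
  p <- lv_params(rS = 1, rR = 1, K = 1e6, delta = 0.5, C = 1)
  tr <- simulate_model(p, S0 = 100, R0 = 0, t_end = 2, treatment_on = TRUE)
  expect_equal(trajectory_at(tr, 2)$S, 100 * exp(-1), tolerance = 1e-6)

  # off-treatment single-population logistic growth
  p2 <- lv_params(rS = 1, rR = 1, K = 100, delta = 0, C = 1)
  tr2 <- simulate_model(p2, S0 = 10, R0 = 0, t_end = log(9),
                        treatment_on = FALSE)
  expect_equal(trajectory_at(tr2, log(9))$S, 50, tolerance = 1e-6)
  ts <- c(0.3, 1.1, 1.9)
  expect_equal(trajectory_at(tr2, ts)$S,
               logistic_closed_form(10, 1, 100, ts), tolerance = 1e-6)

  # on-treatment SW: decay at delta + alpha
  p3 <- sw_params(rS = 1, rR = 0, K = 1e6, delta = 0.2, alpha = 0.1,
                  beta = 0)
  tr3 <- simulate_model(p3, S0 = 80, R0 = 0, t_end = 5, treatment_on = TRUE)
  expect_equal(trajectory_at(tr3, 5)$S, 80 * exp(-1.5), tolerance = 1e-6)
})

test_that("multi-segment schedules hand state across boundaries continuously", {
  p <- lv_params(rS = 0.4, rR = 0.3, K = 2000, delta = 1, C = 1.3)
  sched <- data.frame(start = c(0, 2, 5), end = c(2, 5, 8),
                      on = c(TRUE, FALSE, TRUE))
  tr <- simulate_model(p, S0 = 600, R0 = 50, schedule = sched)
  # duplicated boundary rows agree (state continuity)
  for (tb in c(2, 5)) {
    rows <- which(abs(tr$t - tb) < 1e-12)
    expect_length(rows, 2)
    expect_equal(tr$S[rows[1]], tr$S[rows[2]], tolerance = 1e-10)
    expect_equal(tr$R[rows[1]], tr$R[rows[2]], tolerance = 1e-10)
  }
  expect_error(simulate_model(p, 1, 1, schedule = data.frame(
    start = c(0, 3), end = c(2, 5), on = c(TRUE, FALSE))), "partition")
})

test_that("adaptive integration agrees with a fixed-step RK4 reference", {
  set.seed(11)
  for (i in 1:10) {
    lv <- i <= 5
    K <- runif(1, 500, 3000)
    params <- if (lv) {
      lv_params(rS = runif(1, 0.1, 1), rR = runif(1, 0.1, 1), K = K,
                delta = runif(1, 0.3, 2), C = runif(1, 1, 1.6))
    } else {
      sw_params(rS = runif(1, 0.1, 1), rR = runif(1, 0.1, 1), K = K,
                delta = runif(1, 0.3, 2), alpha = runif(1, 0.01, 0.4),
                beta = runif(1, 0.05, 0.9))
    }
    on <- i %% 2 == 0
    S0 <- runif(1, 0.05, 0.5) * K
    R0 <- runif(1, 0.01, 0.2) * K
    t_end <- 2
    ref <- rk4_reference(params, S0, R0, on, t_end, dt = 1e-4)
    tr <- simulate_model(params, S0, R0, t_end = t_end, treatment_on = on)
    got <- trajectory_at(tr, t_end)
    expect_lt(max(abs(c(got$S, got$R) - ref) / pmax(abs(ref), 1e-8)), 1e-5)
  }
})

test_that("trajectories stay non-negative and bounded by carrying capacity", {
  set.seed(21)
  for (i in 1:8) {
    K <- runif(1, 500, 2000)
    tot0 <- runif(1, 0.3, 1) * K
    frac <- runif(1, 0.05, 0.95)
    params <- if (i %% 2) {
      lv_params(rS = runif(1, 0.1, 1.2), rR = runif(1, 0.1, 1.2), K = K,
                delta = runif(1, 0.5, 3), C = runif(1, 1, 1.6))
    } else {
      sw_params(rS = runif(1, 0.1, 1.2), rR = runif(1, 0.1, 1.2), K = K,
                delta = runif(1, 0.5, 3), alpha = runif(1, 0.05, 0.5),
                beta = runif(1, 0.05, 0.9))
    }
    sched <- data.frame(start = c(0, 3), end = c(3, 8), on = c(TRUE, FALSE))
    tr <- simulate_model(params, frac * tot0, (1 - frac) * tot0,
                         schedule = sched)
    expect_true(all(tr$S >= 0) && all(tr$R >= 0))
    expect_true(all(tr$S + tr$R <= K * (1 + 1e-6)))
  }
})

test_that("halving solver tolerances leaves reported values unchanged to 1e-6", {
  p <- lv_params(rS = 0.5, rR = 0.4, K = 1500, delta = 1.2, C = 1.4)
  tr1 <- simulate_model(p, 400, 60, t_end = 10, treatment_on = TRUE)
  tr2 <- simulate_model(p, 400, 60, t_end = 10, treatment_on = TRUE,
                        rtol = 5e-9, atol = 0.5e-10 * p$K)
  sc <- pmax(abs(tr1$S + tr1$R), 1)
  expect_lt(max(abs(tr1$S - tr2$S) / sc + abs(tr1$R - tr2$R) / sc), 1e-6)
})

test_that("nondimensionalization follows its definition and round-trips", {
  p <- lv_params(rS = 1, rR = 2, K = 100, delta = 0, C = 1)
  sc <- nondimensionalize(p, c(S = 50, R = 5, t = 3))
  expect_equal(unname(sc), c(0.5, 0.05, 6))

  p1 <- lv_params(rS = 1, rR = 1, K = 1, delta = 0, C = 1)
  st <- c(S = 0.3, R = 0.4, t = 1.7)
  expect_equal(unname(nondimensionalize(p1, st)), unname(st))

  back <- dimensionalize(p, nondimensionalize(p, c(S = 50, R = 5, t = 3)))
  expect_equal(unname(back), c(50, 5, 3))
  expect_error(nondimensionalize(lv_params(1, 0, 10, 0, 1), c(S = 1, R = 1)),
               "rR")
})

test_that("scaled and unscaled simulations of the same system agree", {
  p <- lv_params(rS = 0.6, rR = 0.8, K = 1200, delta = 1.1, C = 1.3)
  S0 <- 300; R0 <- 40; t_end <- 6
  tr <- simulate_model(p, S0, R0, t_end = t_end, treatment_on = FALSE)
  # dimensionless twin: rates divided by rR, burdens by K, time is tau
  p_sc <- lv_params(rS = p$rS / p$rR, rR = 1, K = 1, delta = p$delta / p$rR,
                    C = p$C)
  tr_sc <- simulate_model(p_sc, S0 / p$K, R0 / p$K, t_end = p$rR * t_end,
                          treatment_on = FALSE)
  ts <- seq(0.5, t_end, by = 0.5)
  a <- trajectory_at(tr, ts)
  b <- trajectory_at(tr_sc, p$rR * ts)
  expect_lt(max(abs(a$S / p$K - b$S), abs(a$R / p$K - b$R)), 1e-8)
})

test_that("nullclines annihilate the corresponding derivative", {
  check_desc <- function(desc, params) {
    pts <- nullcline_points(desc, n = 20, s_max = 1)
    for (k in seq_len(nrow(pts))) {
      state <- c(S = pts[k, 1] * params$K, R = pts[k, 2] * params$K)
      d <- model_rhs(state, params, desc$treatment_on)
      dd <- if (desc$population == "S") d[["dS"]] else d[["dR"]]
      expect_lt(abs(dd) / (params$rR * params$K), 1e-9)
    }
  }
  p_lv <- lv_params(rS = 0.7, rR = 0.5, K = 900, delta = 1.2, C = 1.4)
  for (on in c(TRUE, FALSE)) {
    for (desc in nullclines(p_lv, on)) check_desc(desc, p_lv)
  }
  p_sw <- sw_params(rS = 0.7, rR = 0.5, K = 900, delta = 1.2, alpha = 0.2,
                    beta = 0.3)
  for (on in c(TRUE, FALSE)) {
    for (desc in nullclines(p_sw, on)) check_desc(desc, p_sw)
  }
})

test_that("LV nullcline geometry: intercepts and the C = 1 degeneracy", {
  p <- lv_params(rS = 1, rR = 1, K = 100, delta = 0, C = 1.4)
  nc <- nullclines(p, treatment_on = FALSE)
  rline <- Filter(function(d) d$population == "R" && d$coef["a"] != 0, nc)[[1]]
  # S_bar-intercept 1/C, R_bar-intercept 1
  expect_equal(unname(rline$coef["c"] / rline$coef["a"]), 1 / 1.4)
  expect_equal(unname(rline$coef["c"] / rline$coef["b"]), 1)

  p1 <- lv_params(rS = 1, rR = 1, K = 100, delta = 0, C = 1)
  nc1 <- nullclines(p1, treatment_on = FALSE)
  rline1 <- Filter(function(d) d$population == "R" && d$coef["a"] != 0, nc1)[[1]]
  sline1 <- Filter(function(d) d$population == "S" && d$coef["b"] != 0, nc1)[[1]]
  expect_equal(rline1$coef, sline1$coef)
})

test_that("trajectory CSV export carries modeled LDH and the treatment flag", {
  p <- lv_params(rS = 0.5, rR = 0.5, K = 800, delta = 1, C = 1.2)
  tr <- simulate_model(p, 200, 30, t_end = 3, treatment_on = TRUE)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f, basal = 100)
  df <- read.csv(f)
  expect_named(df, c("t_months", "S", "R", "ldh_model", "treatment_on"))
  expect_equal(df$ldh_model, 100 + df$S + df$R)
  expect_true(all(df$treatment_on == 1))
  unlink(f)
})
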