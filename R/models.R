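#' Lotka-Volterra competition model parameters
#'
#' Parameterizes the two-population competition model of drug-sensitive (S)
#' and drug-resistant (R) tumor cells sharing one carrying capacity:
#' \deqn{dS/dt = r_S (1 - (S+R)/K) S - \delta S}
#' \deqn{dR/dt = r_R (1 - (C S + R)/K) R}
#' Treatment gates the sensitive-cell terms: on-treatment the intrinsic
#' growth rate of S is set to zero and the therapy death rate \eqn{\delta}
#' acts; off-treatment S grows at `rS` and \eqn{\delta} is zero. Resistant
#' cells are unaffected by the drug. The competition coefficient `C` scales
#' the inhibitory effect of sensitive cells on resistant-cell growth only
#' (C > 1: S suppresses R more strongly than R suppresses itself).
#'
#' @param rS Intrinsic growth rate of sensitive cells, per month
#'   (off-treatment value).
#' @param rR Intrinsic growth rate of resistant cells, per month.
#' @param K Shared carrying capacity, in LDH-equivalent U/L.
#' @param delta Therapy-induced death rate of sensitive cells, per month.
#' @param C Dimensionless competition coefficient (effect of S on R).
#' @return An object of class `c("lv_params", "model_params")`.
#' @seealso [sw_params()], [lv_rhs()], [simulate_model()]
#' @export
#' @examples
#' p <- lv_params(rS = 0.3, rR = 0.3, K = 2000, delta = 1.2, C = 1.4)
#' lv_rhs(c(S = 400, R = 50), p, treatment_on = TRUE)
lv_params <- function(rS, rR, K, delta, C) {
  check_finite(c(rS, rR, K, delta, C), "LV parameters")
  if (any(c(rS, rR, delta) < 0)) stop_invalid("rates must be >= 0")
  if (K <= 0) stop_invalid("K must be > 0")
  if (C <= 0) stop_invalid("C must be > 0")
  structure(list(rS = rS, rR = rR, K = K, delta = delta, C = C),
            class = c("lv_params", "model_params"))
}

#' Phenotypic-switching model parameters
#'
#' Parameterizes the switching variant, in which cells transition between
#' sensitive and resistant states depending on treatment:
#' \deqn{dS/dt = r_S (1 - (S+R)/K) S - \delta S - \alpha S + \beta R}
#' \deqn{dR/dt = r_R (1 - (S+R)/K) R + \alpha S - \beta R}
#' The S-to-R switching rate \eqn{\alpha} is active only while treatment is
#' on; the R-to-S (re-sensitization) rate \eqn{\beta} only while it is off.
#' As in the LV model, on-treatment `rS` is gated to zero and the death rate
#' `delta` acts on S. Competition is unscaled (both populations inhibit each
#' other equally).
#'
#' @inheritParams lv_params
#' @param alpha S-to-R switching rate, per month (on-treatment only).
#' @param beta R-to-S switching rate, per month (off-treatment only).
#' @return An object of class `c("sw_params", "model_params")`.
#' @export
sw_params <- function(rS, rR, K, delta, alpha, beta) {
  check_finite(c(rS, rR, K, delta, alpha, beta), "SW parameters")
  if (any(c(rS, rR, delta, alpha, beta) < 0)) stop_invalid("rates must be >= 0")
  if (K <= 0) stop_invalid("K must be > 0")
  structure(list(rS = rS, rR = rR, K = K, delta = delta,
                 alpha = alpha, beta = beta),
            class = c("sw_params", "model_params"))
}

#' @export
print.model_params <- function(x, ...) {
  kind <- if (inherits(x, "lv_params")) "Lotka-Volterra competition"
          else "phenotypic switching"
  cat(sprintf("<%s model parameters>\n", kind))
  vals <- unlist(x)
  cat(paste0("  ", names(vals), " = ", signif(vals, 6), collapse = "\n"), "\n")
  invisible(x)
}

model_kind <- function(params) {
  if (inherits(params, "lv_params")) "lv"
  else if (inherits(params, "sw_params")) "sw"
  else stop_invalid("params must be lv_params or sw_params")
}

as_state <- function(state) {
  check_finite(state, "state")
  s <- if (!is.null(names(state)) && all(c("S", "R") %in% names(state))) {
    c(state[["S"]], state[["R"]])
  } else {
    if (length(state) < 2) stop_invalid("state must contain S and R")
    as.numeric(state[1:2])
  }
  if (any(s < 0)) stop_invalid("populations must be non-negative")
  s
}

#' Right-hand side of the Lotka-Volterra competition model
#'
#' Evaluates the instantaneous growth rates of sensitive and resistant
#' populations under the treatment-gated parameterization: on-treatment the
#' effective (rS, delta) pair is (0, delta); off-treatment it is (rS, 0).
#'
#' @param state Numeric state, either `c(S = , R = )` or a length-2 vector
#'   (S first), in LDH-equivalent U/L.
#' @param params An [lv_params()] object.
#' @param treatment_on Logical flag: is the drug being given?
#' @return Named numeric `c(dS = , dR = )` in U/L per month.
#' @export
lv_rhs <- function(state, params, treatment_on) {
  if (!inherits(params, "lv_params")) stop_invalid("params must be lv_params")
  s <- as_state(state)
  S <- s[1]; R <- s[2]
  rS_eff <- if (treatment_on) 0 else params$rS
  delta_eff <- if (treatment_on) params$delta else 0
  c(dS = rS_eff * (1 - (S + R) / params$K) * S - delta_eff * S,
    dR = params$rR * (1 - (params$C * S + R) / params$K) * R)
}

#' Right-hand side of the phenotypic-switching model
#'
#' On-treatment the effective (rS, delta, alpha, beta) is
#' (0, delta, alpha, 0); off-treatment it is (rS, 0, 0, beta).
#'
#' @inheritParams lv_rhs
#' @param params An [sw_params()] object.
#' @return Named numeric `c(dS = , dR = )` in U/L per month.
#' @export
sw_rhs <- function(state, params, treatment_on) {
  if (!inherits(params, "sw_params")) stop_invalid("params must be sw_params")
  s <- as_state(state)
  S <- s[1]; R <- s[2]
  if (treatment_on) {
    rS_eff <- 0; delta_eff <- params$delta
    alpha_eff <- params$alpha; beta_eff <- 0
  } else {
    rS_eff <- params$rS; delta_eff <- 0
    alpha_eff <- 0; beta_eff <- params$beta
  }
  crowd <- 1 - (S + R) / params$K
  c(dS = rS_eff * crowd * S - delta_eff * S - alpha_eff * S + beta_eff * R,
    dR = params$rR * crowd * R + alpha_eff * S - beta_eff * R)
}

model_rhs <- function(state, params, treatment_on) {
  if (inherits(params, "lv_params")) lv_rhs(state, params, treatment_on)
  else sw_rhs(state, params, treatment_on)
}

# deSolve-compatible derivative closure for a fixed treatment mode.
# The gated rates are resolved once per segment, so each segment is a smooth
# ODE and mode switches happen only at segment boundaries.
rhs_closure <- function(params, treatment_on) {
  if (inherits(params, "lv_params")) {
    rS_eff <- if (treatment_on) 0 else params$rS
    delta_eff <- if (treatment_on) params$delta else 0
    rR <- params$rR; K <- params$K; C <- params$C
    function(t, y, parms) {
      S <- y[1]; R <- y[2]
      list(c(rS_eff * (1 - (S + R) / K) * S - delta_eff * S,
             rR * (1 - (C * S + R) / K) * R))
    }
  } else {
    if (treatment_on) {
      rS_eff <- 0; delta_eff <- params$delta
      alpha_eff <- params$alpha; beta_eff <- 0
    } else {
      rS_eff <- params$rS; delta_eff <- 0
      alpha_eff <- 0; beta_eff <- params$beta
    }
    rR <- params$rR; K <- params$K
    function(t, y, parms) {
      S <- y[1]; R <- y[2]
      crowd <- 1 - (S + R) / K
      list(c(rS_eff * crowd * S - delta_eff * S - alpha_eff * S + beta_eff * R,
             rR * crowd * R + alpha_eff * S - beta_eff * R))
    }
  }
}

#' Non-dimensionalize a population state
#'
#' Maps (S, R, t) to the dimensionless coordinates used for phase-plane
#' analysis: `S_bar = S/K`, `R_bar = R/K`, `tau = rR * t`.
#'
#' @param params A model parameter object with positive `K` and `rR`.
#' @param state Named numeric with entries `S`, `R` and optionally `t`
#'   (months; defaults to 0).
#' @return Named numeric `c(S_bar = , R_bar = , tau = )`.
#' @export
nondimensionalize <- function(params, state) {
  if (params$K <= 0 || params$rR <= 0) {
    stop_invalid("nondimensionalization requires K > 0 and rR > 0")
  }
  s <- as_state(state)
  t <- if (!is.null(names(state)) && "t" %in% names(state)) state[["t"]] else 0
  check_finite(t, "t")
  c(S_bar = s[1] / params$K, R_bar = s[2] / params$K, tau = params$rR * t)
}

#' Invert [nondimensionalize()]
#'
#' @param params A model parameter object.
#' @param scaled Named numeric `c(S_bar = , R_bar = , tau = )`.
#' @return Named numeric `c(S = , R = , t = )`.
#' @export
dimensionalize <- function(params, scaled) {
  if (params$K <= 0 || params$rR <= 0) {
    stop_invalid("dimensionalization requires K > 0 and rR > 0")
  }
  c(S = scaled[["S_bar"]] * params$K,
    R = scaled[["R_bar"]] * params$K,
    t = scaled[["tau"]] / params$rR)
}
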