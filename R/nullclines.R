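#' Phase-plane nullclines in dimensionless coordinates
#'
#' Returns the curves in the (S_bar, R_bar) = (S/K, R/K) plane along which
#' one population's rate of change vanishes, under the treatment-gated
#' parameters. Linear nullclines come back as line descriptors
#' `a*S_bar + b*R_bar = c`; nullclines without a convenient closed form
#' (the switching model under active switching) come back as sampled
#' implicit curves.
#'
#' For the LV model the R-nullclines are `R_bar = 0` and
#' `C*S_bar + R_bar = 1` (independent of treatment, since resistant cells
#' are drug-insensitive); the S-nullclines are `S_bar = 0` plus, off
#' treatment, `S_bar + R_bar = 1`. On treatment the S dynamics reduce to
#' pure exponential decay, so the only S-nullcline is the R axis.
#'
#' @param params An [lv_params()] or [sw_params()] object.
#' @param treatment_on Logical treatment state.
#' @param n Number of sample points for implicit curves.
#' @return List of descriptors; each has fields `population` ("S" or "R"),
#'   `treatment_on`, `type` ("line" or "curve"), and either `coef`
#'   (`c(a, b, c)`) or `points` (matrix with columns `S_bar`, `R_bar`).
#' @seealso [nullcline_points()] to sample any descriptor.
#' @export
nullclines <- function(params, treatment_on, n = 200) {
  UseMethod("nullclines")
}

line_desc <- function(population, treatment_on, a, b, c) {
  list(population = population, treatment_on = treatment_on,
       type = "line", coef = c(a = a, b = b, c = c))
}

curve_desc <- function(population, treatment_on, pts) {
  colnames(pts) <- c("S_bar", "R_bar")
  list(population = population, treatment_on = treatment_on,
       type = "curve", points = pts)
}

#' @export
nullclines.lv_params <- function(params, treatment_on, n = 200) {
  out <- list(
    line_desc("R", treatment_on, 0, 1, 0),                 # R_bar = 0
    line_desc("R", treatment_on, params$C, 1, 1),          # C*S + R = 1
    line_desc("S", treatment_on, 1, 0, 0)                  # S_bar = 0
  )
  if (!treatment_on) {
    out <- c(out, list(line_desc("S", FALSE, 1, 1, 1)))    # S + R = 1
  }
  out
}

#' @export
nullclines.sw_params <- function(params, treatment_on, n = 200) {
  rR <- params$rR
  if (treatment_on) {
    # dS/dt = -(delta + alpha) S: S-nullcline is the R axis.
    out <- list(line_desc("S", TRUE, 1, 0, 0))
    if (params$alpha == 0) {
      out <- c(out, list(line_desc("R", TRUE, 0, 1, 0),
                         line_desc("R", TRUE, 1, 1, 1)))
    } else {
      # rR*(1 - S - R)*R + alpha*S = 0: positive root of the quadratic in R.
      a <- params$alpha / rR
      s <- seq(0, 1, length.out = n)
      r <- ((1 - s) + sqrt((1 - s)^2 + 4 * a * s)) / 2
      out <- c(out, list(curve_desc("R", TRUE, cbind(s, r))))
    }
  } else {
    b <- params$beta / rR
    out <- list(line_desc("R", FALSE, 0, 1, 0))            # R_bar = 0
    if (1 - b > 0) {
      out <- c(out, list(line_desc("R", FALSE, 1, 1, 1 - b)))
    }
    if (params$beta == 0) {
      out <- c(out, list(line_desc("S", FALSE, 1, 0, 0),
                         line_desc("S", FALSE, 1, 1, 1)))
    } else if (params$rS > 0) {
      # rS*(1 - S - R)*S + beta*R = 0  =>  R = rS*S*(1-S) / (rS*S - beta),
      # real-valued for S past beta/rS; sampled where R >= 0.
      bs <- params$beta / params$rS
      if (bs < 1) {
        s <- seq(min(bs * 1.0001 + 1e-9, 1), 1, length.out = n)
        r <- params$rS * s * (1 - s) / (params$rS * s - params$beta)
        keep <- is.finite(r) & r >= 0 & r <= 2
        out <- c(out, list(curve_desc("S", FALSE, cbind(s[keep], r[keep]))))
      }
    }
  }
  out
}

#' Sample points on a nullcline descriptor
#'
#' @param desc One descriptor from [nullclines()].
#' @param n Number of points.
#' @param s_max Upper bound of the sampled S_bar (lines only).
#' @return Matrix with columns `S_bar`, `R_bar`.
#' @export
nullcline_points <- function(desc, n = 20, s_max = 1) {
  if (desc$type == "curve") {
    pts <- desc$points
    return(pts[round(seq(1, nrow(pts), length.out = min(n, nrow(pts)))), ,
               drop = FALSE])
  }
  co <- desc$coef
  if (abs(co["b"]) > 1e-12) {
    s <- seq(0, s_max, length.out = n)
    r <- (co["c"] - co["a"] * s) / co["b"]
    keep <- r >= -1e-12
    cbind(S_bar = s[keep], R_bar = pmax(r[keep], 0))
  } else {
    s <- rep(co["c"] / co["a"], n)
    cbind(S_bar = s, R_bar = seq(0, s_max, length.out = n))
  }
}
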