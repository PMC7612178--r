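#' Piecewise-constant coefficient function
#'
#' Represents a right-continuous step function on a breakpoint grid, used for
#' time-varying hazard coefficients.  A plain numeric scalar is accepted
#' anywhere a coefficient function is expected and is treated as constant in
#' time.
#'
#' @param values Numeric vector of piece values.
#' @param breaks Numeric vector of breakpoints, length `length(values) + 1`,
#'   strictly increasing.  The function equals `values[j]` on
#'   `[breaks[j], breaks[j + 1])`.
#' @return An object of class `piecewise_constant`.
#' @examples
#' f <- piecewise_constant(c(0.5, 1), c(0, 0.5, 1))
#' eval_coef(f, c(0.2, 0.7))
#' @export
piecewise_constant <- function(values, breaks) {
  values <- as.numeric(values)
  breaks <- as.numeric(breaks)
  if (length(breaks) != length(values) + 1L)
    stop("`breaks` must have length(values) + 1 entries", call. = FALSE)
  if (any(diff(breaks) <= 0))
    stop("`breaks` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("piece values must be finite", call. = FALSE)
  structure(list(values = values, breaks = breaks),
            class = "piecewise_constant")
}

#' Evaluate a coefficient function
#'
#' @param f A `piecewise_constant` object or a numeric scalar (constant).
#' @param t Numeric vector of evaluation times.
#' @return Numeric vector of coefficient values at `t`.
#' @export
eval_coef <- function(f, t) {
  if (is.numeric(f) && length(f) == 1L) return(rep(f, length(t)))
  if (!inherits(f, "piecewise_constant"))
    stop("coefficient must be a scalar or a piecewise_constant", call. = FALSE)
  idx <- findInterval(t, f$breaks, rightmost.closed = FALSE)
  out <- rep(NA_real_, length(t))
  ok <- idx >= 1L & idx <= length(f$values)
  out[ok] <- f$values[idx[ok]]
  # evaluation at/after the last break carries the last piece forward
  out[idx > length(f$values)] <- f$values[length(f$values)]
  out[idx < 1L] <- f$values[1L]
  out
}

#' @export
print.piecewise_constant <- function(x, ...) {
  cat("piecewise-constant function,", length(x$values), "piece(s) on [",
      x$breaks[1], ",", x$breaks[length(x$breaks)], ")\n")
  invisible(x)
}

# breakpoints of a coefficient that fall strictly inside (lo, hi)
.inner_breaks <- function(f, lo, hi) {
  if (!inherits(f, "piecewise_constant")) return(numeric(0))
  b <- f$breaks
  b[b > lo & b < hi]
}

#' Conditional hazard specification
#'
#' Defines the hazard of the event time given treatment history, covariate
#' history and frailty, either in the additive (Aalen) form
#' \deqn{\lambda(t) = \alpha_0(t) + \sum_j \alpha_{Aj}(t) a_{\lfloor t\rfloor - j}
#'   + \sum_j \alpha_{Lj}(t) L_{\lfloor t\rfloor - j} + \alpha_U(t) U}
#' or the Cox form
#' \deqn{\lambda(t) = \lambda_0(t) \exp(\sum_j \beta_{Aj} a_{\lfloor t\rfloor - j}
#'   + \sum_j \beta_{Lj} L_{\lfloor t\rfloor - j} + \beta_U U).}
#' Lag-0 means the value at the most recent visit.  Coefficients may be
#' scalars (constant in time) or [piecewise_constant()] functions; Cox
#' covariate effects are scalar log-hazard ratios.
#'
#' Negative additive hazards are floored at zero when event times are drawn
#' (and inside the g-formula oracle); the number of floored evaluations is
#' recorded on simulator output.
#'
#' @param alpha0 Baseline coefficient function (additive family).
#' @param alphaA Per-lag treatment coefficients, lag 0 first.  Each entry a
#'   scalar or `piecewise_constant`.
#' @param alphaL Per-lag confounder coefficients, lag 0 first.
#' @param alphaU Frailty coefficient.
#' @return An object of class `hazard_spec`.
#' @examples
#' additive_hazard_spec()            # the default generator's hazard
#' cox_hazard_spec(lambda0 = 0.5, betaA = -0.3)
#' @export
additive_hazard_spec <- function(alpha0 = 0.7, alphaA = -0.2,
                                 alphaL = 0.05, alphaU = 0.05) {
  spec <- structure(list(family = "additive",
                         alpha0 = alpha0,
                         alphaA = .as_coef_list(alphaA),
                         alphaL = .as_coef_list(alphaL),
                         alphaU = alphaU),
                    class = "hazard_spec")
  .validate_hazard_spec(spec)
  spec
}

#' @rdname additive_hazard_spec
#' @param lambda0 Baseline hazard function (Cox family), must be nonnegative.
#' @param betaA,betaL Per-lag log-hazard-ratio vectors, lag 0 first.
#' @param betaU Frailty log-hazard ratio.
#' @export
cox_hazard_spec <- function(lambda0 = 0.5, betaA = -0.3,
                            betaL = 0.2, betaU = 1) {
  spec <- structure(list(family = "cox",
                         alpha0 = lambda0,
                         alphaA = .as_coef_list(betaA),
                         alphaL = .as_coef_list(betaL),
                         alphaU = betaU),
                    class = "hazard_spec")
  .validate_hazard_spec(spec)
  spec
}

.as_coef_list <- function(x) {
  if (inherits(x, "piecewise_constant")) return(list(x))
  if (is.list(x)) return(x)
  as.list(as.numeric(x))
}

.validate_hazard_spec <- function(spec) {
  chk <- function(f, nm) {
    if (is.numeric(f) && length(f) == 1L) {
      if (!is.finite(f)) stop("coefficient `", nm, "` must be finite", call. = FALSE)
    } else if (!inherits(f, "piecewise_constant")) {
      stop("coefficient `", nm, "` must be a scalar or piecewise_constant",
           call. = FALSE)
    }
  }
  chk(spec$alpha0, "baseline")
  for (j in seq_along(spec$alphaA)) chk(spec$alphaA[[j]], paste0("A lag ", j - 1))
  for (j in seq_along(spec$alphaL)) chk(spec$alphaL[[j]], paste0("L lag ", j - 1))
  chk(spec$alphaU, "U")
  invisible(spec)
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat("conditional", x$family, "hazard:",
      length(x$alphaA), "treatment lag(s),",
      length(x$alphaL), "confounder lag(s)\n")
  invisible(x)
}

#' Covariate-process specification
#'
#' The longitudinal confounder process: frailty `U ~ N(0, u_sd^2)`;
#' `L_0 ~ N(l0_u_coef * U, l0_sd^2)`; for `k >= 1`,
#' `L_k ~ N(rho * L_{k-1} + theta_a * A_{k-1} + theta_k * k + theta_u * U, l_sd^2)`.
#' Defaults encode a biomarker that rises with time and frailty and is lowered
#' by treatment.
#'
#' @param u_sd Frailty standard deviation (default 0.1).
#' @param l0_u_coef Coefficient of `U` in the `L_0` mean (default 1).
#' @param l0_sd Standard deviation of `L_0` (default 1).
#' @param rho Autoregressive coefficient on `L_{k-1}` (default 0.8).
#' @param theta_a Coefficient on previous treatment (default -1).
#' @param theta_k Linear drift per visit (default 0.1).
#' @param theta_u Coefficient on frailty (default 1).
#' @param l_sd Innovation standard deviation (default 1).
#' @return An object of class `covariate_process_spec`.
#' @export
covariate_process_spec <- function(u_sd = 0.1, l0_u_coef = 1, l0_sd = 1,
                                   rho = 0.8, theta_a = -1, theta_k = 0.1,
                                   theta_u = 1, l_sd = 1) {
  if (u_sd <= 0 || l0_sd <= 0 || l_sd <= 0)
    stop("standard deviations must be strictly positive", call. = FALSE)
  structure(list(u_sd = u_sd, l0_u_coef = l0_u_coef, l0_sd = l0_sd,
                 rho = rho, theta_a = theta_a, theta_k = theta_k,
                 theta_u = theta_u, l_sd = l_sd),
            class = "covariate_process_spec")
}

#' Treatment-assignment specification
#'
#' The observational propensity model
#' `logit P(A_k = 1 | past) = gamma0 + gammaL * L_k + gammaA * A_{k-1}`
#' (the `A_{k-1}` term is absent at visit 0).
#'
#' @param gamma0 Intercept (default -2).
#' @param gammaL Coefficient on the current confounder (default 0.5).
#' @param gammaA Coefficient on previous treatment (default 1).
#' @return An object of class `treatment_model_spec`.
#' @export
treatment_model_spec <- function(gamma0 = -2, gammaL = 0.5, gammaA = 1) {
  stopifnot(is.finite(gamma0), is.finite(gammaL), is.finite(gammaA))
  structure(list(gamma0 = gamma0, gammaL = gammaL, gammaA = gammaA),
            class = "treatment_model_spec")
}

#' Treatment regimes
#'
#' A static treatment regime is a fixed binary vector `(a_0, ..., a_K)`
#' applied by intervention at each visit.
#'
#' @param a Binary vector of length `K + 1`.
#' @return An object of class `treatment_regime` (an integer vector with a
#'   label attribute).
#' @examples
#' treatment_regime(c(1, 1, 1, 1, 1))  # always treated
#' all_regimes(K = 2)
#' @export
treatment_regime <- function(a) {
  a <- as.integer(a)
  if (length(a) < 1L || !all(a %in% c(0L, 1L)))
    stop("a regime is a binary vector of length K + 1", call. = FALSE)
  structure(a, class = "treatment_regime",
            label = paste(a, collapse = ""))
}

#' @rdname treatment_regime
#' @param K Last visit index; all `2^(K+1)` regimes are enumerated.
#' @export
all_regimes <- function(K = 4L) {
  grid <- expand.grid(rep(list(0:1), K + 1L))[, (K + 1L):1, drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) treatment_regime(as.integer(grid[i, ])))
}

#' @rdname treatment_regime
#' @export
never_treated <- function(K = 4L) treatment_regime(rep(0L, K + 1L))

#' @rdname treatment_regime
#' @export
always_treated <- function(K = 4L) treatment_regime(rep(1L, K + 1L))

regime_label <- function(regime) attr(regime, "label")
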