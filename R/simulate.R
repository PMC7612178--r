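#' Draw an event time within an interval of constant hazard
#'
#' Inverse-transform draw: `T* = -log(V) / lambda`.  A nonpositive hazard is
#' floored at zero, so no event can occur.  The event occurs iff
#' `T* < interval_length` (strict: a draw landing exactly on the boundary
#' survives the interval).
#'
#' @param hazard Hazard value(s); may be any real (negatives floored at 0).
#' @param interval_length Positive interval length.
#' @param uniform_draw Uniform(0,1) draw(s), strictly inside (0, 1).
#' @return Event offset within the interval, or `NA` if the person survives
#'   the interval.  Vectorized over `hazard` and `uniform_draw`.
#' @examples
#' draw_event_time_constant(0.7, 1, 0.5)        # -log(0.5)/0.7
#' draw_event_time_constant(-0.05, 1, 0.5)      # NA: hazard floored at 0
#' @export
draw_event_time_constant <- function(hazard, interval_length, uniform_draw) {
  if (any(uniform_draw <= 0 | uniform_draw >= 1))
    stop("uniform_draw must lie strictly inside (0, 1)", call. = FALSE)
  if (interval_length <= 0)
    stop("interval_length must be positive", call. = FALSE)
  lam <- pmax(hazard, 0)
  tstar <- ifelse(lam > 0, -log(uniform_draw) / lam, Inf)
  ifelse(tstar < interval_length, tstar, NA_real_)
}

#' Draw an event time from a piecewise-constant hazard on an interval
#'
#' Inverts the piecewise-linear cumulative hazard: returns the `t` solving
#' `Lambda(t) = -log(V)`, or `NA` ("survives") if the total cumulative hazard
#' over the interval is below `-log(V)`.  Negative step values are floored at
#' zero.  With a single step this reduces exactly to
#' [draw_event_time_constant()].
#'
#' @param hazard_steps Numeric vector of step values.
#' @param breaks Breakpoints, length `length(hazard_steps) + 1`, starting at 0.
#' @param uniform_draw A Uniform(0,1) draw strictly inside (0, 1).
#' @return Event offset in `[0, max(breaks))` or `NA`.
#' @examples
#' draw_event_time_piecewise(c(0.5, 1), c(0, 0.5, 1), exp(-0.5))  # 0.75
#' @export
draw_event_time_piecewise <- function(hazard_steps, breaks, uniform_draw) {
  if (length(uniform_draw) != 1L)
    stop("uniform_draw must be a single value", call. = FALSE)
  if (uniform_draw <= 0 || uniform_draw >= 1)
    stop("uniform_draw must lie strictly inside (0, 1)", call. = FALSE)
  if (length(breaks) != length(hazard_steps) + 1L || any(diff(breaks) <= 0))
    stop("breaks must be sorted with length(hazard_steps) + 1 entries",
         call. = FALSE)
  rates <- matrix(pmax(hazard_steps, 0), nrow = 1L)
  off <- piecewise_event_offset(rates, diff(breaks), uniform_draw)
  off[1L]
}

# Vectorized inversion of piecewise-linear cumulative hazards.
# rates: n x J matrix (already floored at 0); widths: length-J piece widths;
# V: n uniforms.  Returns offsets (NA = survives the whole interval, with a
# draw landing exactly on the total counting as surviving).
piecewise_event_offset <- function(rates, widths, V) {
  n <- nrow(rates)
  J <- length(widths)
  target <- -log(V)
  cum <- matrix(0, n, J + 1L)
  for (j in seq_len(J)) cum[, j + 1L] <- cum[, j] + rates[, j] * widths[j]
  bounds <- cumsum(c(0, widths))
  offset <- rep(NA_real_, n)
  for (j in seq_len(J)) {
    hit <- is.na(offset) & cum[, j + 1L] > target & rates[, j] > 0
    offset[hit] <- bounds[j] + (target[hit] - cum[hit, j]) / rates[hit, j]
  }
  offset
}

# Piecewise-constant hazard over interval [k, k+1) for a set of persons.
# Ahist/Lhist: matrices with columns for visits 0..k (most recent last).
# Returns list(rates = n x J matrix UNFLOORED, widths).
interval_hazard <- function(hazard, k, Ahist, Lhist, U) {
  lo <- k
  hi <- k + 1
  brks <- sort(unique(c(lo,
                        .inner_breaks(hazard$alpha0, lo, hi),
                        unlist(lapply(hazard$alphaA, .inner_breaks, lo, hi)),
                        unlist(lapply(hazard$alphaL, .inner_breaks, lo, hi)),
                        .inner_breaks(hazard$alphaU, lo, hi),
                        hi)))
  tmid <- (brks[-length(brks)] + brks[-1L]) / 2
  J <- length(tmid)
  n <- length(U)
  lagval <- function(M, j) if (j <= k) M[, k - j + 1L] else numeric(n)
  if (hazard$family == "additive") {
    rates <- matrix(rep(eval_coef(hazard$alpha0, tmid), each = n), n, J)
    for (j in seq_along(hazard$alphaA) - 1L)
      if (j <= k)
        rates <- rates + outer(lagval(Ahist, j),
                               eval_coef(hazard$alphaA[[j + 1L]], tmid))
    for (j in seq_along(hazard$alphaL) - 1L)
      if (j <= k)
        rates <- rates + outer(lagval(Lhist, j),
                               eval_coef(hazard$alphaL[[j + 1L]], tmid))
    rates <- rates + outer(U, eval_coef(hazard$alphaU, tmid))
  } else {
    lp <- numeric(n)
    for (j in seq_along(hazard$alphaA) - 1L)
      if (j <= k) lp <- lp + .coef_scalar(hazard$alphaA[[j + 1L]]) * lagval(Ahist, j)
    for (j in seq_along(hazard$alphaL) - 1L)
      if (j <= k) lp <- lp + .coef_scalar(hazard$alphaL[[j + 1L]]) * lagval(Lhist, j)
    lp <- lp + .coef_scalar(hazard$alphaU) * U
    rates <- outer(exp(lp), eval_coef(hazard$alpha0, tmid))
  }
  list(rates = rates, widths = diff(brks))
}

.coef_scalar <- function(f) {
  if (inherits(f, "piecewise_constant"))
    stop("Cox covariate effects must be scalar log-hazard ratios",
         call. = FALSE)
  f
}

# Shared sequential engine.  `assignment` is either a treatment_model_spec
# (observational draws) or an integer regime vector (set by intervention).
# `streams` holds pre-drawn random numbers so substreams are coupled across
# runs: U (n), Z (n x (K+1) standard normals for L), TU (n x (K+1) uniforms
# for A), V (n x (K+1) uniforms for event times).
.sim_engine <- function(n, K, hazard, covariates, assignment, streams) {
  U <- streams$U
  L <- matrix(NA_real_, n, K + 1L)
  A <- matrix(NA_integer_, n, K + 1L)
  Tt <- rep(NA_real_, n)
  floored <- 0L
  alive <- rep(TRUE, n)
  fixed <- is.integer(assignment) || inherits(assignment, "treatment_regime")
  for (k in 0:K) {
    ids <- which(alive)
    if (!length(ids)) break
    if (k == 0L) {
      L[ids, 1L] <- covariates$l0_u_coef * U[ids] +
        covariates$l0_sd * streams$Z[ids, 1L]
    } else {
      L[ids, k + 1L] <- covariates$rho * L[ids, k] +
        covariates$theta_a * A[ids, k] + covariates$theta_k * k +
        covariates$theta_u * U[ids] + covariates$l_sd * streams$Z[ids, k + 1L]
    }
    if (fixed) {
      A[ids, k + 1L] <- as.integer(assignment)[k + 1L]
    } else {
      eta <- assignment$gamma0 + assignment$gammaL * L[ids, k + 1L] +
        if (k > 0L) assignment$gammaA * A[ids, k] else 0
      A[ids, k + 1L] <- as.integer(streams$TU[ids, k + 1L] < stats::plogis(eta))
    }
    haz <- interval_hazard(hazard, k,
                           Ahist = A[ids, seq_len(k + 1L), drop = FALSE],
                           Lhist = L[ids, seq_len(k + 1L), drop = FALSE],
                           U = U[ids])
    floored <- floored + sum(haz$rates < 0)
    off <- piecewise_event_offset(pmax(haz$rates, 0), haz$widths,
                                  streams$V[ids, k + 1L])
    hit <- !is.na(off)
    Tt[ids[hit]] <- k + off[hit]
    alive[ids[hit]] <- FALSE
  }
  list(U = U, L = L, A = A, T = Tt, floored = floored)
}

.draw_streams <- function(n, K, seed, covariates) {
  s <- derive_stream_seeds(seed, c("frailty", "covariate", "treatment", "event"))
  set.seed(s[["frailty"]])
  U <- stats::rnorm(n, 0, covariates$u_sd)
  set.seed(s[["covariate"]])
  Z <- matrix(stats::rnorm(n * (K + 1L)), n, K + 1L)
  set.seed(s[["treatment"]])
  TU <- matrix(stats::runif(n * (K + 1L)), n, K + 1L)
  set.seed(s[["event"]])
  V <- matrix(stats::runif(n * (K + 1L)), n, K + 1L)
  list(U = U, Z = Z, TU = TU, V = V)
}

.build_panel <- function(sim, K, ids = seq_along(sim$U), regime_label = NULL) {
  Tt <- sim$T
  C <- rep(K + 1, length(ids))
  followup <- pmin(ifelse(is.na(Tt), Inf, Tt), C)
  kmax <- pmin(K, ceiling(followup) - 1L)
  nv <- kmax + 1L
  row_person <- rep(seq_along(ids), nv)
  visit <- unlist(lapply(nv, function(m) 0:(m - 1L)), use.names = FALSE)
  df <- data.frame(
    id = ids[row_person],
    visit = visit,
    A = sim$A[cbind(row_person, visit + 1L)],
    L = sim$L[cbind(row_person, visit + 1L)],
    atrisk = 1L,
    U = sim$U[row_person],
    T = Tt[row_person],
    event = as.integer(!is.na(Tt))[row_person],
    C = C[row_person])
  if (!is.null(regime_label)) df$regime <- regime_label
  df
}

#' Simulate an observational cohort
#'
#' Sequential generation per person: frailty `U`, then for each visit `k`
#' (while at risk) the confounder `L_k`, treatment `A_k` from the propensity
#' model, and an event time in `[k, k + 1)` from the conditional hazard.
#' Administrative censoring at `K + 1`.  Defaults reproduce the package's
#' reference generator: `U ~ N(0, 0.1^2)`, `L_0 ~ N(U, 1)`,
#' `logit P(A_k=1) = -2 + 0.5 L_k + A_{k-1}`, hazard
#' `0.7 - 0.2 A + 0.05 L + 0.05 U`,
#' `L_k ~ N(0.8 L_{k-1} - A_{k-1} + 0.1 k + U, 1)`.
#'
#' @param n Number of persons.
#' @param K Last visit index (default 4; follow-up ends at `K + 1 = 5`).
#' @param hazard An [additive_hazard_spec()].
#' @param covariates A [covariate_process_spec()].
#' @param treatment A [treatment_model_spec()].
#' @param seed Master seed; spawns named substreams (frailty, covariate,
#'   treatment, event) so that changing one model component leaves the other
#'   draws untouched.
#' @return A [cohort_panel()] with a `floored_hazard_count` attribute
#'   recording how many negative hazard evaluations were floored at zero.
#' @examples
#' panel <- simulate_observational(500, seed = 1)
#' panel
#' @export
simulate_observational <- function(n, K = 4L,
                                   hazard = additive_hazard_spec(),
                                   covariates = covariate_process_spec(),
                                   treatment = treatment_model_spec(),
                                   seed = 1L) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  if (!inherits(hazard, "hazard_spec") || hazard$family != "additive")
    stop("hazard must be an additive hazard_spec; ",
         "use simulate_conditional_cox() for the Cox family", call. = FALSE)
  if (!inherits(treatment, "treatment_model_spec"))
    stop("treatment must be a treatment_model_spec", call. = FALSE)
  streams <- .draw_streams(n, K, seed, covariates)
  sim <- .sim_engine(n, K, hazard, covariates, treatment, streams)
  out <- cohort_panel(.build_panel(sim, K), K = K)
  attr(out, "floored_hazard_count") <- sim$floored
  out
}

#' Simulate intervention trials under fixed treatment regimes
#'
#' The propensity model is bypassed: `A_k` is set by intervention to the
#' regime value.  With `share_baseline = TRUE` (default) the baseline draws
#' --- the frailty and the realized `L_0` values --- are drawn once per
#' replicate and reused in every regime arm, while the post-baseline
#' confounder innovations and event draws are fresh in each arm, so the
#' arms contribute independent information about the event process.
#'
#' @param regimes A list of [treatment_regime()] vectors (e.g.
#'   [all_regimes()]).
#' @param m Persons per regime arm.
#' @param K,hazard,covariates,seed As in [simulate_observational()].
#' @param share_baseline Reuse baseline and noise draws across regimes.
#' @return A [cohort_panel()] with a `regime` label column; person ids are
#'   unique across arms.
#' @examples
#' trial <- simulate_under_regimes(list(never_treated(2), always_treated(2)),
#'                                 m = 100, K = 2, seed = 1)
#' table(trial$regime[trial$visit == 0])
#' @export
simulate_under_regimes <- function(regimes, m, K = 4L,
                                   hazard = additive_hazard_spec(),
                                   covariates = covariate_process_spec(),
                                   seed = 1L, share_baseline = TRUE) {
  if (!length(regimes)) stop("regimes must be nonempty", call. = FALSE)
  labels <- vapply(regimes, function(r) attr(r, "label"), character(1))
  if (anyDuplicated(labels))
    warning("duplicate regimes supplied", call. = FALSE)
  if (any(lengths(regimes) != K + 1L))
    stop("each regime must have length K + 1", call. = FALSE)
  shared <- .draw_streams(m, K, seed, covariates)
  panels <- vector("list", length(regimes))
  floored <- 0L
  for (r in seq_along(regimes)) {
    st <- .draw_streams(m, K, derive_replicate_seed(seed, 1000L + r),
                        covariates)
    if (share_baseline) {
      st$U <- shared$U
      st$Z[, 1L] <- shared$Z[, 1L]
    }
    sim <- .sim_engine(m, K, hazard, covariates, regimes[[r]], st)
    floored <- floored + sim$floored
    panels[[r]] <- .build_panel(sim, K, ids = (r - 1L) * m + seq_len(m),
                                regime_label = labels[r])
  }
  out <- cohort_panel(do.call(rbind, panels), K = K)
  attr(out, "floored_hazard_count") <- floored
  out
}

#' Simulate an observational cohort from a conditional Cox hazard
#'
#' Identical sequential structure to [simulate_observational()], but
#' within-interval event times are exponential with rate
#' `lambda_0(t) exp(betaA' v(A) + betaL' w(L) + betaU U)` (piecewise if
#' `lambda_0` has breaks inside the interval).  Default coefficients are an
#' illustration, not calibrated to any reference table.
#'
#' @inheritParams simulate_observational
#' @param hazard A [cox_hazard_spec()].
#' @return A [cohort_panel()].
#' @export
simulate_conditional_cox <- function(n, K = 4L,
                                     hazard = cox_hazard_spec(),
                                     covariates = covariate_process_spec(),
                                     treatment = treatment_model_spec(),
                                     seed = 1L) {
  if (!inherits(hazard, "hazard_spec") || hazard$family != "cox")
    stop("hazard must be a Cox hazard_spec", call. = FALSE)
  streams <- .draw_streams(n, K, seed, covariates)
  sim <- .sim_engine(n, K, hazard, covariates, treatment, streams)
  out <- cohort_panel(.build_panel(sim, K), K = K)
  attr(out, "floored_hazard_count") <- sim$floored
  out
}

#' Apply random (non-administrative) censoring to a panel
#'
#' Draws a censoring time from a per-interval constant censoring hazard
#' `c0 + cA * A_k + cL * L_k` (floored at 0) using its own random stream,
#' replaces `C` by the minimum of the administrative time and the drawn time,
#' and updates the event indicator and visit rows accordingly.
#'
#' @param panel A [cohort_panel()] whose event times are known (i.e.
#'   simulator output, before any masking).
#' @param censoring List with elements `c0`, `cA`, `cL` (defaults 0).
#' @param seed Seed for the censoring stream.
#' @return A [cohort_panel()] with updated `C`, `T`, `event` and rows.
#' @export
apply_random_censoring <- function(panel, censoring = list(c0 = 0, cA = 0, cL = 0),
                                   seed = 1L) {
  validate_panel(panel)
  K <- attr(panel, "K")
  c0 <- censoring$c0 %||% 0
  cA <- censoring$cA %||% 0
  cL <- censoring$cL %||% 0
  if (c0 == 0 && cA == 0 && cL == 0) return(panel)
  s <- derive_stream_seeds(seed, "censoring")
  set.seed(s[["censoring"]])
  Vc <- stats::runif(nrow(panel))
  rate <- pmax(c0 + cA * panel$A + cL * panel$L, 0)
  off <- ifelse(rate > 0, -log(Vc) / rate, Inf)
  cens_row <- panel$visit + off
  cand <- ifelse(off < 1, cens_row, Inf)
  Cnew <- tapply(cand, panel$id, min)
  Cnew <- pmin(Cnew[match(unique(panel$id), names(Cnew))], K + 1)
  first <- !duplicated(panel$id)
  per <- data.frame(id = panel$id[first], T = panel$T[first],
                    U = panel$U[first], C = as.numeric(Cnew))
  per$event <- as.integer(!is.na(per$T) & per$T <= per$C)
  per$T[per$event == 0L] <- NA_real_
  idx <- match(panel$id, per$id)
  out <- as.data.frame(panel)
  out$C <- per$C[idx]
  out$event <- per$event[idx]
  out$T <- per$T[idx]
  followup <- pmin(ifelse(is.na(out$T), Inf, out$T), out$C)
  out <- out[out$visit < followup, , drop = FALSE]
  cohort_panel(out, K = K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
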