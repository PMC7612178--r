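#' Weight-model specification
#'
#' Predictor sets for the stabilized-weight logistic models.  Defaults follow
#' the standard stabilized construction: the numerator conditions on previous
#' treatment only (intercept-only at visit 0, where no previous treatment
#' exists), the denominator additionally on the current confounder
#' (`L_0` only at visit 0).
#'
#' @param numerator Character vector of numerator predictors among
#'   `"A_prev"` (previous treatment).
#' @param denominator Character vector of denominator predictors among
#'   `"A_prev"`, `"L"`.
#' @return An object of class `weight_model_spec`.
#' @export
weight_model_spec <- function(numerator = "A_prev",
                              denominator = c("A_prev", "L")) {
  numerator <- intersect(numerator, c("A_prev", "L"))
  denominator <- intersect(denominator, c("A_prev", "L"))
  if (!all(numerator %in% denominator))
    stop("numerator predictors must be a subset of denominator predictors",
         call. = FALSE)
  structure(list(numerator = numerator, denominator = denominator),
            class = "weight_model_spec")
}

# person-visit table with previous treatment, pooled over at-risk visits
.pv_table <- function(panel) {
  pid <- match(panel$id, unique(panel$id))
  K <- attr(panel, "K")
  Awide <- matrix(NA_integer_, max(pid), K + 1L)
  Awide[cbind(pid, panel$visit + 1L)] <- panel$A
  A_prev <- ifelse(panel$visit > 0L,
                   Awide[cbind(pid, pmax(panel$visit, 1L))], NA_integer_)
  data.frame(id = panel$id, visit = panel$visit, A = panel$A, L = panel$L,
             A_prev = A_prev)
}

.fit_logistic <- function(formula, data, label) {
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial()))
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (!fit$converged || any(p < eps) || any(p > 1 - eps))
    stop("separation / non-convergence in the ", label,
         " treatment model", call. = FALSE)
  fit
}

#' Fit the stabilized-weight treatment models
#'
#' Pooled logistic regressions for the probability of the observed treatment:
#' a pair of models at visit 0 (numerator intercept-only, denominator on
#' `L_0`) and a pair pooled over visits `1..K` (numerator on `A_{k-1}`,
#' denominator on `A_{k-1}` and `L_k`), fitted by maximum likelihood on the
#' at-risk person-visits of the observed view of a panel.
#'
#' @param panel A [cohort_panel()] (the frailty column is never used).
#' @param spec A [weight_model_spec()].
#' @return An object of class `treatment_model_fits` with elements
#'   `num0`, `den0`, `num`, `den` (fitted `glm` objects) and a
#'   `diagnostics` data frame (model, log-likelihood, converged).
#' @export
fit_treatment_models <- function(panel, spec = weight_model_spec()) {
  validate_panel(panel)
  pv <- .pv_table(panel)
  d0 <- pv[pv$visit == 0L, ]
  dk <- pv[pv$visit > 0L, ]
  rhs <- function(preds, baseline) {
    preds <- setdiff(preds, if (baseline) "A_prev" else character(0))
    if (!length(preds)) "1" else paste(preds, collapse = " + ")
  }
  num0 <- .fit_logistic(stats::as.formula(
    paste("A ~", rhs(spec$numerator, TRUE))), d0, "visit-0 numerator")
  den0 <- .fit_logistic(stats::as.formula(
    paste("A ~", rhs(spec$denominator, TRUE))), d0, "visit-0 denominator")
  if (nrow(dk)) {
    num <- .fit_logistic(stats::as.formula(
      paste("A ~", rhs(spec$numerator, FALSE))), dk, "pooled numerator")
    den <- .fit_logistic(stats::as.formula(
      paste("A ~", rhs(spec$denominator, FALSE))), dk, "pooled denominator")
  } else {
    num <- den <- NULL
  }
  diag_row <- function(nm, f) if (is.null(f)) NULL else
    data.frame(model = nm, logLik = as.numeric(stats::logLik(f)),
               converged = f$converged)
  structure(list(num0 = num0, den0 = den0, num = num, den = den,
                 spec = spec,
                 diagnostics = do.call(rbind, Filter(Negate(is.null), list(
                   diag_row("num0", num0), diag_row("den0", den0),
                   diag_row("num", num), diag_row("den", den))))),
            class = "treatment_model_fits")
}

#' @export
print.treatment_model_fits <- function(x, ...) {
  cat("stabilized-weight treatment models (pooled logistic):\n")
  print(x$diagnostics, row.names = FALSE)
  if (!is.null(x$den))
    cat("pooled denominator coefficients:",
        paste(format(stats::coef(x$den), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Compute cumulative stabilized weights
#'
#' For each at-risk person-visit, the probability of the *observed* treatment
#' under the numerator and denominator models (`p` if `A_k = 1`, `1 - p`
#' otherwise) and the cumulative stabilized weight
#' `SW_k = prod_{j <= k} p_num,j / p_den,j`, constant on `[k, k + 1)`.
#'
#' @param panel A [cohort_panel()].
#' @param fits A [fit_treatment_models()] result.
#' @return A data frame of class `stabilized_weights` with columns `id`,
#'   `visit`, `p_num`, `p_den`, `sw`.
#' @export
compute_stabilized_weights <- function(panel, fits) {
  validate_panel(panel)
  pv <- .pv_table(panel)
  prob_obs <- function(fit, newdata) {
    p1 <- stats::predict(fit, newdata = newdata, type = "response")
    ifelse(newdata$A == 1L, p1, 1 - p1)
  }
  p_num <- p_den <- rep(NA_real_, nrow(pv))
  i0 <- pv$visit == 0L
  p_num[i0] <- prob_obs(fits$num0, pv[i0, ])
  p_den[i0] <- prob_obs(fits$den0, pv[i0, ])
  if (any(!i0)) {
    p_num[!i0] <- prob_obs(fits$num, pv[!i0, ])
    p_den[!i0] <- prob_obs(fits$den, pv[!i0, ])
  }
  if (any(p_den <= 0)) {
    bad <- which(p_den <= 0)[1L]
    stop("positivity violation: denominator probability 0 for id ",
         pv$id[bad], " at visit ", pv$visit[bad], call. = FALSE)
  }
  ratio <- p_num / p_den
  sw <- as.numeric(unlist(lapply(split(ratio, pv$id), cumprod),
                          use.names = FALSE))
  out <- data.frame(id = pv$id, visit = pv$visit,
                    p_num = p_num, p_den = p_den, sw = sw)
  class(out) <- c("stabilized_weights", "data.frame")
  out
}

#' @export
print.stabilized_weights <- function(x, ...) {
  cat("stabilized weights:", nrow(x), "person-visits; ")
  cat("mean by visit:",
      paste(format(tapply(x$sw, x$visit, mean), digits = 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Inverse-probability-of-censoring weights
#'
#' For panels with non-administrative censoring, fits pooled logistic models
#' for remaining *uncensored* through each interval (numerator intercept-only,
#' denominator on `A_k` and `L_k`) and returns weights to be multiplied with
#' the treatment weights.  With purely administrative censoring all weights
#' are 1.
#'
#' @param panel A [cohort_panel()].
#' @param sw Optional [compute_stabilized_weights()] table to combine with.
#' @return A data frame with columns `id`, `visit`, `cw` (censoring weight)
#'   and, if `sw` was given, `sw` replaced by the combined weight.
#' @export
compute_censoring_weights <- function(panel, sw = NULL) {
  validate_panel(panel)
  K <- attr(panel, "K")
  followup <- pmin(ifelse(is.na(panel$T), Inf, panel$T), panel$C)
  # uncensored through [k, k+1): either survived past k+1, or event <= C
  admin_only <- all(panel$C[!duplicated(panel$id)] >= K + 1)
  pv <- .pv_table(panel)
  if (admin_only) {
    out <- data.frame(id = pv$id, visit = pv$visit, cw = 1)
  } else {
    cens_in <- as.integer(panel$event == 0L & panel$C < panel$visit + 1 &
                            panel$C >= panel$visit)
    dat <- cbind(pv, uncens = 1L - cens_in)
    num <- .fit_logistic(uncens ~ 1, dat, "censoring numerator")
    den <- .fit_logistic(uncens ~ A + L, dat, "censoring denominator")
    p_num <- stats::predict(num, dat, type = "response")
    p_den <- stats::predict(den, dat, type = "response")
    if (any(p_den <= 0))
      stop("positivity violation in the censoring model", call. = FALSE)
    out <- data.frame(id = pv$id, visit = pv$visit,
                      cw = as.numeric(unlist(lapply(
                        split(p_num / p_den, pv$id), cumprod),
                        use.names = FALSE)))
  }
  if (!is.null(sw)) {
    m <- match(paste(out$id, out$visit), paste(sw$id, sw$visit))
    out$sw <- sw$sw[m] * out$cw
    class(out) <- c("stabilized_weights", "data.frame")
  }
  out
}
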