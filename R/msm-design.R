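#' Marginal structural model design
#'
#' Maps a treatment history and a time to the MSM design vector.  Three named
#' forms are supported for the additive MSM
#' \eqn{\lambda_{T^a}(t) = \tilde\alpha_0(t) + g(\bar a_{\lfloor t\rfloor};
#' \tilde\alpha_A(t))}:
#' \describe{
#'   \item{`current`}{`g = alphaA(t) * a_k`: design `(1, a_k)`.}
#'   \item{`duration`}{`g = alphaA(t) * sum(a_0..a_k)`: design `(1, cumsum)`.}
#'   \item{`history`}{main effects of the whole history,
#'     `g = sum_j alphaAj(t) a_{k-j}`: design `(1, a_k, a_{k-1}, ..., a_0)`,
#'     with lag-`j` columns structurally zero for `t <= j`.}
#' }
#' where `k` is the most recent visit before `t`.  A `cox` form is reserved
#' but not implemented: the weighted partial-likelihood fitter is out of
#' scope, and requesting it fails loudly.
#'
#' @param form One of `"history"`, `"current"`, `"duration"`.
#' @param K Last visit index.
#' @return An object of class `msm_design`.
#' @export
msm_design <- function(form = c("history", "current", "duration", "cox"),
                       K = 4L) {
  form <- match.arg(form)
  if (form == "cox")
    stop("the Cox MSM form is reserved but not implemented; ",
         "use an additive form (history/current/duration)", call. = FALSE)
  K <- as.integer(K)
  cols <- switch(form,
                 history  = c("baseline", paste0("lag", 0:K)),
                 current  = c("baseline", "current"),
                 duration = c("baseline", "duration"))
  structure(list(form = form, K = K, columns = cols), class = "msm_design")
}

#' @export
print.msm_design <- function(x, ...) {
  cat("msm_design(", x$form, "): columns ",
      paste(x$columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# columns active in interval [k, k+1): for the history form the design
# dimension grows with k (lag-j terms do not exist before visit j).
active_columns <- function(design, k) {
  if (design$form == "history") seq_len(k + 2L) else seq_along(design$columns)
}

# Evaluate design columns for every row of a panel (treatment history up to
# the row's visit).  Lags beyond the observed history are 0.
design_columns <- function(design, panel) {
  ids <- panel$id
  k <- panel$visit
  pid <- match(ids, unique(ids))
  K <- attr(panel, "K")
  Awide <- matrix(0L, nrow = max(pid), ncol = K + 1L)
  Awide[cbind(pid, k + 1L)] <- as.integer(panel$A)
  X <- matrix(0, nrow = nrow(panel), ncol = length(design$columns),
              dimnames = list(NULL, design$columns))
  X[, 1L] <- 1
  if (design$form == "history") {
    for (j in 0:design$K) {
      ok <- k >= j
      X[ok, paste0("lag", j)] <- Awide[cbind(pid[ok], k[ok] - j + 1L)]
    }
  } else if (design$form == "current") {
    X[, "current"] <- Awide[cbind(pid, k + 1L)]
  } else {
    Acum <- t(apply(Awide, 1L, cumsum))
    X[, "duration"] <- Acum[cbind(pid, k + 1L)]
  }
  as.data.frame(X)
}

# Design vector for a fixed regime in interval [k, k+1).
design_vector_regime <- function(design, regime, k) {
  a <- as.integer(regime)
  x <- numeric(length(design$columns))
  names(x) <- design$columns
  x[1L] <- 1
  if (design$form == "history") {
    for (j in 0:k) x[paste0("lag", j)] <- a[k - j + 1L]
  } else if (design$form == "current") {
    x["current"] <- a[k + 1L]
  } else {
    x["duration"] <- sum(a[seq_len(k + 1L)])
  }
  x
}
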