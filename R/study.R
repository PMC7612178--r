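#' Compute true MSM parameter values from replicate intervention trials
#'
#' Simulates `replications` large randomized trials (each with `m` persons
#' per regime arm, all `2^(K+1)` regimes, baseline draws shared across arms
#' within a replicate), fits the unweighted history-main-effects additive MSM
#' in each (no weights are needed: treatment is randomized), transforms to
#' counterfactual survival, and averages across replicates.  Direct survival
#' proportions from the trial arms are reported alongside as a cross-check.
#'
#' @param m Persons per regime arm (default 1000).
#' @param replications Number of replicate trials.
#' @param K Last visit index.
#' @param hazard,covariates Generator specification.
#' @param times Estimand grid (default `1:5`).
#' @param seed Master seed; each replicate derives its own sub-seed.
#' @param regimes Regimes for the trial (default all `2^(K+1)`).
#' @return An object of class `msm_truth`: mean cumulative coefficients and
#'   their Monte-Carlo SEs at `times`, mean never/always-treated survival by
#'   the MSM route and by direct proportions (each with Monte-Carlo SEs),
#'   and bookkeeping fields.
#' @examples
#' \donttest{
#' truth <- compute_truth(m = 200, replications = 20, seed = 1)
#' truth
#' }
#' @export
compute_truth <- function(m = 1000L, replications = 100L, K = 4L,
                          hazard = additive_hazard_spec(),
                          covariates = covariate_process_spec(),
                          times = 1:5, seed = 1L,
                          regimes = all_regimes(K)) {
  design <- msm_design("history", K)
  p <- length(design$columns)
  nt <- length(times)
  cc_arr <- array(NA_real_, c(replications, nt, p))
  surv_arr <- array(NA_real_, c(replications, 2L, nt),
                    dimnames = list(NULL, c("never", "always"), NULL))
  prop_arr <- surv_arr
  nev <- never_treated(K)
  alw <- always_treated(K)
  for (r in seq_len(replications)) {
    panel <- simulate_under_regimes(regimes, m, K, hazard, covariates,
                                    seed = derive_replicate_seed(seed, r))
    cp <- expand_to_counting_process(panel, design)
    cc <- fit_weighted_aalen(cp, design)
    cc_arr[r, , ] <- cumulative_coefficients_at(cc, times)
    surv_arr[r, "never", ] <- survival_from_cumcoef(cc, nev, times)
    surv_arr[r, "always", ] <- survival_from_cumcoef(cc, alw, times)
    for (g in c("never", "always")) {
      lab <- attr(if (g == "never") nev else alw, "label")
      sub <- panel[panel$regime == lab & panel$visit == 0L, ]
      prop_arr[r, g, ] <- vapply(times, function(t)
        mean(!(sub$event == 1L & sub$T <= t)), numeric(1))
    }
  }
  structure(list(
    times = times,
    columns = design$columns,
    cumcoef = apply(cc_arr, c(2, 3), mean),
    cumcoef_se = apply(cc_arr, c(2, 3), stats::sd) / sqrt(replications),
    surv = apply(surv_arr, c(2, 3), mean),
    surv_se = apply(surv_arr, c(2, 3), stats::sd) / sqrt(replications),
    surv_direct = apply(prop_arr, c(2, 3), mean),
    surv_direct_se = apply(prop_arr, c(2, 3), stats::sd) / sqrt(replications),
    m = m, replications = replications, K = K, seed = seed),
    class = "msm_truth")
}

#' @export
print.msm_truth <- function(x, ...) {
  cat("true MSM values from", x$replications, "replicate trials (m =", x$m,
      "per regime):\n\ncumulative coefficients:\n")
  cc <- x$cumcoef
  dimnames(cc) <- list(paste0("t=", x$times), x$columns)
  print(round(cc, 3))
  cat("\ncounterfactual survival (MSM route):\n")
  sv <- x$surv
  dimnames(sv) <- list(c("never", "always"), paste0("t=", x$times))
  print(round(sv, 3))
  invisible(x)
}

#' Run a replicate MSM-IPTW simulation study
#'
#' Each replicate draws an observational cohort, fits the stabilized-weight
#' logistic models, computes the weights, expands to counting-process form,
#' fits the weighted history-main-effects additive MSM, and records the
#' cumulative coefficients and never/always-treated survival at the estimand
#' grid.  Replicate-level estimation failures are caught, counted and
#' skipped, not fatal.
#'
#' @param n Persons per replicate cohort (default 5000).
#' @param replications Number of replicates.
#' @param K Last visit index.
#' @param hazard,covariates,treatment Generator specification.
#' @param weight_spec A [weight_model_spec()].
#' @param times Estimand grid.
#' @param seed Master seed.
#' @param truth Optional [compute_truth()] result; if supplied, a
#'   [summarize_study()] table is attached.
#' @return An object of class `msm_study`: per-replicate estimate arrays,
#'   failure count, and (if truth was given) the summary table.
#' @export
run_simulation_study <- function(n = 5000L, replications = 100L, K = 4L,
                                 hazard = additive_hazard_spec(),
                                 covariates = covariate_process_spec(),
                                 treatment = treatment_model_spec(),
                                 weight_spec = weight_model_spec(),
                                 times = 1:5, seed = 1L, truth = NULL) {
  design <- msm_design("history", K)
  p <- length(design$columns)
  nt <- length(times)
  cc_arr <- array(NA_real_, c(replications, nt, p))
  surv_arr <- array(NA_real_, c(replications, 2L, nt),
                    dimnames = list(NULL, c("never", "always"), NULL))
  nev <- never_treated(K)
  alw <- always_treated(K)
  failures <- 0L
  for (r in seq_len(replications)) {
    res <- tryCatch({
      panel <- simulate_observational(n, K, hazard, covariates, treatment,
                                      seed = derive_replicate_seed(seed, r))
      obs <- observed_panel(panel)
      fits <- fit_treatment_models(obs, weight_spec)
      sw <- compute_stabilized_weights(obs, fits)
      cp <- expand_to_counting_process(obs, design, weights = sw)
      cc <- fit_weighted_aalen(cp, design)
      list(cc = cumulative_coefficients_at(cc, times),
           nev = survival_from_cumcoef(cc, nev, times),
           alw = survival_from_cumcoef(cc, alw, times))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      next
    }
    cc_arr[r, , ] <- res$cc
    surv_arr[r, "never", ] <- res$nev
    surv_arr[r, "always", ] <- res$alw
  }
  out <- structure(list(times = times, columns = design$columns,
                        cumcoef = cc_arr, surv = surv_arr,
                        failures = failures, n = n,
                        replications = replications, seed = seed),
                   class = "msm_study")
  if (!is.null(truth)) out$summary <- summarize_study(out, truth)
  out
}

#' @export
print.msm_study <- function(x, ...) {
  cat("MSM-IPTW simulation study:", x$replications, "replicates of n =",
      x$n, "(", x$failures, "failed )\n")
  if (!is.null(x$summary)) {
    cat("\n")
    print(x$summary)
  }
  invisible(x)
}

#' Summarize a simulation study against the truth
#'
#' Per estimand (each cumulative coefficient and each counterfactual survival
#' probability, at each grid time): true value, mean estimate, bias
#' (`mean - truth`), empirical SE (SD across replications) and Monte-Carlo SE
#' of the bias (`empirical SE / sqrt(replications)`).  With a single
#' replicate the SEs are reported as `NA`.
#'
#' @param study A [run_simulation_study()] result (or a compatible list of
#'   estimate arrays).
#' @param truth A [compute_truth()] result on the same grid.
#' @param bands Also compute pointwise 2.5/97.5 empirical percentile bands.
#' @return A data frame of class `study_summary` with columns `estimand`,
#'   `time`, `truth`, `mean`, `bias`, `emp_se`, `mcse_bias` (and the band
#'   columns if requested).
#' @export
summarize_study <- function(study, truth, bands = FALSE) {
  if (!identical(as.numeric(study$times), as.numeric(truth$times)))
    stop("estimate and truth grids are not aligned", call. = FALSE)
  rows <- list()
  add <- function(name, t_idx, est_vec, true_val) {
    est_vec <- est_vec[!is.na(est_vec)]
    R <- length(est_vec)
    emp <- if (R > 1L) stats::sd(est_vec) else NA_real_
    row <- data.frame(estimand = name, time = study$times[t_idx],
                      truth = true_val, mean = mean(est_vec),
                      bias = mean(est_vec) - true_val,
                      emp_se = emp,
                      mcse_bias = if (R > 1L) emp / sqrt(R) else NA_real_)
    if (bands) {
      q <- stats::quantile(est_vec, c(0.025, 0.975), names = FALSE)
      row$lower <- q[1]
      row$upper <- q[2]
    }
    rows[[length(rows) + 1L]] <<- row
  }
  for (j in seq_along(study$columns))
    for (ti in seq_along(study$times))
      add(study$columns[j], ti, study$cumcoef[, ti, j], truth$cumcoef[ti, j])
  for (g in c("never", "always"))
    for (ti in seq_along(study$times))
      add(paste0("surv_", g), ti, study$surv[, g, ti], truth$surv[g, ti])
  out <- do.call(rbind, rows)
  class(out) <- c("study_summary", "data.frame")
  out
}

#' @export
print.study_summary <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
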