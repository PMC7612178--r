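#' Longitudinal cohort panel
#'
#' A `cohort_panel` is a long-format data frame with one row per person per
#' at-risk visit, carrying treatment `A`, confounder `L` and the at-risk flag,
#' plus per-person columns repeated on every row: frailty `U`, event time `T`
#' (`NA` if no event was observed), event indicator and censoring time `C`
#' (administrative default `K + 1`).
#'
#' Invariants enforced by the validator: visits per person are consecutive
#' integers starting at 0; at most one event per person; the event indicator
#' is 1 iff `T <= C`; `A` and `L` are present exactly on at-risk rows.
#'
#' @param data A data frame with columns `id`, `visit`, `A`, `L`, `atrisk`,
#'   `U`, `T`, `event`, `C` (and optionally `regime`).
#' @param K Last scheduled visit index.
#' @return A validated object of class `cohort_panel`.
#' @seealso [read_panel()], [expand_to_counting_process()], [observed_panel()]
#' @export
cohort_panel <- function(data, K) {
  required <- c("id", "visit", "A", "L", "atrisk", "U", "T", "event", "C")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- as.data.frame(data)[, c(required, intersect("regime", names(data)))]
  data <- data[order(data$id, data$visit), , drop = FALSE]
  rownames(data) <- NULL
  out <- structure(data, K = as.integer(K),
                   class = c("cohort_panel", "data.frame"))
  validate_panel(out)
  out
}

#' @rdname cohort_panel
#' @param panel A `cohort_panel`.
#' @export
validate_panel <- function(panel) {
  K <- attr(panel, "K")
  if (is.null(K)) stop("panel lacks its K attribute", call. = FALSE)
  split_idx <- split(seq_len(nrow(panel)), panel$id)
  for (idx in split_idx) {
    v <- panel$visit[idx]
    if (!identical(as.integer(v), seq.int(0L, length.out = length(v))))
      stop("non-consecutive visit sequence for person id ", panel$id[idx[1]],
           call. = FALSE)
    Ti <- panel$T[idx[1]]
    Ci <- panel$C[idx[1]]
    ev <- panel$event[idx[1]]
    if (!is.na(Ti) && Ti <= 0) stop("event time must be positive for id ",
                                    panel$id[idx[1]], call. = FALSE)
    expected_ev <- as.integer(!is.na(Ti) && Ti <= Ci)
    if (ev != expected_ev)
      stop("event indicator inconsistent with T and C for id ",
           panel$id[idx[1]], call. = FALSE)
    last <- v[length(v)]
    followup <- min(if (is.na(Ti)) Inf else Ti, Ci)
    if (last > ceiling(followup) - 1e-12 && last > 0)
      stop("visit rows extend past follow-up for id ", panel$id[idx[1]],
           call. = FALSE)
  }
  if (any(panel$atrisk[!is.na(panel$A)] != 1))
    stop("treatment present on a row not at risk", call. = FALSE)
  if (any(is.na(panel$A[panel$atrisk == 1])) ||
      any(is.na(panel$L[panel$atrisk == 1])))
    stop("A and L must be present on all at-risk rows", call. = FALSE)
  invisible(panel)
}

#' @export
print.cohort_panel <- function(x, ...) {
  n <- length(unique(x$id))
  K <- attr(x, "K")
  ev <- tapply(x$event, x$id, function(e) e[1])
  cat("cohort_panel: ", n, " persons, visits 0..", K, ", ",
      sum(ev), " events (", format(100 * mean(ev), digits = 3),
      "%), admin censoring at ", K + 1, "\n", sep = "")
  fl <- attr(x, "floored_hazard_count")
  if (!is.null(fl) && fl > 0)
    cat("  note:", fl, "negative hazard evaluation(s) floored at 0\n")
  if (!is.null(x$regime))
    cat("  regimes:", length(unique(x$regime)), "\n")
  utils::head(as.data.frame(x), 4L) |> print()
  invisible(x)
}

#' Observed view of a panel
#'
#' Returns a copy of the panel with the unmeasured frailty `U` masked
#' (set to `NA`).  Estimation functions operate on this view; only the
#' simulator and the g-formula oracle may read `U`.
#'
#' @param panel A `cohort_panel`.
#' @return A `cohort_panel` with `U` set to `NA`.
#' @export
observed_panel <- function(panel) {
  panel$U <- NA_real_
  panel
}

#' Read and write cohort panels as CSV
#'
#' Long-format CSV with a header row, comma separator, '.' decimal mark and
#' floats written with 10 significant digits.  `write_panel()` followed by
#' `read_panel()` is the identity on valid panels (to that precision).
#'
#' @param path File path.
#' @param K Last visit index; if `NULL`, inferred as `max(C) - 1`.
#' @return `read_panel()` returns a `cohort_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path, K = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "visit", "A", "L", "atrisk", "U", "T", "event", "C")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("panel file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(K)) K <- as.integer(round(max(df$C))) - 1L
  cohort_panel(df, K = K)
}

#' @rdname read_panel
#' @param panel A `cohort_panel`.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  df <- as.data.frame(panel)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Expand a panel to counting-process (start-stop) form
#'
#' One row per person per at-risk interval `[k, min(k + 1, T, C))`, with the
#' event flag on the terminal row iff the event was observed, MSM design
#' columns evaluated from the treatment history at visit `k`, and a weight
#' column (default 1, or merged from a stabilized-weight table).
#'
#' @param panel A `cohort_panel`.
#' @param design An [msm_design()].
#' @param weights Optional stabilized-weight table from
#'   [compute_stabilized_weights()] (columns `id`, `visit`, `sw`).
#' @return A data frame of class `counting_process` with columns `id`,
#'   `tstart`, `tstop`, `event`, the design columns, and `weight`.
#' @export
expand_to_counting_process <- function(panel, design, weights = NULL) {
  validate_panel(panel)
  K <- attr(panel, "K")
  ids <- panel$id
  k <- panel$visit
  Ti <- panel$T
  Ci <- panel$C
  followup <- pmin(ifelse(is.na(Ti), Inf, Ti), Ci)
  tstop <- pmin(k + 1, followup)
  ev_row <- as.integer(panel$event == 1 & !is.na(Ti) & Ti <= k + 1 & Ti > k)
  keep <- tstop > k
  X <- design_columns(design, panel)
  out <- data.frame(id = ids, tstart = as.numeric(k), tstop = tstop,
                    event = ev_row, check.names = FALSE)
  out <- cbind(out, X)
  out$weight <- 1
  if (!is.null(weights)) {
    m <- match(paste(ids, k), paste(weights$id, weights$visit))
    if (anyNA(m))
      stop("weight table does not cover every at-risk person-visit",
           call. = FALSE)
    out$weight <- weights$sw[m]
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, K = K, design = design,
            class = c("counting_process", "data.frame"))
}

#' @export
print.counting_process <- function(x, ...) {
  cat("counting_process:", nrow(x), "intervals,",
      length(unique(x$id)), "persons,", sum(x$event), "events\n")
  utils::head(as.data.frame(x), 4L) |> print()
  invisible(x)
}
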