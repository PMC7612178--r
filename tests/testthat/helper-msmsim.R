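# Small fixtures built in code.

# report every failure: never let the progress reporter cut the run short
options(testthat.progress.max_fails = Inf)

# hand-built two-person panel: person 1 has an event at 1.4, person 2 is
# administratively censored at K + 1 = 3
tiny_panel <- function() {
  cohort_panel(data.frame(
    id = c(1L, 1L, 2L, 2L, 2L),
    visit = c(0L, 1L, 0L, 1L, 2L),
    A = c(0L, 1L, 1L, 1L, 0L),
    L = c(0.2, -0.5, 1.1, 0.9, 0.3),
    atrisk = 1L,
    U = c(0.05, 0.05, -0.1, -0.1, -0.1),
    T = c(1.4, 1.4, NA, NA, NA),
    event = c(1L, 1L, 0L, 0L, 0L),
    C = 3), K = 2L)
}

# independent dense-matrix Aalen oracle: sequential loop over event times,
# explicit risk sets, no shared code with the package fitter
brute_aalen <- function(data, cols) {
  te <- sort(unique(data$tstop[data$event == 1]))
  inc <- matrix(0, length(te), length(cols))
  for (e in seq_along(te)) {
    risk <- data$tstart < te[e] & data$tstop >= te[e]
    X <- as.matrix(data[risk, cols, drop = FALSE])
    W <- diag(data$weight[risk], nrow = sum(risk))
    dN <- as.numeric(data$event[risk] == 1 & data$tstop[risk] == te[e])
    inc[e, ] <- solve(t(X) %*% W %*% X, t(X) %*% W %*% dN)
  }
  list(times = te, increments = inc, cum = apply(inc, 2, cumsum))
}

# per-person conditional hazard of the default additive generator at visit k
default_hazard_value <- function(A, L, U) 0.7 - 0.2 * A + 0.05 * L + 0.05 * U
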