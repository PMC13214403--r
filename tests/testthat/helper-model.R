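# Shared fixtures and independent oracles, built in code at test time.

# life table with a constant annual death probability (closed at max_age)
const_life <- function(q, max_age = 120L) {
  qx <- rep(q, max_age + 1L)
  qx[max_age + 1L] <- 1
  life_table(0:max_age, qx)
}

base_params <- function(...) ll_parameters(...)

surgery_init <- function() {
  s <- model_states("surgery")
  stats::setNames(as.numeric(s == "LLL"), s)
}

no_treatment_init <- function() {
  s <- model_states("no_treatment")
  stats::setNames(as.numeric(s == "NormalLife"), s)
}

# Individual-level Monte Carlo microsimulation: an independent brute-force
# oracle for the cohort engine. Counts of simulated individuals are pushed
# through each cycle's matrix with multinomial draws.
microsim_occupancy <- function(matrices, init, n_ind = 1e5L) {
  n_state <- ncol(matrices[[1L]])
  counts <- matrix(0L, nrow = length(matrices) + 1L, ncol = n_state,
                   dimnames = list(NULL, colnames(matrices[[1L]])))
  counts[1L, ] <- stats::rmultinom(1L, n_ind, init)[, 1L]
  for (t in seq_along(matrices)) {
    nxt <- integer(n_state)
    for (s in which(counts[t, ] > 0L)) {
      nxt <- nxt + stats::rmultinom(1L, counts[t, s], matrices[[t]][s, ])[, 1L]
    }
    counts[t + 1L, ] <- nxt
  }
  counts / n_ind
}
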