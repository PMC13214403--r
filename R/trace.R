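#' Propagate a cohort through a sequence of transition matrices
#'
#' Starting from an initial occupancy distribution, applies each cycle's
#' transition matrix in turn and records the state-occupancy proportions.
#' The trace has `length(matrices) + 1` rows: row 1 is the initial
#' distribution (cycle 0) and row `t + 1` the distribution after `t`
#' transitions. Mass is conserved at every cycle and the final (absorbing)
#' state's occupancy is non-decreasing.
#'
#' @param init Numeric occupancy vector summing to 1; names, if present,
#'   must match the matrix dimnames.
#' @param matrices Non-empty list of conformable row-stochastic matrices,
#'   one per cycle (e.g. from [transition_matrices()]).
#' @param strategy Optional strategy label stored on the trace.
#' @param start_age Optional age at cycle 0, stored on the trace so exported
#'   traces can carry an age column.
#' @return A `cohort_trace`: numeric matrix of occupancies, one row per
#'   cycle (0..n), one column per state.
#' @export
#' @examples
#' p <- ll_parameters(n_cycles = 5)
#' lt <- gompertz_makeham_table()
#' tr <- run_trace(c(NormalLife = 1, Death = 0),
#'                 transition_matrices("no_treatment", p, lt))
#' rowSums(tr)
run_trace <- function(init, matrices, strategy = NULL, start_age = NULL) {
  if (!length(matrices)) stop("`matrices` must be non-empty", call. = FALSE)
  states <- colnames(matrices[[1L]])
  n_state <- ncol(matrices[[1L]])
  if (length(init) != n_state) {
    stop(sprintf("`init` has length %d but the matrices have %d states",
                 length(init), n_state), call. = FALSE)
  }
  if (any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    stop("`init` must be a non-negative occupancy vector summing to 1",
         call. = FALSE)
  }
  if (!is.null(names(init)) && !is.null(states) &&
      !identical(names(init), states)) {
    stop("`init` names do not match the matrix state labels", call. = FALSE)
  }
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (!is.matrix(m) || any(dim(m) != n_state)) {
      stop(sprintf("matrix %d is not conformable (%d states expected)",
                   i, n_state), call. = FALSE)
    }
    check_transition_matrix(m)
  }
  n <- length(matrices)
  occ <- matrix(0, nrow = n + 1L, ncol = n_state,
                dimnames = list(NULL, states))
  occ[1L, ] <- as.numeric(init)
  for (t in seq_len(n)) {
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% matrices[[t]]
  }
  structure(occ, class = c("cohort_trace", "matrix"),
            strategy = strategy, start_age = start_age)
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x) - 1L
  strat <- attr(x, "strategy")
  cat(sprintf("Cohort trace%s: %d cycles, %d states\n",
              if (is.null(strat)) "" else paste0(" (", strat, ")"),
              n, ncol(x)))
  dead <- x[nrow(x), ncol(x)]
  cat(sprintf("  occupancy of '%s' at cycle %d: %.4f\n",
              colnames(x)[ncol(x)], n, dead))
  show <- unique(pmin(c(0L, 1L, 2L, 5L, n), n))
  print(round(x[show + 1L, , drop = FALSE], 5))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  df <- data.frame(cycle = 0:(nrow(x) - 1L))
  sa <- attr(x, "start_age")
  if (!is.null(sa)) df$age <- sa + df$cycle
  cbind(df, as.data.frame(unclass(x)))
}
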