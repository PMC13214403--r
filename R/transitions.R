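#' State spaces of the two strategies
#'
#' The no-treatment strategy has two states: `NormalLife` and the absorbing
#' `Death`. The surgery strategy tracks the two-stage lengthening programme:
#' lower-limb lengthening (`LLL`), lower-limb complication (`LLComp`),
#' upper-limb lengthening (`ULL`), upper-limb complication (`ULComp`), then
#' lifelong normal life. Normal life is split into two bookkeeping states
#' with identical transition behaviour — `NormalLife_LLLOnly` for patients
#' who withdrew after the lower-limb stage and `NormalLife_Full` for those
#' who completed both stages — because the two carry different lifelong
#' utilities. Their occupancies sum to the single printed normal-life state.
#' `Death` is always last and absorbing.
#'
#' @param strategy `"surgery"` or `"no_treatment"`.
#' @return Character vector of ordered state labels.
#' @export
model_states <- function(strategy = c("surgery", "no_treatment")) {
  strategy <- match.arg(strategy)
  if (strategy == "no_treatment") {
    c("NormalLife", "Death")
  } else {
    c("LLL", "LLComp", "ULL", "ULComp",
      "NormalLife_LLLOnly", "NormalLife_Full", "Death")
  }
}

#' Single-cycle transition matrix, no-treatment strategy
#'
#' A 2x2 matrix: the living state loses mass `dp` to death each cycle;
#' death is absorbing.
#'
#' @param dp Probability of death within the cycle.
#' @return Row-stochastic matrix with dimnames from [model_states()].
#' @export
#' @examples
#' no_treatment_matrix(0.01)
no_treatment_matrix <- function(dp) {
  if (!is.numeric(dp) || length(dp) != 1L || !is.finite(dp) ||
      dp < 0 || dp > 1) {
    stop(sprintf("`dp` must be a probability in [0, 1] (got %s)",
                 format(dp)), call. = FALSE)
  }
  s <- model_states("no_treatment")
  matrix(c(1 - dp, dp,
           0,      1),
         nrow = 2L, byrow = TRUE, dimnames = list(s, s))
}

#' Single-cycle transition matrix, surgery strategy
#'
#' Builds the 7x7 matrix for one annual cycle. Surgical-state rows add the
#' surgical mortality `surg_dp` to the background death probability `dp`;
#' the complication branch takes `p_ll_comp` (or `p_ul_comp`), and the
#' remaining survivors either continue to the next stage or withdraw with
#' probability `p_withdraw` (lower-limb states only). Normal-life rows face
#' background mortality alone.
#'
#' A row is structurally infeasible when its stated outflows exceed 1 (for
#' instance `p_ll_comp + dp + surg_dp > 1`, which arises at very high ages
#' or under extreme sampled probabilities). `infeasible = "error"` raises an
#' error naming the row and its outflow sum; `infeasible = "absorb"`
#' replaces the row with a unit transition to `Death`, which is only
#' appropriate when the row's state cannot be occupied at that cycle (see
#' [transition_matrices()]).
#'
#' @param dp Background probability of death within the cycle.
#' @param params [ll_parameters()].
#' @param infeasible How to handle a row whose outflows exceed 1.
#' @return Row-stochastic 7x7 matrix.
#' @export
#' @examples
#' m <- surgery_matrix(0.001, ll_parameters())
#' rowSums(m)
surgery_matrix <- function(dp, params, infeasible = c("error", "absorb")) {
  infeasible <- match.arg(infeasible)
  if (!is.numeric(dp) || length(dp) != 1L || !is.finite(dp) ||
      dp < 0 || dp > 1) {
    stop(sprintf("`dp` must be a probability in [0, 1] (got %s)",
                 format(dp)), call. = FALSE)
  }
  stopifnot(inherits(params, "ll_parameters"))
  s <- model_states("surgery")
  m <- matrix(0, nrow = 7L, ncol = 7L, dimnames = list(s, s))
  die <- dp + params$surg_dp
  w <- params$p_withdraw

  row_fail <- function(row, outflow) {
    if (infeasible == "error") {
      stop(sprintf(
        "infeasible transition row '%s': stated outflows sum to %.6g > 1",
        row, outflow), call. = FALSE)
    }
    v <- numeric(7L)
    v[7L] <- 1
    v
  }

  # Lower limb lengthening
  out <- params$p_ll_comp + die
  m["LLL", ] <- if (out > 1) row_fail("LLL", out) else {
    rest <- 1 - out
    c(0, params$p_ll_comp, rest * (1 - w), 0, rest * w, 0, die)
  }
  # Lower limb complication
  m["LLComp", ] <- if (die > 1) row_fail("LLComp", die) else {
    rest <- 1 - die
    c(0, 0, rest * (1 - w), 0, rest * w, 0, die)
  }
  # Upper limb lengthening
  out <- params$p_ul_comp + die
  m["ULL", ] <- if (out > 1) row_fail("ULL", out) else {
    c(0, 0, 0, params$p_ul_comp, 0, 1 - out, die)
  }
  # Upper limb complication
  m["ULComp", ] <- if (die > 1) row_fail("ULComp", die) else {
    c(0, 0, 0, 0, 0, 1 - die, die)
  }
  m["NormalLife_LLLOnly", c("NormalLife_LLLOnly", "Death")] <- c(1 - dp, dp)
  m["NormalLife_Full", c("NormalLife_Full", "Death")] <- c(1 - dp, dp)
  m["Death", "Death"] <- 1
  m
}

#' Cycle-indexed transition matrices for one strategy
#'
#' Builds one transition matrix per annual cycle, with the background death
#' probability of cycle `t` looked up at age `start_age + t` plus the
#' mortality age shift. Surgical mortality is added only in surgical-state
#' rows.
#'
#' Because the cohort starts wholly in `LLL`, the four surgical states are
#' transient and empty from cycle 4 onward; their rows at later cycles can
#' never be exercised. Within the first `strict_cycles` cycles an infeasible
#' surgical row raises an error (a probabilistic sensitivity analysis treats
#' that as an invalid draw); at later cycles an infeasible row is redirected
#' to the absorbing death state, which keeps every matrix row-stochastic at
#' all ages without affecting the cohort trace.
#'
#' @inheritParams model_states
#' @param params [ll_parameters()].
#' @param life [life_table()] covering `start_age + n_cycles - 1 +
#'   age_shift`.
#' @param n_cycles Number of matrices to build; defaults to
#'   `params$n_cycles`.
#' @param strict_cycles Number of initial cycles in which an infeasible row
#'   is an error rather than redirected. The default 4 is the length of the
#'   longest surgical pathway (LLL, complication, ULL, complication).
#' @return List of `n_cycles` row-stochastic matrices.
#' @export
transition_matrices <- function(strategy = c("surgery", "no_treatment"),
                                params, life,
                                n_cycles = params$n_cycles,
                                strict_cycles = 4L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "ll_parameters"), inherits(life, "life_table"))
  ages <- params$start_age + 0:(n_cycles - 1L)
  dp <- tryCatch(
    dp_at(life, ages, params$age_shift),
    error = function(e) {
      stop(sprintf("cannot build %d-cycle matrix sequence: %s",
                   n_cycles, conditionMessage(e)), call. = FALSE)
    })
  build_matrices(strategy, params, dp, strict_cycles)
}

# dp is the precomputed per-cycle background death probability; shared by
# transition_matrices() and the PSA fast path (mortality is not sampled).
build_matrices <- function(strategy, params, dp, strict_cycles = 4L) {
  if (strategy == "no_treatment") {
    lapply(dp, no_treatment_matrix)
  } else {
    lapply(seq_along(dp), function(t) {
      surgery_matrix(dp[t], params,
                     infeasible = if (t <= strict_cycles) "error" else "absorb")
    })
  }
}

check_transition_matrix <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) {
    stop("transition matrix entries must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    i <- which.max(abs(rs - 1))
    stop(sprintf("transition matrix row %d sums to %.15g, not 1", i, rs[i]),
         call. = FALSE)
  }
  n <- nrow(m)
  if (m[n, n] != 1) {
    stop("the final (death) state must be absorbing", call. = FALSE)
  }
  invisible(m)
}
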