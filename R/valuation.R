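#' Per-state utilities and costs
#'
#' Maps parameters onto the state space of a strategy. Surgical-year
#' utilities are the stage's disutility multiplier times a base utility: by
#' default the post-stage utility of the pathway being operated on (`u_lll`
#' for the lower-limb states, `u_full` for the upper-limb states); with
#' `multiplier_base = "baseline"` in the parameters, the unoperated utility
#' `u_base` instead. Lifelong normal-life utilities are `u_lll` (withdrew
#' after the lower-limb stage) and `u_full` (completed both stages), or
#' `u_base` for the no-treatment strategy. Costs accrue on occupancy of the
#' procedure and complication states only; normal life carries no
#' incremental cost (shared costs cancel between strategies) and death
#' carries zero utility and cost.
#'
#' @param params [ll_parameters()].
#' @inheritParams model_states
#' @return List with named numeric vectors `utility` and `cost` over the
#'   strategy's states.
#' @export
#' @examples
#' state_values(ll_parameters(), "surgery")
state_values <- function(params, strategy = c("surgery", "no_treatment")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "ll_parameters"))
  s <- model_states(strategy)
  if (strategy == "no_treatment") {
    u <- c(NormalLife = params$u_base, Death = 0)
    cost <- c(NormalLife = 0, Death = 0)
  } else {
    base_l <- if (params$multiplier_base == "pathway") params$u_lll else params$u_base
    base_u <- if (params$multiplier_base == "pathway") params$u_full else params$u_base
    u <- c(LLL = params$m_lll * base_l,
           LLComp = params$m_llc * base_l,
           ULL = params$m_ull * base_u,
           ULComp = params$m_ulc * base_u,
           NormalLife_LLLOnly = params$u_lll,
           NormalLife_Full = params$u_full,
           Death = 0)
    cost <- c(LLL = params$c_lll,
              LLComp = params$c_comp,
              ULL = params$c_ull,
              ULComp = params$c_comp,
              NormalLife_LLLOnly = 0,
              NormalLife_Full = 0,
              Death = 0)
  }
  stopifnot(identical(names(u), s))
  list(utility = u, cost = cost)
}

#' Discount factor
#'
#' `(1 + rate)^(-cycle)`; cycle 0 is undiscounted. Vectorised over `cycle`.
#'
#' @param rate Annual discount rate, >= 0.
#' @param cycle Cycle index (years from present).
#' @return Numeric vector of factors in (0, 1].
#' @export
#' @examples
#' discount_factor(0.03, 0:3)
discount_factor <- function(rate, cycle) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop("`rate` must be a single non-negative number", call. = FALSE)
  }
  (1 + rate)^(-cycle)
}

#' Discounted QALYs and costs of a cohort trace
#'
#' Occupancy at cycle t earns cycle-t rewards: QALYs are
#' \eqn{\sum_t (1+r_h)^{-t} \sum_s occ(t,s)\, u(s)} over all rows of the
#' trace (cycle 0 included, undiscounted), and costs the analogue with the
#' cost rate and per-state costs.
#'
#' @param trace [run_trace()] output.
#' @param values [state_values()] over the same state set.
#' @param r_cost,r_health Annual discount rates.
#' @return Named numeric vector `c(qalys = , cost = )`.
#' @export
accumulate_trace <- function(trace, values, r_cost = 0.03, r_health = 0.03) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (!identical(colnames(trace), names(values$utility))) {
    stop("trace and state values are over different state sets",
         call. = FALSE)
  }
  cyc <- 0:(nrow(trace) - 1L)
  occ <- unclass(trace)
  qalys <- sum(discount_factor(r_health, cyc) * (occ %*% values$utility))
  cost <- sum(discount_factor(r_cost, cyc) * (occ %*% values$cost))
  c(qalys = qalys, cost = cost)
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes incremental QALYs and costs of the comparator over the reference
#' (the first element), the ICER, dominance status, and the net monetary
#' benefit \eqn{NMB_s(\lambda) = \lambda\,QALY_s - cost_s} of each strategy
#' at the willingness-to-pay threshold.
#'
#' The ICER is reported as `delta_cost / delta_qaly` when `delta_qaly > 0`.
#' When the comparator yields fewer QALYs, or the same, the ratio is not a
#' meaningful price per QALY gained and `icer` is `NA`, with the situation
#' described by `dominance` (`"comparator dominant"` when it is cheaper and
#' more effective, `"comparator dominated"` when costlier and less
#' effective, otherwise `"none"`).
#'
#' @param qalys,costs Named numeric vectors of length 2, reference strategy
#'   first.
#' @param wtp Willingness-to-pay threshold (EUR/QALY).
#' @return List of class `cea_comparison`: `qalys`, `costs`, `delta_qaly`,
#'   `delta_cost`, `icer`, `dominance`, `nmb`, `wtp`.
#' @export
#' @examples
#' cea_compare(c(no_treatment = 21.243, surgery = 27.197),
#'             c(no_treatment = 0, surgery = 49480))
cea_compare <- function(qalys, costs, wtp = 25000) {
  if (length(qalys) != 2L || length(costs) != 2L) {
    stop("exactly two strategies are compared (reference first)",
         call. = FALSE)
  }
  delta_qaly <- unname(qalys[2L] - qalys[1L])
  delta_cost <- unname(costs[2L] - costs[1L])
  icer <- if (delta_qaly > 0) delta_cost / delta_qaly else NA_real_
  dominance <- if (delta_qaly > 0 && delta_cost <= 0) {
    "comparator dominant"
  } else if (delta_qaly <= 0 && delta_cost >= 0 &&
             !(delta_qaly == 0 && delta_cost == 0)) {
    "comparator dominated"
  } else {
    "none"
  }
  nmb <- wtp * qalys - costs
  structure(list(qalys = qalys, costs = costs,
                 delta_qaly = delta_qaly, delta_cost = delta_cost,
                 icer = icer, dominance = dominance, nmb = nmb, wtp = wtp),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  tab <- data.frame(QALYs = round(x$qalys, 3),
                    Cost = round(x$costs, 0),
                    NMB = round(x$nmb, 0),
                    row.names = names(x$qalys))
  print(tab)
  cat(sprintf("Incremental: %.3f QALYs, EUR %s\n",
              x$delta_qaly, format(round(x$delta_cost), big.mark = ",")))
  if (is.na(x$icer)) {
    cat(sprintf("ICER: undefined (%s)\n", x$dominance))
  } else {
    cat(sprintf("ICER: EUR %s/QALY (WTP EUR %s/QALY)\n",
                format(round(x$icer), big.mark = ","),
                format(x$wtp, big.mark = ",")))
  }
  invisible(x)
}

# Shared deterministic engine: dp is the per-cycle background death
# probability vector (length n_cycles). Used by ll_model() and per-draw by
# run_psa(), where mortality is fixed and dp need not be recomputed.
model_run <- function(params, dp, keep_traces = FALSE) {
  strategies <- c("no_treatment", "surgery")
  qalys <- costs <- c(no_treatment = NA_real_, surgery = NA_real_)
  traces <- if (keep_traces) list() else NULL
  for (s in strategies) {
    mats <- build_matrices(s, params, dp)
    init <- as.numeric(model_states(s) == if (s == "surgery") "LLL" else "NormalLife")
    names(init) <- model_states(s)
    tr <- run_trace(init, mats, strategy = s, start_age = params$start_age)
    acc <- accumulate_trace(tr, state_values(params, s),
                            r_cost = params$r_cost, r_health = params$r_health)
    qalys[s] <- acc["qalys"]
    costs[s] <- acc["cost"]
    if (keep_traces) traces[[s]] <- tr
  }
  list(qalys = qalys, costs = costs, traces = traces)
}

#' Fit the limb-lengthening cost-effectiveness model
#'
#' Runs the deterministic (base-case) Markov cohort model for both
#' strategies: builds the cycle-indexed transition matrices against the
#' supplied life table, propagates each cohort over the annual horizon,
#' attaches utilities and costs, discounts, and compares the strategies on
#' QALYs, costs, ICER and net monetary benefit.
#'
#' @param params [ll_parameters()].
#' @param life [life_table()]; by default the synthetic Gompertz-Makeham
#'   table.
#' @return Object of class `ll_cea` with elements `parameters`, `life`,
#'   `traces` (one [run_trace()] per strategy), `qalys`, `costs`,
#'   `comparison` (a [cea_compare()] result), and convenience fields
#'   `delta_qaly`, `delta_cost`, `icer`, `nmb`.
#' @seealso [simulate.ll_cea()] for the probabilistic sensitivity analysis,
#'   [voi_curves()], [run_budget()]
#' @export
#' @examples
#' fit <- ll_model(ll_parameters(), gompertz_makeham_table())
#' fit
ll_model <- function(params = ll_parameters(),
                     life = gompertz_makeham_table()) {
  stopifnot(inherits(params, "ll_parameters"), inherits(life, "life_table"))
  ages <- params$start_age + 0:(params$n_cycles - 1L)
  dp <- dp_at(life, ages, params$age_shift)
  run <- model_run(params, dp, keep_traces = TRUE)
  cmp <- cea_compare(run$qalys, run$costs, wtp = params$wtp)
  structure(list(parameters = params, life = life, traces = run$traces,
                 qalys = run$qalys, costs = run$costs,
                 comparison = cmp,
                 delta_qaly = cmp$delta_qaly, delta_cost = cmp$delta_cost,
                 icer = cmp$icer, nmb = cmp$nmb),
            class = "ll_cea")
}

#' @export
print.ll_cea <- function(x, ...) {
  p <- x$parameters
  cat("Markov cohort cost-effectiveness model: limb lengthening vs no treatment\n")
  cat(sprintf("%d annual cycles from age %d; discounting %g%% costs / %g%% health\n\n",
              p$n_cycles, p$start_age, 100 * p$r_cost, 100 * p$r_health))
  print(x$comparison)
  invisible(x)
}

#' @export
summary.ll_cea <- function(object, ...) {
  structure(list(comparison = object$comparison,
                 parameters = object$parameters,
                 final_death = vapply(object$traces, function(tr) {
                   tr[nrow(tr), "Death"]
                 }, numeric(1))),
            class = "summary.ll_cea")
}

#' @export
print.summary.ll_cea <- function(x, ...) {
  print(x$comparison)
  cat(sprintf("Death-state occupancy at the horizon: %s\n",
              paste(sprintf("%s %.4f", names(x$final_death), x$final_death),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.ll_cea <- function(object, ...) {
  p <- object$parameters
  unlist(p[vapply(p, is.numeric, logical(1))])
}

#' Probabilistic sensitivity analysis of a fitted model
#'
#' `simulate()` on a fitted `ll_cea` object reruns the model `nsim` times
#' with parameters drawn from their uncertainty distributions; equivalent to
#' [run_psa()] with the object's parameters and life table.
#'
#' @param object [ll_model()] fit.
#' @param nsim Number of Monte Carlo iterations.
#' @param seed Seed passed to [run_psa()].
#' @param ... Passed on to [run_psa()] (e.g. `specs`).
#' @return An `ll_psa` object; see [run_psa()].
#' @export
simulate.ll_cea <- function(object, nsim = 1000, seed = NULL, ...) {
  run_psa(object$parameters, object$life, n_iter = nsim, seed = seed, ...)
}
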