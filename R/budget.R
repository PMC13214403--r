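#' Per-patient incremental cost stream
#'
#' Expected undiscounted incremental cost incurred in each year since a
#' patient enters the programme: the surgery-strategy cohort trace's
#' occupancy-weighted per-state costs, year by year. Because costs accrue
#' only in the transient surgical states, the stream is zero from year 4
#' onward. Its discounted sum (at the cost rate, from entry) equals the
#' model's per-patient incremental cost.
#'
#' @param params [ll_parameters()].
#' @param life [life_table()].
#' @return Numeric vector of length `n_cycles + 1`; element `y + 1` is the
#'   expected cost in year `y` after entry.
#' @export
#' @examples
#' s <- cost_stream(ll_parameters(), gompertz_makeham_table())
#' s[1:6]
cost_stream <- function(params = ll_parameters(),
                        life = gompertz_makeham_table()) {
  stopifnot(inherits(params, "ll_parameters"), inherits(life, "life_table"))
  mats <- transition_matrices("surgery", params, life)
  states <- model_states("surgery")
  init <- as.numeric(states == "LLL")
  names(init) <- states
  tr <- run_trace(init, mats, strategy = "surgery",
                  start_age = params$start_age)
  vals <- state_values(params, "surgery")
  as.numeric(unclass(tr) %*% vals$cost)
}

#' Multi-cohort budget impact
#'
#' Translates the per-patient cost stream into an aggregate payer spend:
#' each year a new cohort of `patients_per_year` patients enters the
#' programme, and the spend of calendar year `y` (1-based) is the sum of
#' the cost-stream values of all cohorts active that year, discounted to
#' programme start (year 1 undiscounted) when `discounting =
#' "program_start"`. Costs falling beyond the horizon are excluded
#' (truncation), so the last cohorts contribute only their early years.
#' The result is exactly linear in `patients_per_year`.
#'
#' @param stream Per-patient cost stream from [cost_stream()].
#' @param patients_per_year New patients entering each year (15 at full
#'   uptake; 7 in the 50%-uptake scenario).
#' @param horizon Budget horizon in years.
#' @param r_cost Annual discount rate on costs.
#' @param discounting `"program_start"` (default) discounts every year's
#'   spend to the start of the programme; `"none"` reports undiscounted
#'   spend.
#' @param label Scenario label carried in the result.
#' @return `data.frame` of class `ll_budget` with columns `year`,
#'   `annual_spend`, `cumulative_spend` (EUR), and attributes `scenario`
#'   (the inputs) echoed.
#' @export
#' @examples
#' s <- cost_stream()
#' b <- run_budget(s, patients_per_year = 15, horizon = 15)
#' tail(b, 1)$cumulative_spend
run_budget <- function(stream, patients_per_year = 15, horizon = 15,
                       r_cost = 0.03,
                       discounting = c("program_start", "none"),
                       label = "full uptake") {
  discounting <- match.arg(discounting)
  if (!is.numeric(stream) || !length(stream) || any(stream < 0)) {
    stop("`stream` must be a non-negative numeric cost stream",
         call. = FALSE)
  }
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  if (patients_per_year < 0) {
    stop("`patients_per_year` must be >= 0", call. = FALSE)
  }
  annual <- numeric(horizon)
  for (y in seq_len(horizon)) {
    since_entry <- 0:(y - 1L)                  # cohorts entered years 1..y
    idx <- since_entry + 1L
    s <- ifelse(idx <= length(stream), stream[pmin(idx, length(stream))], 0)
    f <- if (discounting == "program_start") {
      discount_factor(r_cost, y - 1L)
    } else 1
    annual[y] <- patients_per_year * sum(s) * f
  }
  out <- data.frame(year = seq_len(horizon), annual_spend = annual,
                    cumulative_spend = cumsum(annual))
  structure(out, class = c("ll_budget", "data.frame"),
            scenario = list(patients_per_year = patients_per_year,
                            horizon = horizon, r_cost = r_cost,
                            discounting = discounting, label = label))
}

#' @export
print.ll_budget <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Budget impact (%s): %g patients/year over %d years, %s\n",
              sc$label, sc$patients_per_year, sc$horizon,
              if (sc$discounting == "program_start")
                sprintf("discounted at %g%% to programme start", 100 * sc$r_cost)
              else "undiscounted"))
  print(data.frame(year = x$year,
                   annual_spend = round(x$annual_spend),
                   cumulative_spend = round(x$cumulative_spend)),
        row.names = FALSE)
  cat(sprintf("Cumulative spend at year %d: EUR %s\n", sc$horizon,
              format(round(x$cumulative_spend[nrow(x)]), big.mark = ",")))
  invisible(x)
}
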