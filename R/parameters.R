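#' Model parameters
#'
#' Assemble and validate the full parameter set of the cost-effectiveness
#' model. Defaults are the base-case values of the source cost-utility
#' analysis: EQ-5D-Y utilities for unoperated, lower-limb-lengthened and
#' fully lengthened individuals, disutility multipliers for the surgical and
#' complication years, per-procedure costs, complication and withdrawal
#' probabilities, the elective paediatric orthopaedic surgical mortality
#' rate, 3% annual discounting on both costs and health, a willingness-to-pay
#' threshold of EUR 25,000/QALY, and a 90-cycle annual horizon.
#'
#' @param u_base Utility of non-lengthened individuals (dimensionless, 0-1).
#' @param u_lll Utility after lower-limb lengthening only.
#' @param u_full Utility after lower plus upper limb lengthening.
#' @param u_base_sd,u_lll_sd,u_full_sd Standard deviations reported with the
#'   three utilities; used by the PSA beta distributions, not by the base
#'   case.
#' @param m_lll,m_ull,m_llc,m_ulc Utility multipliers (0-1] applied during
#'   the lower-limb lengthening, upper-limb lengthening, lower-limb
#'   complication and upper-limb complication years.
#' @param p_ll_comp Probability of a complication (reoperation) during
#'   lower-limb lengthening.
#' @param p_ul_comp Probability of a complication during upper-limb
#'   lengthening.
#' @param p_withdraw Probability of discontinuing the programme after the
#'   lower-limb stage (remaining lower-limb-lengthened only).
#' @param c_lll,c_ull,c_comp Costs in EUR of the lower-limb procedure, the
#'   upper-limb procedure, and a complication procedure.
#' @param surg_dp Probability of dying during a surgical cycle (added to
#'   background mortality in surgical states).
#' @param age_shift Years added to age in the mortality lookup; the 10-year
#'   life-expectancy reduction for achondroplasia.
#' @param r_cost,r_health Annual discount rates for costs and health
#'   outcomes.
#' @param wtp Willingness-to-pay threshold, EUR per QALY.
#' @param start_age Age of the cohort at cycle 0 (years).
#' @param n_cycles Number of annual cycles.
#' @param incident_cases_per_year New eligible patients per year, used by
#'   the budget impact analysis.
#' @param multiplier_base Which utility the surgical-year multipliers scale:
#'   `"pathway"` (default) applies them to the post-stage utility of the
#'   pathway being operated on; `"baseline"` applies them to `u_base`.
#'
#' @return An object of class `ll_parameters` (a named list).
#' @seealso [ll_model()], [psa_distributions()]
#' @export
#' @examples
#' p <- ll_parameters()
#' p$c_lll
ll_parameters <- function(u_base = 0.711,
                          u_lll = 0.888,
                          u_full = 0.944,
                          u_base_sd = 0.266,
                          u_lll_sd = 0.111,
                          u_full_sd = 0.078,
                          m_lll = 0.7,
                          m_ull = 0.8,
                          m_llc = 0.8,
                          m_ulc = 0.75,
                          p_ll_comp = 0.8,
                          p_ul_comp = 0.1,
                          p_withdraw = 0.1,
                          c_lll = 28539,
                          c_ull = 10834,
                          c_comp = 6275,
                          surg_dp = 0.00013,
                          age_shift = 10L,
                          r_cost = 0.03,
                          r_health = 0.03,
                          wtp = 25000,
                          start_age = 12L,
                          n_cycles = 90L,
                          incident_cases_per_year = 15,
                          multiplier_base = c("pathway", "baseline")) {
  multiplier_base <- match.arg(multiplier_base)
  p <- list(u_base = u_base, u_lll = u_lll, u_full = u_full,
            u_base_sd = u_base_sd, u_lll_sd = u_lll_sd, u_full_sd = u_full_sd,
            m_lll = m_lll, m_ull = m_ull, m_llc = m_llc, m_ulc = m_ulc,
            p_ll_comp = p_ll_comp, p_ul_comp = p_ul_comp,
            p_withdraw = p_withdraw,
            c_lll = c_lll, c_ull = c_ull, c_comp = c_comp,
            surg_dp = surg_dp, age_shift = as.integer(age_shift),
            r_cost = r_cost, r_health = r_health, wtp = wtp,
            start_age = as.integer(start_age),
            n_cycles = as.integer(n_cycles),
            incident_cases_per_year = incident_cases_per_year,
            multiplier_base = multiplier_base)
  validate_ll_parameters(p)
  structure(p, class = "ll_parameters")
}

validate_ll_parameters <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    v
  }
  for (nm in c("u_base", "u_lll", "u_full")) {
    v <- num1(nm)
    if (v < 0 || v > 1) {
      stop(sprintf("`%s`: utility must be in [0, 1] (got %g)", nm, v),
           call. = FALSE)
    }
  }
  for (nm in c("u_base_sd", "u_lll_sd", "u_full_sd")) {
    if (num1(nm) < 0) {
      stop(sprintf("`%s`: standard deviation must be >= 0", nm),
           call. = FALSE)
    }
  }
  for (nm in c("m_lll", "m_ull", "m_llc", "m_ulc")) {
    v <- num1(nm)
    if (v <= 0 || v > 1) {
      stop(sprintf("`%s`: utility multiplier must be in (0, 1] (got %g)",
                   nm, v), call. = FALSE)
    }
  }
  for (nm in c("p_ll_comp", "p_ul_comp", "p_withdraw", "surg_dp")) {
    v <- num1(nm)
    if (v < 0 || v > 1) {
      stop(sprintf("`%s`: probability must be in [0, 1] (got %g)", nm, v),
           call. = FALSE)
    }
  }
  for (nm in c("c_lll", "c_ull", "c_comp")) {
    if (num1(nm) < 0) {
      stop(sprintf("`%s`: cost must be >= 0", nm), call. = FALSE)
    }
  }
  for (nm in c("r_cost", "r_health")) {
    v <- num1(nm)
    if (v < 0 || v >= 1) {
      stop(sprintf("`%s`: discount rate must be in [0, 1) (got %g)", nm, v),
           call. = FALSE)
    }
  }
  if (num1("wtp") < 0) stop("`wtp` must be >= 0", call. = FALSE)
  if (p$age_shift < 0) stop("`age_shift` must be >= 0", call. = FALSE)
  if (p$start_age < 0) stop("`start_age` must be >= 0", call. = FALSE)
  if (p$n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (num1("incident_cases_per_year") < 0) {
    stop("`incident_cases_per_year` must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ll_parameters <- function(x, ...) {
  cat("Limb-lengthening model parameters\n")
  cat(sprintf("  utilities: base %.3f, LLL-only %.3f, full %.3f\n",
              x$u_base, x$u_lll, x$u_full))
  cat(sprintf("  multipliers (LLL/ULL/LL-comp/UL-comp): %.2f / %.2f / %.2f / %.2f (base: %s)\n",
              x$m_lll, x$m_ull, x$m_llc, x$m_ulc, x$multiplier_base))
  cat(sprintf("  probabilities: LL comp %.2f, UL comp %.2f, withdraw %.2f, surgical death %.5f\n",
              x$p_ll_comp, x$p_ul_comp, x$p_withdraw, x$surg_dp))
  cat(sprintf("  costs (EUR): LLL %s, ULL %s, complication %s\n",
              format(x$c_lll, big.mark = ","), format(x$c_ull, big.mark = ","),
              format(x$c_comp, big.mark = ",")))
  cat(sprintf("  discounting: costs %.0f%%, health %.0f%%; WTP EUR %s/QALY\n",
              100 * x$r_cost, 100 * x$r_health, format(x$wtp, big.mark = ",")))
  cat(sprintf("  horizon: %d annual cycles from age %d; mortality age shift +%d y\n",
              x$n_cycles, x$start_age, x$age_shift))
  invisible(x)
}
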