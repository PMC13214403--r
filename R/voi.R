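check_wtp_grid <- function(wtp) {
  if (!is.numeric(wtp) || !length(wtp) || anyNA(wtp)) {
    stop("`wtp` must be a non-empty numeric grid", call. = FALSE)
  }
  if (any(wtp < 0)) stop("`wtp` values must be non-negative", call. = FALSE)
  if (is.unsorted(wtp, strictly = TRUE)) {
    stop("`wtp` grid must be strictly increasing", call. = FALSE)
  }
  wtp
}

# incremental NMB of surgery over no treatment, one column per lambda
incremental_nmb <- function(psa, wtp) {
  dq <- psa$qalys[, "surgery"] - psa$qalys[, "no_treatment"]
  dc <- psa$costs[, "surgery"] - psa$costs[, "no_treatment"]
  outer(dq, wtp) - dc
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy attains the maximum net monetary benefit. Ties are
#' awarded to the reference (no-treatment) strategy, a deterministic and
#' conservative rule; ties have probability zero for continuous draws.
#'
#' @param psa [run_psa()] result.
#' @param wtp Strictly increasing non-negative grid of thresholds
#'   (EUR/QALY). The default spans 0-50,000 in steps of 500, covering both
#'   the EUR 25,000 decision threshold and the EUR 60,000 upper bound
#'   discussed for Spain.
#' @return `data.frame` with columns `wtp`, `p_no_treatment`, `p_surgery`.
#' @export
#' @examples
#' p <- ll_parameters(n_cycles = 30)
#' psa <- run_psa(p, gompertz_makeham_table(), n_iter = 50, seed = 1)
#' head(ceac(psa))
ceac <- function(psa, wtp = seq(0, 50000, by = 500)) {
  stopifnot(inherits(psa, "ll_psa"))
  check_wtp_grid(wtp)
  inb <- incremental_nmb(psa, wtp)
  p_surgery <- colMeans(inb > 0)   # strict: ties go to the reference
  data.frame(wtp = wtp, p_no_treatment = 1 - p_surgery,
             p_surgery = p_surgery)
}

#' Cost-effectiveness acceptability frontier
#'
#' At each threshold, the strategy with the highest mean net monetary
#' benefit, together with that strategy's acceptability (its CEAC value).
#' The frontier switches strategy at the ICER of means; it need not
#' coincide with the 50%-probability crossover of the CEACs.
#'
#' @inheritParams ceac
#' @return `data.frame` with columns `wtp`, `frontier_strategy`,
#'   `frontier_p`.
#' @export
ceaf <- function(psa, wtp = seq(0, 50000, by = 500)) {
  stopifnot(inherits(psa, "ll_psa"))
  check_wtp_grid(wtp)
  cc <- ceac(psa, wtp)
  mean_dq <- mean(psa$qalys[, "surgery"] - psa$qalys[, "no_treatment"])
  mean_dc <- mean(psa$costs[, "surgery"] - psa$costs[, "no_treatment"])
  mean_inb <- wtp * mean_dq - mean_dc
  frontier <- ifelse(mean_inb > 0, "surgery", "no_treatment")
  data.frame(wtp = wtp, frontier_strategy = frontier,
             frontier_p = ifelse(frontier == "surgery",
                                 cc$p_surgery, cc$p_no_treatment))
}

#' Expected value of perfect information
#'
#' Per-patient EVPI at each threshold:
#' \eqn{EVPI(\lambda) = E[\max_s NMB_s(\lambda)] - \max_s E[NMB_s(\lambda)]},
#' the expected gain from resolving all parameter uncertainty before
#' choosing a strategy. Computed on incremental net benefit, so it is
#' invariant to costs shared by both strategies. Always non-negative, and
#' zero when all iterations agree.
#'
#' @inheritParams ceac
#' @return `data.frame` with columns `wtp`, `evpi` (EUR per patient).
#' @export
evpi <- function(psa, wtp = seq(0, 50000, by = 500)) {
  stopifnot(inherits(psa, "ll_psa"))
  check_wtp_grid(wtp)
  inb <- incremental_nmb(psa, wtp)
  ev <- colMeans(pmax(inb, 0)) - pmax(colMeans(inb), 0)
  data.frame(wtp = wtp, evpi = ev)
}

#' Decision-uncertainty curves over a willingness-to-pay grid
#'
#' Combines [ceac()], [ceaf()] and [evpi()] into a single table, one row
#' per threshold.
#'
#' @inheritParams ceac
#' @return `data.frame` of class `voi_curves` with columns `wtp`,
#'   `p_no_treatment`, `p_surgery`, `frontier_strategy`, `frontier_p`,
#'   `evpi`.
#' @export
#' @examples
#' p <- ll_parameters(n_cycles = 30)
#' psa <- run_psa(p, gompertz_makeham_table(), n_iter = 50, seed = 1)
#' vc <- voi_curves(psa)
#' vc[vc$wtp == 25000, ]
voi_curves <- function(psa, wtp = seq(0, 50000, by = 500)) {
  cc <- ceac(psa, wtp)
  cf <- ceaf(psa, wtp)
  ev <- evpi(psa, wtp)
  out <- cbind(cc, cf[, c("frontier_strategy", "frontier_p")],
               evpi = ev$evpi)
  class(out) <- c("voi_curves", "data.frame")
  out
}

#' @export
plot.voi_curves <- function(x, which = c("ceac", "evpi"), ...) {
  which <- match.arg(which)
  if (which == "ceac") {
    graphics::plot(x$wtp, x$p_surgery, type = "l", col = "red3",
                   ylim = c(0, 1), xlab = "Willingness to pay (EUR/QALY)",
                   ylab = "P(highest NMB)",
                   main = "Cost-effectiveness acceptability", ...)
    graphics::lines(x$wtp, x$p_no_treatment, col = "blue3")
    graphics::points(x$wtp, x$frontier_p, pch = 1, cex = 0.4)
    graphics::legend("right", legend = c("surgery", "no treatment", "frontier"),
                     col = c("red3", "blue3", "black"),
                     lty = c(1, 1, NA), pch = c(NA, NA, 1), bty = "n")
  } else {
    graphics::plot(x$wtp, x$evpi, type = "l",
                   xlab = "Willingness to pay (EUR/QALY)",
                   ylab = "EVPI (EUR per patient)",
                   main = "Expected value of perfect information", ...)
  }
  invisible(x)
}
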