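# Power analysis for the 2x2 design via the noncentral t distribution.
#
# The three printed effects map onto three t-test designs:
#   stress      -> paired_within: one-sample t on all N difference scores
#                  (delta = d * sqrt(n1), df = n1 - 1)
#   group       -> between_on_averages: two-sample t on the two-scan subject
#                  averages; with the two scans treated as uncorrelated, a
#                  single-scan-scale Cohen's d inflates by sqrt(2)
#                  (delta = d * sqrt(2) * sqrt(n1 n2 / (n1 + n2)), df = N - 2)
#   interaction -> between_on_differences: two-sample t on difference scores
#                  (delta = d * sqrt(n1 n2 / (n1 + n2)), df = N - 2)
# Both the exact noncentral-t evaluation and a normal approximation are
# provided; minimum detectable effect sizes are found by monotone bisection.

POWER_DESIGNS <- c("paired_within", "between_on_averages",
                   "between_on_differences")

power_noncentrality <- function(design, d, n1, n2) {
  switch(design,
    paired_within = list(ncp = d * sqrt(n1), df = n1 - 1),
    between_on_differences = list(ncp = d * sqrt(n1 * n2 / (n1 + n2)),
                                  df = n1 + n2 - 2),
    between_on_averages = list(ncp = d * sqrt(2) * sqrt(n1 * n2 / (n1 + n2)),
                               df = n1 + n2 - 2)
  )
}

#' Power of a two-tailed t test for the 2x2 design
#'
#' @param design one of `"paired_within"` (stress effect),
#'   `"between_on_averages"` (group effect) or `"between_on_differences"`
#'   (interaction effect).
#' @param d Cohen's d on the design's native scale (see Details); must be
#'   positive.
#' @param n1 first (or only) group size.
#' @param n2 second group size; unused for `paired_within`.
#' @param alpha two-tailed significance level (default 0.05).
#' @param method `"nct"` for the exact noncentral t (default) or `"normal"`
#'   for the normal approximation.
#' @return a `power_result` list: design, d, power, noncentrality, df,
#'   alpha, method.
#' @details For `between_on_averages` the d is on the single-scan scale and
#'   the two scans are assumed uncorrelated, so the noncentrality gains a
#'   factor sqrt(2) (averaging two independent scans halves the variance).
#'   The zero between-scan correlation assumption is a modelling choice of
#'   this mapping, not an estimate.
#' @export
power_of <- function(design = POWER_DESIGNS, d, n1, n2 = NULL,
                     alpha = 0.05, method = c("nct", "normal")) {
  design <- match.arg(design)
  method <- match.arg(method)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("d must be a single positive number", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, n1 >= 2)
  if (design != "paired_within" && (is.null(n2) || n2 < 2)) {
    stop("design ", design, " needs n2 >= 2", call. = FALSE)
  }
  nc <- power_noncentrality(design, d, n1, n2)
  if (method == "nct") {
    tcrit <- stats::qt(1 - alpha / 2, nc$df)
    power <- stats::pt(tcrit, nc$df, ncp = nc$ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, nc$df, ncp = nc$ncp)
  } else {
    zcrit <- stats::qnorm(1 - alpha / 2)
    power <- stats::pnorm(nc$ncp - zcrit) + stats::pnorm(-nc$ncp - zcrit)
  }
  structure(list(design = design, d = d, power = power,
                 noncentrality = nc$ncp, df = nc$df, alpha = alpha,
                 method = method),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<%s (%s): d = %.4f, power = %.4f (df = %g, ncp = %.3f)>\n",
              x$design, x$method, x$d, x$power, x$df, x$noncentrality))
  invisible(x)
}

#' Minimum detectable effect size
#'
#' The Cohen's d at which [power_of()] attains `target_power`, found by
#' monotone bisection on [1e-6, 10] to 1e-8.
#'
#' @inheritParams power_of
#' @param target_power desired power, in (alpha, 1).
#' @return a `power_result` list with `d` set to the minimum detectable
#'   effect size and `power` the (recomputed) attained power.
#' @export
mdes <- function(design = POWER_DESIGNS, target_power, n1, n2 = NULL,
                 alpha = 0.05, method = c("nct", "normal")) {
  design <- match.arg(design)
  method <- match.arg(method)
  stopifnot(is.numeric(target_power), length(target_power) == 1L)
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must lie in (alpha, 1)", call. = FALSE)
  }
  pw <- function(d) power_of(design, d, n1, n2, alpha, method)$power
  lo <- 1e-6
  hi <- 10
  if (pw(hi) < target_power) stop("power ", target_power,
                                  " unreachable with d <= 10", call. = FALSE)
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (pw(mid) < target_power) lo <- mid else hi <- mid
  }
  power_of(design, (lo + hi) / 2, n1, n2, alpha, method)
}

#' Minimum-detectable-effect table for the 2x2 design
#'
#' One row per power level, one column per effect: stress (paired t on all
#' n1 + n2 subjects), group (between-groups t on two-scan averages) and
#' interaction (between-groups t on difference scores).
#'
#' @param n1,n2 group sizes.
#' @param powers power levels (default `c(0.80, 0.85, 0.90)`).
#' @param alpha two-tailed alpha.
#' @param method `"nct"` or `"normal"`.
#' @return data.frame with columns power, stress_d, group_d, interaction_d.
#' @export
power_table <- function(n1, n2, powers = c(0.80, 0.85, 0.90), alpha = 0.05,
                        method = c("nct", "normal")) {
  method <- match.arg(method)
  N <- n1 + n2
  rows <- lapply(powers, function(pw) {
    data.frame(
      power = pw,
      stress_d = mdes("paired_within", pw, n1 = N, alpha = alpha,
                      method = method)$d,
      group_d = mdes("between_on_averages", pw, n1 = n1, n2 = n2,
                     alpha = alpha, method = method)$d,
      interaction_d = mdes("between_on_differences", pw, n1 = n1, n2 = n2,
                           alpha = alpha, method = method)$d
    )
  })
  do.call(rbind, rows)
}
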