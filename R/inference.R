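# Statistical battery for the two-group (PTSD vs MDD), two-scan (pre vs post
# stressor) repeated-measures design.
#
# The 2x2 mixed-model GLM is implemented through its exact algebraic
# reduction to t contrasts: with one two-level between factor and one
# two-level within factor, the between-subjects F equals the square of the
# independent-samples t on subject means, the interaction F equals the
# square of the independent-samples t on difference scores, and the within
# (stress) F equals the square of a one-sample t on the unweighted average
# of the two group mean differences with the pooled difference variance.
# All three use df2 = N - 2.

GROUP_LEVELS <- c("PTSD", "MDD")

#' Construct a cohort table
#'
#' One row per subject, with the pre- and post-stressor network strength as
#' the repeated outcome.
#'
#' @param subject_id unique subject labels.
#' @param group character/factor, one of `"PTSD"`, `"MDD"` per subject (any
#'   two-level coding is accepted; levels are taken in order of first
#'   appearance when neither label matches).
#' @param strength_pre,strength_post numeric outcome per scan; no missing
#'   values.
#' @param covariates optional data.frame of per-subject covariates (age,
#'   sex, motion, medication, comorbidity flags, ...).
#' @param scores optional data.frame of symptom scores (QIDS, PCL5_total,
#'   CAPS subscales, ...).
#' @return a data.frame of class `cohort_table`.
#' @export
cohort_table <- function(subject_id, group, strength_pre, strength_post,
                         covariates = NULL, scores = NULL) {
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject ids", call. = FALSE)
  group <- as.character(group)
  stopifnot(length(group) == n, length(strength_pre) == n,
            length(strength_post) == n)
  if (!all(is.finite(strength_pre)) || !all(is.finite(strength_post))) {
    stop("missing/non-finite strength values", call. = FALSE)
  }
  levels <- if (all(group %in% GROUP_LEVELS)) GROUP_LEVELS else unique(group)
  if (length(unique(group)) != 2L) {
    stop("cohort must contain exactly two groups", call. = FALSE)
  }
  out <- data.frame(subject_id = subject_id,
                    group = factor(group, levels = levels),
                    strength_pre = as.numeric(strength_pre),
                    strength_post = as.numeric(strength_post),
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    out <- cbind(out, covariates)
    attr(out, "covariate_names") <- names(covariates)
  }
  if (!is.null(scores)) {
    stopifnot(nrow(scores) == n)
    out <- cbind(out, scores)
    attr(out, "score_names") <- names(scores)
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("subject_id", "group", "strength_pre", "strength_post")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- factor(cohort$group)
  if (nlevels(g) != 2L) stop("cohort must have exactly two groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("each group needs >= 2 subjects", call. = FALSE)
  }
  g
}

anova_result <- function(effect, F, df1, df2) {
  list(effect = effect, F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' 2x2 mixed (repeated-measures) ANOVA
#'
#' Group (between, two levels) by scan (within, two levels) model returning
#' the group, stress and group-by-stress interaction F tests, each on
#' (1, N-2) degrees of freedom. Contrasts use unweighted group means
#' (Type-III style), so the tests are exact t-test reductions:
#' group = independent t on subject means, interaction = independent t on
#' post-pre differences, stress = one-sample t on the unweighted average of
#' the two group mean differences against zero using the pooled difference
#' variance.
#'
#' @param cohort a [cohort_table()] (or data.frame with the same columns).
#' @param within_labels names of the two within-subject conditions, used
#'   only for labelling (default `c("pre", "post")`).
#' @return list with elements `group`, `stress`, `interaction`, each an
#'   `anova_result` list (effect, F, df1, df2, p), plus `n1`, `n2`,
#'   `convention = "unweighted-means"`.
#' @export
mixed_anova_2x2 <- function(cohort, within_labels = c("pre", "post")) {
  g <- check_cohort(cohort)
  pre <- cohort$strength_pre
  post <- cohort$strength_post
  i1 <- g == levels(g)[1L]
  i2 <- g == levels(g)[2L]
  n1 <- sum(i1); n2 <- sum(i2); N <- n1 + n2

  means <- (pre + post) / 2          # between-subject component
  d <- post - pre                    # within-subject component

  pooled_var <- function(x) {
    ((n1 - 1) * stats::var(x[i1]) + (n2 - 1) * stats::var(x[i2])) / (N - 2)
  }

  # group main effect: independent t on subject means
  vM <- pooled_var(means)
  if (vM <= 0) stop("zero variance in subject means", call. = FALSE)
  tG <- (mean(means[i1]) - mean(means[i2])) / sqrt(vM * (1 / n1 + 1 / n2))

  # interaction: independent t on difference scores
  vD <- pooled_var(d)
  if (vD <= 0) stop("zero variance in difference scores", call. = FALSE)
  tI <- (mean(d[i1]) - mean(d[i2])) / sqrt(vD * (1 / n1 + 1 / n2))

  # stress main effect: unweighted mean of the two group mean differences
  est <- (mean(d[i1]) + mean(d[i2])) / 2
  tS <- est / sqrt(vD * (1 / n1 + 1 / n2) / 4)

  out <- list(
    group = anova_result("group", tG^2, 1L, N - 2L),
    stress = anova_result("stress", tS^2, 1L, N - 2L),
    interaction = anova_result("interaction", tI^2, 1L, N - 2L),
    n1 = n1, n2 = n2, groups = levels(g), within_labels = within_labels,
    convention = "unweighted-means"
  )
  class(out) <- "mixed_anova"
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("2x2 mixed ANOVA (%s vs %s, n = %d/%d; %s)\n",
              x$groups[1L], x$groups[2L], x$n1, x$n2, x$convention))
  for (e in c("group", "stress", "interaction")) {
    r <- x[[e]]
    cat(sprintf("  %-12s F(%d,%d) = %.4g, p = %.4g\n",
                r$effect, r$df1, r$df2, r$F, r$p))
  }
  invisible(x)
}

#' Within-group simple effect of the stressor
#'
#' Paired contrast of post vs pre within one group. The change is reported
#' both signed (`signed_difference` = mean(post - pre)) and as a magnitude
#' with a `direction` field, matching the convention of reporting a
#' "reduction" as a positive mean difference.
#'
#' @param cohort a [cohort_table()].
#' @param group which group to test.
#' @return an `effect_contrast` list: label, n, mean_pre, mean_post,
#'   signed_difference, mean_difference (magnitude), direction, sem, t, df,
#'   p.
#' @export
simple_effect <- function(cohort, group) {
  g <- check_cohort(cohort)
  idx <- as.character(g) == as.character(group)
  if (sum(idx) < 2L) stop("group ", group, " has < 2 subjects", call. = FALSE)
  d <- cohort$strength_post[idx] - cohort$strength_pre[idx]
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    stop("degenerate contrast: all within-subject differences identical ",
         "(sem = 0)", call. = FALSE)
  }
  sem <- sdd / sqrt(n)
  t <- mean(d) / sem
  structure(list(
    label = paste0("stress within ", group),
    n = n,
    mean_pre = mean(cohort$strength_pre[idx]),
    mean_post = mean(cohort$strength_post[idx]),
    signed_difference = mean(d),
    mean_difference = abs(mean(d)),
    direction = if (mean(d) < 0) "decrease" else "increase",
    sem = sem, t = t, df = n - 1L,
    p = 2 * stats::pt(abs(t), n - 1L, lower.tail = FALSE)
  ), class = "effect_contrast")
}

#' Between-group contrast at one condition
#'
#' Independent-samples pooled-variance t contrast of the two group means for
#' the chosen condition (`pre`, `post`, or the subject `mean` of both
#' scans). `signed_difference` is first group minus second group (PTSD minus
#' MDD under the standard coding), so the interaction-contrast identity
#' (delta-PTSD minus delta-MDD) == (post group difference minus pre group
#' difference) holds exactly.
#'
#' @param cohort a [cohort_table()].
#' @param condition `"pre"`, `"post"` or `"mean"`.
#' @return an `effect_contrast` list (label, n, group means,
#'   signed_difference, mean_difference, direction, sem, t, df, p).
#' @export
group_contrast <- function(cohort, condition = c("pre", "post", "mean")) {
  condition <- match.arg(condition)
  g <- check_cohort(cohort)
  y <- switch(condition,
              pre = cohort$strength_pre,
              post = cohort$strength_post,
              mean = (cohort$strength_pre + cohort$strength_post) / 2)
  i1 <- g == levels(g)[1L]
  i2 <- g == levels(g)[2L]
  n1 <- sum(i1); n2 <- sum(i2); N <- n1 + n2
  vp <- ((n1 - 1) * stats::var(y[i1]) + (n2 - 1) * stats::var(y[i2])) / (N - 2)
  if (vp <= 0) stop("zero pooled variance", call. = FALSE)
  sem <- sqrt(vp * (1 / n1 + 1 / n2))
  diff <- mean(y[i1]) - mean(y[i2])
  t <- diff / sem
  structure(list(
    label = paste0(levels(g)[1L], " vs ", levels(g)[2L], " at ", condition),
    n = N, n1 = n1, n2 = n2,
    mean_1 = mean(y[i1]), mean_2 = mean(y[i2]),
    signed_difference = diff,
    mean_difference = abs(diff),
    direction = if (diff < 0) paste0(levels(g)[1L], " lower")
                else paste0(levels(g)[1L], " higher"),
    sem = sem, t = t, df = N - 2L,
    p = 2 * stats::pt(abs(t), N - 2L, lower.tail = FALSE)
  ), class = "effect_contrast")
}

#' @export
print.effect_contrast <- function(x, ...) {
  cat(sprintf("%s: mean difference = %.4g (%s), SEM = %.4g, t(%d) = %.3f, p = %.4g\n",
              x$label, x$mean_difference, x$direction, x$sem, x$df, x$t, x$p))
  invisible(x)
}

#' Percent difference relative to a reference mean
#'
#' 100 * effect / reference, sign preserved. The reference is the comparison
#' condition's mean: the pre-stress group mean for stress (within-group)
#' effects, and the MDD mean at the same condition for group effects.
#'
#' @param effect the (signed or magnitude) mean difference.
#' @param reference the reference mean; must be nonzero.
#' @return the percentage.
#' @export
percent_difference <- function(effect, reference) {
  stopifnot(is.numeric(effect), is.numeric(reference))
  if (any(reference == 0)) stop("reference mean is zero", call. = FALSE)
  100 * effect / reference
}

#' Covariate-adjusted interaction test
#'
#' Re-tests the group-by-stress interaction with mean-centered
#' between-subject covariates added to the difference-score submodel:
#' lm(post - pre ~ group + centered covariates), F for group = t^2 on
#' df2 = N - 2 - k, with k the number of retained covariates. Covariates
#' that are constant (zero after centering) are dropped; an exactly
#' collinear covariate pair is an error naming the pair.
#'
#' @param cohort a [cohort_table()] carrying the covariate columns.
#' @param covariates character vector of covariate column names.
#' @return an `anova_result` list for the adjusted interaction, with extra
#'   fields `covariates` (retained names) and `dropped`.
#' @export
ancova_interaction <- function(cohort, covariates) {
  g <- check_cohort(cohort)
  missing <- setdiff(covariates, names(cohort))
  if (length(missing)) {
    stop("covariate column(s) not in cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- cohort$strength_post - cohort$strength_pre
  N <- length(d)
  X <- as.matrix(as.data.frame(lapply(cohort[covariates], as.numeric)))
  if (!all(is.finite(X))) stop("missing/non-finite covariate values", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(Xc, 2L, function(col) any(abs(col) > 1e-12))
  dropped <- covariates[!keep]
  Xc <- Xc[, keep, drop = FALSE]
  if (ncol(Xc) > 1L) {
    cc <- suppressWarnings(stats::cor(Xc))
    cc[upper.tri(cc, diag = TRUE)] <- 0
    bad <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("collinear covariates: ", colnames(Xc)[bad[1L, 2L]], " and ",
           colnames(Xc)[bad[1L, 1L]], call. = FALSE)
    }
  }
  k <- ncol(Xc)
  gi <- as.numeric(g == levels(g)[1L])
  fit <- if (k > 0L) stats::lm(d ~ gi + Xc) else stats::lm(d ~ gi)
  co <- summary(fit)$coefficients
  tg <- co["gi", "t value"]
  df2 <- N - 2L - k
  if (abs(df2 - fit$df.residual) > 0) {
    # residual df disagree only if lm dropped something unexpectedly
    df2 <- fit$df.residual
  }
  out <- anova_result("interaction (covariate-adjusted)", tg^2, 1L, df2)
  out$covariates <- if (k > 0L) colnames(Xc) else character(0)
  out$dropped <- dropped
  out
}

#' Correlation with its two-tailed p-value
#'
#' `correlation_test` computes Pearson's r between two vectors and its
#' two-tailed p; `correlation_p` gives the p implied by a (possibly rounded,
#' e.g. printed) r at sample size n, via t = r * sqrt(n-2) / sqrt(1-r^2) on
#' n-2 df. A perfectly collinear pair (|r| = 1) returns p = 0 with
#' `degenerate = TRUE` rather than erroring.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param r a correlation in [-1, 1].
#' @param n sample size >= 4.
#' @return a `correlation_result` list: r, n, t, df, p, degenerate.
#' @export
correlation_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need n >= 4 complete pairs", call. = FALSE)
  correlation_p(stats::cor(x, y), length(x))
}

#' @rdname correlation_test
#' @export
correlation_p <- function(r, n) {
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  if (abs(r) > 1) stop("|r| > 1", call. = FALSE)
  if (abs(r) >= 1 - 1e-15) {
    return(structure(list(r = r, n = as.integer(n), t = Inf * sign(r),
                          df = n - 2L, p = 0, degenerate = TRUE),
                     class = "correlation_result"))
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  structure(list(r = r, n = as.integer(n), t = t, df = n - 2L,
                 p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, n = %d, t(%d) = %.3f, p = %.4g%s\n",
              x$r, x$n, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate |r| = 1]" else ""))
  invisible(x)
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction (the convention that reproduces the
#' printed demographic-table p-values), df = 1.
#'
#' @param a,b,c,d cell counts of the table rbind(c(a, b), c(c, d)).
#' @return a `contingency_result` list: counts, chi2, df, p.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  tab <- rbind(c(a, b), c(c, d))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(counts = tab, chi2 = unname(ht$statistic), df = 1L,
                 p = ht$p.value),
            class = "contingency_result")
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact enumeration when both samples have n <= 8 and there are no ties;
#' otherwise the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param x,y numeric samples.
#' @return list with `U` (for sample x), `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 8L && length(y) <= 8L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values (monotone, capped at 1);
#' Bonferroni available by flag.
#'
#' @param p vector of p-values in [0, 1].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values, same length/order as input.
#' @export
fdr_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Scan-duration (split-half) 2x2 analysis
#'
#' Identical model to [mixed_anova_2x2()] with the within factor being the
#' first vs second half of a single scan rather than pre vs post stressor.
#' Effects are labelled group / time / interaction.
#'
#' @param cohort a data.frame with columns subject_id, group, strength_h1,
#'   strength_h2 (first- and second-half strengths).
#' @return as [mixed_anova_2x2()], with the `stress` element renamed `time`.
#' @export
duration_analysis <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("subject_id", "group", "strength_h1", "strength_h2")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("duration cohort lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mapped <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                       strength_pre = cohort$strength_h1,
                       strength_post = cohort$strength_h2)
  res <- mixed_anova_2x2(mapped, within_labels = c("h1", "h2"))
  res$time <- res$stress
  res$time$effect <- "time"
  res$stress <- NULL
  res$interaction$effect <- "group x time interaction"
  res
}
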