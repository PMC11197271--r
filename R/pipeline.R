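# Orchestration: the full analysis battery over a cohort (primary 2x2 GLM,
# simple effects with percent differences, group contrasts, severity
# correlations, covariate sensitivity), plus nodal exploration and the
# split-half scan-duration analysis when per-scan timeseries are available,
# and report serialisation (JSON + CSV + text).

#' Run the full strength-level analysis battery
#'
#' Given a cohort table of pre/post network strengths, computes the primary
#' 2x2 mixed ANOVA (group, stress, interaction), the within-group simple
#' effects with percent differences (denominator: the group's pre-stress
#' mean), the between-group contrasts at pre, post and subject-mean
#' (denominator: the second group's mean at the same condition), the
#' covariate-adjusted interaction, and delta-strength/severity correlations.
#'
#' @param cohort a [cohort_table()].
#' @param covariates character vector of covariate column names for the
#'   adjusted model (default none).
#' @param score_columns symptom-score columns to correlate with the
#'   post-minus-pre strength change, per group (default: any of the
#'   generator's score columns present).
#' @param alpha two-tailed significance level (default 0.05).
#' @param fdr_method multiplicity adjustment passed to [fdr_adjust()].
#' @param seed echoed into provenance (the battery itself is deterministic).
#' @return a list of class `analysis_report`.
#' @export
run_analysis <- function(cohort, covariates = character(0),
                         score_columns = NULL, alpha = 0.05,
                         fdr_method = "BH", seed = NA_integer_) {
  g <- check_cohort(cohort)
  groups <- levels(g)
  if (is.null(score_columns)) {
    score_columns <- intersect(
      c("qids", "pcl5_total", "caps_reexperiencing", "caps_avoidance",
        "caps_negative_mood", "caps_arousal"),
      names(cohort))
  }

  anova <- mixed_anova_2x2(cohort)

  simple <- lapply(groups, function(gr) {
    eff <- simple_effect(cohort, gr)
    eff$percent <- percent_difference(eff$signed_difference, eff$mean_pre)
    eff
  })
  names(simple) <- groups

  contrasts <- lapply(c("pre", "post", "mean"), function(cond) {
    eff <- group_contrast(cohort, cond)
    eff$percent <- percent_difference(eff$signed_difference, eff$mean_2)
    eff
  })
  names(contrasts) <- c("pre", "post", "mean")

  adjusted <- if (length(covariates)) {
    ancova_interaction(cohort, covariates)
  } else NULL

  delta <- cohort$strength_post - cohort$strength_pre
  correlations <- list()
  for (gr in groups) {
    idx <- as.character(g) == gr
    for (sc in score_columns) {
      y <- suppressWarnings(as.numeric(cohort[[sc]][idx]))
      ok <- is.finite(y) & is.finite(delta[idx])
      if (sum(ok) >= 4L && stats::sd(y[ok]) > 0) {
        res <- correlation_test(delta[idx][ok], y[ok])
        correlations[[paste(gr, sc, sep = ".")]] <-
          c(list(group = gr, score = sc), unclass(res))
      }
    }
  }

  report <- list(
    anova = anova,
    simple_effects = simple,
    group_contrasts = contrasts,
    covariate_adjusted = adjusted,
    severity_correlations = correlations,
    conventions = list(
      anova = "unweighted-means 2x2 mixed GLM via exact t reductions",
      percent_denominator = "pre-stress group mean (stress effects); second-group mean at same condition (group effects)",
      fdr = fdr_method,
      alpha = alpha,
      sign = "reductions reported as positive magnitudes with a direction field"
    ),
    provenance = list(
      package = "netstress",
      version = as.character(utils::packageVersion("netstress")),
      n = nrow(cohort), n1 = anova$n1, n2 = anova$n2,
      groups = groups, seed = seed
    )
  )
  class(report) <- "analysis_report"
  report
}

#' Nodal exploration of a group difference
#'
#' Per member node of the network, contrasts the two groups' nodal strength
#' (independent pooled t) for the chosen scan — post-stress by default,
#' mirroring the primary question of which nodes drive a post-stressor
#' group difference. Reports raw and FDR-adjusted p-values, sorted by
#' absolute effect.
#'
#' @param zmats named list (by subject) of `list(pre = , post = )`
#'   [connectivity_matrix()] objects on the `fisher_z` scale.
#' @param atlas a [network_atlas()].
#' @param subjects data.frame with columns `subject_id`, `group` matching
#'   the names of `zmats`.
#' @param network network label (default `"DMN"`).
#' @param scan `"post"` (default) or `"pre"`.
#' @param fdr_method adjustment method for [fdr_adjust()].
#' @return data.frame: node, mean per group, signed difference
#'   (first group minus second), sem, t, p, p_adjusted; sorted by
#'   decreasing |difference|.
#' @export
nodal_exploration <- function(zmats, atlas, subjects, network = "DMN",
                              scan = c("post", "pre"), fdr_method = "BH") {
  scan <- match.arg(scan)
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "group") %in% names(subjects)))
  orphans <- setdiff(subjects$subject_id, names(zmats))
  if (length(orphans)) {
    stop("no matrices for subject(s): ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  g <- factor(subjects$group,
              levels = if (all(subjects$group %in% GROUP_LEVELS))
                GROUP_LEVELS else unique(subjects$group))
  members <- network_members(atlas, network)
  if (length(members) < 2L) stop("network needs >= 2 members", call. = FALSE)
  nod <- t(vapply(subjects$subject_id, function(s) {
    m <- zmats[[s]][[scan]]
    if (is.null(m)) stop("missing ", scan, " matrix for subject ", s,
                         call. = FALSE)
    nodal_strength(m, atlas, network)
  }, numeric(length(members))))
  i1 <- g == levels(g)[1L]
  i2 <- g == levels(g)[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(nod[i1, , drop = FALSE])
  m2 <- colMeans(nod[i2, , drop = FALSE])
  v1 <- apply(nod[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(nod[i2, , drop = FALSE], 2L, stats::var)
  vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  sem <- sqrt(vp * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / sem
  p <- 2 * stats::pt(abs(t), n1 + n2 - 2, lower.tail = FALSE)
  out <- data.frame(node = members,
                    mean_1 = m1, mean_2 = m2,
                    difference = m1 - m2, sem = sem, t = t, p = p,
                    p_adjusted = fdr_adjust(p, fdr_method),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", levels(g))
  out[order(-abs(out$difference)), ]
}

#' Split-half duration analysis of one scan session
#'
#' Splits each subject's scan in half, computes the network strength of each
#' half, and runs the 2x2 group-by-time model of [duration_analysis()].
#'
#' @param scans named list (by subject) of [parcel_timeseries()] for one
#'   session (e.g. all pre-stress scans).
#' @param atlas a [network_atlas()].
#' @param subjects data.frame with `subject_id`, `group`.
#' @param network network label.
#' @return list with `anova` (the duration [mixed_anova_2x2()] result) and
#'   `halves` (the per-subject half-strength data.frame).
#' @export
split_half_analysis <- function(scans, atlas, subjects, network = "DMN") {
  stopifnot(is.data.frame(subjects))
  orphans <- setdiff(subjects$subject_id, names(scans))
  if (length(orphans)) {
    stop("no scan for subject(s): ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  hs <- t(vapply(subjects$subject_id, function(s) {
    halves <- split_halves(scans[[s]])
    c(scan_strength(halves[[1L]], atlas, network)$value,
      scan_strength(halves[[2L]], atlas, network)$value)
  }, numeric(2L)))
  tab <- data.frame(subject_id = subjects$subject_id, group = subjects$group,
                    strength_h1 = hs[, 1L], strength_h2 = hs[, 2L],
                    stringsAsFactors = FALSE)
  list(anova = duration_analysis(tab), halves = tab)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write an analysis report
#'
#' Serialises a report from [run_analysis()] as `report.json` (stable field
#' order, no timestamps: identical inputs give byte-identical files),
#' `report.txt` (human-readable) and `strengths.csv`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @param cohort optional cohort to write as `strengths.csv`.
#' @param nodal optional nodal table to write as `nodal.csv`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, cohort = NULL, nodal = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(strip_classes(unclass(report)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(cohort)) {
    utils::write.csv(as.data.frame(cohort), file.path(dir, "strengths.csv"),
                     row.names = FALSE)
  }
  if (!is.null(nodal)) {
    utils::write.csv(nodal, file.path(dir, "nodal.csv"), row.names = FALSE)
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Network strength analysis report ==\n")
  cat(sprintf("cohort: %d subjects (%s n = %d, %s n = %d)\n",
              x$provenance$n, x$provenance$groups[1L], x$provenance$n1,
              x$provenance$groups[2L], x$provenance$n2))
  print(x$anova)
  cat("simple effects:\n")
  for (nm in names(x$simple_effects)) {
    e <- x$simple_effects[[nm]]
    cat(sprintf("  %s: %s of %.4g (%.0f%%), SEM = %.4g, p = %.4g\n",
                nm, e$direction, e$mean_difference, abs(e$percent), e$sem, e$p))
  }
  cat("group contrasts:\n")
  for (nm in names(x$group_contrasts)) {
    e <- x$group_contrasts[[nm]]
    cat(sprintf("  %s: mean difference = %.4g (%.0f%%), SEM = %.4g, p = %.4g\n",
                nm, e$mean_difference, abs(e$percent), e$sem, e$p))
  }
  if (!is.null(x$covariate_adjusted)) {
    a <- x$covariate_adjusted
    cat(sprintf("covariate-adjusted interaction: F(%d,%d) = %.4g, p = %.4g (k = %d)\n",
                a$df1, a$df2, a$F, a$p, length(a$covariates)))
  }
  if (length(x$severity_correlations)) {
    cat("delta-strength vs severity:\n")
    for (cr in x$severity_correlations) {
      cat(sprintf("  %s / %s: r = %.3f, n = %d, p = %.4g\n",
                  cr$group, cr$score, cr$r, cr$n, cr$p))
    }
  }
  invisible(x)
}
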