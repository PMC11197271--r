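# Seeded synthetic cohorts emulating the study design: two diagnostic groups
# (28 PTSD / 24 MDD), two resting-state scans around an affective stressor,
# block-structured inter-node correlations over a six-network atlas, and
# injectable group, stress (interaction) and within-run drift effects.
#
# Effects are injected additively in Fisher-z space and back-transformed, so
# an injected decrement is exact on the analysis scale (which averages z).
# Timeseries are Gaussian white noise with the target correlation structure:
# real BOLD is autocorrelated, but white noise keeps the closed-form
# calibration targets (NRS -> atanh(rho)) exact.

# Run code with a private RNG stream: the global .Random.seed is saved and
# restored, so interleaved generators with different seeds behave exactly as
# when run separately.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic six-network atlas
#'
#' Partitions `n_nodes` labelled nodes into the six intrinsic connectivity
#' networks, giving the DMN `round(dmn_fraction * n_nodes)` members (at
#' least 2) and splitting the remainder as evenly as possible over the other
#' five networks. The assignment is deterministic: same arguments, same
#' atlas.
#'
#' @param n_nodes total node count, >= 12.
#' @param dmn_fraction fraction of nodes given to the DMN, in (0, 1).
#'   The default 75/360 puts 75 of 360 nodes in the DMN.
#' @return a [network_atlas()].
#' @export
make_default_atlas <- function(n_nodes, dmn_fraction = 75 / 360) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L)
  if (n_nodes < 12L) stop("need n_nodes >= 12", call. = FALSE)
  if (!is.numeric(dmn_fraction) || dmn_fraction <= 0 || dmn_fraction >= 1) {
    stop("dmn_fraction must lie in (0, 1)", call. = FALSE)
  }
  n_dmn <- max(2L, as.integer(round(dmn_fraction * n_nodes)))
  rest <- n_nodes - n_dmn
  others <- setdiff(NETWORK_LABELS, "DMN")
  if (rest < length(others)) {
    stop("dmn_fraction leaves fewer than one node per remaining network",
         call. = FALSE)
  }
  base <- rest %/% length(others)
  extra <- rest %% length(others)
  sizes <- c(n_dmn, rep(base, length(others)) +
               c(rep(1L, extra), rep(0L, length(others) - extra)))
  ids <- sprintf("n%03d", seq_len(n_nodes))
  network_atlas(ids, rep(c("DMN", others), times = sizes))
}

#' Simulation configuration
#'
#' Bundles the generative parameters for [simulate_cohort()] (timeseries
#' mode) and [simulate_strengths()] (strength mode). Defaults are the study
#' conditions at reduced spatial scale: 28 PTSD / 24 MDD subjects, two scans,
#' a 60-node six-network atlas, 200 frames at TR = 0.7 s; pass
#' `n_nodes = 360, frames = 645` for full study scale.
#'
#' @param n_ptsd,n_mdd group sizes (default 28 and 24).
#' @param n_nodes atlas size for timeseries mode (default 60).
#' @param frames frames per scan (default 200; the study retains 645).
#' @param tr_seconds sampling interval (default 0.7).
#' @param atlas optional [network_atlas()]; default
#'   `make_default_atlas(n_nodes)`.
#' @param rho_within baseline within-network Pearson correlation, a scalar
#'   or a vector named by network label (default 0.3).
#' @param rho_between between-network correlation (default 0).
#' @param dmn_interaction_effect standardized decrement of within-DMN
#'   connectivity for the PTSD group in the post scan (Cohen's d on
#'   difference scores); 0 = null.
#' @param stress_effect common (both-group) post-minus-pre shift. Strength
#'   mode: on the strength scale. Timeseries mode: in Fisher z.
#' @param group_pre_shift baseline (pre) PTSD-minus-MDD shift, same scale
#'   convention as `stress_effect`.
#' @param drift_effect length-2 named vector `c(PTSD = , MDD = )`: Fisher-z
#'   change of within-DMN connectivity in the second half of each run
#'   (timeseries mode only).
#' @param mu_strength population mean within-DMN strength (Fisher z), used
#'   by strength mode and as the subject-effect anchor; default 0.146,
#'   a typical within-DMN strength for this parcellation.
#' @param subject_sd between-subject SD of within-DMN z (default 0.032).
#' @param diff_sd SD of the post-minus-pre strength difference (default
#'   0.026; strength mode draws the difference noise with exactly this SD).
#' @param scan_sd subject-by-scan z jitter in timeseries mode (default
#'   0.018).
#' @param noise_sd observation noise added to each timeseries sample
#'   (default 0, keeping NRS -> atanh(rho) exact).
#' @param diff_sd_z timeseries mode: total SD of the measured NRS difference
#'   used to convert `dmn_interaction_effect` into a raw z decrement; when
#'   `NULL` it is calibrated once by [calibrate_diff_sd()].
#' @param effect_nodes optional DMN node ids: when given, the interaction
#'   decrement applies only to pairs with at least one endpoint in this set
#'   (nodal-localization experiments).
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_ptsd = 28L, n_mdd = 24L, n_nodes = 60L,
                       frames = 200L, tr_seconds = 0.7, atlas = NULL,
                       rho_within = 0.3, rho_between = 0,
                       dmn_interaction_effect = 0, stress_effect = 0,
                       group_pre_shift = 0,
                       drift_effect = c(PTSD = 0, MDD = 0),
                       mu_strength = 0.146, subject_sd = 0.032,
                       diff_sd = 0.026, scan_sd = 0.018, noise_sd = 0,
                       diff_sd_z = NULL, effect_nodes = NULL, seed = 1L) {
  stopifnot(n_ptsd >= 2L, n_mdd >= 2L, frames >= 10L, n_nodes >= 12L,
            subject_sd >= 0, diff_sd > 0, scan_sd >= 0, noise_sd >= 0)
  if (is.null(atlas)) atlas <- make_default_atlas(n_nodes)
  stopifnot(inherits(atlas, "network_atlas"))
  if (length(atlas$node_ids) != n_nodes) n_nodes <- length(atlas$node_ids)
  if (is.null(names(drift_effect))) names(drift_effect) <- GROUP_LEVELS
  cfg <- list(n_ptsd = as.integer(n_ptsd), n_mdd = as.integer(n_mdd),
              n_nodes = as.integer(n_nodes), frames = as.integer(frames),
              tr_seconds = tr_seconds, atlas = atlas,
              rho_within = rho_within, rho_between = rho_between,
              dmn_interaction_effect = dmn_interaction_effect,
              stress_effect = stress_effect,
              group_pre_shift = group_pre_shift,
              drift_effect = drift_effect, mu_strength = mu_strength,
              subject_sd = subject_sd, diff_sd = diff_sd, scan_sd = scan_sd,
              noise_sd = noise_sd, diff_sd_z = diff_sd_z,
              effect_nodes = effect_nodes, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rho_for <- function(cfg, network) {
  rw <- cfg$rho_within
  if (!is.null(names(rw)) && network %in% names(rw)) unname(rw[[network]])
  else unname(rw[[1L]])
}

# base correlation matrix: block-constant within networks, rho_between
# elsewhere, unit diagonal
base_correlation <- function(cfg) {
  aff <- cfg$atlas$affiliation[cfg$atlas$node_ids]
  n <- length(aff)
  C <- matrix(cfg$rho_between, n, n)
  for (net in unique(aff)) {
    idx <- which(aff == net)
    C[idx, idx] <- rho_for(cfg, net)
  }
  diag(C) <- 1
  dimnames(C) <- list(cfg$atlas$node_ids, cfg$atlas$node_ids)
  C
}

# Cholesky with an explicit PSD failure message (no silent repair)
chol_or_fail <- function(C) {
  tryCatch(chol(C), error = function(e) {
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    stop("correlation matrix not positive definite after effect shifts ",
         "(smallest eigenvalue ", format(ev, digits = 4), ")", call. = FALSE)
  })
}

# one scan draw: frames x nodes gaussian with correlation C
draw_scan <- function(C, frames, noise_sd) {
  U <- chol_or_fail(C)
  X <- matrix(stats::rnorm(frames * ncol(C)), frames, ncol(C)) %*% U
  if (noise_sd > 0) X <- X + stats::rnorm(length(X), sd = noise_sd)
  t(X)
}

clamp_z <- function(z) pmin(pmax(z, -5), 5)

# covariates and symptom scores emulating the demographic table: rates and
# moments match the printed full-group values; PTSD-only scales are NA for
# the MDD group
draw_covariates <- function(group) {
  n <- length(group)
  is_ptsd <- group == "PTSD"
  age <- stats::rnorm(n, 41.4, 10)
  while (any(bad <- age < 21 | age > 68)) {
    age[bad] <- stats::rnorm(sum(bad), 41.4, 10)
  }
  cov <- data.frame(
    age = round(age, 1),
    sex_male = stats::rbinom(n, 1L, 0.67),
    motion_pre = round(stats::rlnorm(n, log(0.10), 0.3), 4),
    motion_post = round(stats::rlnorm(n, log(0.09), 0.3), 4),
    antidepressant = stats::rbinom(n, 1L, 0.46),
    comorbid_substance = stats::rbinom(n, 1L, 0.10),
    comorbid_alcohol = stats::rbinom(n, 1L, 0.13),
    comorbid_gad = stats::rbinom(n, 1L, 0.29),
    comorbid_panic = stats::rbinom(n, 1L, 0.21),
    comorbid_ocd = stats::rbinom(n, 1L, 0.04),
    comorbid_social_anxiety = stats::rbinom(n, 1L, 0.27)
  )
  scores <- data.frame(
    qids = round(pmax(0, stats::rnorm(n, ifelse(is_ptsd, 13.43, 12.17),
                                      ifelse(is_ptsd, 4.6, 5.4)))),
    pcl5_total = ifelse(is_ptsd, round(pmax(0, stats::rnorm(n, 45, 12))), NA),
    caps_reexperiencing = ifelse(is_ptsd, round(pmax(0, stats::rnorm(n, 7, 3))), NA),
    caps_avoidance = ifelse(is_ptsd, round(pmax(0, stats::rnorm(n, 4, 2))), NA),
    caps_negative_mood = ifelse(is_ptsd, round(pmax(0, stats::rnorm(n, 12, 5))), NA),
    caps_arousal = ifelse(is_ptsd, round(pmax(0, stats::rnorm(n, 10, 4))), NA)
  )
  list(covariates = cov, scores = scores)
}

#' Calibrate the NRS difference SD for timeseries mode
#'
#' Converts a standardized interaction effect into a raw Fisher-z decrement:
#' the total SD of a post-minus-pre NRS difference combines the
#' subject-by-scan jitter (`2 * scan_sd^2`) with the NRS sampling variance
#' at the configured frame count, which is estimated here by a seeded
#' Monte-Carlo over independent null scans.
#'
#' @param cfg a [sim_config()].
#' @param reps number of calibration scans (default 200).
#' @return the calibrated difference SD (a single number).
#' @export
calibrate_diff_sd <- function(cfg, reps = 200L) {
  stopifnot(inherits(cfg, "sim_config"))
  C <- base_correlation(cfg)
  with_seed(cfg$seed + 990001L, {
    vals <- vapply(seq_len(reps), function(i) {
      ts <- parcel_timeseries(draw_scan(C, cfg$frames, cfg$noise_sd),
                              node_ids = cfg$atlas$node_ids,
                              tr_seconds = cfg$tr_seconds)
      scan_strength(ts, cfg$atlas, "DMN")$value
    }, numeric(1L))
    sqrt(2 * cfg$scan_sd^2 + 2 * stats::var(vals))
  })
}

#' Simulate a cohort of parcellated timeseries
#'
#' For every subject and scan, draws `frames` samples from a zero-mean
#' multivariate normal whose correlation matrix is block-structured by the
#' atlas. Each subject carries a random within-DMN Fisher-z level
#' (`mu_strength + N(0, subject_sd)`), each scan an independent jitter
#' (`N(0, scan_sd)`); the group/scan interaction decrement and per-group
#' within-run drift are added in z space and back-transformed. Identical
#' config and seed give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_output` with elements `scans` (per subject:
#'   `list(pre = , post = )` of [parcel_timeseries()]), `cohort` (a
#'   [cohort_table()] holding measured pre/post DMN strengths and the drawn
#'   covariates/scores), `atlas`, and `metadata` (seed, mode, config echo).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  group <- rep(GROUP_LEVELS, c(cfg$n_ptsd, cfg$n_mdd))
  n <- length(group)
  subject_id <- sprintf("sub%03d", seq_len(n))
  dmn_nodes <- network_members(cfg$atlas, "DMN")
  if (!is.null(cfg$effect_nodes)) {
    bad <- setdiff(cfg$effect_nodes, dmn_nodes)
    if (length(bad)) stop("effect_nodes outside the DMN: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  raw_shift <- 0
  if (cfg$dmn_interaction_effect != 0) {
    sd_d <- cfg$diff_sd_z %||% calibrate_diff_sd(cfg)
    raw_shift <- cfg$dmn_interaction_effect * sd_d
  }
  z_base <- atanh(rho_for(cfg, "DMN"))
  C0 <- base_correlation(cfg)
  di <- match(dmn_nodes, cfg$atlas$node_ids)

  # set the within-DMN block to tanh of per-pair z values
  dmn_block <- function(z_all, z_affected) {
    B <- matrix(tanh(clamp_z(z_all)), length(di), length(di))
    if (!is.null(cfg$effect_nodes) && z_affected != z_all) {
      hit <- dmn_nodes %in% cfg$effect_nodes
      aff <- outer(hit, hit, `|`)
      B[aff] <- tanh(clamp_z(z_affected))
    } else if (z_affected != z_all) {
      B[] <- tanh(clamp_z(z_affected))
    }
    diag(B) <- 1
    B
  }

  with_seed(cfg$seed, {
    b_subj <- stats::rnorm(n, 0, cfg$subject_sd)
    scans <- vector("list", n)
    names(scans) <- subject_id
    for (s in seq_len(n)) {
      per_scan <- list()
      for (scan in c("pre", "post")) {
        e_scan <- stats::rnorm(1L, 0, cfg$scan_sd)
        z <- z_base + b_subj[s] + e_scan
        if (scan == "post") z <- z + cfg$stress_effect
        if (group[s] == "PTSD") {
          z <- z + cfg$group_pre_shift
        }
        z_aff <- z
        if (scan == "post" && group[s] == "PTSD") z_aff <- z - raw_shift
        drift <- unname(cfg$drift_effect[group[s]])
        halves_differ <- !is.na(drift) && drift != 0
        make_C <- function(zv, zva) {
          C <- C0
          C[di, di] <- dmn_block(zv, zva)
          C
        }
        vals <- if (halves_differ) {
          h <- cfg$frames %/% 2L
          cbind(draw_scan(make_C(z, z_aff), h, cfg$noise_sd),
                draw_scan(make_C(z + drift, z_aff + drift),
                          cfg$frames - h, cfg$noise_sd))
        } else {
          draw_scan(make_C(z, z_aff), cfg$frames, cfg$noise_sd)
        }
        per_scan[[scan]] <- parcel_timeseries(
          vals, node_ids = cfg$atlas$node_ids,
          tr_seconds = cfg$tr_seconds, scan_label = scan)
      }
      scans[[s]] <- per_scan
    }
    cs <- draw_covariates(group)
    strength_pre <- vapply(scans, function(x)
      scan_strength(x$pre, cfg$atlas, "DMN")$value, numeric(1L))
    strength_post <- vapply(scans, function(x)
      scan_strength(x$post, cfg$atlas, "DMN")$value, numeric(1L))
    cohort <- cohort_table(subject_id, group, strength_pre, strength_post,
                           covariates = cs$covariates, scores = cs$scores)
    structure(list(scans = scans, cohort = cohort, atlas = cfg$atlas,
                   metadata = list(seed = cfg$seed, mode = "timeseries",
                                   generator = "netstress",
                                   version = as.character(utils::packageVersion("netstress")),
                                   config = cfg[setdiff(names(cfg), "atlas")])),
              class = "sim_output")
  })
}

#' Simulate a strength-level cohort
#'
#' Fast path that draws the pre/post network strengths directly:
#' `pre ~ N(mu_strength, subject_sd^2)` (PTSD shifted by `group_pre_shift`),
#' `post = pre + stress_effect + group shift + N(0, diff_sd^2)`, with the
#' PTSD post shift chosen as `-dmn_interaction_effect * diff_sd` so the
#' standardized interaction effect equals `dmn_interaction_effect` exactly.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_output` list with elements `cohort`, `metadata` (no
#'   timeseries).
#' @export
simulate_strengths <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  group <- rep(GROUP_LEVELS, c(cfg$n_ptsd, cfg$n_mdd))
  n <- length(group)
  with_seed(cfg$seed, {
    pre <- stats::rnorm(n, cfg$mu_strength, cfg$subject_sd) +
      ifelse(group == "PTSD", cfg$group_pre_shift, 0)
    shift <- cfg$stress_effect -
      ifelse(group == "PTSD", cfg$dmn_interaction_effect * cfg$diff_sd, 0)
    post <- pre + shift + stats::rnorm(n, 0, cfg$diff_sd)
    cs <- draw_covariates(group)
    cohort <- cohort_table(sprintf("sub%03d", seq_len(n)), group, pre, post,
                           covariates = cs$covariates, scores = cs$scores)
    structure(list(cohort = cohort,
                   metadata = list(seed = cfg$seed, mode = "strengths",
                                   generator = "netstress",
                                   version = as.character(utils::packageVersion("netstress")),
                                   config = cfg[setdiff(names(cfg), "atlas")])),
              class = "sim_output")
  })
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output (%s mode): %d subjects, seed %d>\n",
              x$metadata$mode, nrow(x$cohort), x$metadata$seed))
  invisible(x)
}
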