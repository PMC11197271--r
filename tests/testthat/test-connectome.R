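test_that("correlation_matrix reproduces hand-computed Pearson r", {
  x <- c(1, 2, 3, 4)
  ts <- parcel_timeseries(rbind(x = x, y = 2 * x, w = c(1, -1, 1, -1)),
                          c("x", "y", "w"))
  cm <- correlation_matrix(ts)
  expect_identical(cm$scale, "pearson_r")
  expect_equal(cm$values["x", "y"], 1, tolerance = 1e-12)
  expect_equal(cm$values["x", "w"], -0.4472135955, tolerance = 1e-9)
  expect_equal(cm$values, t(cm$values))

  # duplicated series -> r = 1; negated -> r = -1
  r <- correlation_matrix(
    parcel_timeseries(rbind(a = x, b = x, c = -x), c("a", "b", "c")))
  expect_equal(r$values["a", "b"], 1)
  expect_equal(r$values["a", "c"], -1)

  flat <- parcel_timeseries(rbind(a = x, z = rep(2, 4)), c("a", "z"))
  expect_error(correlation_matrix(flat), "zero-variance node.*z")
})

test_that("fisher_z is the clipped atanh, odd, increasing, and double-transform guarded", {
  ids <- c("a", "b", "c")
  cm <- matrix_from_pairs(ids, c(0, 0.5, 1), scale = "pearson_r")
  z <- fisher_z(cm)
  expect_identical(z$scale, "fisher_z")
  expect_equal(z$values["a", "b"], 0)
  expect_equal(z$values["a", "c"], 0.5493061443, tolerance = 1e-9)
  expect_equal(z$values["b", "c"], atanh(1 - 1e-7), tolerance = 1e-12)
  expect_lt(z$values["b", "c"], 8.5)
  expect_error(fisher_z(z), "already")

  # odd and strictly increasing on a grid
  r <- seq(-0.95, 0.95, by = 0.05)
  zp <- atanh(r)
  neg <- fisher_z(matrix_from_pairs(c("a", "b"), 0.3, "pearson_r"))
  pos <- fisher_z(matrix_from_pairs(c("a", "b"), -0.3, "pearson_r"))
  expect_equal(neg$values["a", "b"], -pos$values["a", "b"], tolerance = 1e-14)
  expect_true(all(diff(zp) > 0))
})

test_that("network strength is the unweighted pair mean; nodal mean matches exactly", {
  atlas <- network_atlas(c("a", "b", "c", "v1", "v2"),
                         c("DMN", "DMN", "DMN", "VI", "VI"))
  # DMN pair z-values z_ab = 0.1, z_ac = 0.2, z_bc = 0.6 (others arbitrary)
  z <- matrix_from_pairs(c("a", "b", "c", "v1", "v2"),
                         c(0.1,
                           0.2, 0.6,
                           0.05, 0.07, 0.02,
                           0.04, 0.03, 0.01, 0.9))
  s <- network_strength(z, atlas, "DMN")
  expect_equal(s$value, 0.3, tolerance = 1e-12)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_pairs, 3L)

  nod <- nodal_strength(z, atlas, "DMN")
  expect_equal(as.numeric(nod), c(0.15, 0.35, 0.40), tolerance = 1e-12)
  expect_equal(mean(nod), s$value, tolerance = 1e-12)

  # 2-member network
  vi <- nodal_strength(z, atlas, "VI")
  expect_equal(as.numeric(vi), c(0.9, 0.9))

  # all-equal pairs -> value = c
  ze <- matrix_from_pairs(c("a", "b", "c"), rep(0.4, 3))
  ae <- network_atlas(c("a", "b", "c"), rep("DMN", 3))
  expect_equal(network_strength(ze, ae, "DMN")$value, 0.4)
  expect_equal(as.numeric(nodal_strength(ze, ae, "DMN")), rep(0.4, 3))
})

test_that("strength is invariant under simultaneous node permutation", {
  set.seed(8)
  atlas <- make_default_atlas(20, dmn_fraction = 0.4)
  ts <- toy_timeseries(n_nodes = 20L, frames = 60L, seed = 8L)
  ts$node_ids <- atlas$node_ids
  rownames(ts$values) <- atlas$node_ids
  ref <- scan_strength(ts, atlas, "DMN")$value
  perm <- sample(20)
  ts2 <- parcel_timeseries(ts$values[perm, ], ts$node_ids[perm])
  expect_equal(scan_strength(ts2, atlas, "DMN")$value, ref, tolerance = 1e-12)
  # nodal mean == network strength for every network and random matrices
  z <- fisher_z(correlation_matrix(ts))
  for (net in NETWORK_LABELS) {
    if (length(network_members(atlas, net)) >= 2) {
      expect_equal(mean(nodal_strength(z, atlas, net)),
                   network_strength(z, atlas, net)$value, tolerance = 1e-12)
    }
  }
})

test_that("missing atlas nodes and undersized networks are errors", {
  atlas <- network_atlas(c("a", "b", "q"), c("DMN", "DMN", "VI"))
  z <- matrix_from_pairs(c("a", "b", "c"), c(0.1, 0.2, 0.3))
  expect_error(network_strength(z, atlas, "VI"), "1 member")
  atlas2 <- network_atlas(c("a", "b", "q", "r"), c("DMN", "DMN", "DMN", "VI"))
  expect_error(network_strength(z, atlas2, "DMN"), "missing.*q")
})

test_that("split_halves gives equal contiguous halves, dropping an odd middle frame", {
  ts <- toy_timeseries(frames = 645L)
  halves <- split_halves(ts)
  expect_equal(ncol(halves[[1]]$values), 322L)
  expect_equal(ncol(halves[[2]]$values), 322L)
  expect_equal(halves[[1]]$values, ts$values[, 1:322])
  expect_equal(halves[[2]]$values, ts$values[, 324:645])
  expect_match(halves[[1]]$scan_label, "_h1$")
  # even count: exact reconstruction
  ts10 <- toy_timeseries(frames = 10L)
  h10 <- split_halves(ts10)
  expect_equal(cbind(h10[[1]]$values, h10[[2]]$values), ts10$values)
  expect_error(split_halves(toy_timeseries(frames = 4L)), ">= 6 frames")
})

test_that("scan_strength approaches atanh(rho) on block-correlated data", {
  # single scan with known within-DMN rho = 0.3, between = 0
  cfg <- sim_config(n_ptsd = 2, n_mdd = 2, n_nodes = 24, frames = 645,
                    rho_within = 0.3, rho_between = 0, subject_sd = 0,
                    scan_sd = 0, seed = 91)
  out <- simulate_cohort(cfg)
  vals <- c(out$cohort$strength_pre, out$cohort$strength_post)
  # each scan within ~3 SE of atanh(0.3); SE bounded by single-pair SE
  expect_true(all(abs(vals - atanh(0.3)) < 3 / sqrt(645 - 3)))
})

test_that("connectivity long format is consistent between scales", {
  cm <- matrix_from_pairs(c("a", "b", "c"), c(0.1, 0.2, 0.3),
                          scale = "pearson_r")
  long <- connectivity_long(cm)
  expect_equal(nrow(long), 3L)
  expect_equal(long$z, atanh(long$r), tolerance = 1e-12)
})
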