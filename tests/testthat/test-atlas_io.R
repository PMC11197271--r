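test_that("timeseries TSV round trip is the identity and bad cells are rejected", {
  ts <- toy_timeseries()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(ts, path)
  back <- read_timeseries(path, tr_seconds = ts$tr_seconds,
                          scan_label = ts$scan_label)
  expect_equal(back$values, ts$values, ignore_attr = FALSE)
  expect_identical(back$node_ids, ts$node_ids)

  # corrupt one cell
  lines <- readLines(path)
  lines[3] <- sub("\t[^\t]+$", "\tNA", lines[3])
  writeLines(lines, path)
  expect_error(read_timeseries(path), "line 3")
})

test_that("parcel_timeseries validates shape, finiteness and node ids", {
  expect_error(parcel_timeseries(matrix(1:4, 1, 4)), ">= 2 nodes")
  expect_error(parcel_timeseries(matrix(1:4, 4, 1)), ">= 2 frames")
  m <- matrix(rnorm(6), 2, 3)
  m[2, 2] <- NaN
  expect_error(parcel_timeseries(m, c("a", "b")), "non-finite")
  expect_error(parcel_timeseries(matrix(rnorm(6), 2, 3), c("a", "a")),
               "duplicate")
  expect_error(parcel_timeseries(matrix(rnorm(6), 2, 3), c("a", "b"),
                                 tr_seconds = -1), "positive")
})

test_that("atlas I/O enforces the six-network vocabulary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(toy_atlas(), path)
  back <- read_atlas(path)
  expect_identical(back$affiliation, toy_atlas()$affiliation)
  expect_length(back$affiliation, 4L)

  writeLines(c("node\tnetwork", "n1\tDMN", "n2\tLIMBIC"), path)
  expect_error(read_atlas(path), "DMN, CE, DS, VS, SM, VI")
  writeLines(c("node\tnetwork", "n1\tDMN", "n1\tDMN"), path)
  expect_error(read_atlas(path), "duplicate")
})

test_that("packaged synthetic atlas fixture has 360 nodes across 6 networks", {
  atlas <- read_atlas(system.file("extdata", "atlas360_synthetic.tsv",
                                  package = "netstress"))
  expect_length(atlas$node_ids, 360L)
  expect_setequal(unique(atlas$affiliation), NETWORK_LABELS)
  expect_length(network_members(atlas, "DMN"), 75L)
})

test_that("drop_initial_frames drops exactly k frames and guards k >= T", {
  ts <- toy_timeseries(frames = 650L)
  expect_equal(ncol(drop_initial_frames(ts, 5)$values), 645L)
  expect_identical(drop_initial_frames(ts, 0), ts)
  expect_equal(drop_initial_frames(ts, 5)$values, ts$values[, 6:650])
  small <- toy_timeseries(frames = 10L)
  expect_error(drop_initial_frames(small, 10), "cannot drop")
})

test_that("motion expansion yields 4k columns with the documented contents", {
  base <- confound_set(matrix(rnorm(60), 10, 6),
                       labels = paste0("mot", 1:6))
  out <- expand_motion_confounds(base)
  expect_equal(ncol(out$regressors), 24L)

  tri <- confound_set(cbind(x = c(1, 2, 4)))
  ex <- expand_motion_confounds(tri)
  expect_equal(unname(ex$regressors[, "x_d1"]), c(0, 1, 2))
  expect_equal(unname(ex$regressors[, "x_sq"]), c(1, 4, 16))
  expect_equal(unname(ex$regressors[, "x_d1sq"]), c(0, 1, 4))

  const <- expand_motion_confounds(confound_set(cbind(c = rep(3, 5))))
  expect_equal(unname(const$regressors[, "c_d1"]), rep(0, 5))

  # property: always 4x the input column count
  for (k in c(1L, 3L, 6L)) {
    cs <- confound_set(matrix(rnorm(20 * k), 20, k))
    expect_equal(ncol(expand_motion_confounds(cs)$regressors), 4L * k)
  }
})

test_that("confound regression matches the normal-equations oracle and is idempotent", {
  set.seed(21)
  ts <- toy_timeseries(n_nodes = 5L, frames = 50L, seed = 21L)
  X <- matrix(rnorm(150), 50, 3)
  conf <- confound_set(X)
  out <- regress_confounds(ts, conf)
  expect_equal(out$values, normal_equations_residuals(ts$values, X),
               tolerance = 1e-10)
  # residuals orthogonal to every regressor and the intercept
  expect_lt(max(abs(out$values %*% cbind(1, X))), 1e-8 * 50)
  # idempotent
  twice <- regress_confounds(out, conf)
  expect_equal(twice$values, out$values, tolerance = 1e-8)

  # a confound equal to a node's own series flattens that node
  conf2 <- confound_set(cbind(ts$values[2, ]))
  out2 <- regress_confounds(ts, conf2)
  expect_lt(max(abs(out2$values[2, ])), 1e-10)

  # mean-zero confounds orthogonal to all nodes: output = centered input
  Q <- qr.Q(qr(cbind(1, t(ts$values), matrix(rnorm(100), 50, 2))))[, 7:8]
  out3 <- regress_confounds(ts, confound_set(Q))
  expect_equal(out3$values, ts$values - rowMeans(ts$values),
               tolerance = 1e-8)
})

test_that("collinear confound columns are dropped with a warning, not an error", {
  ts <- toy_timeseries(n_nodes = 3L, frames = 20L, seed = 5L)
  x <- rnorm(20)
  expect_warning(out <- regress_confounds(ts, confound_set(cbind(a = x, b = 2 * x))),
                 "collinear")
  ref <- regress_confounds(ts, confound_set(cbind(a = x)))
  expect_equal(out$values, ref$values, tolerance = 1e-10)
})

test_that("mgtr residuals are orthogonal to the pre-regression mean series", {
  ts <- toy_timeseries(n_nodes = 4L, frames = 80L, seed = 31L)
  m <- colMeans(ts$values)
  out <- mgtr(ts)
  expect_equal(out$values,
               normal_equations_residuals(ts$values, cbind(m)),
               tolerance = 1e-10)
  for (i in seq_len(4)) {
    expect_lt(abs(cor(out$values[i, ], m)), 1e-8)
  }

  # all nodes identical -> all residuals 0
  same <- parcel_timeseries(rbind(m, m), c("a", "b"))
  expect_lt(max(abs(mgtr(same)$values)), 1e-10)

  # anti-correlated pair -> zero-variance mean -> error
  anti <- parcel_timeseries(rbind(m, -m), c("a", "b"))
  expect_error(mgtr(anti), "zero variance")
})
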