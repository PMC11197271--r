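# Shared fixtures built in code.

# small deterministic parcel timeseries
toy_timeseries <- function(n_nodes = 3L, frames = 5L, seed = 11L,
                           scan_label = "pre") {
  set.seed(seed)
  parcel_timeseries(matrix(rnorm(n_nodes * frames), n_nodes, frames),
                    node_ids = paste0("n", seq_len(n_nodes)),
                    scan_label = scan_label)
}

# 4-node toy atlas: 2 DMN, 2 VI
toy_atlas <- function() {
  network_atlas(paste0("n", 1:4), c("DMN", "DMN", "VI", "VI"))
}

# connectivity matrix from explicit upper-triangle pair values
matrix_from_pairs <- function(node_ids, pairs, scale = "fisher_z") {
  n <- length(node_ids)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- pairs
  m <- m + t(m)
  connectivity_matrix(m, node_ids = node_ids, scale = scale)
}

# random two-group cohort
random_cohort <- function(n1 = 10L, n2 = 10L, seed = 1L) {
  set.seed(seed)
  cohort_table(sprintf("s%03d", seq_len(n1 + n2)),
               rep(c("PTSD", "MDD"), c(n1, n2)),
               rnorm(n1 + n2, 0.15, 0.04),
               rnorm(n1 + n2, 0.15, 0.04))
}

# independent least-squares oracle via the normal equations
normal_equations_residuals <- function(Y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% t(Y))
  t(t(Y) - X1 %*% beta)
}
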