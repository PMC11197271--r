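# Connectome construction and network-restricted strength (NRS).
#
# NRS for a network is the unweighted mean of the Fisher z-transformed
# Pearson correlations over all unordered within-network node pairs;
# self-pairs are excluded (z(1) is infinite and carries no information).

#' Construct a connectivity matrix
#'
#' @param values symmetric node-by-node numeric matrix; the diagonal is
#'   stored as 0 and flagged as excluded — it is never read by any strength
#'   computation.
#' @param node_ids ordered node labels.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, node_ids = rownames(values),
                                scale = c("pearson_r", "fisher_z")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(node_ids)) node_ids <- paste0("node", seq_len(nrow(values)))
  node_ids <- as.character(node_ids)
  if (nrow(values) != ncol(values)) stop("matrix not square", call. = FALSE)
  if (length(node_ids) != nrow(values)) {
    stop("node_ids do not match matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) stop("duplicate node_ids", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) {
    stop("matrix not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  diag(values) <- 0
  if (!all(is.finite(values))) stop("non-finite connectivity values", call. = FALSE)
  if (scale == "pearson_r" && max(abs(values)) > 1 + 1e-12) {
    stop("pearson_r entries must lie in [-1, 1]", call. = FALSE)
  }
  dimnames(values) <- list(node_ids, node_ids)
  structure(list(values = values, node_ids = node_ids, scale = scale),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix: %d nodes, scale = %s>\n",
              length(x$node_ids), x$scale))
  invisible(x)
}

#' Pairwise Pearson correlation matrix of a scan
#'
#' @param ts a [parcel_timeseries()] with >= 3 frames and no zero-variance
#'   node.
#' @return a [connectivity_matrix()] on the `pearson_r` scale.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  if (n_frames(ts) < 3L) stop("need >= 3 frames for correlation", call. = FALSE)
  v <- apply(ts$values, 1L, stats::var)
  if (any(v <= 0)) {
    stop("zero-variance node(s): ",
         paste(ts$node_ids[v <= 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(ts$values))
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  connectivity_matrix(r, node_ids = ts$node_ids, scale = "pearson_r")
}

#' Fisher z-transform a correlation matrix
#'
#' Applies z = atanh(r) entrywise after clipping |r| at `1 - clip` so that
#' degenerate (perfectly correlated) pairs stay finite rather than poisoning
#' the within-network mean.
#'
#' @param c a [connectivity_matrix()] on the `pearson_r` scale.
#' @param clip clipping margin (default 1e-7).
#' @return a [connectivity_matrix()] on the `fisher_z` scale.
#' @export
fisher_z <- function(c, clip = 1e-7) {
  stopifnot(inherits(c, "connectivity_matrix"))
  if (c$scale == "fisher_z") {
    stop("matrix is already Fisher z-transformed", call. = FALSE)
  }
  r <- c$values
  lim <- 1 - clip
  r[r > lim] <- lim
  r[r < -lim] <- -lim
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(z, node_ids = c$node_ids, scale = "fisher_z")
}

# index of a network's members in a connectivity matrix, with validation
network_index <- function(z, atlas, network) {
  members <- network_members(atlas, network)
  if (length(members) < 2L) {
    stop("network ", network, " has ", length(members),
         " member(s); need >= 2", call. = FALSE)
  }
  missing <- setdiff(members, z$node_ids)
  if (length(missing)) {
    stop("atlas nodes missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  match(members, z$node_ids)
}

#' Network-restricted strength
#'
#' The mean Fisher-z connectivity over all n(n-1)/2 unordered node pairs
#' within one network ("DMN strength" when the network is the default mode
#' network). The diagonal is never included.
#'
#' @param z a [connectivity_matrix()] on the `fisher_z` scale.
#' @param atlas a [network_atlas()] covering the matrix nodes.
#' @param network network label with >= 2 members.
#' @return an object of class `strength_value` with fields `value`,
#'   `network`, `scan_label`, `n_nodes`, `n_pairs`.
#' @export
network_strength <- function(z, atlas, network = "DMN") {
  stopifnot(inherits(z, "connectivity_matrix"))
  if (z$scale != "fisher_z") {
    stop("network_strength expects a fisher_z matrix; call fisher_z() first",
         call. = FALSE)
  }
  idx <- network_index(z, atlas, network)
  sub <- z$values[idx, idx, drop = FALSE]
  k <- length(idx)
  value <- sum(sub[upper.tri(sub)]) / (k * (k - 1) / 2)
  structure(list(value = value, network = network,
                 scan_label = attr(z, "scan_label") %||% "",
                 n_nodes = k, n_pairs = k * (k - 1L) %/% 2L),
            class = "strength_value")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strength_value <- function(x, ...) {
  cat(sprintf("<strength %s: %.6f over %d nodes (%d pairs)>\n",
              x$network, x$value, x$n_nodes, x$n_pairs))
  invisible(x)
}

#' Nodal strength within a network
#'
#' Entry i is the mean Fisher-z connectivity between member node i and the
#' other members of the network; the mean of the entries equals the
#' network-restricted strength exactly (pair-mean and node-mean coincide).
#'
#' @inheritParams network_strength
#' @return named numeric vector over the network's member nodes, with
#'   attribute `network`.
#' @export
nodal_strength <- function(z, atlas, network = "DMN") {
  stopifnot(inherits(z, "connectivity_matrix"))
  if (z$scale != "fisher_z") {
    stop("nodal_strength expects a fisher_z matrix", call. = FALSE)
  }
  idx <- network_index(z, atlas, network)
  sub <- z$values[idx, idx, drop = FALSE]
  k <- length(idx)
  out <- rowSums(sub) / (k - 1)
  names(out) <- z$node_ids[idx]
  attr(out, "network") <- network
  out
}

#' Split a scan into two equal contiguous halves
#'
#' The first half is frames 1..h, the second the last h frames; when the
#' frame count is odd the single middle frame is dropped so the halves have
#' identical duration. Scan labels are suffixed `_h1` / `_h2`.
#'
#' @param ts a [parcel_timeseries()] with >= 6 frames.
#' @return list of two [parcel_timeseries()] objects.
#' @export
split_halves <- function(ts) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  Tn <- n_frames(ts)
  if (Tn < 6L) stop("need >= 6 frames to split (have ", Tn, ")", call. = FALSE)
  h <- Tn %/% 2L
  first <- seq_len(h)
  second <- seq.int(Tn - h + 1L, Tn)
  list(
    parcel_timeseries(ts$values[, first, drop = FALSE], ts$node_ids,
                      ts$tr_seconds, paste0(ts$scan_label, "_h1")),
    parcel_timeseries(ts$values[, second, drop = FALSE], ts$node_ids,
                      ts$tr_seconds, paste0(ts$scan_label, "_h2"))
  )
}

#' Network strength of a scan
#'
#' Composition correlation_matrix -> fisher_z -> network_strength.
#'
#' @inheritParams network_strength
#' @param ts a [parcel_timeseries()].
#' @return a `strength_value`.
#' @export
scan_strength <- function(ts, atlas, network = "DMN") {
  s <- network_strength(fisher_z(correlation_matrix(ts)), atlas, network)
  s$scan_label <- ts$scan_label
  s
}

#' Write a connectivity matrix
#'
#' `write_connectivity` writes the square matrix as TSV with node ids as
#' header and first column; `connectivity_long` returns (and optionally
#' writes) the flat long format with one row per unordered pair.
#'
#' @param cm a [connectivity_matrix()].
#' @param path output path.
#' @return `path` (or, for `connectivity_long`, the long data.frame)
#'   invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  tab <- data.frame(node = cm$node_ids, cm$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
connectivity_long <- function(cm, path = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  ut <- which(upper.tri(cm$values), arr.ind = TRUE)
  val <- cm$values[ut]
  out <- data.frame(node_i = cm$node_ids[ut[, 1L]],
                    node_j = cm$node_ids[ut[, 2L]])
  if (cm$scale == "pearson_r") {
    out$r <- val
    out$z <- atanh(pmin(pmax(val, -(1 - 1e-7)), 1 - 1e-7))
  } else {
    out$z <- val
    out$r <- tanh(val)
  }
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Strength table for many scans
#'
#' @param scans named list of [parcel_timeseries()] (names = subject ids) or
#'   a list of lists `list(pre = ts, post = ts)` per subject.
#' @param atlas a [network_atlas()].
#' @param network network label.
#' @return data.frame with columns subject, scan_label, network, n_nodes,
#'   value.
#' @export
strength_table <- function(scans, atlas, network = "DMN") {
  rows <- list()
  for (subj in names(scans)) {
    entry <- scans[[subj]]
    if (inherits(entry, "parcel_timeseries")) entry <- list(entry)
    for (ts in entry) {
      s <- scan_strength(ts, atlas, network)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, scan_label = ts$scan_label, network = network,
        n_nodes = s$n_nodes, value = s$value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
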