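# Parcellated-timeseries containers, TSV I/O, and post-preprocessing cleanup
# (frame dropping, motion-confound expansion/regression, mean-timeseries
# regression). The pipeline starts from cleaned, parcel-averaged timeseries;
# upstream volume/surface preprocessing is out of scope.

#' Intrinsic connectivity network vocabulary
#'
#' The six network labels recognised by [read_atlas()] and
#' [make_default_atlas()]: default mode (DMN), central executive (CE),
#' dorsal salience (DS), ventral salience (VS), somatomotor (SM) and
#' visual (VI).
#'
#' @export
NETWORK_LABELS <- c("DMN", "CE", "DS", "VS", "SM", "VI")

#' Construct a parcellated timeseries
#'
#' A `parcel_timeseries` holds one scan's node-by-frame matrix of parcel-
#' averaged BOLD values, the ordered node identifiers, the sampling interval
#' (TR) in seconds, and a free-text scan label (e.g. `"pre"`, `"post"`).
#'
#' @param values numeric matrix, nodes in rows, frames in columns. All
#'   entries must be finite; at least 2 nodes and 2 frames.
#' @param node_ids character vector of unique node labels, one per row.
#'   Defaults to the matrix rownames.
#' @param tr_seconds positive sampling interval in seconds (default 0.7).
#' @param scan_label free-text label for the scan.
#' @return an object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(values, node_ids = rownames(values),
                              tr_seconds = 0.7, scan_label = "scan") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(node_ids)) {
    node_ids <- paste0("node", seq_len(nrow(values)))
  }
  node_ids <- as.character(node_ids)
  if (nrow(values) < 2L) stop("parcel_timeseries needs >= 2 nodes", call. = FALSE)
  if (ncol(values) < 2L) stop("parcel_timeseries needs >= 2 frames", call. = FALSE)
  if (length(node_ids) != nrow(values)) {
    stop("node_ids length (", length(node_ids), ") does not match row count (",
         nrow(values), ")", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) {
    stop("duplicate node_ids: ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at node ", node_ids[bad[1L]], ", frame ", bad[2L],
         call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number", call. = FALSE)
  }
  rownames(values) <- node_ids
  structure(
    list(values = values, node_ids = node_ids,
         tr_seconds = as.numeric(tr_seconds),
         scan_label = as.character(scan_label)),
    class = "parcel_timeseries"
  )
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat(sprintf("<parcel_timeseries '%s': %d nodes x %d frames, TR = %g s>\n",
              x$scan_label, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

n_frames <- function(ts) ncol(ts$values)
n_nodes <- function(ts) nrow(ts$values)

#' Read a parcellated timeseries
#'
#' The canonical interchange format is TSV: tab-separated, UTF-8, one row per
#' node, first column `node` holding the node id, remaining columns one per
#' frame (header `node<TAB>f0<TAB>f1...`).
#'
#' @param path path to the file.
#' @param format `"tsv"` (the canonical format). `"cifti-ptseries"` is
#'   recognised but not supported in this build and raises an error.
#' @param tr_seconds sampling interval to attach (TSV carries no TR).
#' @param scan_label scan label to attach.
#' @return a [parcel_timeseries()].
#' @export
read_timeseries <- function(path, format = c("tsv", "cifti-ptseries"),
                            tr_seconds = 0.7, scan_label = "scan") {
  format <- match.arg(format)
  if (format == "cifti-ptseries") {
    stop("CIFTI parcellated-timeseries input is not supported; ",
         "convert to the TSV interchange format", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3L) {
    stop("malformed timeseries TSV (need a node column and >= 2 frames): ",
         path, call. = FALSE)
  }
  ids <- tab[[1L]]
  num <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab)))
  )
  num <- matrix(num, nrow = nrow(tab))
  if (!all(is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing value at line ", bad[1L] + 1L,
         " (node ", ids[bad[1L]], ") of ", path, call. = FALSE)
  }
  parcel_timeseries(num, node_ids = ids, tr_seconds = tr_seconds,
                    scan_label = scan_label)
}

#' Write a parcellated timeseries as TSV
#'
#' @param ts a [parcel_timeseries()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  tab <- data.frame(node = ts$node_ids, ts$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab) <- c("node", paste0("f", seq_len(n_frames(ts)) - 1L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a network atlas
#'
#' Maps each node to exactly one of the six intrinsic connectivity networks
#' (see [NETWORK_LABELS]).
#'
#' @param node_ids ordered, unique node labels.
#' @param affiliation character vector of network labels, one per node, each
#'   in [NETWORK_LABELS].
#' @return an object of class `network_atlas` with fields `node_ids` and
#'   `affiliation` (named by node).
#' @export
network_atlas <- function(node_ids, affiliation) {
  node_ids <- as.character(node_ids)
  affiliation <- as.character(affiliation)
  if (length(node_ids) != length(affiliation)) {
    stop("node_ids and affiliation differ in length", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) {
    stop("duplicate node ids in atlas: ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(affiliation), NETWORK_LABELS)
  if (length(unknown)) {
    stop("unknown network label(s) ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(NETWORK_LABELS, collapse = ", "), call. = FALSE)
  }
  sizes <- table(affiliation)
  if (!any(sizes >= 2L)) {
    stop("at least one network must have >= 2 member nodes", call. = FALSE)
  }
  names(affiliation) <- node_ids
  structure(list(node_ids = node_ids, affiliation = affiliation),
            class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  sizes <- table(factor(x$affiliation, levels = NETWORK_LABELS))
  cat(sprintf("<network_atlas: %d nodes; %s>\n", length(x$node_ids),
              paste(names(sizes), sizes, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Members of one network
#'
#' @param atlas a [network_atlas()].
#' @param network a label from [NETWORK_LABELS].
#' @return character vector of node ids affiliated with `network`.
#' @export
network_members <- function(atlas, network) {
  stopifnot(inherits(atlas, "network_atlas"))
  atlas$node_ids[atlas$affiliation[atlas$node_ids] == network]
}

#' Read a node-to-network atlas table
#'
#' Expects a two-column TSV with header `node<TAB>network`; network labels
#' must come from [NETWORK_LABELS].
#'
#' @param path path to the atlas TSV.
#' @return a [network_atlas()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("atlas TSV needs columns node, network", call. = FALSE)
  network_atlas(tab[[1L]], tab[[2L]])
}

#' Write a network atlas as TSV
#'
#' @param atlas a [network_atlas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "network_atlas"))
  utils::write.table(
    data.frame(node = atlas$node_ids,
               network = unname(atlas$affiliation[atlas$node_ids])),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop initial frames from a scan
#'
#' Removes the first `k` frames (e.g. the customary removal of initial
#' volumes before steady-state magnetisation).
#'
#' @param ts a [parcel_timeseries()].
#' @param k nonnegative integer, strictly less than the frame count.
#' @return the trimmed [parcel_timeseries()].
#' @export
drop_initial_frames <- function(ts, k) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k)) {
    stop("k must be a single nonnegative integer", call. = FALSE)
  }
  if (k >= n_frames(ts)) {
    stop("cannot drop ", k, " frames from a ", n_frames(ts), "-frame scan",
         call. = FALSE)
  }
  if (k == 0L) return(ts)
  parcel_timeseries(ts$values[, -seq_len(k), drop = FALSE],
                    node_ids = ts$node_ids, tr_seconds = ts$tr_seconds,
                    scan_label = ts$scan_label)
}

#' Construct a confound set
#'
#' Frame-by-k matrix of nuisance regressors aligned with a scan.
#'
#' @param regressors numeric matrix, one row per frame, one column per
#'   regressor; all entries finite.
#' @param labels column names (default taken from the matrix).
#' @return an object of class `confound_set`.
#' @export
confound_set <- function(regressors, labels = colnames(regressors)) {
  regressors <- as.matrix(regressors)
  storage.mode(regressors) <- "double"
  if (ncol(regressors) == 0L) stop("confound set has zero columns", call. = FALSE)
  if (!all(is.finite(regressors))) stop("non-finite confound values", call. = FALSE)
  if (is.null(labels)) labels <- paste0("conf", seq_len(ncol(regressors)))
  stopifnot(length(labels) == ncol(regressors))
  colnames(regressors) <- labels
  structure(list(regressors = regressors, labels = as.character(labels)),
            class = "confound_set")
}

#' Expand motion parameters to the 24-regressor set
#'
#' From k base regressors (typically the 6 rigid-body motion parameters)
#' builds 4k columns: the originals, their first (backward) differences with
#' the first frame backfilled with 0, the squares of the originals, and the
#' squares of the differences. This is the standard derivatives-and-squares
#' expansion used in motion regression.
#'
#' @param base a [confound_set()] with k columns.
#' @return a [confound_set()] with 4k columns, labels suffixed
#'   `_d1`, `_sq`, `_d1sq`.
#' @export
expand_motion_confounds <- function(base) {
  stopifnot(inherits(base, "confound_set"))
  x <- base$regressors
  d1 <- rbind(0, diff(x))
  out <- cbind(x, d1, x^2, d1^2)
  labs <- c(base$labels,
            paste0(base$labels, "_d1"),
            paste0(base$labels, "_sq"),
            paste0(base$labels, "_d1sq"))
  confound_set(out, labs)
}

# Residualise each row of Y (node x frame) on design X (frame x p) plus an
# intercept. Exactly collinear columns are dropped with a warning; returns
# the residual matrix. Shared by regress_confounds() and mgtr().
residualise <- function(Y, X, what = "confound") {
  Tn <- ncol(Y)
  design <- cbind(intercept = rep(1, Tn), X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warning("dropping exactly collinear ", what, " column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    design <- design[, sort(keep), drop = FALSE]
    qrd <- qr(design)
  }
  if (qrd$rank == 0L) stop("usable design has rank 0", call. = FALSE)
  # residuals of t(Y) ~ design, node-wise
  t(qr.resid(qrd, t(Y)))
}

#' Regress confounds out of a scan
#'
#' Residualises every node's series on the confound columns plus an
#' intercept (ordinary least squares). Exactly collinear confound columns
#' are dropped with a warning.
#'
#' @param ts a [parcel_timeseries()].
#' @param conf a [confound_set()] with one row per frame of `ts`.
#' @return the residual [parcel_timeseries()].
#' @export
regress_confounds <- function(ts, conf) {
  stopifnot(inherits(ts, "parcel_timeseries"), inherits(conf, "confound_set"))
  if (nrow(conf$regressors) != n_frames(ts)) {
    stop("confound rows (", nrow(conf$regressors),
         ") do not match frame count (", n_frames(ts), ")", call. = FALSE)
  }
  res <- residualise(ts$values, conf$regressors)
  parcel_timeseries(res, node_ids = ts$node_ids, tr_seconds = ts$tr_seconds,
                    scan_label = ts$scan_label)
}

#' Mean-timeseries regression
#'
#' Regresses the across-node mean series (the parcel-level analogue of the
#' mean grayordinate timeseries, MGTR) out of every node, with an intercept.
#' Each output series is orthogonal to the input mean series.
#'
#' @param ts a [parcel_timeseries()] with >= 2 nodes.
#' @return the residual [parcel_timeseries()].
#' @export
mgtr <- function(ts) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  m <- colMeans(ts$values)
  if (stats::sd(m) < .Machine$double.eps^0.5) {
    stop("across-node mean series has (near-)zero variance; ",
         "mean-timeseries regression is degenerate", call. = FALSE)
  }
  res <- residualise(ts$values, matrix(m, ncol = 1L,
                                       dimnames = list(NULL, "mean_ts")),
                     what = "mean-series")
  parcel_timeseries(res, node_ids = ts$node_ids, tr_seconds = ts$tr_seconds,
                    scan_label = ts$scan_label)
}

#' Standard cleanup for a raw parcel timeseries
#'
#' Applies, in order: initial-frame dropping, motion-confound regression
#' (with the derivatives-and-squares expansion), and mean-timeseries
#' regression.
#'
#' @param ts a [parcel_timeseries()].
#' @param motion optional [confound_set()] of base motion parameters, one
#'   row per frame of the *original* scan; trimmed along with the frames.
#' @param drop_frames number of initial frames to discard (default 5).
#' @param run_mgtr apply mean-timeseries regression (default TRUE).
#' @return the cleaned [parcel_timeseries()].
#' @export
clean_timeseries <- function(ts, motion = NULL, drop_frames = 5L,
                             run_mgtr = TRUE) {
  out <- drop_initial_frames(ts, drop_frames)
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "confound_set"))
    reg <- motion$regressors
    if (nrow(reg) == n_frames(ts) && drop_frames > 0L) {
      reg <- reg[-seq_len(drop_frames), , drop = FALSE]
    }
    out <- regress_confounds(out, expand_motion_confounds(
      confound_set(reg, motion$labels)))
  }
  if (run_mgtr) out <- mgtr(out)
  out
}
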