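# Subject-level connectivity: Pearson correlation matrices, Fisher z,
# sparsity-thresholded binary and weighted networks.

new_connectivity <- function(values, kind, node_labels) {
  dimnames(values) <- list(node_labels, node_labels)
  structure(list(values = values, kind = kind, node_labels = node_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Pearson correlation matrix of ROI time series
#'
#' Entry (i, j) is the sample Pearson correlation between the time
#' courses of regions i and j; the diagonal is fixed at 0 by convention
#' (self-connections are excluded from all thresholding and statistics).
#'
#' @param ts a [roi_timeseries()] with at least 3 time points.
#' @return A `connectivity_matrix` of kind `"pearson_r"`.
#' @export
pearson_matrix <- function(ts) {
  ts <- as_roi(ts)
  x <- ts$data
  if (nrow(x) < 3L) stop_wmhnet("need at least 3 time points")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop_wmhnet("zero-variance node(s): ",
                paste(ts$node_labels[sds == 0], collapse = ", "))
  r <- cor(x)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 0
  new_connectivity(r, "pearson_r", ts$node_labels)
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies z = artanh(r) off-diagonal to improve normality; |r| is first
#' clipped to 1 - 1e-7 so perfect correlations map to a finite value.
#'
#' @param c a `connectivity_matrix` of kind `"pearson_r"`.
#' @return A `connectivity_matrix` of kind `"fisher_z"`.
#' @export
fisher_z <- function(c) {
  if (!inherits(c, "connectivity_matrix") || c$kind != "pearson_r")
    stop_wmhnet("fisher_z expects a pearson_r connectivity matrix")
  r <- c$values
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  new_connectivity(z, "fisher_z", c$node_labels)
}

#' Sparsity grid
#'
#' @param thresholds strictly increasing sparsity values in (0, 1);
#'   default 0.05 to 0.40 in steps of 0.05.
#' @return Numeric vector of class `sparsity_grid`.
#' @export
sparsity_grid <- function(thresholds = seq(0.05, 0.40, by = 0.05)) {
  thresholds <- as.numeric(thresholds)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop_wmhnet("sparsity values must lie in (0, 1)")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_wmhnet("sparsity values must be strictly increasing")
  structure(thresholds, class = "sparsity_grid")
}

# ranking of the upper-triangle entries used for edge retention:
# strongest z first, ties broken by ascending (i, j) node-index pair
edge_order <- function(values, keep = c("positive", "absolute")) {
  keep <- match.arg(keep)
  n <- nrow(values)
  ut <- which(upper.tri(values))
  v <- values[ut]
  if (keep == "absolute") v <- abs(v)
  cols <- ((ut - 1) %/% n) + 1
  rows <- ut - (cols - 1) * n
  ord <- order(-v, rows, cols)
  list(ut = ut[ord], rows = rows[ord], cols = cols[ord])
}

edge_count_for <- function(s, n) {
  m <- n * (n - 1) / 2
  e <- round(s * m)          # round-half-even, documented convention
  if (e <= 0 || e >= m)
    stop_wmhnet(sprintf(
      "degenerate sparsity %.4g: would retain %d of %d edges", s, e, m))
  as.integer(e)
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  reached <- logical(n)
  frontier <- 1L
  reached[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !reached)
    reached[nb] <- TRUE
    frontier <- nb
  }
  all(reached)
}

#' Binarize a connectivity matrix at a sparsity threshold
#'
#' Retains exactly `round(s * N * (N - 1) / 2)` undirected edges with the
#' largest z-values (most-positive by default; GRETNA-style sparsity
#' thresholding).  Ties at the cutoff are broken by ascending node-index
#' pair, so the edge set is deterministic and nested across thresholds.
#'
#' @param z a `connectivity_matrix` (typically Fisher z).
#' @param s target sparsity in (0, 1).
#' @param keep `"positive"` ranks raw values, `"absolute"` ranks |z|.
#' @return Object of class `binary_network` with fields `adjacency`,
#'   `sparsity`, `n_edges`, `connected`, `node_labels`.
#' @export
binarize_at_sparsity <- function(z, s, keep = c("positive", "absolute")) {
  keep <- match.arg(keep)
  if (!inherits(z, "connectivity_matrix"))
    stop_wmhnet("expected a connectivity_matrix")
  if (!(s > 0 && s < 1)) stop_wmhnet("sparsity must lie in (0, 1)")
  n <- nrow(z$values)
  e <- edge_count_for(s, n)
  ord <- edge_order(z$values, keep)
  adj <- matrix(0L, n, n, dimnames = list(z$node_labels, z$node_labels))
  sel <- seq_len(e)
  adj[cbind(ord$rows[sel], ord$cols[sel])] <- 1L
  adj[cbind(ord$cols[sel], ord$rows[sel])] <- 1L
  structure(list(adjacency = adj, sparsity = s, n_edges = e,
                 connected = is_connected_adj(adj),
                 node_labels = z$node_labels, keep = keep),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %.3g)%s\n",
              nrow(x$adjacency), x$n_edges, x$sparsity,
              if (x$connected) "" else " [disconnected]"))
  invisible(x)
}

#' Threshold a matrix over a sparsity grid
#'
#' @inheritParams binarize_at_sparsity
#' @param grid a [sparsity_grid()].
#' @return List of `binary_network`, one per threshold; edge sets are
#'   nested (lower sparsity is a subgraph of higher).
#' @export
sparsity_sweep <- function(z, grid = sparsity_grid(),
                           keep = c("positive", "absolute")) {
  keep <- match.arg(keep)
  lapply(as.numeric(grid), function(s) binarize_at_sparsity(z, s, keep))
}

#' Weighted network at a sparsity threshold
#'
#' Same edge-retention rule as [binarize_at_sparsity()]; retained entries
#' carry |z| as weight (weights are magnitudes, invariant to the sign of
#' z), others 0.  `s = "dense"` keeps every off-diagonal entry.
#'
#' @inheritParams binarize_at_sparsity
#' @param s sparsity in (0, 1), or `"dense"`.
#' @return Object of class `weighted_network`.
#' @export
weighted_network <- function(z, s = "dense",
                             keep = c("positive", "absolute")) {
  keep <- match.arg(keep)
  if (!inherits(z, "connectivity_matrix"))
    stop_wmhnet("expected a connectivity_matrix")
  n <- nrow(z$values)
  if (identical(s, "dense")) {
    w <- abs(z$values)
    diag(w) <- 0
  } else {
    bn <- binarize_at_sparsity(z, s, keep)
    w <- abs(z$values) * bn$adjacency
  }
  dimnames(w) <- list(z$node_labels, z$node_labels)
  structure(list(weights = w, sparsity = s, node_labels = z$node_labels),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, %d edges (sparsity %s)\n",
              nrow(x$weights), sum(x$weights[upper.tri(x$weights)] > 0),
              format(x$sparsity)))
  invisible(x)
}
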