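# Topological indices on binary and weighted networks: clustering,
# characteristic path length, global/local/nodal efficiency.
#
# Conventions (GRETNA-style): nodes with degree < 2 contribute 0 to the
# Cp and Eloc means; unreachable pairs have infinite distance, which
# efficiencies treat as 0 and Lp excludes (with a disconnected flag).

adjacency_of <- function(net) {
  if (inherits(net, "binary_network")) return(net$adjacency)
  if (is.matrix(net)) {
    a <- (net != 0) * 1L
    diag(a) <- 0L
    return(a)
  }
  stop_wmhnet("expected a binary_network or adjacency matrix")
}

#' Clustering coefficient
#'
#' Node i's value is the fraction of realized edges among its
#' neighbors, `2 t_i / (k_i (k_i - 1))` with `t_i` triangles through i;
#' nodes of degree < 2 contribute 0.  Cp is the mean over all nodes.
#'
#' @param net a `binary_network` (or 0/1 adjacency matrix).
#' @return List with `per_node` values and the mean `cp`.
#' @export
clustering_coefficient <- function(net) {
  a <- adjacency_of(net)
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)     # = 2 * triangles per node
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri2 / denom, 0)
  list(per_node = unname(ci), cp = mean(ci))
}

# all-pairs BFS distances via boolean matrix powers (fast for N <= a few
# hundred); Inf marks unreachable pairs
bfs_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- a > 0
  step <- 1
  repeat {
    new <- reach & !is.finite(d)
    if (!any(new)) break
    d[new] <- step
    nxt <- (reach %*% a) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
    step <- step + 1
  }
  d
}

# Dijkstra from every source on a nonnegative-length matrix (Inf = no edge)
dijkstra_all <- function(len) {
  n <- nrow(len)
  out <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    done <- logical(n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      relax <- dist[u] + len[u, ]
      upd <- relax < dist
      dist[upd] <- relax[upd]
    }
    out[src, ] <- dist
  }
  diag(out) <- 0
  out
}

#' Shortest-path distance matrix
#'
#' Breadth-first distances for binary networks; Dijkstra least-cost paths
#' with edge length 1/weight for weighted networks.  Unreachable pairs
#' are `Inf`, the diagonal 0.
#'
#' @param net a `binary_network` or `weighted_network`.
#' @return N x N numeric distance matrix.
#' @export
shortest_path_matrix <- function(net) {
  if (inherits(net, "weighted_network")) {
    len <- ifelse(net$weights > 0, 1 / net$weights, Inf)
    diag(len) <- Inf
    return(dijkstra_all(len))
  }
  bfs_distances(adjacency_of(net))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs.  If the network
#' is disconnected the mean is taken over reachable pairs only and the
#' result is flagged.
#'
#' @inheritParams shortest_path_matrix
#' @param d optional precomputed distance matrix.
#' @return List with `lp` and logical `disconnected`.
#' @export
characteristic_path_length <- function(net, d = NULL) {
  if (is.null(d)) d <- shortest_path_matrix(net)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin) || all(fin == 0))
    stop_wmhnet("path length undefined: network has no edges")
  list(lp = mean(fin), disconnected = any(!is.finite(off)))
}

#' Global efficiency
#'
#' Mean over ordered off-diagonal pairs of inverse distance, with
#' `1/Inf = 0`, so disconnection is penalized rather than excluded.
#'
#' @inheritParams characteristic_path_length
#' @return Scalar Eglob in `[0, 1]` for binary networks.
#' @export
global_efficiency <- function(net, d = NULL) {
  if (is.null(d)) d <- shortest_path_matrix(net)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' Node i's value is `mean_j 1/d(i, j)` over the other N - 1 nodes; the
#' mean over nodes equals the global efficiency exactly.
#'
#' @inheritParams characteristic_path_length
#' @return Numeric vector of per-node efficiencies.
#' @export
nodal_efficiency <- function(net, d = NULL) {
  if (is.null(d)) d <- shortest_path_matrix(net)
  inv <- 1 / d
  diag(inv) <- 0
  unname(rowSums(inv) / (nrow(d) - 1))
}

#' Local efficiency
#'
#' Node i's value is the global efficiency of the subgraph induced by
#' i's neighbors (i excluded); nodes with fewer than 2 neighbors
#' contribute 0.  Eloc is the mean over all nodes.
#'
#' @param net a `binary_network` or `weighted_network`.
#' @return List with `per_node` values and the mean `eloc`.
#' @export
local_efficiency <- function(net) {
  weighted <- inherits(net, "weighted_network")
  a <- if (weighted) net$weights else adjacency_of(net)
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) next
    sub <- a[nb, nb, drop = FALSE]
    d <- if (weighted) {
      len <- ifelse(sub > 0, 1 / sub, Inf)
      diag(len) <- Inf
      dijkstra_all(len)
    } else bfs_distances((sub > 0) * 1L)
    inv <- 1 / d
    diag(inv) <- 0
    m <- length(nb)
    vals[i] <- sum(inv) / (m * (m - 1))
  }
  list(per_node = vals, eloc = mean(vals))
}

#' All whole-brain metrics of a binary network
#'
#' Convenience wrapper computing Cp, Lp, Eglob, Eloc and the per-node
#' efficiency vectors in one pass over the distance matrix.
#'
#' @param net a `binary_network`.
#' @return List with `cp`, `lp`, `eglob`, `eloc`, `nodal_e`,
#'   `nodal_eloc`, `disconnected`.
#' @export
binary_metrics <- function(net) {
  d <- shortest_path_matrix(net)
  cl <- clustering_coefficient(net)
  pl <- characteristic_path_length(net, d)
  le <- local_efficiency(net)
  list(cp = cl$cp, lp = pl$lp, eglob = global_efficiency(net, d),
       eloc = le$eloc, nodal_e = nodal_efficiency(net, d),
       nodal_eloc = le$per_node, disconnected = pl$disconnected)
}

#' Metrics of a weighted network
#'
#' Distances use edge length 1/weight (Dijkstra); clustering uses the
#' Onnela geometric-mean-of-triangle-weights rule with weights normalized
#' by the maximum weight; local efficiency is the weighted global
#' efficiency of each neighbor subgraph.  With 0/1 weights every metric
#' reduces exactly to its binary counterpart.
#'
#' @param net a `weighted_network` with nonnegative weights.
#' @return List with `cp`, `lp`, `eglob`, `eloc`, `nodal_e`,
#'   `nodal_eloc`, `disconnected`.
#' @export
weighted_metrics <- function(net) {
  if (!inherits(net, "weighted_network"))
    stop_wmhnet("expected a weighted_network")
  w <- net$weights
  if (any(w < 0)) stop_wmhnet("weights must be nonnegative")
  wmax <- max(w)
  if (wmax == 0) stop_wmhnet("network has no edges")
  wn <- (w / wmax)^(1 / 3)
  k <- rowSums(w > 0)
  tri <- diag(wn %*% wn %*% wn)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri / denom, 0)
  d <- shortest_path_matrix(net)
  pl <- characteristic_path_length(net, d)
  le <- local_efficiency(net)
  list(cp = mean(ci), lp = pl$lp, eglob = global_efficiency(net, d),
       eloc = le$eloc, nodal_e = nodal_efficiency(net, d),
       nodal_eloc = le$per_node, disconnected = pl$disconnected)
}
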