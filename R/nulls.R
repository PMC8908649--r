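# Degree-preserving random null networks (Maslov-Sneppen double-edge
# swaps) and the small-world indices gamma, lambda, sigma.

#' Null-ensemble parameters
#'
#' @param n_random number of random networks (default 100).
#' @param swaps_per_edge attempted double-edge swaps per edge; 0 returns
#'   the input unchanged (self-null, useful for testing).
#' @param seed integer master seed.
#' @return List of class `null_ensemble_params`.
#' @export
null_ensemble_params <- function(n_random = 100L, swaps_per_edge = 10L,
                                 seed = 1L) {
  n_random <- as.integer(n_random)
  swaps_per_edge <- as.integer(swaps_per_edge)
  if (n_random < 1L) stop_wmhnet("n_random must be >= 1")
  if (swaps_per_edge < 0L) stop_wmhnet("swaps_per_edge must be >= 0")
  structure(list(n_random = n_random, swaps_per_edge = swaps_per_edge,
                 seed = as.integer(seed)),
            class = "null_ensemble_params")
}

#' Degree-preserving rewiring
#'
#' Performs `swaps_per_edge * E` attempted double-edge swaps
#' (Maslov-Sneppen), rejecting any swap that would create a self-loop or
#' duplicate edge.  The degree sequence is exactly preserved.  Graphs
#' admitting no valid swap (e.g. complete graphs) are returned unchanged
#' with `rewired = FALSE`.
#'
#' @param net a `binary_network` with at least 2 edges.
#' @param params a [null_ensemble_params()]; only `swaps_per_edge` and
#'   `seed` are used.
#' @return A rewired `binary_network` (attribute field `rewired`).
#' @export
degree_preserving_rewire <- function(net, params = null_ensemble_params()) {
  adj <- adjacency_of(net)
  n <- nrow(adj)
  ut <- which(upper.tri(adj) & adj > 0)
  e <- length(ut)
  if (e < 2L) stop_wmhnet("need at least 2 edges to rewire")
  cols <- ((ut - 1) %/% n) + 1
  rows <- ut - (cols - 1) * n
  edges <- cbind(rows, cols)
  attempts <- params$swaps_per_edge * e
  swapped <- 0L
  if (attempts > 0) {
    with_seed(params$seed, {
      pick <- matrix(sample.int(e, 2L * attempts, replace = TRUE),
                     ncol = 2L)
      flip <- runif(attempts) < 0.5
      for (t in seq_len(attempts)) {
        i1 <- pick[t, 1]; i2 <- pick[t, 2]
        if (i1 == i2) next
        a <- edges[i1, 1]; b <- edges[i1, 2]
        c_ <- edges[i2, 1]; d <- edges[i2, 2]
        if (flip[t]) { tmp <- c_; c_ <- d; d <- tmp }
        # propose (a,d) and (c_,b)
        if (a == d || c_ == b) next
        if (adj[a, d] == 1L || adj[c_, b] == 1L) next
        adj[a, b] <- adj[b, a] <- 0L
        adj[c_, d] <- adj[d, c_] <- 0L
        adj[a, d] <- adj[d, a] <- 1L
        adj[c_, b] <- adj[b, c_] <- 1L
        edges[i1, ] <- if (a < d) c(a, d) else c(d, a)
        edges[i2, ] <- if (c_ < b) c(c_, b) else c(b, c_)
        swapped <- swapped + 1L
      }
    })
  }
  out <- net
  out$adjacency <- adj
  out$connected <- is_connected_adj(adj)
  out$rewired <- swapped > 0L
  out
}

#' Small-world indices
#'
#' Computes gamma = Cp(net) / mean Cp over `n_random` degree-preserving
#' null networks, lambda = Lp(net) / mean null Lp, and sigma =
#' gamma / lambda.  A network is called small-world when gamma > 1 with
#' lambda close to 1, equivalently sigma > 1.
#'
#' @param net a connected `binary_network` (disconnected inputs are
#'   processed with the reachable-pairs Lp convention and flagged).
#' @param params a [null_ensemble_params()].
#' @return List with `gamma`, `lambda`, `sigma`, `cp`, `lp`,
#'   `disconnected`.
#' @export
small_world_indices <- function(net, params = null_ensemble_params()) {
  cp <- clustering_coefficient(net)$cp
  pl <- characteristic_path_length(net)
  seeds <- derive_seeds(params$seed, params$n_random)
  null_cp <- null_lp <- numeric(params$n_random)
  for (i in seq_len(params$n_random)) {
    p_i <- params
    p_i$seed <- seeds[i]
    rn <- degree_preserving_rewire(net, p_i)
    null_cp[i] <- clustering_coefficient(rn)$cp
    null_lp[i] <- characteristic_path_length(rn)$lp
  }
  if (mean(null_cp) == 0)
    stop_wmhnet("null ensemble has zero mean clustering; gamma undefined")
  g <- cp / mean(null_cp)
  l <- pl$lp / mean(null_lp)
  list(gamma = g, lambda = l, sigma = g / l, cp = cp, lp = pl$lp,
       disconnected = pl$disconnected)
}
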