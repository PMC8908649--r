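# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately share no code with R/.

# O(N^3) Floyd-Warshall reference on an edge-length matrix
fw_oracle <- function(len) {
  n <- nrow(len)
  d <- len
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

fw_binary <- function(adj) {
  len <- ifelse(adj > 0, 1, Inf)
  fw_oracle(len)
}

# per-node triangle enumeration
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in seq(a + 1, k))
        links <- links + adj[nb[a], nb[b]]
    2 * links / (k * (k - 1))
  })
}

global_eff_oracle <- function(adj) {
  d <- fw_binary(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(adj) * (nrow(adj) - 1))
}

local_eff_oracle <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_eff_oracle(adj[nb, nb, drop = FALSE])
  })
}

# BH step-up straight from the formula
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(ord == i)           # rank of p[i]
    adj[i] <- min(1, min(p[ord][seq(k, m)] * m / seq(k, m)))
  }
  adj
}

# partial correlation by explicit double residualization with lm()
partial_oracle <- function(x, y, covs) {
  df <- data.frame(x = x, y = y, covs)
  rx <- residuals(lm(x ~ ., data = df[setdiff(names(df), "y")]))
  ry <- residuals(lm(y ~ ., data = df[setdiff(names(df), "x")]))
  cor(rx, ry)
}

# seeded Erdos-Renyi adjacency with at least `min_edges` edges
random_adj <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0L, n, n)
    ut <- upper.tri(a)
    a[ut] <- rbinom(sum(ut), 1, p)
    a <- a + t(a)
    a
  })
}

# Watts-Strogatz ring lattice (k nearest neighbours) with rewiring prob p
ws_adjacency <- function(n, k, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(0L, n, n)
    for (i in seq_len(n))
      for (off in seq_len(k / 2)) {
        j <- ((i - 1 + off) %% n) + 1
        a[i, j] <- a[j, i] <- 1L
      }
    for (i in seq_len(n))
      for (off in seq_len(k / 2)) {
        j <- ((i - 1 + off) %% n) + 1
        if (runif(1) < p) {
          cand <- which(a[i, ] == 0)
          cand <- cand[cand != i]
          if (length(cand)) {
            nw <- cand[sample.int(length(cand), 1)]
            a[i, j] <- a[j, i] <- 0L
            a[i, nw] <- a[nw, i] <- 1L
          }
        }
      }
    a
  })
}

adj_to_binary_net <- function(adj, sparsity = NA_real_) {
  labels <- paste0("node_", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, sparsity = sparsity,
                 n_edges = sum(adj[upper.tri(adj)]),
                 connected = NA, node_labels = labels),
            class = "binary_network")
}

adj_to_weighted_net <- function(w) {
  labels <- paste0("node_", seq_len(nrow(w)))
  dimnames(w) <- list(labels, labels)
  structure(list(weights = w, sparsity = NA_real_, node_labels = labels),
            class = "weighted_network")
}

random_connectivity <- function(n, seed, kind = "fisher_z") {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n * n), n)
    v <- (v + t(v)) / 2
    diag(v) <- 0
    labels <- paste0("node_", seq_len(n))
    dimnames(v) <- list(labels, labels)
    structure(list(values = v, kind = kind, node_labels = labels),
              class = "connectivity_matrix")
  })
}

small_cohort_params <- function(seed = 1, ...) {
  defaults <- list(n_group_a = 6L, n_group_b = 6L, n_regions = 24L,
                   n_timepoints = 90L, n_modules = 3L, seed = seed)
  do.call(cohort_params, utils::modifyList(defaults, list(...)))
}
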