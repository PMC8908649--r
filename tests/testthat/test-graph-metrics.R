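k_n <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}
path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
star <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}

test_that("canonical graphs give exact closed forms", {
  expect_equal(clustering_coefficient(adj_to_binary_net(k_n(3)))$cp, 1)
  expect_equal(clustering_coefficient(adj_to_binary_net(path3))$cp, 0)
  expect_equal(characteristic_path_length(adj_to_binary_net(path3))$lp,
               4 / 3)
  expect_equal(characteristic_path_length(adj_to_binary_net(k_n(5)))$lp, 1)
  expect_equal(global_efficiency(adj_to_binary_net(path3)), 5 / 6)
  expect_equal(global_efficiency(adj_to_binary_net(k_n(6))), 1)
  expect_equal(local_efficiency(adj_to_binary_net(k_n(4)))$eloc, 1)
  expect_equal(local_efficiency(adj_to_binary_net(star(5)))$eloc, 0)
  ne <- nodal_efficiency(adj_to_binary_net(star(4)))
  expect_equal(ne[1], 1)            # hub reaches everyone in one step
  expect_equal(ne[2], 2 / 3)        # leaf: (1 + 1/2 + 1/2) / 3
  d <- shortest_path_matrix(adj_to_binary_net(k_n(4)))
  expect_true(all(d[row(d) != col(d)] == 1))
  expect_equal(shortest_path_matrix(adj_to_binary_net(path3))[1, 3], 2)
})

test_that("distances, clustering and local efficiency match brute-force oracles", {
  for (seed in 1:6) {
    n <- sample(8:20, 1)
    adj <- random_adj(n, p = 0.25, seed = seed)
    net <- adj_to_binary_net(adj)
    expect_equal(shortest_path_matrix(net), fw_binary(adj))
    expect_equal(clustering_coefficient(net)$per_node,
                 clustering_oracle(adj))
    expect_equal(local_efficiency(net)$per_node, local_eff_oracle(adj))
    expect_equal(global_efficiency(net), global_eff_oracle(adj))
  }
})

test_that("mean nodal efficiency equals global efficiency (identity)", {
  for (seed in 1:5) {
    net <- adj_to_binary_net(random_adj(15, 0.3, seed))
    expect_equal(mean(nodal_efficiency(net)), global_efficiency(net),
                 tolerance = 1e-12)
  }
})

test_that("disconnected graphs follow the reachable-pairs convention", {
  two_edges <- matrix(0L, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1L
  two_edges[3, 4] <- two_edges[4, 3] <- 1L
  pl <- characteristic_path_length(adj_to_binary_net(two_edges))
  expect_equal(pl$lp, 1)
  expect_true(pl$disconnected)
  expect_equal(global_efficiency(adj_to_binary_net(two_edges)),
               (1 + 1) * 2 / (4 * 3))
  empty <- matrix(0L, 4, 4)
  expect_error(characteristic_path_length(adj_to_binary_net(empty)),
               "no edges")
})

test_that("metrics are invariant under node relabeling", {
  adj <- random_adj(14, 0.3, seed = 21)
  net <- adj_to_binary_net(adj)
  perm <- withr::with_seed(5, sample(14))
  padj <- adj[perm, perm]
  pnet <- adj_to_binary_net(padj)
  expect_equal(clustering_coefficient(pnet)$cp,
               clustering_coefficient(net)$cp)
  expect_equal(characteristic_path_length(pnet)$lp,
               characteristic_path_length(net)$lp)
  expect_equal(global_efficiency(pnet), global_efficiency(net))
  expect_equal(local_efficiency(pnet)$eloc, local_efficiency(net)$eloc)
  expect_equal(sort(nodal_efficiency(pnet)), sort(nodal_efficiency(net)))
})

test_that("adding an edge never decreases Eglob or any NodalE", {
  for (seed in 1:5) {
    adj <- random_adj(12, 0.2, seed = seed + 30)
    net <- adj_to_binary_net(adj)
    holes <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    h <- holes[withr::with_seed(seed, sample(nrow(holes), 1)), ]
    adj2 <- adj
    adj2[h[1], h[2]] <- adj2[h[2], h[1]] <- 1L
    net2 <- adj_to_binary_net(adj2)
    expect_gte(global_efficiency(net2), global_efficiency(net))
    expect_true(all(nodal_efficiency(net2) >= nodal_efficiency(net) - 1e-12))
  }
})

test_that("degree_preserving_rewire preserves degrees, seeds reproduce", {
  z <- random_connectivity(30, seed = 2)
  net <- binarize_at_sparsity(z, 0.15)
  par <- null_ensemble_params(1, 10, seed = 42)
  r1 <- degree_preserving_rewire(net, par)
  r2 <- degree_preserving_rewire(net, par)
  expect_identical(r1$adjacency, r2$adjacency)
  expect_equal(rowSums(r1$adjacency), rowSums(net$adjacency))
  expect_true(r1$rewired)
  expect_false(identical(r1$adjacency, net$adjacency))
  expect_true(all(diag(r1$adjacency) == 0))
  expect_equal(r1$adjacency, t(r1$adjacency))
  # a different seed gives a different rewiring
  par2 <- null_ensemble_params(1, 10, seed = 43)
  expect_false(identical(degree_preserving_rewire(net, par2)$adjacency,
                         r1$adjacency))
  # complete graph admits no valid swap
  k5 <- adj_to_binary_net(k_n(5))
  rk <- degree_preserving_rewire(k5, par)
  expect_equal(rk$adjacency, k5$adjacency)
  expect_false(rk$rewired)
})

test_that("small_world_indices: self-null gives exactly 1", {
  z <- random_connectivity(25, seed = 6)
  net <- binarize_at_sparsity(z, 0.2)
  sw <- small_world_indices(net, null_ensemble_params(5, 0, seed = 1))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  # sigma = gamma / lambda always
  sw2 <- small_world_indices(net, null_ensemble_params(10, 5, seed = 1))
  expect_equal(sw2$sigma, sw2$gamma / sw2$lambda, tolerance = 1e-12)
})

test_that("weighted metrics reduce to binary on 0/1 weights and match Dijkstra oracle", {
  adj <- random_adj(12, 0.35, seed = 8)
  bnet <- adj_to_binary_net(adj)
  wnet <- adj_to_weighted_net(adj * 1.0)
  bm <- binary_metrics(bnet)
  wm <- weighted_metrics(wnet)
  for (f in c("cp", "lp", "eglob", "eloc"))
    expect_equal(wm[[f]], bm[[f]], tolerance = 1e-12)
  expect_equal(wm$nodal_e, bm$nodal_e, tolerance = 1e-12)

  # uniform weight w on K3: distances scale by 1/w
  w <- 0.5
  k3w <- adj_to_weighted_net(k_n(3) * w)
  d <- shortest_path_matrix(k3w)
  expect_true(all(d[row(d) != col(d)] == 1 / w))
  expect_equal(global_efficiency(k3w, d), w)

  # random weighted graph vs Floyd-Warshall on 1/weight lengths
  withr::with_seed(17, {
    wmat <- matrix(runif(100, 0.2, 1), 10) * random_adj(10, 0.4, seed = 99)
    wmat <- pmax(wmat, t(wmat))
  })
  net <- adj_to_weighted_net(wmat)
  len <- ifelse(wmat > 0, 1 / wmat, 0)
  expect_equal(shortest_path_matrix(net), fw_oracle(len),
               tolerance = 1e-12)
})

test_that("global_profile rows and summary follow the mean convention", {
  z <- random_connectivity(30, seed = 10)
  grid <- sparsity_grid(c(0.1, 0.2, 0.3))
  gp <- global_profile(z, grid)
  expect_equal(nrow(gp$per_threshold), 3)
  expect_equal(gp$summary[["cp"]], mean(gp$per_threshold$cp))
  expect_equal(gp$summary[["lp"]], mean(gp$per_threshold$lp))
  # single-threshold grid: summary equals the row
  g1 <- global_profile(z, sparsity_grid(0.2))
  expect_equal(g1$summary[["eglob"]], g1$per_threshold$eglob[1])
  # sigma = gamma / lambda per row when nulls are on
  gp2 <- global_profile(z, sparsity_grid(0.2),
                        null_ensemble_params(5, 3, seed = 4))
  expect_equal(gp2$per_threshold$sigma,
               gp2$per_threshold$gamma / gp2$per_threshold$lambda,
               tolerance = 1e-9)
})

test_that("nodal_profile means tie out against global efficiency", {
  z <- random_connectivity(25, seed = 12)
  grid <- sparsity_grid(c(0.15, 0.3))
  np <- nodal_profile(z, grid)
  gp <- global_profile(z, grid)
  # mean over nodes of nodal_e equals eglob per threshold
  expect_equal(unname(colMeans(np$nodal_e)),
               gp$per_threshold$eglob, tolerance = 1e-9)
  expect_equal(nrow(np$summary), 25)
  expect_equal(np$summary$nodal_e_mean, rowMeans(np$nodal_e),
               ignore_attr = TRUE)
})
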