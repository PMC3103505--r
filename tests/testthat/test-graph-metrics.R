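test_that("clustering matches analytic limits and brute force", {
  tri <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3)
  cl <- clustering_coef(tri)
  expect_equal(cl$per_node, rep(1, 3))
  expect_equal(cl$C, 1)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coef(star)$C, 0)
  for (s in 1:5) {
    w <- random_test_graph(6, seed = s)
    expect_equal(clustering_coef(w)$per_node, brute_clustering(w)$per_node,
                 tolerance = 1e-12)
    expect_equal(clustering_coef(w, scaled = FALSE)$C,
                 brute_clustering(w, scaled = FALSE)$C, tolerance = 1e-12)
  }
  # equal weights reduce to the unweighted clustering coefficient
  w <- (random_test_graph(7, seed = 9) > 0) * 3
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  expect_equal(clustering_coef(w)$C,
               mean(replace(igraph::transitivity(g, type = "local"),
                            is.na(igraph::transitivity(g, type = "local")), 0)),
               tolerance = 1e-12)
})

test_that("scaled clustering stays in [0, 1] on random graphs", {
  for (s in 1:10) {
    w <- random_test_graph(8, p = 0.5, seed = 40 + s)
    cl <- clustering_coef(w)
    expect_true(all(cl$per_node >= 0 & cl$per_node <= 1))
  }
})

test_that("path length uses inverse-weight geodesics", {
  two <- matrix(c(0, 10, 10, 0), 2, 2)
  expect_equal(path_length(two)$L, 0.1)
  ring <- matrix(0, 4, 4)
  for (k in 1:4) {
    j <- k %% 4 + 1
    ring[k, j] <- ring[j, k] <- 1
  }
  expect_equal(path_length(ring)$L, 4 / 3)
  # weak direct arc bypassed by two strong hops
  tri <- matrix(c(0, 10, 1, 10, 0, 10, 1, 10, 0), 3, 3)
  expect_equal(path_length(tri)$distances[1, 3], 0.2)
  for (s in 1:5) {
    w <- random_test_graph(6, p = 0.5, seed = 50 + s)
    expect_equal(path_length(w)$L, brute_path_length(w), tolerance = 1e-12)
  }
  disc <- matrix(0, 3, 3)
  disc[1, 2] <- disc[2, 1] <- 1
  expect_error(path_length(disc), "global_efficiency")
})

test_that("efficiencies match analytic limits and brute force", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(local_efficiency(k5), 1)
  iso <- matrix(0, 2, 2)
  expect_equal(global_efficiency(iso), 0)
  # trees have zero local efficiency
  tree <- matrix(0, 5, 5)
  for (k in 1:4) tree[k, k + 1] <- tree[k + 1, k] <- 1
  expect_equal(local_efficiency(tree), 0)
  for (s in 1:5) {
    w <- random_test_graph(6, p = 0.5, seed = 60 + s)
    expect_equal(global_efficiency(w), brute_global_efficiency(w),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(w), brute_local_efficiency(w),
                 tolerance = 1e-12)
  }
  # two-node identity E_glob = 1/L
  two <- matrix(c(0, 4, 4, 0), 2, 2)
  expect_equal(global_efficiency(two), 1 / path_length(two)$L)
})

test_that("global efficiency is monotone under edge removal", {
  w <- random_test_graph(7, p = 0.7, seed = 77)
  e0 <- global_efficiency(w)
  ed <- which(upper.tri(w) & w > 0)
  for (e in ed) {
    w2 <- w
    w2[e] <- 0
    w2 <- pmin(w2, t(w2))
    expect_lte(global_efficiency(w2), e0 + 1e-12)
  }
})

test_that("modularity matches the community-fraction formula", {
  # two disconnected equal cliques: natural partition has Q = 1/2
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  expect_equal(modularity_q(w, rep(1:2, each = 4)), 0.5)
  expect_equal(modularity_q(w, rep(1, 8)), 0)
  expect_error(modularity_q(w, c(1, 2)), "membership")
  # agreement with igraph's weighted modularity on random graphs/partitions
  for (s in 1:5) {
    wg <- random_test_graph(8, p = 0.5, seed = 70 + s)
    memb <- withr::with_seed(s, sample(1:3, 8, TRUE))
    g <- igraph::graph_from_adjacency_matrix(wg, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_q(wg, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("random partitions of a random graph have near-zero mean Q", {
  w <- random_test_graph(20, p = 0.4, seed = 5)
  qs <- withr::with_seed(11, {
    replicate(300, modularity_q(w, sample(1:2, 20, TRUE)))
  })
  expect_lt(abs(mean(qs)), 0.05)
})

test_that("spectral module detection recovers planted and exhaustive optima", {
  # two cliques joined by a negligible bridge: matches exhaustive search
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  w[4, 5] <- w[5, 4] <- 1e-6
  fm <- find_modules(w)
  best <- brute_best_partition(w)
  expect_equal(length(unique(fm$membership)), 2)
  expect_equal(fm$membership[1:4], rep(fm$membership[1], 4))
  expect_equal(fm$membership[5:8], rep(fm$membership[5], 4))
  expect_equal(fm$Q, best$Q, tolerance = 1e-6)
  # planted-partition graphs with strong modules: labels recovered exactly
  for (s in 1:5) {
    memb <- rep(1:3, each = 8)
    wp <- withr::with_seed(s, {
      n <- 24
      m <- matrix(0, n, n)
      ut <- upper.tri(m)
      same <- outer(memb, memb, "==")
      p <- ifelse(same, 0.95, 0.03)
      m[ut] <- (runif(sum(ut)) < p[ut]) * runif(sum(ut), 0.9, 1.1)
      m + t(m)
    })
    fm <- find_modules(wp)
    tab <- table(fm$membership, memb)
    # one recovered module per planted block, up to relabeling
    expect_equal(length(unique(fm$membership)), 3)
    expect_true(all(apply(tab > 0, 2, sum) == 1))
    # the refined spectral optimum is at least as modular as an independent
    # leading-eigenvector implementation's
    g <- igraph::graph_from_adjacency_matrix(wp, mode = "undirected",
                                             weighted = TRUE)
    q_ig <- igraph::modularity(igraph::cluster_leading_eigen(g))
    expect_gte(fm$Q, q_ig - 1e-9)
    expect_equal(fm$Q, q_ig, tolerance = 0.1)
  }
})

test_that("random reference preserves degrees and the weight multiset", {
  w <- random_test_graph(12, p = 0.4, seed = 31)
  r <- random_reference(w, seed = 4)
  expect_equal(unname(rowSums(r > 0)), unname(rowSums(w > 0)))
  expect_equal(sort(r[upper.tri(r) & r > 0]), sort(w[upper.tri(w) & w > 0]))
  expect_identical(random_reference(w, n_swaps = 0, seed = 1), w)
  # star admits no swap
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 2
  expect_warning(rs <- random_reference(star, seed = 2), "swap")
  expect_equal(rs, star, ignore_attr = TRUE)
})

test_that("small-worldness identities hold", {
  w <- random_test_graph(12, p = 0.4, seed = 8)
  sw0 <- small_worldness(w, n_swaps = 0, seed = 1)
  expect_equal(sw0$gamma, 1)
  expect_equal(sw0$lambda, 1)
  expect_equal(sw0$sigma, 1)
  sw <- small_worldness(w, ensemble_size = 5, gamma_ensemble = 10, seed = 2)
  expect_identical(sw$sigma, sw$gamma / sw$lambda)
})

test_that("the compiled null ensemble agrees with the R reference sampler", {
  d <- group_design(n_per_group = 2, n_nodes = 60, n_modules = 4, p_in = 0.6, seed = 12)
  w <- extract_backbone(generate_group_connectomes(d)$network[[1]])
  sw <- small_worldness(w, ensemble_size = 50, gamma_ensemble = 400, seed = 3)
  # independent estimate via the exported matrix-based null sampler
  cr <- vapply(1:200, function(k) clustering_coef(random_reference(w, seed = k))$C,
               numeric(1))
  gamma_ref <- clustering_coef(w)$C / mean(cr)
  expect_equal(sw$gamma, gamma_ref, tolerance = 0.1)
})

test_that("modular high-clustering networks are small-world in almost all seeds", {
  d <- group_design(n_per_group = 2, n_nodes = 80, n_modules = 4, p_in = 0.6, seed = 19)
  w <- extract_backbone(generate_group_connectomes(d)$network[[1]])
  sig <- vapply(1:20, function(k) {
    small_worldness(w, ensemble_size = 10, gamma_ensemble = 30, seed = k)$sigma
  }, numeric(1))
  expect_gte(mean(sig > 1), 0.95)
})

test_that("metric_set returns the six measures with the sigma identity", {
  d <- group_design(n_per_group = 2, n_nodes = 50, n_modules = 4, p_in = 0.6, seed = 23)
  w <- extract_backbone(generate_group_connectomes(d)$network[[1]])
  ms <- metric_set(w, ensemble_size = 5, gamma_ensemble = 10, seed = 2)
  expect_named(ms, c("C", "L", "Q", "E_glob", "E_loc",
                     "gamma", "lambda", "sigma"))
  expect_equal(ms$sigma, ms$gamma / ms$lambda)
  expect_true(ms$C >= 0 && ms$C <= 1)
  expect_lte(ms$Q, 1)
  expect_gte(ms$E_glob, 0)
  expect_gte(ms$E_loc, 0)
})

test_that("metrics_table is tidy, complete and seed-deterministic", {
  d <- group_design(n_per_group = 2, n_nodes = 40, n_modules = 4, p_in = 0.6, seed = 29)
  s <- generate_group_connectomes(d)
  m1 <- metrics_table(s, ensemble_size = 3, gamma_ensemble = 5, seed = 17)
  m2 <- metrics_table(s, ensemble_size = 3, gamma_ensemble = 5, seed = 17)
  expect_identical(m1, m2)
  expect_setequal(unique(m1$measure),
                  c("C", "L", "Q", "E_glob", "E_loc",
                    "gamma", "lambda", "sigma"))
  expect_equal(nrow(m1), nrow(s) * 8)
  expect_false(anyNA(m1$value))
})
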