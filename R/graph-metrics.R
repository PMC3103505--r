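#' Weighted clustering coefficient (geometric triangle mean)
#'
#' Clustering around node i is the geometric average of the weights of the
#' triangles through i:
#' `C_i = 1/(k_i (k_i - 1)) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)`,
#' where `k_i` is the node degree and, with `scaled = TRUE` (the default),
#' `w' = w / max(w)` so that `C_i` lies in `[0, 1]` and equals the
#' unweighted clustering coefficient when all weights are equal. The network
#' value C is the mean of `C_i` over all n nodes; nodes of degree < 2
#' contribute 0.
#'
#' @param w Symmetric nonnegative weight matrix.
#' @param scaled Normalize weights by the largest weight in the network.
#' @return List with `per_node` (numeric vector) and `C` (their mean).
#' @export
clustering_coef <- function(w, scaled = TRUE) {
  validate_network(w)
  n <- nrow(w)
  if (n == 0L) abort("Empty graph.")
  mx <- max(w)
  if (mx == 0) return(list(per_node = rep(0, n), C = 0))
  wh <- if (scaled) w / mx else w
  a <- wh^(1 / 3)
  num <- diag(a %*% a %*% a)
  k <- rowSums(w > 0)
  per_node <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  list(per_node = as.numeric(per_node), C = mean(per_node))
}

# all-pairs geodesic matrix with arc length 1/w
geodesic_distances <- function(w) {
  g <- as_igraph(w)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(w), ncol(w))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

# Floyd-Warshall geodesics for small dense matrices (no igraph overhead);
# used on neighbor subgraphs where n is a handful of nodes
geodesic_small <- function(w) {
  d <- 1 / w
  d[w == 0] <- Inf
  diag(d) <- 0
  n <- nrow(w)
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    upd <- dk < d
    d[upd] <- dk[upd]
  }
  d
}

# mean inverse geodesic over ordered pairs (0 for disconnected pairs)
efficiency_from_distances <- function(d) {
  off <- d[row(d) != col(d)]
  mean(ifelse(is.infinite(off), 0, 1 / off))
}

#' Characteristic path length
#'
#' The physical length of an arc is taken inversely proportional to its
#' weight, `l_ij = 1/w_ij`; the geodesic between two nodes is the minimum
#' total arc length over all paths, and L is the mean geodesic over all
#' ordered pairs of distinct nodes.
#'
#' @param w Symmetric nonnegative weight matrix of a connected network.
#' @return List with `distances` (n x n geodesic matrix) and `L`.
#' @export
path_length <- function(w) {
  validate_network(w)
  if (nrow(w) < 2) abort("Need at least 2 nodes.")
  d <- geodesic_distances(w)
  if (any(is.infinite(d))) {
    abort(paste("Network is disconnected, so L is undefined;",
                "use global_efficiency(), which tolerates disconnection."))
  }
  list(distances = d, L = mean(d[row(d) != col(d)]))
}

#' Global efficiency
#'
#' Mean inverse geodesic distance over all ordered pairs of distinct nodes,
#' with disconnected pairs contributing 0 (1/Inf). For a connected two-node
#' network this is exactly 1/L.
#'
#' @inheritParams clustering_coef
#' @return Nonnegative real.
#' @export
global_efficiency <- function(w) {
  validate_network(w)
  n <- nrow(w)
  if (n < 2) abort("Need at least 2 nodes.")
  d <- geodesic_distances(w)
  inv <- 1 / d[row(d) != col(d)]
  inv[is.infinite(d[row(d) != col(d)])] <- 0
  mean(inv)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbor
#' subgraph (the subgraph induced by the first neighbors of i, excluding i
#' itself). Nodes with fewer than 2 neighbors contribute 0.
#'
#' @inheritParams clustering_coef
#' @return Nonnegative real.
#' @export
local_efficiency <- function(w) {
  validate_network(w)
  n <- nrow(w)
  per_node <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_from_distances(geodesic_small(w[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(per_node)
}

#' Modularity of a partition
#'
#' `Q = sum_c (e_cc - a_c^2)` over communities, where `e_cc` is the fraction
#' of total edge weight falling within community c and `a_c` the fraction
#' attached to community c — the within-community weight minus its
#' expectation under random connections with the same strengths. A
#' single-community partition has Q = 0; Q approaches 1 for strong community
#' structure.
#'
#' @param w Symmetric nonnegative weight matrix.
#' @param membership Integer/character vector assigning every node to a
#'   community.
#' @return Q.
#' @export
modularity_q <- function(w, membership) {
  validate_network(w)
  if (length(membership) != nrow(w) || anyNA(membership)) {
    abort("`membership` must assign every node to a community.")
  }
  m2 <- sum(w)
  if (m2 == 0) return(0)
  comms <- unique(membership)
  q <- 0
  s <- rowSums(w)
  for (cc in comms) {
    in_c <- membership == cc
    q <- q + sum(w[in_c, in_c]) / m2 - (sum(s[in_c]) / m2)^2
  }
  q
}

# refine a +-1 bisection vector by single-node moves with positive Q gain
refine_bisection <- function(Bg, s) {
  repeat {
    # gain of flipping node v: -4 s_v (Bg[v,] s - Bg[v,v] s_v) / (2 m2);
    # m2 constant > 0, so compare numerators only
    gains <- -4 * s * (as.numeric(Bg %*% s) - diag(Bg) * s)
    best <- which.max(gains)
    if (gains[best] <= 1e-12) break
    s[best] <- -s[best]
  }
  s
}

#' Detect community structure by spectral modularity optimization
#'
#' Recursive leading-eigenvector bisection of the weighted modularity matrix
#' `B = W - s s^T / 2m` (s = node strengths), with a Kernighan-Lin-style
#' single-node refinement pass after each split; a split is kept only if it
#' increases Q. Returns the partition and its modularity.
#'
#' @param w Symmetric nonnegative weight matrix (connected network).
#' @return List with `membership` (integer vector, communities numbered from
#'   1) and `Q`.
#' @export
find_modules <- function(w) {
  validate_network(w)
  n <- nrow(w)
  m2 <- sum(w)
  if (m2 == 0) return(list(membership = rep(1L, n), Q = 0))
  s <- rowSums(w)
  B <- w - outer(s, s) / m2
  membership <- rep(1L, n)
  queue <- list(seq_len(n))
  next_id <- 2L
  while (length(queue) > 0) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    if (length(g) < 2) next
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    es <- eigen(Bg, symmetric = TRUE)
    if (es$values[1L] <= 1e-10) next
    sv <- ifelse(es$vectors[, 1L] >= 0, 1, -1)
    if (all(sv == sv[1L])) next
    sv <- refine_bisection(Bg, sv)
    if (all(sv == sv[1L])) next
    dq <- as.numeric(sv %*% Bg %*% sv) / (2 * m2)
    if (dq <= 1e-10) next
    g_pos <- g[sv > 0]
    g_neg <- g[sv < 0]
    membership[g_neg] <- next_id
    next_id <- next_id + 1L
    queue <- c(queue, list(g_pos), list(g_neg))
  }
  membership <- as.integer(factor(membership))
  list(membership = membership, Q = modularity_q(w, membership))
}

#' Degree-preserving random reference network
#'
#' Null model for small-worldness: the topology is randomized by
#' double-edge swaps that preserve every node's degree, and the multiset of
#' weights is then reassigned to the surviving edges in random order. With
#' `n_swaps = 0` the input is returned unchanged.
#'
#' @param w Symmetric nonnegative weight matrix with at least 2 edges.
#' @param n_swaps Number of swap attempts (default 10 per edge).
#' @param seed Integer seed.
#' @return A weight matrix with the same degree sequence and weight multiset.
#' @export
random_reference <- function(w, n_swaps = NULL, seed = 1L) {
  validate_network(w)
  n_edges <- sum(w[upper.tri(w)] > 0)
  if (n_edges < 2) {
    warn("Fewer than 2 edges; returning the input network.")
    return(w)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * n_edges
  if (n_swaps == 0) return(w)
  g <- as_igraph(w)
  out <- with_seed_if(seed, {
    sample_null(g, igraph::E(g)$weight, n_swaps, nrow(w), node_labels(w))$w
  })
  if (identical(which(out > 0), which(w > 0)) &&
      isTRUE(all.equal(out, w, check.attributes = FALSE))) {
    warn("No degree-preserving swap was possible; returning the input network.")
  }
  out
}

# draw one degree-preserving, weight-shuffled null network; returns both the
# igraph (with its permuted weight vector, for fast geodesics) and the matrix
sample_null <- function(g, ed_weights, n_swaps, n, labs) {
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  wts <- sample(ed_weights)
  ends <- igraph::ends(g2, igraph::E(g2), names = FALSE)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  m[ends] <- wts
  m[ends[, c(2, 1)]] <- wts
  list(graph = g2, weights = wts, w = m)
}

# Onnela clustering mean without revalidation (internal fast path)
clustering_mean_fast <- function(w, scaled) {
  mx <- max(w)
  if (mx == 0) return(0)
  a <- if (scaled) (w / mx)^(1 / 3) else w^(1 / 3)
  num <- diag(a %*% a %*% a)
  k <- rowSums(w > 0)
  mean(ifelse(k >= 2, num / (k * (k - 1)), 0))
}

#' Small-worldness against a degree-preserving null ensemble
#'
#' gamma is the clustering coefficient relative to the mean clustering of an
#' ensemble of random reference networks, lambda the analogous path-length
#' ratio, and sigma = gamma / lambda. sigma > 1 indicates small-world
#' organization (clustering much higher than random at near-random path
#' length); a network drifts toward randomness as gamma falls and/or lambda
#' rises. Null networks that come out disconnected are resampled (bounded
#' retries).
#'
#' @param w Symmetric nonnegative weight matrix of a connected network.
#' @param ensemble_size Number of null networks for the path-length ratio
#'   lambda (default 20; the per-draw error of L_rand is small).
#' @param gamma_ensemble Number of null networks for the clustering ratio
#'   gamma (default 150). Sparse backbones carry only a handful of
#'   triangles, so each null's clustering is strongly Poisson-noisy and
#'   the clustering null needs a much larger ensemble than the path-length
#'   null for ⟨C_rand⟩ to be estimated with a few-percent error.
#' @param n_swaps Swap attempts per null network (default 10 per edge);
#'   `n_swaps = 0` makes the ensemble the network itself, so
#'   gamma = lambda = sigma = 1 exactly.
#' @param seed Integer seed.
#' @param scaled Passed to [clustering_coef()].
#' @param max_retries Resampling attempts per ensemble member before erroring.
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
small_worldness <- function(w, ensemble_size = 20, gamma_ensemble = 150,
                            n_swaps = NULL, seed = 1L,
                            scaled = TRUE, max_retries = 20L) {
  validate_network(w)
  n <- nrow(w)
  labs <- node_labels(w)
  g <- as_igraph(w)
  ew <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = 1 / ew)
  if (any(is.infinite(d))) {
    abort("Network is disconnected; small-worldness is undefined.")
  }
  off <- row(d) != col(d)
  C_obs <- clustering_coef(w, scaled = scaled)$C
  L_obs <- mean(d[off])
  n_edges <- length(ew)
  if (is.null(n_swaps)) n_swaps <- 10L * n_edges
  if (n_swaps == 0 || n_edges < 2) {
    # the null ensemble is the network itself
    return(list(gamma = 1, lambda = 1, sigma = 1))
  }
  k_deg <- rowSums(w > 0)
  ends0 <- igraph::ends(g, igraph::E(g), names = FALSE)
  # one seeded stream drives the whole ensemble (retries included);
  # the first ensemble_size draws serve both ratios
  res <- with_seed_if(seed, {
    null_ensemble_stats(ends0, ew, n, as.integer(k_deg),
                        as.integer(gamma_ensemble),
                        as.integer(ensemble_size),
                        as.integer(n_swaps), scaled,
                        as.integer(max_retries))
  })
  gamma <- C_obs / mean(res$C_rand)
  lambda <- L_obs / mean(res$L_rand)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All six topological measures of one network
#'
#' Convenience wrapper computing clustering C, characteristic path length L,
#' modularity Q (spectral optimization), global and local efficiency, and
#' the small-world parameters gamma, lambda, sigma for a single connected
#' weighted network.
#'
#' @inheritParams small_worldness
#' @return One-row tibble with columns `C`, `L`, `Q`, `E_glob`, `E_loc`,
#'   `gamma`, `lambda`, `sigma`.
#' @export
metric_set <- function(w, ensemble_size = 20, gamma_ensemble = 150,
                       n_swaps = NULL, seed = 1L, scaled = TRUE) {
  sw <- small_worldness(w, ensemble_size = ensemble_size,
                        gamma_ensemble = gamma_ensemble, n_swaps = n_swaps,
                        seed = seed, scaled = scaled)
  d <- geodesic_distances(w)
  off <- row(d) != col(d)
  tibble(
    C = clustering_coef(w, scaled = scaled)$C,
    L = mean(d[off]),       # connectivity already enforced by small_worldness
    Q = find_modules(w)$Q,
    E_glob = efficiency_from_distances(d),
    E_loc = local_efficiency(w),
    gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma
  )
}

#' Tidy metric table for a set of subject connectomes
#'
#' Applies backbone extraction (optional) and [metric_set()] to every
#' subject-by-variant network of a sample tibble, returning the long
#' (subject, algorithm, measure, value) table the representation-space and
#' permutation-test stages consume.
#'
#' @param samples Tibble from [generate_group_connectomes()] /
#'   [read_subject_samples()] (columns `subject_id`, `group`, `algorithm`,
#'   `network`).
#' @param backbone Extract the connectivity backbone before measuring.
#' @param target_avg_degree Backbone stopping rule (default 4).
#' @inheritParams metric_set
#' @return Tibble with columns `subject_id`, `group`, `algorithm`,
#'   `measure`, `value`; measures ordered C, L, Q, E_glob, E_loc, gamma,
#'   lambda, sigma.
#' @export
metrics_table <- function(samples, backbone = TRUE, target_avg_degree = 4,
                          ensemble_size = 20, gamma_ensemble = 150,
                          n_swaps = NULL, seed = 1L, scaled = TRUE) {
  stopifnot(all(c("subject_id", "algorithm", "network") %in% names(samples)))
  # every network gets the same ensemble seed: common random numbers make
  # the null-ensemble Monte-Carlo error a shared offset across subjects
  # (it cancels in group comparisons) instead of independent per-subject noise
  rows <- purrr::map(seq_len(nrow(samples)), function(r) {
    w <- samples$network[[r]]
    if (backbone) w <- extract_backbone(w, target_avg_degree)
    ms <- metric_set(w, ensemble_size = ensemble_size,
                     gamma_ensemble = gamma_ensemble, n_swaps = n_swaps,
                     seed = seed, scaled = scaled)
    out <- tidyr::pivot_longer(ms, dplyr::everything(),
                               names_to = "measure", values_to = "value")
    out$subject_id <- samples$subject_id[r]
    out$algorithm <- samples$algorithm[r]
    if ("group" %in% names(samples)) out$group <- samples$group[r]
    out
  })
  out <- dplyr::bind_rows(rows)
  cols <- intersect(c("subject_id", "group", "algorithm", "measure", "value"),
                    names(out))
  out[, cols]
}
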