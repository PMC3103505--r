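# Independent brute-force oracles for the graph measures, used only on tiny
# graphs. They share no code with the package implementations: clustering by
# explicit triple loops, geodesics by exhaustive simple-path enumeration,
# modularity by direct evaluation of the community-fraction formula, and the
# maximum spanning tree by enumerating every labeled tree via Prufer
# sequences.

brute_clustering <- function(w, scaled = TRUE) {
  n <- nrow(w)
  wh <- if (scaled && max(w) > 0) w / max(w) else w
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h) s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  list(per_node = ci, C = mean(ci))
}

# exhaustive shortest path over all simple paths, arc length 1/w
brute_geodesics <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  explore <- function(v, target, visited, len) {
    if (v == target) return(len)
    best <- Inf
    for (u in which(w[v, ] > 0)) {
      if (!visited[u]) {
        vis2 <- visited
        vis2[u] <- TRUE
        best <- min(best, explore(u, target, vis2, len + 1 / w[v, u]))
      }
    }
    best
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      vis <- rep(FALSE, n)
      vis[i] <- TRUE
      d[i, j] <- d[j, i] <- explore(i, j, vis, 0)
    }
  }
  d
}

brute_path_length <- function(w) {
  d <- brute_geodesics(w)
  mean(d[row(d) != col(d)])
}

brute_global_efficiency <- function(w) {
  d <- brute_geodesics(w)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.infinite(off), 0, 1 / off))
}

brute_local_efficiency <- function(w) {
  n <- nrow(w)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- brute_global_efficiency(w[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# direct Q: within-community weight fraction minus squared strength fraction
brute_modularity <- function(w, membership) {
  m2 <- sum(w)
  s <- rowSums(w)
  q <- 0
  for (cc in unique(membership)) {
    in_c <- membership == cc
    q <- q + sum(w[in_c, in_c]) / m2 - (sum(s[in_c]) / m2)^2
  }
  q
}

# all set partitions of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (c in seq_len(maxc + 1L)) {
      rec(c(prefix, c), max(maxc, c))
    }
  }
  rec(integer(0), 0L)
  out
}

brute_best_partition <- function(w) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) brute_modularity(w, p), numeric(1))
  list(membership = parts[[which.max(qs)]], Q = max(qs))
}

# maximum spanning tree by Prufer-sequence enumeration of all labeled trees
brute_max_spanning_tree <- function(w) {
  n <- nrow(w)
  stopifnot(n >= 3, n <= 7)
  prufer_to_edges <- function(seq) {
    degree <- rep(1L, n)
    for (v in seq) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, 0, 2)
    for (v in seq) {
      leaf <- min(which(degree == 1L))
      edges <- rbind(edges, c(leaf, v))
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    rbind(edges, last)
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- NULL
  best_w <- -Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_to_edges(as.integer(seqs[r, ]))
    wt <- sum(w[ed])
    if (all(w[ed] > 0) && wt > best_w) {
      best_w <- wt
      best <- ed
    }
  }
  list(edges = best, weight = best_w)
}

# random connected weighted graph on n nodes
random_test_graph <- function(n, p = 0.6, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      w <- matrix(0, n, n)
      ut <- upper.tri(w)
      edge <- runif(sum(ut)) < p
      w[ut] <- round(runif(sum(ut), 0.2, 3), 3) * edge
      w <- w + t(w)
      g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
      if (igraph::is_connected(g)) return(w)
    }
  })
}

# small straight-bundle phantom shared by tractography tests
straight_phantom <- function(fa_inside = 0.8) {
  generate_tensor_phantom(
    shape = c(40, 9, 9),
    bundles = list(list(start = c(0.24, 0.36, 0.36),
                        end = c(2.96, 0.36, 0.36), radius = 0.1)),
    fa_inside = fa_inside, voxel_size = 0.08
  )
}
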