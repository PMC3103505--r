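#' Specify a two-group synthetic connectome study design
#'
#' Describes a balanced two-group study emulating a dysmyelination experiment:
#' a control group whose connectomes are drawn around a modular small-world
#' base graph, and a case group whose connectomes are derived from the same
#' base by globally attenuating arc weights (loss of fiber-pathway integrity)
#' and randomly rewiring a fraction of edges degree-preservingly (network
#' randomization). Each subject carries three correlated network estimates
#' standing in for the three deterministic fiber-tracking algorithms.
#'
#' The base graph is a weighted planted-partition graph: `n_modules` equal
#' communities, within-community edge probability `p_in`, between-community
#' probability `p_out`, and log-normal arc weights centred on `base_weight`
#' (sdlog 0.5). Defaults give two groups of 6 subjects on 150-node networks.
#'
#' @param n_per_group Subjects per group.
#' @param n_nodes Network nodes (brain regions); must be at least 4.
#' @param n_modules Planted communities in the base graph.
#' @param base_weight Median arc weight of the base graph (arbitrary units).
#' @param attenuation Multiplicative weight reduction in the case group:
#'   case weights are `(1 - attenuation)` times control weights. In `[0, 1)`.
#' @param rewire_frac Fraction of case-group edges rewired by degree-preserving
#'   double-edge swaps, per subject. In `[0, 1)`.
#' @param subject_noise Standard deviation (log scale) of the per-subject
#'   multiplicative log-normal weight jitter. Nonnegative.
#' @param algo_jitter Standard deviation (log scale) of the per-algorithm-variant
#'   multiplicative jitter. Nonnegative.
#' @param p_in,p_out Within/between-module edge probabilities of the base graph.
#' @param seed Integer master seed; all randomness derives from it via
#'   [split_seed()].
#' @return An object of class `group_design` (a named list).
#' @export
#' @examples
#' design <- group_design(seed = 1)
#' samples <- generate_group_connectomes(design)
#' samples
group_design <- function(n_per_group = 6, n_nodes = 150, n_modules = 6,
                         base_weight = 1, attenuation = 0.3,
                         rewire_frac = 0.1, subject_noise = 0.05,
                         algo_jitter = 0.05, p_in = 0.3, p_out = 0.02,
                         seed = 1L) {
  if (n_nodes < 4) abort("`n_nodes` must be at least 4.")
  if (n_per_group < 2) abort("`n_per_group` must be at least 2.")
  if (attenuation < 0 || attenuation >= 1) abort("`attenuation` must lie in [0, 1).")
  if (rewire_frac < 0 || rewire_frac >= 1) abort("`rewire_frac` must lie in [0, 1).")
  if (subject_noise < 0) abort("`subject_noise` must be nonnegative.")
  if (algo_jitter < 0) abort("`algo_jitter` must be nonnegative.")
  if (base_weight <= 0) abort("`base_weight` must be positive.")
  if (n_modules < 1 || n_modules > n_nodes) abort("`n_modules` must lie in [1, n_nodes].")
  structure(
    list(
      n_per_group = as.integer(n_per_group), n_nodes = as.integer(n_nodes),
      n_modules = as.integer(n_modules), base_weight = base_weight,
      attenuation = attenuation, rewire_frac = rewire_frac,
      subject_noise = subject_noise, algo_jitter = algo_jitter,
      p_in = p_in, p_out = p_out, seed = as.integer(seed)
    ),
    class = "group_design"
  )
}

#' @export
print.group_design <- function(x, ...) {
  cat("<group_design>\n")
  cat(sprintf("  %d vs %d subjects, %d nodes, %d modules\n",
              x$n_per_group, x$n_per_group, x$n_nodes, x$n_modules))
  cat(sprintf("  attenuation %.2f, rewire %.2f, subject noise %.2f, variant jitter %.2f\n",
              x$attenuation, x$rewire_frac, x$subject_noise, x$algo_jitter))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# weighted planted-partition base graph; retries until connected
planted_partition_graph <- function(n_nodes, n_modules, p_in, p_out,
                                    base_weight, seed, max_tries = 50L) {
  membership <- rep(seq_len(n_modules), length.out = n_nodes)
  membership <- sort(membership)
  seeds <- split_seed(seed, max_tries)
  for (k in seq_len(max_tries)) {
    w <- with_seed_if(seeds[k], {
      same <- outer(membership, membership, "==")
      p <- ifelse(same, p_in, p_out)
      u <- matrix(0, n_nodes, n_nodes)
      ut <- upper.tri(u)
      edge <- runif(sum(ut)) < p[ut]
      # within-module arcs are systematically stronger (median base_weight)
      # than between-module arcs (median base_weight/2), so the
      # highest-weight backbone retains the clustered modular structure
      mlog <- ifelse(same[ut], log(base_weight), log(base_weight / 2))
      wt <- rlnorm(sum(ut), meanlog = mlog, sdlog = 0.5) * edge
      u[ut] <- wt
      u + t(u)
    })
    if (igraph::is_connected(as_igraph(w))) {
      attr(w, "membership") <- membership
      return(w)
    }
  }
  abort("Could not generate a connected base graph; raise `p_in`/`p_out`.")
}

# degree-preserving rewiring of approximately `frac` of the edges of a
# weighted graph: double-edge swaps, each relocating two edges (weights
# travel with their edge, as in the small-world null construction)
rewire_edges <- function(w, frac, seed) {
  if (frac <= 0) return(w)
  ed <- edge_table(w)
  n_edges <- nrow(ed)
  target_swaps <- ceiling(frac * n_edges / 2)
  with_seed_if(seed, {
    done <- 0L
    tries <- 0L
    max_tries <- 200L * target_swaps
    while (done < target_swaps && tries < max_tries) {
      tries <- tries + 1L
      ed_pair <- sample.int(n_edges, 2L)
      a <- ed$i[ed_pair[1L]]; b <- ed$j[ed_pair[1L]]
      c_ <- ed$i[ed_pair[2L]]; d <- ed$j[ed_pair[2L]]
      if (length(unique(c(a, b, c_, d))) < 4L) next
      # swap to (a,d) and (c_,b); skip if either already exists
      if (w[a, d] > 0 || w[c_, b] > 0) next
      w_ad <- w[a, b]; w_cb <- w[c_, d]
      w[a, b] <- w[b, a] <- 0
      w[c_, d] <- w[d, c_] <- 0
      w[a, d] <- w[d, a] <- w_ad
      w[c_, b] <- w[b, c_] <- w_cb
      ed$i[ed_pair[1L]] <- min(a, d); ed$j[ed_pair[1L]] <- max(a, d)
      ed$i[ed_pair[2L]] <- min(c_, b); ed$j[ed_pair[2L]] <- max(c_, b)
      done <- done + 1L
    }
    w
  })
}

# symmetric multiplicative log-normal jitter on existing edges
jitter_weights <- function(w, sdlog, seed) {
  if (sdlog <= 0) return(w)
  with_seed_if(seed, {
    ut <- upper.tri(w) & w > 0
    f <- rlnorm(sum(ut), meanlog = 0, sdlog = sdlog)
    w[ut] <- w[ut] * f
    w[lower.tri(w)] <- 0
    w + t(w)
  })
}

#' Emulate correlated tracking-algorithm variants of one connectome
#'
#' Produces three perturbed copies of a base connectivity matrix, standing in
#' for the three network estimates per subject that different deterministic
#' fiber-tracking algorithms yield. Each variant multiplies every arc weight
#' by an independent log-normal factor; the edge support (which arcs exist)
#' is shared across variants. With `algo_jitter = 0` the three variants are
#' exact copies.
#'
#' @param base Symmetric nonnegative weight matrix with zero diagonal.
#' @param algo_jitter Log-scale standard deviation of the multiplicative jitter.
#' @param seed Integer seed.
#' @return Named list of three matrices (`"alg1"`, `"alg2"`, `"alg3"`).
#' @export
emulate_algorithm_variants <- function(base, algo_jitter, seed = 1L) {
  validate_network(base)
  if (algo_jitter < 0) abort("`algo_jitter` must be nonnegative.")
  seeds <- split_seed(seed, 3L)
  out <- lapply(seeds, function(s) jitter_weights(base, algo_jitter, s))
  names(out) <- paste0("alg", 1:3)
  out
}

#' Generate a two-group set of synthetic subject connectomes
#'
#' Draws `2 * n_per_group` subjects from the design in [group_design()].
#' Control subjects are per-subject jittered copies of the modular base
#' graph. The case group shares a single lesioned base derived from the
#' control base by multiplying every weight by `(1 - attenuation)` and
#' rewiring a fraction `rewire_frac` of edges degree-preservingly (the
#' group-level analogue of a common disease process); case subjects are
#' then per-subject jittered copies of that lesioned base. Each subject's
#' network is finally expanded into three algorithm variants via
#' [emulate_algorithm_variants()].
#'
#' @param design A `group_design`.
#' @return A tibble with one row per subject x variant: columns `subject_id`,
#'   `group` (factor control/case), `algorithm` (alg1--alg3) and `network`
#'   (list column of weight matrices).
#' @export
generate_group_connectomes <- function(design) {
  stopifnot(inherits(design, "group_design"))
  n_sub <- 2L * design$n_per_group
  # child seeds: base graph, case-group rewiring, then 2 per subject
  # (subject jitter, variant jitter)
  seeds <- split_seed(design$seed, 2L + 2L * n_sub)
  base <- planted_partition_graph(design$n_nodes, design$n_modules,
                                  design$p_in, design$p_out,
                                  design$base_weight, seeds[1L])
  attr(base, "membership") <- NULL
  # the case base: globally attenuated weights plus one degree-preserving
  # rewiring pass (the group-level lesion shared by all case subjects)
  case_base <- rewire_edges(base * (1 - design$attenuation),
                            design$rewire_frac, seeds[2L])
  groups <- rep(c("control", "case"), each = design$n_per_group)
  ids <- paste0(groups, "_", rep(seq_len(design$n_per_group), 2L))
  rows <- purrr::map(seq_len(n_sub), function(s) {
    s_seeds <- seeds[2L + (s - 1L) * 2L + 1:2]
    w <- if (groups[s] == "case") case_base else base
    w <- jitter_weights(w, design$subject_noise, s_seeds[1L])
    variants <- emulate_algorithm_variants(w, design$algo_jitter, s_seeds[2L])
    tibble(
      subject_id = ids[s], group = groups[s],
      algorithm = names(variants), network = unname(variants)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = c("control", "case"))
  out
}

#' Write a subject-sample set to disk
#'
#' One CSV weight matrix per subject-variant plus a JSON manifest recording
#' subject ids, groups, the design parameters and the file layout, so a
#' sample set round-trips losslessly.
#'
#' @param samples Tibble from [generate_group_connectomes()].
#' @param dir Output directory (created if missing).
#' @param design Optional `group_design` to embed in the manifest.
#' @return `dir`, invisibly.
#' @export
write_subject_samples <- function(samples, dir, design = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%s.csv", samples$subject_id, samples$algorithm)
  purrr::walk2(samples$network, files,
               ~ write_matrix(.x, file.path(dir, .y)))
  manifest <- list(
    subjects = unique(samples$subject_id),
    groups = as.character(samples$group[!duplicated(samples$subject_id)]),
    algorithms = unique(samples$algorithm),
    files = files,
    design = if (!is.null(design)) unclass(design)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a subject-sample set written by [write_subject_samples()]
#'
#' @param dir Directory containing the CSV matrices and `manifest.json`.
#' @return A tibble with the same shape as [generate_group_connectomes()].
#' @export
read_subject_samples <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  grid <- tidyr::expand_grid(subject_id = manifest$subjects,
                             algorithm = manifest$algorithms)
  grid$group <- factor(
    manifest$groups[match(grid$subject_id, manifest$subjects)],
    levels = c("control", "case")
  )
  grid$network <- purrr::map2(grid$subject_id, grid$algorithm, function(s, a) {
    read_matrix(file.path(dir, sprintf("%s_%s.csv", s, a)))
  })
  grid[, c("subject_id", "group", "algorithm", "network")]
}
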