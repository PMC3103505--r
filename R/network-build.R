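#' Number of nodes of a split-hemisphere parcellation scheme
#'
#' A whole-brain parcellation built from a set of gray-matter structures in
#' which the hemispheres are separated and the single cortex structure is
#' subdivided into equal-volume subregions has, per hemisphere, the
#' non-cortical structures plus the cortical subregions. The defaults (26
#' structures of which one is cortex, 50 cortical subregions, 2 hemispheres)
#' give the 150-node scheme used throughout the package.
#'
#' @param n_structures Gray-matter structures selected per hemisphere,
#'   including the cortex as a single structure.
#' @param cortex_subregions Subregions the hemispheric cortex is split into.
#' @param hemispheres Number of hemispheres.
#' @return Total node count.
#' @export
#' @examples
#' parcellation_node_count()  # 150
parcellation_node_count <- function(n_structures = 26, cortex_subregions = 50,
                                    hemispheres = 2) {
  stopifnot(n_structures >= 1, cortex_subregions >= 1, hemispheres >= 1)
  hemispheres * ((n_structures - 1) + cortex_subregions)
}

#' Per-region surface-voxel counts of a label volume
#'
#' A voxel is a surface voxel of its region if it touches the volume boundary
#' or has a 6-connected neighbor with a different label. These counts are the
#' region-size normalizers of the arc-weight definitions.
#'
#' @param labels 3-D integer array of region ids (0 = background).
#' @return Named integer vector, one entry per region id present.
#' @export
surface_voxel_counts <- function(labels) {
  d <- dim(labels)
  stopifnot(length(d) == 3L)
  pad <- array(-1L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- labels
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  differs <- array(FALSE, d)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (sh in shifts) {
    nb <- pad[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2], 2:(d[3] + 1) + sh[3]]
    differs <- differs | (nb != core)
  }
  surf <- differs & core > 0
  counts <- table(factor(core[surf], levels = sort(unique(core[core > 0]))))
  setNames(as.integer(counts), names(counts))
}

#' Build a weighted region-by-region connectivity network from trajectories
#'
#' An arc between regions i and j accumulates the fiber trajectories whose
#' two endpoints lie in i and j, normalized by the regions' surface sizes.
#' Three arc-weight definitions are available:
#' \describe{
#'   \item{`inv_md`}{each trajectory contributes the arithmetic mean of the
#'     inverse of its per-step mean-diffusivity samples — an effective fiber
#'     count modulated by pathway integrity; the default.}
#'   \item{`mean_fa`}{each trajectory contributes its mean per-step
#'     fractional anisotropy.}
#'   \item{`count`}{each trajectory contributes 1 (a pure fiber count).}
#' }
#' In every mode the sum over trajectories is divided by `n_i + n_j`, the
#' number of surface voxels of the two regions.
#'
#' @param trajectories List of `trajectory` objects (from [track()] or
#'   [read_trajectories()]); `inv_md` mode requires per-step `md` samples
#'   and `mean_fa` mode per-step `fa` samples.
#' @param parcellation 3-D integer label array (region ids 1..R, 0 =
#'   background) locating each trajectory endpoint, or an integer number of
#'   regions when `endpoint_regions` is supplied directly.
#' @param voxel_size Voxel edge length(s) in mm (to map endpoint coordinates
#'   to voxels). Ignored when `endpoint_regions` is given.
#' @param weight_mode One of `"inv_md"`, `"mean_fa"`, `"count"`.
#' @param surface_counts Optional named vector of per-region surface-voxel
#'   counts `n_i`; computed from `parcellation` by [surface_voxel_counts()]
#'   when it is an array, else defaulting to 1 per region.
#' @param endpoint_regions Optional n x 2 integer matrix giving the region of
#'   each trajectory's two endpoints (bypasses the label-volume lookup).
#' @return Symmetric weight matrix with node labels `r1..rR` and attributes
#'   `weight_mode` and `n_skipped` (trajectories with an endpoint outside
#'   every region).
#' @export
build_network <- function(trajectories, parcellation, voxel_size = NULL,
                          weight_mode = c("inv_md", "mean_fa", "count"),
                          surface_counts = NULL, endpoint_regions = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(endpoint_regions)) {
    stopifnot(is.array(parcellation), length(dim(parcellation)) == 3L,
              !is.null(voxel_size))
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    d <- dim(parcellation)
    region_of <- function(pt) {
      vox <- floor(pt / voxel_size) + 1
      if (any(vox < 1) || any(vox > d)) return(0L)
      parcellation[vox[1], vox[2], vox[3]]
    }
    endpoint_regions <- t(vapply(trajectories, function(tr) {
      p <- tr$points
      c(region_of(p[1L, ]), region_of(p[nrow(p), ]))
    }, integer(2L)))
    n_regions <- max(parcellation)
  } else {
    endpoint_regions <- matrix(as.integer(endpoint_regions), ncol = 2L)
    n_regions <- if (is.array(parcellation)) max(parcellation)
                 else as.integer(parcellation)
  }
  if (is.null(surface_counts)) {
    surface_counts <- if (is.array(parcellation)) {
      full <- setNames(rep(1L, n_regions), as.character(seq_len(n_regions)))
      sc <- surface_voxel_counts(parcellation)
      full[names(sc)] <- sc
      full
    } else {
      setNames(rep(1L, n_regions), as.character(seq_len(n_regions)))
    }
  }
  w <- matrix(0, n_regions, n_regions)
  n_skipped <- 0L
  for (f in seq_along(trajectories)) {
    i <- endpoint_regions[f, 1L]
    j <- endpoint_regions[f, 2L]
    if (i == 0L || j == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (i == j) next
    contrib <- switch(weight_mode,
      inv_md = {
        mds <- trajectories[[f]]$samples$md
        if (is.null(mds)) {
          abort(sprintf("Trajectory %d carries no MD samples (inv_md mode).", f))
        }
        if (any(mds <= 0)) {
          abort(sprintf("Trajectory %d has nonpositive MD at a step.", f))
        }
        mean(1 / mds)
      },
      mean_fa = {
        fas <- trajectories[[f]]$samples$fa
        if (is.null(fas)) {
          abort(sprintf("Trajectory %d carries no FA samples (mean_fa mode).", f))
        }
        mean(fas)
      },
      count = 1
    )
    w[i, j] <- w[i, j] + contrib
    w[j, i] <- w[i, j]
  }
  if (n_skipped > 0L) {
    message(sprintf("%d trajectories skipped (endpoint outside all regions).",
                    n_skipped))
  }
  ni <- as.numeric(surface_counts[as.character(seq_len(n_regions))])
  denom <- outer(ni, ni, "+")
  w <- w / denom
  diag(w) <- 0
  dimnames(w) <- list(paste0("r", seq_len(n_regions)),
                      paste0("r", seq_len(n_regions)))
  attr(w, "weight_mode") <- weight_mode
  attr(w, "n_skipped") <- n_skipped
  w
}

#' Extract the connectivity backbone of a weighted network
#'
#' The backbone keeps the maximum spanning tree — the tree connecting all
#' nodes with maximal total weight — and then adds the remaining edges in
#' strictly decreasing weight order until the average node degree first
#' reaches `target_avg_degree` (ties broken by ascending node-pair order for
#' determinism). Edge weights are preserved; the result is connected whenever
#' the input is. Average degree counts each undirected edge as 2 in the
#' degree sum, so a 150-node backbone at target 4 has exactly 300 edges.
#'
#' @param w Symmetric nonnegative weight matrix (connected; if not, the
#'   largest component is used with a warning).
#' @param target_avg_degree Average node degree to stop at (default 4).
#' @return Backbone weight matrix of the same dimension as `w`.
#' @export
extract_backbone <- function(w, target_avg_degree = 4) {
  validate_network(w)
  n <- nrow(w)
  labs <- node_labels(w)
  g <- as_igraph(w)
  comp <- igraph::components(g)
  keep <- seq_len(n)
  if (comp$no > 1L) {
    warn("Input network is disconnected; extracting the backbone of its largest component.")
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  # maximum spanning tree: minimize (max_w + 1 - w)
  ew <- igraph::E(g)$weight
  mst <- igraph::mst(g, weights = max(ew) + 1 - ew)
  out <- matrix(0, n, n, dimnames = list(labs, labs))
  mst_ends <- igraph::ends(mst, igraph::E(mst), names = FALSE)
  for (e in seq_len(nrow(mst_ends))) {
    a <- keep[mst_ends[e, 1L]]; b <- keep[mst_ends[e, 2L]]
    out[a, b] <- out[b, a] <- w[a, b]
  }
  n_edges <- sum(out[upper.tri(out)] > 0)
  target_edges <- ceiling(target_avg_degree * n / 2)
  if (n_edges < target_edges) {
    cand <- edge_table(w)
    in_bb <- out[cbind(cand$i, cand$j)] > 0
    cand <- cand[!in_bb & cand$i %in% keep & cand$j %in% keep, ]
    cand <- cand[order(-cand$weight, cand$i, cand$j), ]
    n_add <- min(target_edges - n_edges, nrow(cand))
    if (n_add < target_edges - n_edges) {
      warn(sprintf(
        "Only %d edges available; backbone stops at average degree %.3g.",
        n_edges + n_add, 2 * (n_edges + n_add) / n
      ))
    }
    if (n_add > 0) {
      add <- cand[seq_len(n_add), ]
      out[cbind(add$i, add$j)] <- add$weight
      out[cbind(add$j, add$i)] <- add$weight
    }
  }
  attr(out, "weight_mode") <- attr(w, "weight_mode", exact = TRUE)
  out
}
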