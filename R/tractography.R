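#' Fractional anisotropy of a diffusion tensor
#'
#' FA is the normalized dispersion of the tensor's eigenvalues:
#' `sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, 0 for an isotropic
#' tensor and 1 in the rank-1 limit. Tiny negative eigenvalues (numerical
#' noise) are clamped to zero; the all-zero tensor is defined to have FA 0.
#'
#' @param tensor A symmetric 3x3 matrix, or a length-3 vector of eigenvalues.
#' @return FA in `[0, 1]`.
#' @export
#' @examples
#' compute_fa(c(2, 1, 1))  # 1/sqrt(6)
compute_fa <- function(tensor) {
  lam <- tensor_eigenvalues(tensor)
  if (all(lam == 0)) return(0)
  m <- mean(lam)
  fa <- sqrt(3 / 2) * sqrt(sum((lam - m)^2)) / sqrt(sum(lam^2))
  min(max(fa, 0), 1)
}

#' Mean diffusivity of a diffusion tensor
#'
#' MD is the mean of the three eigenvalues, equal to trace/3.
#'
#' @inheritParams compute_fa
#' @return Nonnegative real.
#' @export
#' @examples
#' compute_md(c(2, 1, 1))  # 4/3
compute_md <- function(tensor) {
  mean(tensor_eigenvalues(tensor))
}

tensor_eigenvalues <- function(tensor) {
  if (is.matrix(tensor)) {
    stopifnot(all(dim(tensor) == c(3L, 3L)))
    if (max(abs(tensor - t(tensor))) > 1e-8) abort("Tensor must be symmetric.")
    lam <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  } else {
    stopifnot(length(tensor) == 3L)
    lam <- as.numeric(tensor)
  }
  pmax(lam, 0)
}

# FA over a whole field, computed from tensor invariants
# (||D - mI||_F / ||D||_F form, identical to the eigenvalue formula)
fa_map <- function(field) {
  D <- field$D
  tr <- D[, , , 1] + D[, , , 2] + D[, , , 3]
  frob2 <- D[, , , 1]^2 + D[, , , 2]^2 + D[, , , 3]^2 +
    2 * (D[, , , 4]^2 + D[, , , 5]^2 + D[, , , 6]^2)
  dev2 <- frob2 - tr^2 / 3
  fa <- sqrt(3 / 2) * sqrt(pmax(dev2, 0) / pmax(frob2, .Machine$double.eps))
  fa[frob2 == 0] <- 0
  array(pmin(pmax(fa, 0), 1), dim(D)[1:3])
}

# MD over a whole field
md_map <- function(field) {
  array((field$D[, , , 1] + field$D[, , , 2] + field$D[, , , 3]) / 3,
        dim(field$D)[1:3])
}

#' Select tractography seed voxels (brute-force approach)
#'
#' Seeds are all voxels whose fractional anisotropy strictly exceeds the
#' threshold; every such voxel launches one bidirectional streamline.
#'
#' @param field A [tensor_field()].
#' @param fa_threshold FA cutoff (default 0.12).
#' @return Integer matrix with one row per seed voxel and columns i, j, k.
#' @export
select_seeds <- function(field, fa_threshold = 0.12) {
  fa <- fa_map(field)
  idx <- which(fa > fa_threshold, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Deterministic fiber-tracking parameters
#'
#' Bundles the stopping and integration parameters of the deterministic
#' trackers: step size 25 um, maximum trace length 200 mm, curvature
#' threshold +-80 degrees per step, and FA threshold 0.12, with three update
#' rules -- `FACT` follows the voxel's principal eigenvector, `TEND`
#' propagates the incoming direction through the tensor (v_out ~ D v_in),
#' and `TL` (tensorline) blends the two with the local FA as mixing weight.
#'
#' @param step Step size in mm.
#' @param max_length Maximum trace length in mm (whole trajectory; each
#'   direction of the bidirectional integration gets half).
#' @param max_angle Maximum step-to-step turning angle in degrees.
#' @param fa_threshold Tracking stops where FA falls to or below this value.
#' @param mode One of "FACT", "TL", "TEND".
#' @return An object of class `track_params`.
#' @export
track_params <- function(step = 0.025, max_length = 200, max_angle = 80,
                         fa_threshold = 0.12, mode = c("FACT", "TL", "TEND")) {
  mode <- match.arg(mode)
  if (step <= 0) abort("`step` must be positive.")
  if (max_angle <= 0 || max_angle >= 180) abort("`max_angle` must lie in (0, 180).")
  if (fa_threshold < 0 || fa_threshold >= 1) abort("`fa_threshold` must lie in [0, 1).")
  if (max_length <= 0) abort("`max_length` must be positive.")
  structure(list(step = step, max_length = max_length, max_angle = max_angle,
                 fa_threshold = fa_threshold, mode = mode),
            class = "track_params")
}

# principal eigenvector of a 3x3 symmetric tensor
principal_eigenvector <- function(Dt) {
  eigen(Dt, symmetric = TRUE)$vectors[, 1L]
}

# one direction of streamline integration from physical position x0 with
# initial direction v0; returns matrix of positions AFTER x0 (may be empty)
integrate_streamline <- function(field, fa, x0, v0, params, half_length) {
  vs <- field$voxel_size
  dims <- dim(field$D)[1:3]
  cos_thresh <- cos(params$max_angle * pi / 180)
  pts <- matrix(0, 0L, 3L)
  x <- x0
  v_prev <- v0
  len <- 0
  repeat {
    vox <- floor(x / vs) + 1
    if (any(vox < 1) || any(vox > dims)) break
    if (fa[vox[1], vox[2], vox[3]] <= params$fa_threshold) break
    Dt <- tensor_at(field, vox[1], vox[2], vox[3])
    v <- switch(params$mode,
      FACT = principal_eigenvector(Dt),
      TEND = {
        u <- as.numeric(Dt %*% v_prev)
        u / sqrt(sum(u^2))
      },
      TL = {
        e1 <- principal_eigenvector(Dt)
        if (sum(e1 * v_prev) < 0) e1 <- -e1
        u <- as.numeric(Dt %*% v_prev)
        u <- u / sqrt(sum(u^2))
        f <- fa[vox[1], vox[2], vox[3]]
        b <- f * e1 + (1 - f) * u
        b / sqrt(sum(b^2))
      }
    )
    if (sum(v * v_prev) < 0) v <- -v
    if (sum(v * v_prev) < cos_thresh) break
    x_new <- x + params$step * v
    len <- len + params$step
    if (len > half_length) break
    # stop before stepping outside the volume or into sub-threshold FA,
    # so endpoints stay inside the tracked (high-FA) region
    vox_new <- floor(x_new / vs) + 1
    if (any(vox_new < 1) || any(vox_new > dims)) break
    if (fa[vox_new[1], vox_new[2], vox_new[3]] <= params$fa_threshold) break
    pts <- rbind(pts, x_new)
    x <- x_new
    v_prev <- v
  }
  pts
}

#' Track fiber trajectories through a tensor field
#'
#' Launches one bidirectional streamline from the center of each seed voxel
#' and integrates it with the selected update rule until FA drops to the
#' threshold, the turn angle exceeds the curvature threshold, the trajectory
#' leaves the volume, or the length budget is exhausted. Direction lookup is
#' nearest-neighbor (voxel-wise); eigenvector sign is chosen for continuity
#' with the previous step.
#'
#' @param field A [tensor_field()].
#' @param seeds Integer matrix of seed voxel indices (rows i, j, k), e.g.
#'   from [select_seeds()].
#' @param params A [track_params()].
#' @param md Optional MD map (3-D array matching the field); when supplied,
#'   each trajectory records the MD at every step.
#' @return List of `trajectory` objects: each has `points` (n x 3 matrix of
#'   mm coordinates) and `samples` (list with per-step `fa` and, when an MD
#'   map was given, `md`).
#' @export
track <- function(field, seeds, params = track_params(), md = NULL) {
  stopifnot(inherits(field, "tensor_field"), inherits(params, "track_params"))
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  dims <- dim(field$D)[1:3]
  bad <- seeds[, 1] < 1 | seeds[, 1] > dims[1] |
         seeds[, 2] < 1 | seeds[, 2] > dims[2] |
         seeds[, 3] < 1 | seeds[, 3] > dims[3]
  if (any(bad)) {
    abort(sprintf("%d seed voxel(s) lie outside the volume (first: row %d).",
                  sum(bad), which(bad)[1L]))
  }
  fa <- fa_map(field)
  vs <- field$voxel_size
  half <- params$max_length / 2
  out <- vector("list", nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    vox <- seeds[s, ]
    x0 <- (vox - 0.5) * vs
    v0 <- principal_eigenvector(tensor_at(field, vox[1], vox[2], vox[3]))
    fwd <- integrate_streamline(field, fa, x0, v0, params, half)
    bwd <- integrate_streamline(field, fa, x0, -v0, params, half)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(x0, 1L, 3L), fwd)
    vox_pts <- pmin(pmax(floor(t(t(pts) / vs)) + 1, 1),
                    matrix(dims, nrow(pts), 3L, byrow = TRUE))
    flat <- vox_pts[, 1] + dims[1] * (vox_pts[, 2] - 1) +
      dims[1] * dims[2] * (vox_pts[, 3] - 1)
    samples <- list(fa = fa[flat])
    if (!is.null(md)) samples$md <- md[flat]
    out[[s]] <- structure(list(points = pts, samples = samples),
                          class = "trajectory")
  }
  out
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$points)
  len <- if (n > 1) sum(sqrt(rowSums(diff(x$points)^2))) else 0
  cat(sprintf("<trajectory> %d points, length %.3f mm\n", n, len))
  invisible(x)
}

trajectory_length <- function(traj) {
  if (nrow(traj$points) < 2) return(0)
  sum(sqrt(rowSums(diff(traj$points)^2)))
}

#' Write/read trajectories as plain text
#'
#' One line per point (`x y z [md]`), a blank line between trajectories.
#'
#' @param trajectories List of `trajectory` objects.
#' @param path Output file.
#' @return `path` invisibly; for the reader, a list of trajectories.
#' @export
write_trajectories <- function(trajectories, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in trajectories) {
    m <- tr$points
    if (!is.null(tr$samples$md)) m <- cbind(m, tr$samples$md)
    writeLines(apply(m, 1L, paste, collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path)
  groups <- split(lines, cumsum(lines == ""))
  groups <- lapply(groups, function(g) g[g != ""])
  groups <- groups[lengths(groups) > 0]
  lapply(groups, function(g) {
    m <- do.call(rbind, lapply(strsplit(g, " +"), as.numeric))
    samples <- if (ncol(m) >= 4) list(md = m[, 4]) else list()
    structure(list(points = m[, 1:3, drop = FALSE], samples = samples),
              class = "trajectory")
  })
}
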