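#' Construct a tensor field
#'
#' A tensor field is a voxel grid of symmetric 3x3 diffusion tensors plus a
#' physical voxel size. Tensors are stored component-wise in a 4-D array with
#' the last dimension ordered `(xx, yy, zz, xy, xz, yz)`.
#'
#' @param D Numeric array of dimension `c(nx, ny, nz, 6)`.
#' @param voxel_size Physical edge length(s) of a voxel in mm; scalar or
#'   length-3 vector.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(D, voxel_size) {
  stopifnot(is.array(D), length(dim(D)) == 4L, dim(D)[4L] == 6L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) abort("`voxel_size` must be positive.")
  structure(list(D = D, voxel_size = voxel_size), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<tensor_field> %d x %d x %d voxels, voxel size %s mm\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

# 3x3 symmetric tensor at one voxel
tensor_at <- function(field, i, j, k) {
  v <- field$D[i, j, k, ]
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

# eigenvalues of an axially symmetric tensor with given FA and MD:
# lambda = md * (1 + 2t, 1 - t, 1 - t) with t = fa / sqrt(3 - 2 fa^2)
axisym_eigenvalues <- function(fa, md) {
  stopifnot(fa >= 0, fa < 1, md > 0)
  t <- fa / sqrt(3 - 2 * fa^2)
  md * c(1 + 2 * t, 1 - t, 1 - t)
}

# symmetric tensor with principal axis `u` (unit) and eigenvalues lam
# (lam[2] = lam[3] assumed for the transverse plane)
axisym_tensor <- function(u, lam) {
  u <- u / sqrt(sum(u^2))
  lam[2] * diag(3) + (lam[1] - lam[2]) * tcrossprod(u)
}

# sample a centerline: straight segment, or quadratic Bezier when `via` given
centerline_points <- function(start, end, via = NULL, n = 200L) {
  s <- seq(0, 1, length.out = n)
  if (is.null(via)) {
    p <- outer(1 - s, start) + outer(s, end)
    tangents <- matrix(rep(end - start, each = n), n, 3L)
  } else {
    p <- outer((1 - s)^2, start) + outer(2 * s * (1 - s), via) + outer(s^2, end)
    tangents <- outer(-2 * (1 - s), start) + outer(2 - 4 * s, via) + outer(2 * s, end)
  }
  tangents <- tangents / sqrt(rowSums(tangents^2))
  list(points = p, tangents = tangents, s = s)
}

#' Generate a synthetic diffusion-tensor phantom
#'
#' Builds a small tensor volume containing one or more fiber bundles on an
#' isotropic background, the matching mean-diffusivity map, and a parcellation
#' that labels the two end-caps of each bundle as distinct regions. This is
#' the controlled input for the deterministic fiber trackers: inside a bundle
#' the tensor is axially symmetric with its principal axis along the local
#' bundle tangent and fractional anisotropy `fa_inside`; outside it is
#' isotropic (FA = 0). The MD map is positive everywhere.
#'
#' Bundles are given as lists with elements `start` and `end` (physical mm
#' coordinates of the centerline endpoints), `radius` (mm) and optionally
#' `via` (a control point making the centerline a quadratic Bezier curve).
#'
#' @param shape Integer voxel dimensions `c(nx, ny, nz)`.
#' @param bundles List of bundle specifications (see Details).
#' @param fa_inside Fractional anisotropy inside bundles, in `[0, 1)`.
#' @param md_inside,md_background Mean diffusivity inside/outside bundles
#'   (arbitrary units, must be positive).
#' @param voxel_size Voxel edge length in mm.
#' @param cap_frac Fraction of the centerline arc length at each end labelled
#'   as that bundle's end-cap region.
#' @param seed Unused (the phantom is deterministic); accepted so phantom
#'   generation can sit in seeded pipelines.
#' @return A list with elements `field` (a [tensor_field()]), `md` (3-D
#'   array), and `parcellation` (3-D integer array; bundle `b` owns region
#'   labels `2b - 1` and `2b`, background is 0).
#' @export
#' @examples
#' ph <- generate_tensor_phantom(
#'   shape = c(30, 10, 10),
#'   bundles = list(list(start = c(0.2, 0.4, 0.4), end = c(2.2, 0.4, 0.4),
#'                       radius = 0.1))
#' )
#' ph$field
generate_tensor_phantom <- function(shape, bundles, fa_inside = 0.8,
                                    md_inside = 1, md_background = 1,
                                    voxel_size = 0.08, cap_frac = 0.15,
                                    seed = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(bundles) >= 1)
  if (fa_inside < 0 || fa_inside >= 1) abort("`fa_inside` must lie in [0, 1).")
  if (md_inside <= 0 || md_background <= 0) abort("MD values must be positive.")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  extent <- shape * voxel_size

  D <- array(0, c(shape, 6L))
  # isotropic background: lambda = md_background everywhere
  D[, , , 1:3] <- md_background
  md <- array(md_background, shape)
  labels <- array(0L, shape)

  # voxel centers in physical coordinates
  centers <- as.matrix(expand.grid(
    x = (seq_len(shape[1]) - 0.5) * voxel_size[1],
    y = (seq_len(shape[2]) - 0.5) * voxel_size[2],
    z = (seq_len(shape[3]) - 0.5) * voxel_size[3]
  ))
  lam <- axisym_eigenvalues(fa_inside, md_inside)

  for (b in seq_along(bundles)) {
    bu <- bundles[[b]]
    if (any(bu$start < 0) || any(bu$end < 0) ||
        any(bu$start > extent) || any(bu$end > extent)) {
      abort(sprintf("Bundle %d centerline leaves the volume.", b))
    }
    cl <- centerline_points(bu$start, bu$end, bu$via)
    # nearest centerline sample per voxel center
    d2 <- matrix(Inf, nrow(centers), 1L)
    nearest <- integer(nrow(centers))
    for (q in seq_len(nrow(cl$points))) {
      dq <- (centers[, 1] - cl$points[q, 1])^2 +
            (centers[, 2] - cl$points[q, 2])^2 +
            (centers[, 3] - cl$points[q, 3])^2
      upd <- dq < d2
      d2[upd] <- dq[upd]
      nearest[upd] <- q
    }
    inside <- which(d2 <= bu$radius^2)
    if (length(inside) == 0L) {
      warn(sprintf("Bundle %d contains no voxel centers.", b))
      next
    }
    arr_idx <- arrayInd(inside, shape)
    for (r in seq_along(inside)) {
      Dt <- axisym_tensor(cl$tangents[nearest[inside[r]], ], lam)
      ii <- arr_idx[r, 1]; jj <- arr_idx[r, 2]; kk <- arr_idx[r, 3]
      D[ii, jj, kk, ] <- c(Dt[1, 1], Dt[2, 2], Dt[3, 3],
                           Dt[1, 2], Dt[1, 3], Dt[2, 3])
      md[ii, jj, kk] <- md_inside
      s <- cl$s[nearest[inside[r]]]
      lab <- if (s <= cap_frac) 2L * b - 1L
             else if (s >= 1 - cap_frac) 2L * b
             else 0L
      if (lab > 0L) {
        if (labels[ii, jj, kk] != 0L && labels[ii, jj, kk] != lab) {
          abort(sprintf(
            "End-cap regions overlap at voxel (%d, %d, %d): labels %d and %d.",
            ii, jj, kk, labels[ii, jj, kk], lab
          ))
        }
        labels[ii, jj, kk] <- lab
      }
    }
  }
  list(field = tensor_field(D, voxel_size), md = md, parcellation = labels)
}

#' Write a phantom to NIfTI volumes
#'
#' Writes the tensor field as a 4-D lower-triangle component image plus the
#' MD map and parcellation labels as scalar images. Requires the RNifti
#' package.
#'
#' @param phantom Output of [generate_tensor_phantom()].
#' @param prefix Path prefix; files `<prefix>_tensor.nii.gz`,
#'   `<prefix>_md.nii.gz` and `<prefix>_labels.nii.gz` are written.
#' @return The three paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Writing NIfTI requires the RNifti package.")
  }
  vs <- phantom$field$voxel_size
  paths <- paste0(prefix, c("_tensor", "_md", "_labels"), ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$field$D, pixdim = c(vs, 1)), paths[1])
  RNifti::writeNifti(RNifti::asNifti(phantom$md, pixdim = vs), paths[2])
  RNifti::writeNifti(RNifti::asNifti(phantom$parcellation + 0, pixdim = vs), paths[3])
  invisible(paths)
}
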