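#' Define a regular volumetric grid
#'
#' A volume grid couples an array shape with voxel dimensions and a
#' voxel-to-world affine.  All spatial objects in the package (masks,
#' pattern maps, accuracy maps) live on such a grid.  The default preset
#' is an isotropic 2 mm grid, the resolution that functional data are
#' resampled to before multivoxel analysis.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size_mm positive numeric vector of length 3 (mm).
#' @param origin_affine optional 4x4 affine mapping 0-based voxel indices
#'   to world mm.  Defaults to a diagonal affine centred on the volume.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape = c(40, 48, 36), voxel_size_mm = c(2, 2, 2),
                        origin_affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (is.null(origin_affine)) {
    origin_affine <- diag(c(voxel_size_mm, 1))
    origin_affine[1:3, 4] <- -voxel_size_mm * (shape - 1) / 2
  }
  stopifnot(is.matrix(origin_affine), all(dim(origin_affine) == c(4, 4)))
  if (abs(det(origin_affine)) < .Machine$double.eps)
    stop("origin_affine must be invertible")
  structure(list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_affine = origin_affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(x$voxel_size_mm, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Enumerate searchlight sphere offsets
#'
#' Returns every integer lattice offset `v` with
#' `||v * voxel_size_mm|| <= radius_mm`, in lexicographic order with the
#' centre voxel always included.  With a 4 mm radius on an isotropic 2 mm
#' grid the sphere contains exactly 33 voxels.
#'
#' @param radius_mm sphere radius in mm (>= 0).
#' @param voxel_size_mm isotropic voxel size in mm (> 0).
#' @return an object of class `searchlight_spec` with fields `radius_mm`,
#'   `voxel_size_mm` and the integer offset matrix `offsets` (n x 3).
#' @export
sphere_offsets <- function(radius_mm = 4, voxel_size_mm = 2) {
  stopifnot(length(radius_mm) == 1, radius_mm >= 0,
            length(voxel_size_mm) == 1, voxel_size_mm > 0)
  r <- floor(radius_mm / voxel_size_mm)
  g <- as.matrix(expand.grid(z = -r:r, y = -r:r, x = -r:r))[, 3:1, drop = FALSE]
  colnames(g) <- c("x", "y", "z")
  keep <- rowSums(g^2) * voxel_size_mm^2 <= radius_mm^2 + 1e-9
  off <- g[keep, , drop = FALSE]
  off <- off[order(off[, 1], off[, 2], off[, 3]), , drop = FALSE]
  structure(list(radius_mm = radius_mm, voxel_size_mm = voxel_size_mm,
                 offsets = off),
            class = "searchlight_spec")
}

#' Mock bilateral insula mask
#'
#' Builds a boolean volume containing two mirrored ellipsoids, one per
#' hemisphere, standing in for the insular cortex on a synthetic grid.
#' Sizes scale with the grid so that a down-sampled grid carries a
#' proportionally smaller mask.
#'
#' @param grid a [volume_grid()].
#' @param lateral_frac lateral displacement of each ellipsoid centre as a
#'   fraction of the x extent.
#' @param semi_frac ellipsoid semi-axes as fractions of the grid shape.
#' @return logical 3D array of `grid$shape`.
#' @export
insula_mask <- function(grid, lateral_frac = 0.28,
                        semi_frac = c(0.10, 0.25, 0.18)) {
  shp <- grid$shape
  semi <- pmax(semi_frac * shp, 1)
  ctr <- (shp + 1) / 2
  ax <- seq_len(shp[1]) - ctr[1]
  ay <- seq_len(shp[2]) - ctr[2]
  az <- seq_len(shp[3]) - ctr[3]
  cx <- lateral_frac * shp[1]
  m <- array(FALSE, shp)
  for (sgn in c(-1, 1)) {
    dx2 <- ((ax - sgn * cx) / semi[1])^2
    dy2 <- (ay / semi[2])^2
    dz2 <- (az / semi[3])^2
    m <- m | (outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1)
  }
  m
}

#' Spherical subregion inside a grid
#'
#' @param grid a [volume_grid()].
#' @param center_vox sphere centre in (possibly fractional) voxel indices.
#' @param radius_mm sphere radius in mm.
#' @return logical 3D array.
#' @keywords internal
sphere_region <- function(grid, center_vox, radius_mm) {
  shp <- grid$shape
  vox <- grid$voxel_size_mm
  dx2 <- ((seq_len(shp[1]) - center_vox[1]) * vox[1])^2
  dy2 <- ((seq_len(shp[2]) - center_vox[2]) * vox[2])^2
  dz2 <- ((seq_len(shp[3]) - center_vox[3]) * vox[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_mm^2 + 1e-9
}
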