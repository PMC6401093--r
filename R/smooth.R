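#' Gaussian spatial smoothing of a volume
#'
#' Separable Gaussian smoothing parameterised by full width at half
#' maximum.  When a mask is supplied the kernel is renormalised inside
#' the mask (the smoothed volume is divided by the smoothed mask), so a
#' constant volume stays constant near mask edges and values outside the
#' mask neither leak in nor dilute the result; output voxels outside the
#' mask are set to `NA`.  `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @param voxel_size_mm voxel size per axis in mm (length 1 or 3).
#' @param mask optional logical array of the same shape.
#' @return smoothed array of the same shape.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_size_mm = 2, mask = NULL) {
  stopifnot(length(dim(volume)) == 3)
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (fwhm_mm == 0) {
    if (!is.null(mask)) volume[!mask] <- NA_real_
    return(volume)
  }
  kerns <- lapply(1:3, function(a) gauss_kernel(fwhm_mm, voxel_size_mm[a]))
  if (is.null(mask)) return(separable_smooth(volume, kerns))
  stopifnot(all(dim(mask) == dim(volume)))
  v <- volume
  v[!mask] <- 0
  num <- separable_smooth(v, kerns)
  den <- separable_smooth(array(as.numeric(mask), dim(mask)), kerns)
  out <- num / den
  out[!mask] <- NA_real_
  out
}

# normalized 1-D Gaussian kernel for a given FWHM and voxel size
gauss_kernel <- function(fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3.5 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# apply 1-D kernels along each axis by shift-and-add with zero padding
separable_smooth <- function(vol, kerns) {
  for (axis in 1:3) {
    w <- kerns[[axis]]
    r <- (length(w) - 1L) / 2L
    out <- array(0, dim(vol))
    for (o in -r:r) out <- out + w[o + r + 1L] * shift_array(vol, o, axis)
    vol <- out
  }
  vol
}

# shift an array by `o` voxels along `axis`, zero-filling the exposed edge
shift_array <- function(a, o, axis) {
  if (o == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  if (abs(o) >= n) return(array(0, d))
  src <- if (o > 0) 1:(n - o) else (1 - o):n
  dst <- if (o > 0) (1 + o):n else 1:(n + o)
  out <- array(0, d)
  idx_src <- lapply(seq_along(d), function(i) if (i == axis) src else seq_len(d[i]))
  idx_dst <- lapply(seq_along(d), function(i) if (i == axis) dst else seq_len(d[i]))
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# band matrix applying the 1-D kernel along an axis of length n with
# zero padding (rows sum to <= 1 at the edges, matching shift-and-add)
kernel_band_matrix <- function(w, n) {
  r <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + w[o + r + 1L]
  }
  K
}

# smooth many volumes at once: vols is an nvox_grid x n matrix of
# vectorised volumes over `shape`; returns the same layout smoothed
batch_smooth <- function(vols, shape, fwhm_mm, voxel_size_mm) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (fwhm_mm == 0) return(vols)
  n <- ncol(vols)
  a <- array(vols, c(shape, n))
  for (axis in 1:3) {
    K <- kernel_band_matrix(gauss_kernel(fwhm_mm, voxel_size_mm[axis]),
                            shape[axis])
    perm <- c(axis, setdiff(1:4, axis))
    a <- aperm(a, perm)
    d <- dim(a)
    a <- array(K %*% matrix(a, d[1]), d)
    a <- aperm(a, order(perm))
  }
  matrix(a, prod(shape), n)
}

# variance attenuation factor of the separable kernel: smoothing unit
# white noise leaves sd sqrt(prod(sum(w_axis^2)))
smooth_noise_sd_factor <- function(fwhm_mm, voxel_size_mm) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (fwhm_mm == 0) return(1)
  sqrt(prod(vapply(1:3, function(a) sum(gauss_kernel(fwhm_mm, voxel_size_mm[a])^2),
                   numeric(1))))
}
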