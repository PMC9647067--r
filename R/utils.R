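#' @useDynLib qdmi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif setNames var wilcox.test sd
#' @importFrom utils read.delim
NULL

# Internal axis order is (z, y, x): a[z, y, x], matching plane-sequential
# acquisition. voxel_size_nm is user-facing (x, y, z); spacing_zyx() flips it.
spacing_zyx <- function(voxel_size_nm) {
  stopifnot(length(voxel_size_nm) == 3, all(voxel_size_nm > 0))
  as.numeric(voxel_size_nm[c(3, 2, 1)])
}

voxel_volume_um3 <- function(voxel_size_nm) {
  prod(as.numeric(voxel_size_nm)) / 1e9
}

# Truncated 1D Gaussian kernel as a dense band matrix K (n x n) such that
# K %*% along-axis profiles performs the convolution with renormalised
# (edge-clamped) tails. sigma in voxels.
gauss_band <- function(n, sigma, truncate = 3) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

# Separable anisotropic Gaussian blur of a (z, y, x) volume; sigma_nm is
# (x, y, z) physical scale, converted with the voxel size.
blur_gaussian <- function(vol, sigma_nm, voxel_size_nm, truncate = 3) {
  d <- dim(vol)
  stopifnot(length(sigma_nm) == 3, all(sigma_nm >= 0))
  sig_vox <- as.numeric(sigma_nm[c(3, 2, 1)]) / spacing_zyx(voxel_size_nm)
  # z axis: vol is (nz, ny*nx) when flattened column-major
  if (sig_vox[1] > 0) {
    Kz <- gauss_band(d[1], sig_vox[1], truncate)
    vol <- array(Kz %*% matrix(vol, d[1]), d)
  }
  if (sig_vox[2] > 0) {
    Ky <- gauss_band(d[2], sig_vox[2], truncate)
    p <- aperm(vol, c(2, 1, 3))
    p <- array(Ky %*% matrix(p, d[2]), dim(p))
    vol <- aperm(p, c(2, 1, 3))
  }
  if (sig_vox[3] > 0) {
    Kx <- gauss_band(d[3], sig_vox[3], truncate)
    p <- aperm(vol, c(3, 1, 2))
    p <- array(Kx %*% matrix(p, d[3]), dim(p))
    vol <- aperm(p, c(2, 3, 1))
  }
  vol
}

params_digest <- function(x) rlang::hash(x)

qdmi_log <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " qdmi: ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
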