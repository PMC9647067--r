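#' Multi-channel 3D image stack
#'
#' An `ImageStack` bundles one 3D voxel array per channel with the physical
#' voxel size and the detector bit depth. Arrays are stored `(z, y, x)`
#' (plane-sequential order); `voxel_size_nm` is given `(x, y, z)` as on the
#' microscope. Intensities are detector units in `[0, 2^bit_depth - 1]`.
#'
#' @param voxels named list of 3D numeric arrays, identical dimensions,
#'   one per channel. Names are the channel labels (e.g. `"DAPI"`, `"5mC"`).
#' @param voxel_size_nm numeric length-3, physical voxel extents in nm,
#'   ordered `(x, y, z)`; all strictly positive.
#' @param bit_depth integer bits per sample (12 for the typical confocal
#'   acquisition this package targets).
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(voxels, voxel_size_nm, bit_depth = 12L) {
  if (!is.list(voxels) || is.null(names(voxels)) || any(names(voxels) == ""))
    stop("`voxels` must be a named list of 3D arrays", call. = FALSE)
  dims <- lapply(voxels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array", call. = FALSE)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share identical dimensions", call. = FALSE)
  if (length(voxel_size_nm) != 3L || any(voxel_size_nm <= 0))
    stop("voxel_size_nm must be three strictly positive values (x, y, z)",
         call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  maxv <- 2^bit_depth - 1
  for (ch in names(voxels)) {
    v <- voxels[[ch]]
    if (anyNA(v) || min(v) < 0 || max(v) > maxv)
      stop(sprintf("channel '%s' has intensities outside [0, %d]", ch, maxv),
           call. = FALSE)
  }
  structure(
    list(voxels = voxels,
         channel_names = names(voxels),
         voxel_size_nm = as.numeric(voxel_size_nm),
         bit_depth = bit_depth),
    class = "ImageStack")
}

#' Extract one channel of an ImageStack
#'
#' @param stack an `ImageStack`.
#' @param channel channel name.
#' @return The channel's 3D `(z, y, x)` array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!channel %in% stack$channel_names)
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(stack$channel_names, collapse = ", ")), call. = FALSE)
  stack$voxels[[channel]]
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels[[1]])
  cat(sprintf("ImageStack: %d x %d x %d (x,y,z), %d channel(s): %s\n",
              d[3], d[2], d[1], length(x$voxels),
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  voxel %g x %g x %g nm, %d-bit\n",
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3],
              x$bit_depth))
  invisible(x)
}

stack_dims_zyx <- function(stack) dim(stack$voxels[[1]])
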