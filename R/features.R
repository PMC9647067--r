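#' Global 5mC load of a nucleus
#'
#' The first of the two per-nucleus parameters: integrated (and mean) 5mC
#' immunofluorescence over all voxels of the nucleus, with the integrated
#' DAPI signal alongside.
#'
#' @param pairs data.frame with columns `dapi`, `mc5` (one row per voxel),
#'   as from [extract_nucleus_voxels()].
#' @return list with `mc5_total`, `mc5_mean`, `dapi_total`.
#' @export
global_mc5_load <- function(pairs) {
  if (is.null(nrow(pairs)) || nrow(pairs) == 0L)
    stop("no voxel pairs supplied", call. = FALSE)
  list(mc5_total = sum(pairs$mc5),
       mc5_mean = sum(pairs$mc5) / nrow(pairs),
       dapi_total = sum(pairs$dapi))
}

#' Joint DAPI/5mC intensity histogram (the codistribution "scatter plot")
#'
#' Bin edges are fixed to the full dynamic range `[0, 2^bit_depth - 1]`
#' (not data-driven), so histograms from different nuclei of one acquisition
#' batch are directly comparable; the right-most bin is closed.
#'
#' @param pairs data.frame with columns `dapi`, `mc5`.
#' @param n_bins bins per axis (default 64).
#' @param bit_depth detector bits defining the intensity range.
#' @return A `JointDistribution`: list with `counts` (`n_bins x n_bins`
#'   matrix, rows = DAPI bins, cols = 5mC bins), `bin_edges`, `n_bins`,
#'   `bit_depth`, `n_voxels`.
#' @export
joint_histogram <- function(pairs, n_bins = 64L, bit_depth = 12L) {
  maxv <- 2^bit_depth - 1
  bad <- which(pairs$dapi < 0 | pairs$dapi > maxv |
               pairs$mc5 < 0 | pairs$mc5 > maxv)
  if (length(bad))
    stop(sprintf("intensity out of [0, %d] at voxel pair %d (DAPI=%g, 5mC=%g)",
                 maxv, bad[1], pairs$dapi[bad[1]], pairs$mc5[bad[1]]),
         call. = FALSE)
  n_bins <- as.integer(n_bins)
  width <- maxv / n_bins
  bx <- pmin(floor(pairs$dapi / width) + 1L, n_bins)
  by <- pmin(floor(pairs$mc5 / width) + 1L, n_bins)
  counts <- matrix(0, n_bins, n_bins)
  tab <- table(factor(bx, levels = seq_len(n_bins)),
               factor(by, levels = seq_len(n_bins)))
  counts[] <- as.numeric(tab)
  structure(list(counts = counts,
                 bin_edges = seq(0, maxv, length.out = n_bins + 1L),
                 n_bins = n_bins, bit_depth = as.integer(bit_depth),
                 n_voxels = nrow(pairs)),
            class = "JointDistribution")
}

#' Normalize a JointDistribution to probabilities
#'
#' @param jd a `JointDistribution`.
#' @param epsilon pseudocount added to every bin before normalizing
#'   (0 = plain relative frequencies).
#' @return matrix of probabilities summing to 1.
#' @export
normalize_distribution <- function(jd, epsilon = 0) {
  stopifnot(inherits(jd, "JointDistribution"))
  p <- jd$counts + epsilon
  p / sum(p)
}

#' 5mC/DAPI colocalization index (regression angle delta)
#'
#' Both channels are rescaled to `[0, 1]` by the full dynamic range, then
#' 5mC is regressed on DAPI (DAPI on the x-axis) by ordinary least squares
#' with intercept over all voxel pairs. The colocalization index is
#' `delta = atan(slope)` in degrees: about 45 degrees when 5mC tracks DNA
#' density one-to-one at equal gain, near 0 when 5mC is flat or decoupled.
#'
#' @param pairs data.frame with columns `dapi`, `mc5`; at least 2 rows with
#'   non-zero DAPI variance.
#' @param bit_depth detector bits used for axis normalization.
#' @return list with `slope` (dimensionless) and `delta_deg` in `[-90, 90]`.
#' @export
codistribution_index <- function(pairs, bit_depth = 12L) {
  if (nrow(pairs) < 2L)
    stop("need at least 2 voxel pairs to fit a regression", call. = FALSE)
  maxv <- 2^bit_depth - 1
  x <- pairs$dapi / maxv
  y <- pairs$mc5 / maxv
  if (var(x) == 0)
    stop("DAPI variance is zero; regression undefined", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  list(slope = slope, delta_deg = atan(slope) * 180 / pi)
}

#' Regression angle from a binned joint histogram
#'
#' Alternative delta estimate fitted on count-weighted bin centers of the
#' joint histogram instead of raw voxels (the display route). Agrees with
#' [codistribution_index()] up to binning resolution.
#'
#' @param jd a `JointDistribution`.
#' @return list with `slope` and `delta_deg`.
#' @export
codistribution_index_binned <- function(jd) {
  stopifnot(inherits(jd, "JointDistribution"))
  maxv <- 2^jd$bit_depth - 1
  mids <- (jd$bin_edges[-1] + jd$bin_edges[-length(jd$bin_edges)]) / 2 / maxv
  w <- jd$counts
  x <- rep(mids, times = jd$n_bins)
  y <- rep(mids, each = jd$n_bins)
  wt <- as.vector(w)
  keep <- wt > 0
  x <- x[keep]; y <- y[keep]; wt <- wt[keep]
  xb <- sum(wt * x) / sum(wt)
  yb <- sum(wt * y) / sum(wt)
  slope <- sum(wt * (x - xb) * (y - yb)) / sum(wt * (x - xb)^2)
  list(slope = slope, delta_deg = atan(slope) * 180 / pi)
}

#' Percent reduction of mean integrated 5mC between two populations
#'
#' `100 * (1 - mean(test) / mean(normal))` over per-nucleus `mc5_total`;
#' negative values indicate hypermethylation of the test group.
#'
#' @param normal_records,test_records data.frames with an `mc5_total` column
#'   (e.g. from [analyze_stack()]).
#' @return percent reduction (scalar).
#' @export
population_reduction <- function(normal_records, test_records) {
  if (!nrow(normal_records) || !nrow(test_records))
    stop("both record sets must be non-empty", call. = FALSE)
  m0 <- mean(normal_records$mc5_total)
  if (m0 == 0) stop("normal population has zero mean 5mC load", call. = FALSE)
  100 * (1 - mean(test_records$mc5_total) / m0)
}

#' Per-nucleus feature extraction over a labeled stack
#'
#' Runs [extract_nucleus_voxels()], [global_mc5_load()], [joint_histogram()]
#' and [codistribution_index()] for every labeled nucleus.
#'
#' @param stack an [image_stack()].
#' @param labels a `LabelVolume`.
#' @param n_bins histogram bins per axis.
#' @param delta_cutoff_deg nuclei with `delta_deg` below this are flagged
#'   aberrantly hypomethylated (the `aberrant` attribute on the result).
#' @return data.frame of `NucleusRecord` rows (`kl_score`/`similarity_class`
#'   are `NA` until [classify_cells()] fills them), with the per-nucleus
#'   `JointDistribution`s in `attr(, "distributions")` and the aberrant
#'   flags in `attr(, "aberrant")`.
#' @export
analyze_stack <- function(stack, labels, n_bins = 64L, delta_cutoff_deg = 15) {
  stopifnot(inherits(stack, "ImageStack"))
  arr <- if (inherits(labels, "LabelVolume")) labels$labels else labels
  ids <- sort(unique(arr[arr > 0L]))
  vol_um3 <- voxel_volume_um3(stack$voxel_size_nm)
  recs <- vector("list", length(ids))
  dists <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    pairs <- extract_nucleus_voxels(stack, arr, ids[k])
    load <- global_mc5_load(pairs)
    ci <- codistribution_index(pairs, stack$bit_depth)
    dists[[k]] <- joint_histogram(pairs, n_bins, stack$bit_depth)
    recs[[k]] <- data.frame(
      nucleus_id = ids[k], voxel_count = nrow(pairs),
      volume_um3 = nrow(pairs) * vol_um3,
      dapi_total = load$dapi_total, mc5_total = load$mc5_total,
      mc5_mean = load$mc5_mean, slope = ci$slope, delta_deg = ci$delta_deg,
      kl_score = NA_real_, similarity_class = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- empty_records()
  names(dists) <- as.character(ids)
  attr(out, "distributions") <- dists
  attr(out, "aberrant") <- out$delta_deg < delta_cutoff_deg
  out
}

empty_records <- function() {
  data.frame(nucleus_id = integer(), voxel_count = integer(),
             volume_um3 = numeric(), dapi_total = numeric(),
             mc5_total = numeric(), mc5_mean = numeric(), slope = numeric(),
             delta_deg = numeric(), kl_score = numeric(),
             similarity_class = character(), stringsAsFactors = FALSE)
}
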