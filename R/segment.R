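#' Labeled 3D segmentation volume
#'
#' @param labels 3D integer `(z, y, x)` array; 0 = background, k > 0 =
#'   nucleus k. Positive labels are compacted to consecutive `1..n_objects`.
#' @param params_digest hash of the parameters that produced the labels.
#' @return A `LabelVolume`.
#' @export
label_volume <- function(labels, params_digest = "") {
  stopifnot(length(dim(labels)) == 3L)
  labels <- compact_labels(labels)
  structure(list(labels = labels,
                 n_objects = max(0L, max(labels)),
                 params_digest = params_digest),
            class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("LabelVolume: %d x %d x %d (x,y,z), %d object(s)\n",
              d[3], d[2], d[1], x$n_objects))
  invisible(x)
}

# renumber positive labels to 1..n in order of first (column-major)
# occurrence; volumes already labeled 1..n keep their ids
compact_labels <- function(labels) {
  pos <- labels[labels > 0L]
  if (!length(pos)) return(labels)
  old <- unique(pos)
  if (length(old) == max(old)) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  map <- integer(max(old))
  map[old] <- seq_along(old)
  labels[labels > 0L] <- map[pos]
  storage.mode(labels) <- "integer"
  labels
}

#' Segmentation parameters
#'
#' @param smoothing_sigma_nm Gaussian pre-smoothing `(x, y, z)` in nm.
#' @param threshold_method `"otsu"` (global Otsu on the smoothed volume) or
#'   `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method="fixed"`.
#' @param min_volume_um3 smallest admissible nucleus volume.
#' @param split_touching separate touching nuclei by distance-transform
#'   watershed.
#' @param exclude_xy_border drop objects touching the lateral image border
#'   (z-truncated objects are kept: thin confocal stacks cut most nuclei
#'   axially).
#' @param seed_min_sep_um minimum separation between watershed seeds.
#' @param seed_h_um saddle depth: a candidate seed is kept only if the
#'   distance profile toward its nearest accepted seed dips at least this far
#'   below the candidate (suppresses spurious splits along the medial ridge
#'   of a single eccentric nucleus).
#' @return A `SegmentationParams` list.
#' @export
seg_params <- function(smoothing_sigma_nm = c(200, 200, 400),
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NA_real_,
                       min_volume_um3 = 30,
                       split_touching = TRUE,
                       exclude_xy_border = TRUE,
                       seed_min_sep_um = 1,
                       seed_h_um = 0.4) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && !is.finite(fixed_threshold))
    stop("fixed_threshold must be set when threshold_method='fixed'",
         call. = FALSE)
  if (min_volume_um3 <= 0) stop("min_volume_um3 must be > 0", call. = FALSE)
  structure(list(smoothing_sigma_nm = as.numeric(smoothing_sigma_nm),
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_volume_um3 = min_volume_um3,
                 split_touching = isTRUE(split_touching),
                 exclude_xy_border = isTRUE(exclude_xy_border),
                 seed_min_sep_um = seed_min_sep_um,
                 seed_h_um = seed_h_um),
            class = "SegmentationParams")
}

# global Otsu threshold over a fixed 256-bin histogram
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# fill interior cavities: background components (6-connected) not touching
# any face of the volume become foreground
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- .cc_label(!mask, as.integer(d), 6L)
  border <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                     bg[, , 1], bg[, , d[3]]))
  border <- border[border > 0L]
  holes <- !(bg %in% c(0L, border))
  array(mask | holes, d)
}

# greedy seed selection on the smoothed distance transform: descending by
# distance value; keep a candidate if it is >= min_sep from every accepted
# seed AND the distance profile along the straight line to the nearest
# accepted seed dips at least h below the candidate (saddle criterion).
find_seeds <- function(dist, mask, spacing_nm, min_sep_um, h_um) {
  d <- dim(dist)
  cand <- .local_maxima(dist, mask, as.integer(d))
  if (!length(cand)) return(integer(0))
  vals <- dist[cand]
  ord <- order(-vals, cand)
  cand <- cand[ord]; vals <- vals[ord]
  coords <- arrayInd(cand, d)                      # (z, y, x), 1-based
  pos_nm <- sweep(coords, 2, spacing_nm, `*`)
  accepted <- integer(0)
  for (k in seq_along(cand)) {
    if (!length(accepted)) { accepted <- k; next }
    dd <- sqrt(colSums((t(pos_nm[accepted, , drop = FALSE]) - pos_nm[k, ])^2))
    if (min(dd) < min_sep_um * 1000) next
    nearest <- accepted[which.min(dd)]
    # sample the distance transform along the segment to the nearest seed
    ns <- max(2L, ceiling(min(dd) / min(spacing_nm)))
    tseq <- seq(0, 1, length.out = ns)
    line <- round(outer(1 - tseq, coords[k, ]) + outer(tseq, coords[nearest, ]))
    line <- pmin(pmax(line, 1L), matrix(d, ns, 3, byrow = TRUE))
    saddle <- min(dist[cbind(line[, 1], line[, 2], line[, 3])])
    if (saddle <= vals[k] - h_um * 1000) accepted <- c(accepted, k)
  }
  cand[accepted]
}

#' Segment nuclei in 3D from the DAPI channel
#'
#' Deterministic pipeline: Gaussian smoothing, global threshold (Otsu by
#' default), 3D hole filling, 26-connected labeling, optional
#' distance-transform watershed split of touching objects, volume filter,
#' optional lateral-border exclusion. Surviving labels are compacted to
#' `1..n_objects`.
#'
#' @param dapi single-channel 3D `(z, y, x)` array, or an [image_stack()]
#'   (its `"DAPI"` channel is used).
#' @param voxel_size_nm `(x, y, z)` nm; ignored when `dapi` is an
#'   `ImageStack`.
#' @param params a [seg_params()].
#' @return A `LabelVolume`. All-background thresholding yields an empty
#'   `LabelVolume` with a warning, not an error.
#' @export
segment_nuclei <- function(dapi, voxel_size_nm = c(189, 189, 500),
                           params = seg_params()) {
  if (inherits(dapi, "ImageStack")) {
    voxel_size_nm <- dapi$voxel_size_nm
    dapi <- get_channel(dapi, "DAPI")
  }
  stopifnot(length(dim(dapi)) == 3L, inherits(params, "SegmentationParams"))
  d <- dim(dapi)
  sm <- blur_gaussian(dapi, params$smoothing_sigma_nm, voxel_size_nm)
  thr <- switch(params$threshold_method,
                otsu = otsu_threshold(as.vector(sm)),
                fixed = params$fixed_threshold)
  mask <- sm > thr
  if (!any(mask)) {
    warning("thresholding left no foreground; returning empty segmentation",
            call. = FALSE)
    return(label_volume(array(0L, d), params_digest = params_digest(params)))
  }
  mask <- fill_holes_3d(mask)
  lab <- .cc_label(mask, as.integer(d), 26L)

  sp <- spacing_zyx(voxel_size_nm)
  if (params$split_touching) {
    dist <- .edt(mask, as.integer(d), sp)
    dist_sm <- blur_gaussian(dist, c(300, 300, 300), voxel_size_nm)
    dist_sm[!mask] <- 0
    seeds_idx <- find_seeds(dist_sm, mask, sp, params$seed_min_sep_um,
                            params$seed_h_um)
    if (length(seeds_idx) > 1L) {
      # split only components holding >= 2 seeds
      comp_of_seed <- lab[seeds_idx]
      multi <- unique(comp_of_seed[duplicated(comp_of_seed)])
      if (length(multi)) {
        seeds <- array(0L, d)
        keep <- comp_of_seed %in% multi
        seeds[seeds_idx[keep]] <- seq_len(sum(keep))
        sub_mask <- array(lab %in% multi, d)
        ws <- .watershed(dist, sub_mask, seeds, as.integer(d))
        lab[sub_mask] <- max(lab) + ws[sub_mask]
      }
    }
  }

  # volume filter
  min_vox <- ceiling(params$min_volume_um3 / voxel_volume_um3(voxel_size_nm))
  tab <- tabulate(lab[lab > 0L])
  drop <- which(tab > 0L & tab < min_vox)
  if (length(drop)) lab[lab %in% drop] <- 0L

  if (params$exclude_xy_border) {
    edge <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
    edge <- edge[edge > 0L]
    if (length(edge)) lab[lab %in% edge] <- 0L
  }
  label_volume(array(as.integer(lab), d), params_digest = params_digest(params))
}

#' Paired per-voxel intensities of one nucleus
#'
#' @param stack an [image_stack()] with `"DAPI"` and `"5mC"` channels.
#' @param labels a `LabelVolume` (or 3D integer array).
#' @param nucleus_id positive integer label present in `labels`.
#' @return data.frame with columns `dapi`, `mc5`, one row per voxel of the
#'   object; pairing is voxelwise.
#' @export
extract_nucleus_voxels <- function(stack, labels, nucleus_id) {
  arr <- if (inherits(labels, "LabelVolume")) labels$labels else labels
  nucleus_id <- as.integer(nucleus_id)
  if (length(nucleus_id) != 1L || is.na(nucleus_id) || nucleus_id <= 0L)
    stop("nucleus_id must be a single positive integer (0 is background)",
         call. = FALSE)
  idx <- which(arr == nucleus_id)
  if (!length(idx))
    stop(sprintf("nucleus_id %d is not present in the label volume",
                 nucleus_id), call. = FALSE)
  data.frame(dapi = get_channel(stack, "DAPI")[idx],
             mc5 = get_channel(stack, "5mC")[idx])
}
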