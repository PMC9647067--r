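SIMILARITY_CLASSES <- c("similar", "likely_similar", "unlikely_similar",
                        "dissimilar")
# fixed pseudo-color mapping of the four soft-qualifiers
SIMILARITY_COLORS <- c(similar = "green", likely_similar = "blue",
                       unlikely_similar = "yellow", dissimilar = "red")
SIMILARITY_RGB <- rbind(similar = c(0, 1, 0), likely_similar = c(0, 0, 1),
                        unlikely_similar = c(1, 1, 0), dissimilar = c(1, 0, 0))

#' Composite codistribution of a cell population
#'
#' Bin-wise sum of raw counts over all nuclei, then normalized: pooling is
#' count-weighted, so larger nuclei contribute proportionally more voxels.
#'
#' @param dists non-empty list of `JointDistribution`s sharing bin edges.
#' @return A `JointDistribution` holding the pooled counts.
#' @export
composite_distribution <- function(dists) {
  if (!length(dists)) stop("no distributions supplied", call. = FALSE)
  ref <- dists[[1]]
  for (d in dists) {
    stopifnot(inherits(d, "JointDistribution"))
    if (!isTRUE(all.equal(d$bin_edges, ref$bin_edges)) ||
        d$n_bins != ref$n_bins)
      stop("distributions have mismatched bin edges", call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(dists, `[[`, "counts"))
  structure(list(counts = counts, bin_edges = ref$bin_edges,
                 n_bins = ref$n_bins, bit_depth = ref$bit_depth,
                 n_voxels = sum(vapply(dists, `[[`, 0, "n_voxels"))),
            class = "JointDistribution")
}

#' Kullback-Leibler divergence between two codistributions, in bits
#'
#' `D(P || Q) = sum p * log2(p / q)` after adding the pseudocount `epsilon`
#' to every raw count of both histograms and renormalizing (Jeffreys-style
#' smoothing keeps the score finite on empty bins). Non-negative, zero iff
#' the smoothed distributions coincide.
#'
#' @param P,Q `JointDistribution`s with matching bin edges.
#' @param epsilon pseudocount per bin, > 0.
#' @return divergence in bits (scalar).
#' @export
kl_divergence <- function(P, Q, epsilon = 0.5) {
  stopifnot(inherits(P, "JointDistribution"), inherits(Q, "JointDistribution"))
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (!identical(dim(P$counts), dim(Q$counts)) ||
      !isTRUE(all.equal(P$bin_edges, Q$bin_edges)))
    stop("distributions have mismatched shape or bin edges", call. = FALSE)
  p <- P$counts + epsilon
  p <- p / sum(p)
  q <- Q$counts + epsilon
  q <- q / sum(q)
  sum(p * log2(p / q))
}

#' Score nuclei against the population composite and classify
#'
#' Each nucleus receives `kl_score = D(cell || composite)` and one of the
#' four soft-qualifiers by ascending thresholds: `similar` if
#' `score <= t1`, `likely_similar` if `<= t2`, `unlikely_similar` if
#' `<= t3`, else `dissimilar` (boundary scores take the lower class).
#'
#' @param records data.frame from [analyze_stack()] (its
#'   `"distributions"` attribute is used unless `dists` is given).
#' @param dists optional list of `JointDistribution`s, one per record row.
#' @param thresholds ascending KL cutoffs `(t1, t2, t3)` in bits.
#' @param quantile_mode if `TRUE`, thresholds are instead taken at the 25th,
#'   50th and 75th percentile of the population's own scores.
#' @param epsilon pseudocount for [kl_divergence()].
#' @return list with `records` (kl_score / similarity_class filled) and
#'   `profile` (a `PopulationProfile`: composite distribution, thresholds,
#'   per-class counts, homogeneity fraction).
#' @export
classify_cells <- function(records, dists = NULL,
                           thresholds = c(1.2, 1.7, 2.6),
                           quantile_mode = FALSE, epsilon = 0.5) {
  if (is.null(dists)) dists <- attr(records, "distributions")
  if (is.null(dists) || length(dists) != nrow(records))
    stop("need one JointDistribution per record row", call. = FALSE)
  if (!(length(thresholds) == 3L && all(diff(thresholds) > 0)))
    stop("thresholds must be three ascending values", call. = FALSE)
  if (nrow(records) == 0L) stop("no records to classify", call. = FALSE)
  if (nrow(records) == 1L)
    warning("single nucleus: composite is the cell itself (kl_score 0)",
            call. = FALSE)

  composite <- composite_distribution(dists)
  scores <- vapply(dists, function(d) kl_divergence(d, composite, epsilon), 0)
  if (quantile_mode)
    thresholds <- unname(stats::quantile(scores, c(0.25, 0.5, 0.75)))
  cls <- SIMILARITY_CLASSES[findInterval(scores, thresholds,
                                         left.open = TRUE) + 1L]
  records$kl_score <- unname(scores)
  records$similarity_class <- cls
  counts <- table(factor(cls, levels = SIMILARITY_CLASSES))
  profile <- structure(
    list(composite = composite, thresholds = thresholds,
         class_counts = counts,
         homogeneity_fraction =
           unname((counts["similar"] + counts["likely_similar"]) / sum(counts))),
    class = "PopulationProfile")
  list(records = records, profile = profile)
}

#' @export
print.PopulationProfile <- function(x, ...) {
  cat("PopulationProfile:", sum(x$class_counts), "nuclei\n")
  cat(sprintf("  thresholds (bits): %s\n",
              paste(signif(x$thresholds, 4), collapse = " / ")))
  for (cl in SIMILARITY_CLASSES)
    cat(sprintf("  %-17s %d (%s)\n", cl, x$class_counts[[cl]],
                SIMILARITY_COLORS[[cl]]))
  cat(sprintf("  homogeneity fraction: %.3f\n", x$homogeneity_fraction))
  invisible(x)
}

#' Render a cell-similarity map
#'
#' Maximum-intensity XY projection of the label volume with each nucleus
#' pseudo-colored by its soft-qualifier (green/blue/yellow/red for
#' similar / likely similar / unlikely similar / dissimilar), background
#' black. Where nuclei overlap in projection the brighter (nearer-surface,
#' higher-label) voxel wins.
#'
#' @param labels a `LabelVolume` or 3D integer array.
#' @param classes character vector of similarity classes named by nucleus
#'   id (as from `classify_cells()$records`).
#' @param path optional PNG output path.
#' @return `(ny, nx, 3)` RGB array in `[0, 1]`, invisibly if written.
#' @export
render_similarity_map <- function(labels, classes, path = NULL) {
  arr <- if (inherits(labels, "LabelVolume")) labels$labels else labels
  ids <- sort(unique(arr[arr > 0L]))
  missing <- setdiff(as.character(ids), names(classes))
  if (length(missing))
    stop(sprintf("unclassified nucleus id(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- !classes %in% SIMILARITY_CLASSES
  if (any(bad))
    stop(sprintf("unknown similarity class '%s'", classes[bad][1]),
         call. = FALSE)
  d <- dim(arr)
  proj <- apply(arr, c(2, 3), max)                 # max label along z
  img <- array(0, c(d[2], d[3], 3))
  for (id in ids) {
    px <- proj == id
    rgb <- SIMILARITY_RGB[classes[[as.character(id)]], ]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[px] <- rgb[ch]
      img[, , ch] <- plane
    }
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
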