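#' Pipeline run configuration
#'
#' Exactly one of `input_stacks` (paths to TIFF stacks on disk) or
#' `simulation` (a [sim_config()], run fresh) must be supplied.
#'
#' @param input_stacks character vector of stack paths (TIFF file or
#'   per-plane directory each).
#' @param simulation a [sim_config()].
#' @param channel_map named 0-based channel indices for [read_stack()].
#' @param segmentation a [seg_params()].
#' @param n_bins joint-histogram bins per axis.
#' @param delta_cutoff_deg aberrant-cell flag cutoff in degrees.
#' @param thresholds similarity KL cutoffs `(t1, t2, t3)` in bits.
#' @param quantile_mode use population score quantiles instead of absolute
#'   thresholds.
#' @param epsilon KL pseudocount.
#' @param out_dir output directory (created); `NULL` keeps everything in
#'   memory.
#' @param seed seed recorded in the manifest (the simulation carries its
#'   own seed).
#' @return A `RunConfig` list.
#' @export
run_config <- function(input_stacks = NULL, simulation = NULL,
                       channel_map = c(DAPI = 0L, `5mC` = 1L),
                       segmentation = seg_params(), n_bins = 64L,
                       delta_cutoff_deg = 15, thresholds = c(1.2, 1.7, 2.6),
                       quantile_mode = FALSE, epsilon = 0.5,
                       out_dir = NULL, seed = 1L) {
  if (is.null(input_stacks) == is.null(simulation))
    stop("supply exactly one of input_stacks or simulation", call. = FALSE)
  if (!is.null(simulation)) stopifnot(inherits(simulation, "SimulationConfig"))
  structure(list(input_stacks = input_stacks, simulation = simulation,
                 channel_map = channel_map, segmentation = segmentation,
                 n_bins = as.integer(n_bins),
                 delta_cutoff_deg = delta_cutoff_deg, thresholds = thresholds,
                 quantile_mode = isTRUE(quantile_mode), epsilon = epsilon,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Segment and analyze a list of stacks as one population
#'
#' Convenience for populations spread over several fields of view: segments
#' each stack (unless `labels_list` is given), extracts per-nucleus records,
#' and concatenates them with globally unique `nucleus_id`s
#' (`stack_index`/`local_id` keep the trace to the source stack).
#'
#' @param stacks list of [image_stack()]s.
#' @param segmentation a [seg_params()].
#' @param n_bins,delta_cutoff_deg passed to [analyze_stack()].
#' @param labels_list optional list of precomputed `LabelVolume`s (e.g.
#'   simulation ground truth), one per stack.
#' @return Combined record data.frame with `"distributions"` and `"labels"`
#'   attributes.
#' @export
analyze_stacks <- function(stacks, segmentation = seg_params(),
                           n_bins = 64L, delta_cutoff_deg = 15,
                           labels_list = NULL) {
  recs <- list(); dists <- list(); labs <- list()
  offset <- 0L
  for (s in seq_along(stacks)) {
    stack <- stacks[[s]]
    lab <- if (!is.null(labels_list)) labels_list[[s]]
           else segment_nuclei(stack, params = segmentation)
    r <- analyze_stack(stack, lab, n_bins, delta_cutoff_deg)
    d <- attr(r, "distributions")
    if (nrow(r)) {
      r$stack_index <- s
      r$local_id <- r$nucleus_id
      r$nucleus_id <- r$nucleus_id + offset
      offset <- offset + nrow(r)
    }
    recs[[s]] <- r
    dists <- c(dists, d)
    labs[[s]] <- lab
  }
  out <- do.call(rbind, recs)
  attr(out, "distributions") <- dists
  attr(out, "labels") <- labs
  out
}

#' Run the full pipeline: (simulate |) read, segment, analyze, classify
#'
#' Executes the three analysis steps in order -- 3D segmentation, per-nucleus
#' parameter extraction (global 5mC load and regression-angle index), and
#' KL-divergence similarity scoring against the population composite -- and,
#' when `out_dir` is set, writes the result table (TSV), one similarity map
#' PNG per stack, and a YAML run manifest with parameter digests.
#'
#' @param config a [run_config()].
#' @return list with `records` (result table), `profile`
#'   (`PopulationProfile`), `labels` (list of `LabelVolume`), `truth`
#'   (simulation ground truth, if simulated), `artifacts` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- generate_stack(config$simulation)
    stacks <- list(sim$stack)
    truth <- sim$truth
    qdmi_log(sprintf("simulated stack: %d nuclei, seed %d",
                     nrow(truth), config$simulation$seed))
  } else {
    stacks <- lapply(config$input_stacks, read_stack,
                     channel_map = config$channel_map)
    qdmi_log(sprintf("read %d stack(s)", length(stacks)))
  }
  records <- analyze_stacks(stacks, config$segmentation, config$n_bins,
                            config$delta_cutoff_deg)
  if (!nrow(records))
    warning("no nuclei survived segmentation", call. = FALSE)
  cl <- classify_cells(records, attr(records, "distributions"),
                       thresholds = config$thresholds,
                       quantile_mode = config$quantile_mode,
                       epsilon = config$epsilon)
  records_out <- cl$records
  labels <- attr(records, "labels")

  artifacts <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    digest <- params_digest(config[setdiff(names(config), "out_dir")])
    tsv <- file.path(config$out_dir, "results.tsv")
    write_results(records_out, tsv,
                  provenance = list(
                    source = paste(config$input_stacks %||% "simulation",
                                   collapse = ","),
                    config_digest = digest, seed = config$seed))
    artifacts <- c(artifacts, tsv)
    for (s in seq_along(labels)) {
      rs <- records_out[records_out$stack_index == s, ]
      classes <- setNames(rs$similarity_class, rs$local_id)
      mp <- file.path(config$out_dir, sprintf("similarity_map_%02d.png", s))
      render_similarity_map(labels[[s]], classes, path = mp)
      artifacts <- c(artifacts, mp)
    }
    manifest <- file.path(config$out_dir, "run_manifest.yaml")
    yaml::write_yaml(list(
      software = paste0("qdmi ", as.character(utils::packageVersion("qdmi"))),
      config_digest = digest, seed = config$seed,
      n_stacks = length(stacks), n_nuclei = nrow(records_out),
      homogeneity_fraction = as.numeric(cl$profile$homogeneity_fraction),
      artifacts = artifacts), manifest)
    artifacts <- c(artifacts, manifest)
  }
  list(records = records_out, profile = cl$profile, labels = labels,
       truth = truth, artifacts = artifacts)
}

#' Compare two analyzed populations
#'
#' Summarizes per-group 5mC load and colocalization index, the percent
#' reduction of mean integrated 5mC in B relative to A, a two-sided
#' Mann-Whitney rank-sum test on the per-nucleus delta index, and the
#' per-group aberrant-cell tally (`delta_deg < delta_cutoff_deg`).
#'
#' @param tableA,tableB result tables (data.frames with `mc5_total` and
#'   `delta_deg`), e.g. from [run_pipeline()] or [read_results()].
#' @param delta_cutoff_deg aberrant-cell cutoff in degrees.
#' @param names group labels for printing.
#' @return A `GroupComparison` list.
#' @export
compare_groups <- function(tableA, tableB, delta_cutoff_deg = 15,
                           names = c("A", "B")) {
  need <- c("mc5_total", "delta_deg")
  for (tb in list(tableA, tableB)) {
    miss <- setdiff(need, colnames(tb))
    if (length(miss))
      stop(sprintf("result table lacks column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(tableA) || !nrow(tableB))
    stop("both tables must be non-empty", call. = FALSE)
  wt <- wilcox.test(tableA$delta_deg, tableB$delta_deg,
                    alternative = "two.sided", exact = FALSE)
  summ <- function(tb) list(
    n = nrow(tb),
    mc5_total_mean = mean(tb$mc5_total), mc5_total_sd = sd(tb$mc5_total),
    delta_mean = mean(tb$delta_deg), delta_sd = sd(tb$delta_deg),
    n_aberrant = sum(tb$delta_deg < delta_cutoff_deg),
    frac_aberrant = mean(tb$delta_deg < delta_cutoff_deg))
  structure(list(
    group_names = names, groups = setNames(list(summ(tableA), summ(tableB)), names),
    percent_reduction = population_reduction(tableA, tableB),
    delta_cutoff_deg = delta_cutoff_deg,
    rank_sum_statistic = unname(wt$statistic),
    rank_sum_p = wt$p.value), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("GroupComparison:", paste(x$group_names, collapse = " vs "), "\n")
  for (g in x$group_names) {
    s <- x$groups[[g]]
    cat(sprintf("  %-10s n=%3d  mc5_total %.4g +/- %.3g  delta %.3g +/- %.3g deg  aberrant %d (%.1f%%)\n",
                g, s$n, s$mc5_total_mean, s$mc5_total_sd, s$delta_mean,
                s$delta_sd, s$n_aberrant, 100 * s$frac_aberrant))
  }
  cat(sprintf("  reduction of mean 5mC load: %.2f%%\n", x$percent_reduction))
  cat(sprintf("  rank-sum test on delta: W=%g, p=%.3g\n",
              x$rank_sum_statistic, x$rank_sum_p))
  invisible(x)
}
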