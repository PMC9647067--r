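#' Methylation-class presets for the synthetic generator
#'
#' Each preset controls a nucleus class through two knobs: `mc5_scale`, the
#' multiplicative factor on the 5mC amplitude relative to the normal class,
#' and `coupling`, the weight in `[0, 1]` of the DAPI texture in the 5mC
#' signal (1 = 5mC fully proportional to chromatin density, 0 = independent).
#' The four classes emulate a normal bronchial epithelial phenotype, a
#' moderately hypomethylated adenocarcinoma-like phenotype (~20% reduced
#' load), a severely hypomethylated aggressive-carcinoma-like phenotype
#' (65% reduced load), and a severely decoupled aberrant phenotype whose
#' regression angle falls below the 15-degree flag.
#'
#' @return data.frame with columns `name`, `mc5_scale`, `coupling`.
#' @export
class_presets <- function() {
  data.frame(
    name = c("normal", "a549_like", "h157_like", "aberrant_decoupled"),
    mc5_scale = c(1.00, 0.80, 0.35, 0.15),
    coupling = c(0.95, 0.85, 0.45, 0.10),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe a reduced confocal field at the paper-typical voxel
#' geometry: 256 x 256 x 24 voxels of 189 x 189 x 500 nm, 12-bit range,
#' 10 nuclei per stack. Nuclei are ellipsoids (semi-axes `radius_um` mean
#' +/- sd, in micrometres) carrying 3-8 bright heterochromatic DAPI foci
#' (Gaussian blobs, sd 0.4 um, `focus_contrast`-fold over the euchromatin
#' baseline). Optics are an anisotropic Gaussian PSF; noise is Poisson photon
#' noise plus Gaussian read noise (sd 2% of the channel amplitude), clipped
#' to the dynamic range.
#'
#' @param grid_dims integer `(nx, ny, nz)` voxels.
#' @param voxel_size_nm numeric `(x, y, z)` nm.
#' @param n_nuclei nuclei per stack.
#' @param radius_um `c(mean, sd)` of nucleus semi-axes in um.
#' @param focus_density expected heterochromatic foci per nucleus; counts are
#'   drawn uniformly from `focus_density +/- 2.5`, floored at 1.
#' @param focus_contrast fold-brightness of foci over the euchromatin DAPI
#'   baseline.
#' @param class_mix named proportions over [class_presets()] names; must sum
#'   to 1.
#' @param psf_sigma_nm Gaussian PSF sigma `(x, y, z)` nm.
#' @param noise_poisson_gain photons per detector unit (1 = shot noise at
#'   face value).
#' @param noise_gaussian_sd absolute read-noise sd in detector units;
#'   `NULL` means 2% of `base_intensity`.
#' @param base_intensity euchromatin DAPI baseline and normal-class 5mC
#'   amplitude, detector units.
#' @param seed integer RNG seed; every stochastic draw flows from it.
#' @param bit_depth detector bits.
#' @param max_place_tries placement retries per nucleus before failing.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(grid_dims = c(256L, 256L, 24L),
                       voxel_size_nm = c(189, 189, 500),
                       n_nuclei = 10L,
                       radius_um = c(mean = 2.5, sd = 0.3),
                       focus_density = 5.5,
                       focus_contrast = 3,
                       class_mix = c(normal = 1),
                       psf_sigma_nm = c(150, 150, 350),
                       noise_poisson_gain = 1.0,
                       noise_gaussian_sd = NULL,
                       base_intensity = 800,
                       seed = 1L,
                       bit_depth = 12L,
                       max_place_tries = 2000L) {
  mix <- unlist(class_mix)
  if (abs(sum(mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1", call. = FALSE)
  unknown <- setdiff(names(mix), class_presets()$name)
  if (length(unknown))
    stop(sprintf("unknown class preset(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (is.null(noise_gaussian_sd)) noise_gaussian_sd <- 0.02 * base_intensity
  structure(list(
    grid_dims = as.integer(grid_dims), voxel_size_nm = as.numeric(voxel_size_nm),
    n_nuclei = as.integer(n_nuclei), radius_um = as.numeric(radius_um),
    focus_density = focus_density, focus_contrast = focus_contrast,
    class_mix = mix, psf_sigma_nm = as.numeric(psf_sigma_nm),
    noise_poisson_gain = noise_poisson_gain,
    noise_gaussian_sd = noise_gaussian_sd,
    base_intensity = base_intensity, seed = as.integer(seed),
    bit_depth = as.integer(bit_depth),
    max_place_tries = as.integer(max_place_tries)),
    class = "SimulationConfig")
}

# sample a point uniformly inside the ellipsoid scaled by `shrink`
sample_in_ellipsoid <- function(semi_vox, shrink) {
  repeat {
    p <- runif(3, -1, 1)
    if (sum(p^2) <= 1) return(p * semi_vox * shrink)
  }
}

#' Generate a synthetic two-channel stack with ground truth
#'
#' Forward model, per nucleus of class with parameters `(mc5_scale, c)`:
#' the DAPI texture is `T = 1 + (focus_contrast - 1) * sum of foci blobs`
#' inside the ellipsoid; the DAPI channel is `base * T`; the 5mC channel is
#' `base * mc5_scale * (c * T + (1 - c) * R)` where `R` is a PSF-smoothed
#' white-noise field rescaled, within the nucleus, to the mean and variance
#' of `T` (so the mixture preserves the mean 5mC load at every coupling).
#' Both channels are then blurred by the PSF and noised identically.
#' Ground-truth integrated intensities are the sums of the blurred,
#' noise-free fields over the truth label voxels.
#'
#' @param config a [sim_config()].
#' @param keep_noiseless if `TRUE`, attach the blurred noise-free channels
#'   (`$noiseless`) for conservation checks.
#' @return list with `stack` ([image_stack()]), `labels` (`LabelVolume` of
#'   ground-truth ellipsoids), `truth` (per-nucleus data.frame: id, class,
#'   center voxel, semi-axes, true coupling parameters, noise-free
#'   integrated DAPI/5mC), and optionally `noiseless`.
#' @export
generate_stack <- function(config, keep_noiseless = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  dz <- config$grid_dims[3]; dy <- config$grid_dims[2]; dx <- config$grid_dims[1]
  dims <- c(dz, dy, dx)
  sp <- spacing_zyx(config$voxel_size_nm)              # (z, y, x) nm
  maxv <- 2^config$bit_depth - 1

  presets <- class_presets()
  classes <- sample(names(config$class_mix), config$n_nuclei, replace = TRUE,
                    prob = config$class_mix)

  # --- placement: non-overlapping ellipsoids fully inside the grid ---------
  centers <- matrix(0, config$n_nuclei, 3)             # (z, y, x) voxel, 1-based
  semis_um <- matrix(0, config$n_nuclei, 3)            # (x, y, z) um
  placed <- 0L
  for (i in seq_len(config$n_nuclei)) {
    ok <- FALSE
    for (try in seq_len(config$max_place_tries)) {
      s_um <- pmax(1.0, rnorm(3, config$radius_um[1], config$radius_um[2]))
      s_vox <- s_um * 1000 / sp[c(3, 2, 1)]            # (x, y, z) voxels
      lo <- ceiling(s_vox[c(3, 2, 1)]) + 2             # (z, y, x)
      hi <- dims - lo + 1
      if (any(hi < lo)) next
      ctr <- floor(runif(3, lo, hi + 1))
      ctr <- pmin(pmax(ctr, lo), hi)
      clear <- TRUE
      if (placed > 0L) {
        for (j in seq_len(placed)) {
          d_nm <- sqrt(sum(((ctr - centers[j, ]) * sp)^2))
          min_nm <- (max(s_um) + max(semis_um[j, ])) * 1000 + max(sp)
          if (d_nm <= min_nm) { clear <- FALSE; break }
        }
      }
      if (clear) {
        placed <- placed + 1L
        centers[i, ] <- ctr
        semis_um[i, ] <- s_um
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("could not place nucleus %d after %d tries; use a larger grid or fewer nuclei",
                   i, config$max_place_tries), call. = FALSE)
  }

  # --- independent smooth field for the decoupled 5mC component ------------
  rfield <- array(rnorm(prod(dims)), dims)
  rfield <- blur_gaussian(rfield, config$psf_sigma_nm, config$voxel_size_nm)

  dapi <- array(0, dims)
  mc5 <- array(0, dims)
  labels <- array(0L, dims)

  for (i in seq_len(config$n_nuclei)) {
    cls <- presets[presets$name == classes[i], ]
    ctr <- centers[i, ]                                 # (z, y, x)
    s_vox_zyx <- semis_um[i, c(3, 2, 1)] * 1000 / sp    # (z, y, x) voxels
    zr <- max(1, floor(ctr[1] - s_vox_zyx[1])):min(dz, ceiling(ctr[1] + s_vox_zyx[1]))
    yr <- max(1, floor(ctr[2] - s_vox_zyx[2])):min(dy, ceiling(ctr[2] + s_vox_zyx[2]))
    xr <- max(1, floor(ctr[3] - s_vox_zyx[3])):min(dx, ceiling(ctr[3] + s_vox_zyx[3]))
    gz <- (zr - ctr[1]) / s_vox_zyx[1]
    gy <- (yr - ctr[2]) / s_vox_zyx[2]
    gx <- (xr - ctr[3]) / s_vox_zyx[3]
    u <- outer(outer(gz^2, gy^2, `+`), gx^2, `+`)
    inside <- u <= 1

    # heterochromatic foci: Gaussian blobs, sd 0.4 um, centers well inside
    n_foci <- max(1L, as.integer(round(runif(1, config$focus_density - 2.5,
                                             config$focus_density + 2.5))))
    Tloc <- array(0, dim(u))
    pz <- (zr - ctr[1]) * sp[1]
    py <- (yr - ctr[2]) * sp[2]
    px <- (xr - ctr[3]) * sp[3]
    sigma_f <- 400                                      # nm
    for (f in seq_len(n_foci)) {
      fc <- sample_in_ellipsoid(s_vox_zyx, 0.7)         # (z, y, x) voxel offset
      fc_nm <- fc * sp
      d2 <- outer(outer((pz - fc_nm[1])^2, (py - fc_nm[2])^2, `+`),
                  (px - fc_nm[3])^2, `+`)
      Tloc <- Tloc + exp(-d2 / (2 * sigma_f^2))
    }
    Tex <- 1 + (config$focus_contrast - 1) * Tloc
    Tin <- Tex[inside]

    rloc <- rfield[zr, yr, xr][inside]
    sd_r <- sd(rloc)
    if (!is.finite(sd_r) || sd_r == 0) sd_r <- 1
    rhat <- pmax(0, mean(Tin) + (rloc - mean(rloc)) * sd(Tin) / sd_r)

    mix5 <- cls$coupling * Tin + (1 - cls$coupling) * rhat

    sub <- dapi[zr, yr, xr]
    sub[inside] <- config$base_intensity * Tin
    dapi[zr, yr, xr] <- sub
    sub <- mc5[zr, yr, xr]
    sub[inside] <- config$base_intensity * cls$mc5_scale * mix5
    mc5[zr, yr, xr] <- sub
    lsub <- labels[zr, yr, xr]
    lsub[inside] <- i
    labels[zr, yr, xr] <- lsub
  }

  dapi <- blur_gaussian(dapi, config$psf_sigma_nm, config$voxel_size_nm)
  mc5 <- blur_gaussian(mc5, config$psf_sigma_nm, config$voxel_size_nm)

  truth <- data.frame(
    nucleus_id = seq_len(config$n_nuclei),
    class = classes,
    center_z = centers[, 1] - 1L, center_y = centers[, 2] - 1L,
    center_x = centers[, 3] - 1L,                       # 0-based voxel coords
    semi_x_um = semis_um[, 1], semi_y_um = semis_um[, 2],
    semi_z_um = semis_um[, 3],
    mc5_scale = presets$mc5_scale[match(classes, presets$name)],
    coupling = presets$coupling[match(classes, presets$name)],
    voxel_count = NA_integer_, dapi_true = NA_real_, mc5_true = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(config$n_nuclei)) {
    idx <- labels == i
    truth$voxel_count[i] <- sum(idx)
    truth$dapi_true[i] <- sum(dapi[idx])
    truth$mc5_true[i] <- sum(mc5[idx])
  }

  noiseless <- if (keep_noiseless) list(DAPI = dapi, `5mC` = mc5) else NULL

  add_noise <- function(v) {
    g <- config$noise_poisson_gain
    n <- length(v)
    noisy <- rpois(n, lambda = as.vector(v) * g) / g +
      rnorm(n, 0, config$noise_gaussian_sd)
    array(pmin(pmax(round(noisy), 0), maxv), dim(v))
  }
  stack <- image_stack(list(DAPI = add_noise(dapi), `5mC` = add_noise(mc5)),
                       voxel_size_nm = config$voxel_size_nm,
                       bit_depth = config$bit_depth)

  out <- list(stack = stack,
              labels = label_volume(labels, params_digest = params_digest(config)),
              truth = truth)
  if (keep_noiseless) out$noiseless <- noiseless
  out
}

#' Generate a single-class population across one or more stacks
#'
#' Produces `n` nuclei of one preset class, split into stacks of
#' `base_config$n_nuclei` each (per-stack seeds derived from
#' `base_config$seed`). Nucleus ids in the combined truth table are globally
#' unique; `stack_index` and `local_id` trace each nucleus to its stack.
#'
#' @param preset_name one of [class_presets()] names.
#' @param n total nuclei.
#' @param base_config a [sim_config()]; its `class_mix` is overridden.
#' @param keep_stacks if `FALSE`, only the truth table is returned (for
#'   truth-level statistics without holding all voxel data).
#' @return list with `stacks` (list of [generate_stack()] results, or `NULL`)
#'   and `truth` (combined data.frame).
#' @export
make_population <- function(preset_name, n, base_config = sim_config(),
                            keep_stacks = TRUE) {
  if (!preset_name %in% class_presets()$name)
    stop(sprintf("unknown preset '%s' (have: %s)", preset_name,
                 paste(class_presets()$name, collapse = ", ")), call. = FALSE)
  per <- base_config$n_nuclei
  n_stacks <- ceiling(n / per)
  stacks <- if (keep_stacks) vector("list", n_stacks) else NULL
  truths <- vector("list", n_stacks)
  offset <- 0L
  for (s in seq_len(n_stacks)) {
    cfg <- base_config
    cfg$class_mix <- setNames(1, preset_name)
    cfg$n_nuclei <- min(per, n - (s - 1L) * per)
    cfg$seed <- (base_config$seed + 7919L * s) %% 2147483647L
    res <- generate_stack(cfg)
    tr <- res$truth
    tr$local_id <- tr$nucleus_id
    tr$stack_index <- s
    tr$nucleus_id <- tr$nucleus_id + offset
    offset <- offset + nrow(tr)
    truths[[s]] <- tr
    if (keep_stacks) stacks[[s]] <- res
  }
  list(stacks = stacks, truth = do.call(rbind, truths))
}
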