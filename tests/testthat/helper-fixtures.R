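# Shared fixtures. Everything is generated in code at test time; expensive
# objects are memoised for the duration of the run.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fx_cache)) assign(key, force(expr), .fx_cache)
  get(key, .fx_cache)
}

# small, fast simulation world for unit tests: default-size nuclei (so the
# default volume filter behaves as in production) on a reduced field
tiny_config <- function(seed, n_nuclei = 5L, class_mix = c(normal = 1), ...) {
  sim_config(grid_dims = c(160L, 160L, 22L), n_nuclei = n_nuclei,
             radius_um = c(mean = 2.5, sd = 0.25), class_mix = class_mix,
             seed = seed, ...)
}

tiny_stack7 <- function() memo("tiny7", generate_stack(tiny_config(7)))

# object id containing each truth nucleus center (0 if background)
labels_at_truth_centers <- function(truth, labels) {
  arr <- if (inherits(labels, "LabelVolume")) labels$labels else labels
  arr[cbind(truth$center_z + 1L, truth$center_y + 1L, truth$center_x + 1L)]
}

random_pairs <- function(n, bit_depth = 12L) {
  maxv <- 2^bit_depth - 1
  data.frame(dapi = round(runif(n, 0, maxv)), mc5 = round(runif(n, 0, maxv)))
}

random_jd <- function(n_bins, n = 500L, bit_depth = 12L) {
  joint_histogram(random_pairs(n, bit_depth), n_bins = n_bins,
                  bit_depth = bit_depth)
}

# two spheres (radius r voxels) joined by a 1-voxel-wide bridge, as a binary
# volume embedded in a (z, y, x) grid
bridged_spheres <- function(r = 6L, gap = 4L, dims = c(24L, 24L, 48L)) {
  arr <- array(0, dims)
  c1 <- c(12, 12, 14); c2 <- c(12, 12, 14 + 2 * r + gap)
  for (ctr in list(c1, c2)) {
    zr <- (ctr[1] - r):(ctr[1] + r); yr <- (ctr[2] - r):(ctr[2] + r)
    xr <- (ctr[3] - r):(ctr[3] + r)
    u <- outer(outer((zr - ctr[1])^2, (yr - ctr[2])^2, `+`),
               (xr - ctr[3])^2, `+`)
    sub <- arr[zr, yr, xr]
    sub[u <= r^2] <- 1
    arr[zr, yr, xr] <- sub
  }
  arr[12, 12, (c1[3] + r):(c2[3] - r)] <- 1       # the bridge
  arr
}
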