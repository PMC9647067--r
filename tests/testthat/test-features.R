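test_that("global 5mC load is an exact sum", {
  p <- data.frame(dapi = c(10, 20, 30), mc5 = c(1, 2, 3))
  load <- global_mc5_load(p)
  expect_identical(load$mc5_total, 6)
  expect_identical(load$mc5_mean, 2)
  expect_identical(load$dapi_total, 60)

  z <- data.frame(dapi = c(5, 5), mc5 = c(0, 0))
  expect_identical(global_mc5_load(z)$mc5_total, 0)

  set.seed(201)
  big <- random_pairs(1e4)
  naive <- 0; for (v in big$mc5) naive <- naive + v
  expect_identical(global_mc5_load(big)$mc5_total, naive)
  expect_error(global_mc5_load(big[0, ]), "no voxel")
})

test_that("joint histogram uses fixed full-range edges with closed top bin", {
  p0 <- data.frame(dapi = rep(0, 4), mc5 = rep(0, 4))
  jd <- joint_histogram(p0, n_bins = 64L, bit_depth = 12L)
  expect_identical(jd$counts[1, 1], 4)
  expect_identical(sum(jd$counts), 4)
  expect_identical(jd$bin_edges[c(1, 65)], c(0, 4095))

  ptop <- data.frame(dapi = 4095, mc5 = 4095)
  jtop <- joint_histogram(ptop, 64L, 12L)
  expect_identical(jtop$counts[64, 64], 1)

  expect_error(joint_histogram(data.frame(dapi = 4096, mc5 = 0), 64L, 12L),
               "voxel pair 1")

  # brute-force per-pair binning oracle
  set.seed(202)
  p <- random_pairs(1000)
  jd <- joint_histogram(p, n_bins = 32L, bit_depth = 12L)
  oracle <- matrix(0, 32, 32)
  w <- 4095 / 32
  for (i in seq_len(nrow(p))) {
    bx <- min(floor(p$dapi[i] / w) + 1, 32)
    by <- min(floor(p$mc5[i] / w) + 1, 32)
    oracle[bx, by] <- oracle[bx, by] + 1
  }
  expect_identical(jd$counts, oracle)
  expect_equal(sum(normalize_distribution(jd)), 1, tolerance = 1e-12)
})

test_that("delta is the arctangent of the axis-normalized OLS slope", {
  set.seed(203)
  x <- round(runif(200, 100, 4000))
  ident <- data.frame(dapi = x, mc5 = x)
  ci <- codistribution_index(ident, 12L)
  expect_equal(ci$slope, 1)
  expect_equal(ci$delta_deg, 45)

  flat <- data.frame(dapi = x, mc5 = 0)
  ci0 <- codistribution_index(flat, 12L)
  expect_equal(ci0$slope, 0)
  expect_equal(ci0$delta_deg, 0)

  # closed-form normal-equations oracle on arbitrary pairs
  p <- random_pairs(50)
  ci <- codistribution_index(p, 12L)
  xs <- p$dapi / 4095; ys <- p$mc5 / 4095
  oracle <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  expect_lt(abs(ci$slope - oracle), 1e-10)
  expect_equal(ci$delta_deg, atan(ci$slope) * 180 / pi)

  expect_error(codistribution_index(p[1, , drop = FALSE]), "at least 2")
  expect_error(codistribution_index(data.frame(dapi = c(7, 7), mc5 = c(1, 2))),
               "variance")
})

test_that("delta is gain-invariant jointly but not per channel", {
  set.seed(204)
  p <- data.frame(dapi = runif(300, 200, 2000))
  p$mc5 <- 0.6 * p$dapi + rnorm(300, 0, 30)
  d0 <- codistribution_index(p, 12L)$delta_deg
  # identical scale factor on both channels: delta unchanged
  p2 <- data.frame(dapi = 1.8 * p$dapi, mc5 = 1.8 * p$mc5)
  expect_equal(codistribution_index(p2, 12L)$delta_deg, d0, tolerance = 1e-9)
  # identical offset on both channels: delta unchanged (intercept absorbs it)
  p3 <- data.frame(dapi = p$dapi + 300, mc5 = p$mc5 + 300)
  expect_equal(codistribution_index(p3, 12L)$delta_deg, d0, tolerance = 1e-9)
  # single-channel gain shifts delta: acquisition consistency is assumed
  p4 <- data.frame(dapi = p$dapi, mc5 = 1.8 * p$mc5)
  expect_gt(codistribution_index(p4, 12L)$delta_deg, d0 + 5)
})

test_that("binned regression agrees with voxelwise OLS at fine binning", {
  sim <- tiny_stack7()
  pairs <- extract_nucleus_voxels(sim$stack, sim$labels, 1L)
  vox <- codistribution_index(pairs, 12L)
  jd <- joint_histogram(pairs, n_bins = 256L, bit_depth = 12L)
  binned <- codistribution_index_binned(jd)
  expect_equal(binned$delta_deg, vox$delta_deg, tolerance = 0.02)
})

test_that("population reduction is the ratio of mean loads", {
  a <- data.frame(mc5_total = c(90, 110))
  expect_equal(population_reduction(a, a), 0)
  b <- data.frame(mc5_total = c(30, 40))
  expect_equal(population_reduction(a, b), 65)
  hyper <- data.frame(mc5_total = c(150, 150))
  expect_lt(population_reduction(a, hyper), 0)
  expect_error(population_reduction(data.frame(mc5_total = 0), b), "zero mean")
  expect_error(population_reduction(a[0, , drop = FALSE], b), "non-empty")
})

test_that("analyze_stack produces one traceable record per nucleus", {
  sim <- tiny_stack7()
  recs <- analyze_stack(sim$stack, sim$labels)
  expect_identical(recs$nucleus_id, sim$truth$nucleus_id)
  expect_identical(recs$voxel_count, sim$truth$voxel_count)
  expect_equal(recs$volume_um3, recs$voxel_count * 0.189 * 0.189 * 0.5)
  expect_identical(recs$delta_deg, atan(recs$slope) * 180 / pi)
  dists <- attr(recs, "distributions")
  expect_length(dists, nrow(recs))
  expect_identical(unname(vapply(dists, function(d) sum(d$counts), 0)),
                   as.numeric(recs$voxel_count))
  expect_false(any(attr(recs, "aberrant")))       # normal class: delta ~ 43 deg
})
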