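test_that("well-separated synthetic nuclei are recovered 1:1", {
  sim <- tiny_stack7()
  lab <- segment_nuclei(sim$stack)
  expect_s3_class(lab, "LabelVolume")
  expect_identical(lab$n_objects, nrow(sim$truth))
  hits <- labels_at_truth_centers(sim$truth, lab)
  expect_true(all(hits > 0))                      # recall: every center covered
  expect_identical(sort(unique(hits)), seq_len(lab$n_objects))  # precision 1:1
  # labels are consecutive and 26-connected
  arr <- lab$labels
  for (i in seq_len(lab$n_objects)) {
    comp <- qdmi:::.cc_label(arr == i, dim(arr), 26L)
    expect_identical(max(comp), 1L)
  }
  # voxel conservation
  expect_identical(sum(tabulate(arr[arr > 0])) + sum(arr == 0), length(arr))
})

test_that("degenerate volumes segment to empty with a warning", {
  z <- array(0, c(8, 8, 8))
  expect_warning(lab <- segment_nuclei(z, c(200, 200, 200)), "no foreground")
  expect_identical(lab$n_objects, 0L)
})

test_that("watershed splits nuclei fused by a thin bridge", {
  vol <- bridged_spheres()
  p_split <- seg_params(smoothing_sigma_nm = c(0, 0, 0),
                        threshold_method = "fixed", fixed_threshold = 0.5,
                        min_volume_um3 = 2, split_touching = TRUE,
                        exclude_xy_border = FALSE)
  lab <- segment_nuclei(vol, c(200, 200, 200), p_split)
  expect_identical(lab$n_objects, 2L)

  p_keep <- p_split
  p_keep$split_touching <- FALSE
  lab1 <- segment_nuclei(vol, c(200, 200, 200), p_keep)
  expect_identical(lab1$n_objects, 1L)

  # a single eccentric ellipsoid must NOT be split by its medial ridge
  ell <- array(0, c(24, 40, 40))
  zr <- 1:24; yr <- 1:40; xr <- 1:40
  u <- outer(outer(((zr - 12) / 8)^2, ((yr - 20) / 15)^2, `+`),
             ((xr - 20) / 11)^2, `+`)
  ell[u <= 1] <- 1
  lab2 <- segment_nuclei(ell, c(200, 200, 200), p_split)
  expect_identical(lab2$n_objects, 1L)
})

test_that("volume filter and XY-border exclusion drop the right objects", {
  vol <- array(0, c(10, 32, 32))
  vol[4:7, 10:20, 10:20] <- 1       # big block, interior
  vol[5:6, 1:4, 25:28] <- 1         # touches y border
  vol[5, 30, 5] <- 1                # speck below min volume
  p <- seg_params(smoothing_sigma_nm = c(0, 0, 0), threshold_method = "fixed",
                  fixed_threshold = 0.5, min_volume_um3 = 1,
                  split_touching = FALSE, exclude_xy_border = TRUE)
  lab <- segment_nuclei(vol, c(500, 500, 500), p)
  expect_identical(lab$n_objects, 1L)
  expect_true(all(lab$labels[, c(1, 32), ] == 0))

  p$exclude_xy_border <- FALSE
  expect_identical(segment_nuclei(vol, c(500, 500, 500), p)$n_objects, 2L)
})

test_that("interior cavities are filled before labeling", {
  vol <- array(0, c(12, 16, 16))
  vol[3:10, 3:14, 3:14] <- 1
  vol[5:8, 6:10, 6:10] <- 0         # cavity
  p <- seg_params(smoothing_sigma_nm = c(0, 0, 0), threshold_method = "fixed",
                  fixed_threshold = 0.5, min_volume_um3 = 1,
                  split_touching = FALSE, exclude_xy_border = FALSE)
  lab <- segment_nuclei(vol, c(500, 500, 500), p)
  expect_identical(lab$n_objects, 1L)
  expect_true(all(lab$labels[5:8, 6:10, 6:10] == 1L))
})

test_that("extract_nucleus_voxels pairs voxels and matches a masked-sum oracle", {
  sim <- tiny_stack7()
  lab <- sim$labels
  pairs <- extract_nucleus_voxels(sim$stack, lab, 2L)
  expect_identical(nrow(pairs), sum(lab$labels == 2L))
  # brute-force masked sums
  idx <- which(lab$labels == 2L)
  expect_identical(sum(pairs$dapi), sum(sim$stack$voxels$DAPI[idx]))
  expect_identical(sum(pairs$mc5), sum(sim$stack$voxels$`5mC`[idx]))

  expect_error(extract_nucleus_voxels(sim$stack, lab, 0L), "background")
  expect_error(extract_nucleus_voxels(sim$stack, lab, 99L), "not present")
})

test_that("per-object measurements are invariant to label permutation", {
  sim <- tiny_stack7()
  arr <- sim$labels$labels
  n <- sim$labels$n_objects
  perm <- rev(seq_len(n))
  relab <- arr
  relab[arr > 0] <- perm[arr[arr > 0]]
  r1 <- analyze_stack(sim$stack, sim$labels)
  r2 <- analyze_stack(sim$stack, label_volume(relab))
  # match objects by voxel count + totals, independent of id
  key <- function(r) r[order(r$mc5_total), c("voxel_count", "dapi_total",
                                             "mc5_total", "slope", "delta_deg")]
  expect_equal(key(r1), key(r2), ignore_attr = TRUE)
})
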