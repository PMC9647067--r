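test_that("composite pooling is count-weighted bin-wise summation", {
  set.seed(301)
  d1 <- random_jd(16); d2 <- random_jd(16); d3 <- random_jd(16)

  single <- composite_distribution(list(d1))
  expect_equal(normalize_distribution(single), normalize_distribution(d1))

  twin <- composite_distribution(list(d1, d1))
  expect_equal(normalize_distribution(twin), normalize_distribution(d1))

  comp <- composite_distribution(list(d1, d2, d3))
  oracle <- matrix(0, 16, 16)
  for (d in list(d1, d2, d3))
    for (i in 1:16) for (j in 1:16) oracle[i, j] <- oracle[i, j] + d$counts[i, j]
  expect_identical(comp$counts, oracle)

  dmis <- random_jd(32)
  expect_error(composite_distribution(list(d1, dmis)), "mismatched")
  expect_error(composite_distribution(list()), "no distributions")
})

test_that("KL divergence matches its closed forms and a naive oracle", {
  set.seed(302)
  P <- random_jd(8)
  expect_identical(kl_divergence(P, P), 0)

  # point mass vs uniform over 4 bins: -> log2(4) = 2 bits as epsilon -> 0
  mk <- function(counts2x2) {
    structure(list(counts = counts2x2, bin_edges = c(0, 2047.5, 4095),
                   n_bins = 2L, bit_depth = 12L, n_voxels = sum(counts2x2)),
              class = "JointDistribution")
  }
  point <- mk(matrix(c(4e6, 0, 0, 0), 2))
  unif <- mk(matrix(1e6, 2, 2))
  expect_equal(kl_divergence(point, unif, epsilon = 1e-8), 2, tolerance = 1e-4)

  Q <- random_jd(8)
  kl <- kl_divergence(P, Q, epsilon = 0.5)
  p <- (P$counts + 0.5) / sum(P$counts + 0.5)
  q <- (Q$counts + 0.5) / sum(Q$counts + 0.5)
  oracle <- 0
  for (i in 1:8) for (j in 1:8) oracle <- oracle + p[i, j] * log2(p[i, j] / q[i, j])
  expect_lt(abs(kl - oracle), 1e-12)

  expect_error(kl_divergence(P, random_jd(16)), "mismatched")
  expect_error(kl_divergence(P, Q, epsilon = 0), "epsilon")
})

test_that("KL is non-negative and zero only for identical smoothed histograms", {
  set.seed(303)
  for (r in 1:20) {
    nb <- sample(c(8L, 16L, 32L, 64L), 1)
    P <- random_jd(nb, n = sample(50:2000, 1))
    Q <- random_jd(nb, n = sample(50:2000, 1))
    kl <- kl_divergence(P, Q)
    expect_gte(kl, 0)
    if (!identical(P$counts, Q$counts)) expect_gt(kl, 0)
  }
})

test_that("classification is thresholded with lower-class boundaries", {
  set.seed(304)
  sim <- tiny_stack7()
  recs <- analyze_stack(sim$stack, sim$labels)
  cl <- classify_cells(recs)
  expect_identical(sum(cl$profile$class_counts), nrow(recs))
  expect_identical(
    cl$records$similarity_class,
    c("similar", "likely_similar", "unlikely_similar",
      "dissimilar")[findInterval(cl$records$kl_score, cl$profile$thresholds,
                                 left.open = TRUE) + 1L])

  # identical distributions: every cell scores alike and lands in "similar"
  # (scores are small but nonzero: the pseudocount is applied to raw counts,
  # and the composite has a larger total than any single cell)
  dists <- rep(attr(recs, "distributions")[1], nrow(recs))
  cli <- classify_cells(recs, dists)
  expect_true(all(cli$records$similarity_class == "similar"))
  expect_equal(cli$profile$homogeneity_fraction, 1)
  expect_identical(length(unique(cli$records$kl_score)), 1L)

  # permutation invariance: shuffling nuclei does not change scores
  ord <- sample(nrow(recs))
  shuf <- classify_cells(recs[ord, ], attr(recs, "distributions")[ord])
  expect_equal(setNames(shuf$records$kl_score, shuf$records$nucleus_id)[
                 as.character(recs$nucleus_id)],
               setNames(cl$records$kl_score, cl$records$nucleus_id)[
                 as.character(recs$nucleus_id)])

  # raising any threshold never demotes a cell to a less similar class
  t0 <- cl$profile$thresholds
  rank0 <- match(cl$records$similarity_class, qdmi:::SIMILARITY_CLASSES)
  for (k in 1:3) {
    tk <- t0; tk[k] <- tk[k] + 0.04
    rk <- match(classify_cells(recs, thresholds = tk)$records$similarity_class,
                qdmi:::SIMILARITY_CLASSES)
    expect_true(all(rk <= rank0))
  }

  expect_error(classify_cells(recs, thresholds = c(2, 1, 3)), "ascending")
  expect_warning(classify_cells(recs[1, ], attr(recs, "distributions")[1]),
                 "single nucleus")
})

test_that("quantile mode sets thresholds from the population scores", {
  sim <- tiny_stack7()
  recs <- analyze_stack(sim$stack, sim$labels)
  cl <- classify_cells(recs, quantile_mode = TRUE)
  expect_equal(cl$profile$thresholds,
               unname(quantile(cl$records$kl_score, c(0.25, 0.5, 0.75))))
})

test_that("similarity maps color projected nuclei by class", {
  sim <- tiny_stack7()
  n <- sim$labels$n_objects
  classes <- setNames(rep("similar", n), seq_len(n))
  img <- render_similarity_map(sim$labels, classes)
  proj <- apply(sim$labels$labels, c(2, 3), max)
  expect_identical(dim(img), c(dim(proj), 3L))
  expect_true(all(img[, , 2][proj > 0] == 1))     # green channel
  expect_true(all(img[, , 1][proj > 0] == 0))
  expect_true(all(img[cbind(which(proj == 0, arr.ind = TRUE), 2)] == 0))

  # four distinct classes -> four distinct non-background colors
  cl4 <- setNames(c(qdmi:::SIMILARITY_CLASSES,
                    rep("similar", n - 4))[seq_len(n)], seq_len(n))
  img4 <- render_similarity_map(sim$labels, cl4)
  cols <- unique(apply(matrix(img4, ncol = 3)[as.vector(proj) > 0, ], 1, paste,
                       collapse = ","))
  expect_identical(length(cols), 4L)

  # zero nuclei -> all black
  empty <- label_volume(array(0L, dim(sim$labels$labels)))
  img0 <- render_similarity_map(empty, character())
  expect_true(all(img0 == 0))

  expect_error(render_similarity_map(sim$labels, classes[-1]), "unclassified")
  bad <- classes; bad[1] <- "greenish"
  expect_error(render_similarity_map(sim$labels, bad), "unknown similarity")

  # PNG writing round-trips through the png package
  path <- withr::local_tempfile(fileext = ".png")
  render_similarity_map(sim$labels, classes, path = path)
  expect_equal(png::readPNG(path), img, tolerance = 1e-7)
})

test_that("aberrant spike-ins top the KL ranking (45 normal + 5 decoupled)", {
  norm <- make_population("normal", 45, tiny_config(9))
  aber <- make_population("aberrant_decoupled", 5, tiny_config(909))
  stacks <- c(lapply(norm$stacks, `[[`, "stack"),
              lapply(aber$stacks, `[[`, "stack"))
  labels <- c(lapply(norm$stacks, `[[`, "labels"),
              lapply(aber$stacks, `[[`, "labels"))
  recs <- analyze_stacks(stacks, labels_list = labels)
  cl <- classify_cells(recs)
  is_aber <- c(rep(FALSE, 45), rep(TRUE, 5))
  top5 <- order(cl$records$kl_score, decreasing = TRUE)[1:5]
  expect_setequal(cl$records$nucleus_id[top5], cl$records$nucleus_id[is_aber])
  expect_gt(mean(cl$records$kl_score[is_aber]),
            mean(cl$records$kl_score[!is_aber]))
})
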