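test_that("first-order RDMs equal hand-computed correlation distances", {
  act <- matrix(c(1, 2, 3, 5,
                  2, 4, 6, 9,
                  4, 1, 0, 2), nrow = 3, byrow = TRUE)
  rdm <- compute_rdm(act)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(rdm[i, j], 1 - cor(act[i, ], act[j, ]))
  dup <- compute_rdm(rbind(c(1, 2, 3), c(1, 2, 3), c(0, 1, 5)))
  expect_equal(dup[1, 2], 0)                         # identical rows
  anti <- compute_rdm(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(anti[1, 2], 2)                        # perfect anticorrelation
  expect_error(compute_rdm(rbind(c(1, 1, 1), c(0, 1, 2))), "zero variance")
  expect_error(compute_rdm(matrix(1:3, 1)), "2 stimuli")
})

test_that("every produced RDM is symmetric, hollow and bounded", {
  set.seed(21)
  for (rep in 1:10) {
    act <- matrix(rnorm(8 * 15), 8, 15)
    rdm <- compute_rdm(act)
    expect_identical(unclass(rdm), t(unclass(rdm)))
    expect_equal(diag(rdm), rep(0, 8))
    expect_true(all(rdm >= 0 - 1e-12 & rdm <= 2 + 1e-12))
  }
})

test_that("second-order RDMs compare layer RDMs by their upper triangles", {
  set.seed(4)
  base <- compute_rdm(matrix(rnorm(5 * 9), 5, 9))
  so <- second_order_rdm(list(a = base, b = base, c = base))
  expect_equal(max(abs(so)), 0)
  r1 <- compute_rdm(matrix(rnorm(4 * 6), 4, 6))
  r2 <- compute_rdm(matrix(rnorm(4 * 6), 4, 6))
  so2 <- second_order_rdm(list(r1, r2))
  expect_equal(so2[1, 2], 1 - cor(r1[upper.tri(r1)], r2[upper.tri(r2)]))
  expect_error(second_order_rdm(list(base, r1)), "same side")
  avg <- average_rdms(list(r1, r2))
  expect_equal(diag(avg), rep(0, 4))
  expect_identical(unclass(avg), t(unclass(avg)))
})

test_that("explained variance between RDMs is an affine-invariant R^2", {
  set.seed(6)
  a <- compute_rdm(matrix(rnorm(6 * 10), 6, 10))
  b <- compute_rdm(matrix(rnorm(6 * 10), 6, 10))
  expect_equal(rdm_r2(a, a), 1)
  aff <- 0.5 * unclass(a) + 0.1
  diag(aff) <- 0
  expect_equal(rdm_r2(a, aff), 1)
  expect_equal(rdm_r2(a, b), cor(a[upper.tri(a)], b[upper.tri(b)])^2)
  expect_equal(rdm_r2(a, b), rdm_r2(b, a))
  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_error(rdm_r2(flat, flat), "constant")
})

test_that("classical scaling reconstructs planar configurations exactly", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(3, 4))
  d <- as.matrix(dist(pts))
  emb <- mds_embed(d, dims = 2)
  expect_equal(as.matrix(dist(emb)), d, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(attr(emb, "stress"), 1e-8)
  zero <- mds_embed(matrix(0, 3, 3))
  expect_equal(unname(zero[, 1]), rep(0, 3))
  expect_equal(attr(zero, "stress"), 0)
  # residual stress does not increase with embedding dimension
  set.seed(8)
  conf <- matrix(rnorm(6 * 3), 6, 3)
  d3 <- as.matrix(dist(conf))
  stresses <- sapply(1:3, function(k) attr(mds_embed(d3, dims = k), "stress"))
  expect_true(all(diff(stresses) <= 1e-10))
})

test_that("the sensitivity contrast separates a constructed representation collapse", {
  # 4 classes of 4x4 images; the "small" extractor collapses the two
  # sensitive classes onto one axis, the "large" extractor keeps all four
  set.seed(9)
  n_per <- 12L
  sz <- 4L
  protos <- list(diag(4), matrix(1, 4, 4) - diag(4),
                 rbind(matrix(1, 2, 4), matrix(0, 2, 4)),
                 cbind(matrix(1, 4, 2), matrix(0, 4, 2)))
  x <- array(0, c(sz, sz, 1, 4 * n_per)); y <- integer(4 * n_per)
  for (cl in 1:4) for (i in 1:n_per) {
    idx <- (cl - 1) * n_per + i
    x[, , 1, idx] <- protos[[cl]] + matrix(rnorm(16, sd = 0.05), 4)
    y[idx] <- cl
  }
  ds <- image_dataset(x, y, classes = paste0("k", 1:4),
                      split = rep("test", 4 * n_per))
  flatten <- function(xb) t(apply(xb, 4, identity))
  collapse <- function(xb) {
    f <- flatten(xb)
    # project out the direction separating sensitive prototypes 1 and 2
    dir <- as.numeric(protos[[1]] - protos[[2]])
    dir <- dir / sqrt(sum(dir^2))
    f - (f %*% dir) %*% t(dir)
  }
  out <- sensitivity_contrast(collapse, flatten, ds,
                              sensitive = c("k1", "k2"),
                              insensitive = c("k3", "k4"),
                              reps = 30, n_images = 8, seed = 2)
  expect_equal(nrow(out), 30)
  expect_gt(mean(out$delta < 0), 0.5)   # collapse hurts the sensitive pair
  # a model contrasted with itself explains itself perfectly
  self <- sensitivity_contrast(flatten, flatten, ds, c("k1", "k2"),
                               c("k3", "k4"), reps = 3, n_images = 6, seed = 3)
  expect_equal(self$delta, rep(0, 3), tolerance = 1e-12)
  expect_equal(self$r2_sensitive, rep(1, 3), tolerance = 1e-12)
  # single repetition is reproducible under the same seed
  one_a <- sensitivity_contrast(collapse, flatten, ds, c("k1", "k2"),
                                c("k3", "k4"), reps = 1, n_images = 6, seed = 4)
  one_b <- sensitivity_contrast(collapse, flatten, ds, c("k1", "k2"),
                                c("k3", "k4"), reps = 1, n_images = 6, seed = 4)
  expect_identical(one_a, one_b)
  expect_warning(
    sensitivity_contrast(flatten, flatten, ds, "k1", "k2", reps = 1,
                         n_images = 50, seed = 1),
    "replacement")
})

test_that("layer probing exposes 12 layers per canonical model", {
  spec <- make_erf_variant("erf11", width_multiplier = 1 / 16, n_classes = 4L,
                           input_size = 32L, in_channels = 1L)
  model <- build_network(spec, seed = 3)
  set.seed(10)
  x <- array(runif(32 * 32 * 1 * 5), c(32, 32, 1, 5))
  rdms <- layer_rdms(model, x, batch_stats = TRUE)
  expect_length(rdms, 12)
  expect_named(rdms, c(sprintf("unit%02d", 1:10), "gap", "softmax"))
  expect_true(all(vapply(rdms, nrow, integer(1)) == 5))
})
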