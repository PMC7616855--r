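test_that("descendants are corner-anchored 75% crops with floor rounding", {
  p <- patch(0, 0, 224, 224)
  kids <- descendants(p)
  expect_length(kids, 4)
  expect_true(all(vapply(kids, `[[`, integer(1), "height") == 168L))
  anchors <- t(vapply(kids, function(k) c(k$row, k$col), integer(2)))
  expect_equal(anchors, rbind(c(0, 0), c(0, 56), c(56, 0), c(56, 56)))
  expect_true(all(vapply(kids, `[[`, integer(1), "level") == 1L))
  expect_equal(descendants(patch(0, 0, 126, 126))[[1]]$height, 94L)  # floor(94.5)
  tiny <- descendants(patch(5, 5, 1, 1))
  expect_true(all(vapply(tiny, function(k)
    k$height == 1L && k$row == 5L && k$col == 5L, logical(1))))
})

test_that("patch side at level L follows the iterated floor recurrence", {
  sides <- c(224)
  for (l in 1:3) sides <- c(sides, floor(0.75 * sides[l]))
  expect_equal(sides, c(224, 168, 126, 94))
})

test_that("the search reproduces closed-form results for side-threshold oracles", {
  img <- matrix(0, 224, 224)
  for (thr in c(60, 100, 130, 200)) {
    tree <- mirc_search(side_oracle(thr), img, true_class = 1L, max_level = 6)
    exp <- expected_mirc_closed_form(224, thr, max_level = 6)
    levels <- vapply(tree$mircs, function(m) m$patch$level, integer(1))
    expect_true(all(levels == exp$level), info = paste("thr", thr))
    expect_length(tree$mircs, exp$count)
    expect_silent(erfscope:::validate_mirc_tree(tree))
  }
  # the printed example: threshold 100 on a 224 image -> 16 MIRCs at level 2
  tree100 <- mirc_search(side_oracle(100), img, 1L)
  expect_length(tree100$mircs, 16)
  expect_true(all(vapply(tree100$mircs, function(m) m$patch$level,
                         integer(1)) == 2L))
})

test_that("misclassified roots give empty trees and caps flag their leaves", {
  img <- matrix(0, 64, 64)
  empty <- mirc_search(side_oracle(100), img, 1L)   # 64 < 100
  expect_null(empty$root)
  expect_length(empty$mircs, 0)
  expect_identical(empty$reason, "misclassified_root")
  always <- mirc_search(function(image, p, tc) list(correct = TRUE,
                                                    probability = 1),
                        img, 1L, max_level = 3)
  expect_true(all(vapply(always$mircs, function(m) m$patch$level,
                         integer(1)) == 3L))
  expect_true(all(vapply(always$mircs, `[[`, logical(1), "capped")))
})

test_that("level histograms conserve mass over non-empty trees", {
  img <- matrix(0, 224, 224)
  trees <- list(mirc_search(side_oracle(100), img, 1L),
                mirc_search(side_oracle(150), img, 1L),
                mirc_search(side_oracle(500), img, 1L))   # empty
  h <- mirc_level_hist(trees)
  expect_equal(sum(h), 2)                  # two non-empty trees
  expect_equal(unname(h["2"]), 1L)         # threshold 100 -> deepest level 2
  expect_equal(unname(h["1"]), 1L)         # threshold 150 -> deepest level 1
  expect_identical(mirc_level_hist(list()), integer(0))
})

test_that("relaxing the oracle threshold never lowers the deepest MIRC level", {
  img <- matrix(0, 224, 224)
  deepest <- sapply(c(180, 140, 100, 70), function(thr) {
    tr <- mirc_search(side_oracle(thr), img, 1L, max_level = 6)
    max(vapply(tr$mircs, function(m) m$patch$level, integer(1)))
  })
  expect_true(all(diff(deepest) >= 0))
})

test_that("model-backed patch classification upsamples and scores correctly", {
  spec <- tiny_spec(input_size = 16L, n_classes = 2L)
  model <- build_network(spec, seed = 8)
  set.seed(12)
  img <- matrix(runif(40 * 40), 40, 40)
  full <- patch(0, 0, 40, 40)
  res <- classify_patch(model, img, full, true_class = 1L)
  probs <- predict(model, erfscope:::resize_bilinear(img, 16) |>
                     array(c(16, 16, 1, 1)))
  expect_equal(res$probability, probs[1, 1])
  expect_identical(res$correct, which.max(probs[, 1]) == 1L)
  expect_error(classify_patch(model, img, patch(30, 30, 20, 20), 1L),
               "outside")
  # a constant image yields the same prediction for every patch of it
  flat <- matrix(0.5, 40, 40)
  r1 <- classify_patch(model, flat, patch(0, 0, 30, 30), 1L)
  r2 <- classify_patch(model, flat, patch(10, 10, 18, 18), 1L)
  expect_equal(r1$probability, r2$probability, tolerance = 1e-8)
  # the tree search plugs in models directly
  tr <- mirc_search(model, img, true_class = res$pred, max_level = 2)
  expect_silent(erfscope:::validate_mirc_tree(tr))
})

test_that("MIRC clustering returns distinct-source exemplars", {
  spec <- tiny_spec(input_size = 16L, n_classes = 2L)
  model <- build_network(spec, seed = 9)
  # two image families with very different intensity -> separable latents
  images <- c(lapply(1:4, function(i) matrix(0.05 + 0.01 * i, 24, 24)),
              lapply(1:4, function(i) matrix(0.95 - 0.01 * i, 24, 24)))
  mk_tree <- function() {
    list(mircs = list(list(patch = patch(0, 0, 12, 12, level = 2),
                           probability = 0.9, capped = FALSE),
                      list(patch = patch(6, 6, 12, 12, level = 2),
                           probability = 0.8, capped = FALSE)),
         max_level = 10L, reason = "ok")
  }
  trees <- replicate(8, mk_tree(), simplify = FALSE)
  cl <- cluster_mircs(model, trees, images, k = 2, n_exemplars = 3, seed = 1)
  expect_equal(cl$k, 2)
  expect_equal(nrow(cl$assignment), 16)
  for (ex in cl$exemplars) {
    expect_lte(nrow(ex), 3)
    expect_false(any(duplicated(ex$image)))
  }
  # clusters recover the two intensity families
  fam <- cl$assignment$cluster[cl$assignment$image <= 4]
  expect_equal(length(unique(fam)), 1)
  expect_false(unique(fam) %in% cl$assignment$cluster[cl$assignment$image > 4])
  # identical latents collapse k with a warning and zero inertia
  same <- lapply(1:4, function(i) matrix(0.5, 24, 24))
  expect_warning(c1 <- cluster_mircs(model, trees[1:4], same, k = 3,
                                     n_exemplars = 2, seed = 1),
                 "reducing k")
  expect_equal(c1$inertia, 0, tolerance = 1e-20)
})

test_that("trees serialize to JSON with bounding boxes and flags", {
  img <- matrix(0, 64, 64)
  tree <- mirc_search(side_oracle(40), img, 1L)
  js <- jsonlite::fromJSON(mirc_tree_to_json(tree), simplifyVector = FALSE)
  expect_equal(js$reason, "ok")
  expect_equal(unlist(js$root$bbox), c(0, 0, 64, 64))
  expect_true(js$root$correct)
  expect_length(js$root$children, 4)
})
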