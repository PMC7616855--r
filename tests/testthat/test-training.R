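test_that("learning rate follows the constant-then-exponential schedule", {
  cfg <- train_config(epochs = 20, decay_rate = 0.9)
  expect_equal(lr_at(cfg, 1), 0.01)
  expect_equal(lr_at(cfg, 10), 0.01)
  expect_equal(lr_at(cfg, 11), 0.01 * 0.9)
  expect_equal(lr_at(cfg, 15), 0.01 * 0.9^5)
  expect_true(all(sapply(1:50, function(e) lr_at(cfg, e)) > 0))
})

test_that("evaluation preprocessing is deterministic central cropping", {
  set.seed(1)
  img <- matrix(runif(256 * 256), 256, 256)
  out <- preprocess_eval(img)
  expect_equal(dim(out), c(224, 224))
  expect_equal(out, img[16 + 1:224, 16 + 1:224])   # offset (16, 16)
  expect_identical(preprocess_eval(img), preprocess_eval(img))
  # non-square input: central square with the shortest dimension first
  wide <- matrix(runif(256 * 512), 256, 512)
  expect_equal(preprocess_eval(wide),
               preprocess_eval(wide[, 128 + 1:256]))
})

test_that("training preprocessing crops and flips reproducibly from the RNG stream", {
  set.seed(2)
  img <- matrix(runif(300 * 400), 300, 400)
  set.seed(3)
  a <- preprocess_train(img)
  set.seed(3)
  b <- preprocess_train(img)
  expect_identical(a, b)
  expect_equal(dim(a), c(224, 224))
  # corner-pinned deterministic regression mode
  pinned <- preprocess_train(img, flip = FALSE, random_crop = FALSE)
  full <- erfscope:::resize_bilinear(img[, 50 + 1:300], 256)
  expect_equal(pinned, full[1:224, 1:224])
  # channelled images keep their channels
  rgb <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(dim(preprocess_train(rgb, resize_to = 32, crop_to = 28)),
               c(28, 28, 3))
})

test_that("per-class metrics match hand-computed confusion counts", {
  met <- class_metrics(pred = c(1, 1, 1, 2, 2), truth = c(1, 1, 2, 1, 2),
                       classes = c("a", "b"))
  # class a: TP=2 FP=1 FN=1 -> precision = recall = f1 = 2/3
  expect_equal(met$precision[1], 2 / 3)
  expect_equal(met$recall[1], 2 / 3)
  expect_equal(met$f1[1], 2 / 3)
  expect_equal(attr(met, "accuracy"), 3 / 5)
  perfect <- class_metrics(1:3, 1:3, letters[1:3])
  expect_equal(perfect$f1, rep(1, 3))
  # constant predictor on a balanced two-class set
  onesided <- class_metrics(rep(1, 8), rep(1:2, each = 4), c("a", "b"))
  expect_equal(onesided$f1, c(2 / 3, 0))
  # class absent from the truth is flagged, not silently scored
  missing <- class_metrics(c(1, 1), c(1, 1), c("a", "b"))
  expect_true(is.na(missing$f1[2]))
  expect_false(missing$present[2])
})

test_that("scrambling ratios respect the eligibility threshold", {
  mk <- function(f1) {
    out <- data.frame(class = paste0("c", seq_along(f1)), f1 = f1)
    out$present <- TRUE
    out
  }
  rep0 <- scrambling_ratio(mk(c(0.9, 0.8, 0.9)), mk(c(0.9, 0.8, 0.9)))
  expect_equal(rep0$ratio, rep(1, 3))
  rep1 <- scrambling_ratio(mk(c(0.8, 0.7)), mk(c(0.4, 0.1)))
  expect_equal(rep1$ratio[1], 0.5)
  expect_true(is.na(rep1$ratio[2]))       # f1 0.7 below the 0.75 threshold
  expect_false(rep1$eligible[2])
  expect_identical(attr(rep1, "ranking"), "c1")
  expect_warning(scrambling_ratio(mk(c(0.2, 0.3)), mk(c(0.2, 0.3))), "empty")
})

test_that("ranking overlaps count shared classes per tail", {
  r1 <- paste0("c", 1:30)                 # ascending ratio: most sensitive first
  r2 <- c(paste0("c", 1:7), paste0("x", 1:23))
  ov <- class_set_overlap(list(a = r1, b = r2), k = 20)
  expect_identical(ov$most["a", "a"], 20L)
  expect_identical(ov$most["a", "b"], 7L)
  expect_identical(ov$most, t(ov$most))
  ov0 <- class_set_overlap(list(a = paste0("p", 1:20), b = paste0("q", 1:20)),
                           k = 20)
  expect_identical(ov0$most["a", "b"], 0L)
  expect_warning(class_set_overlap(list(a = r1[1:5], b = r1[1:5]), k = 20),
                 "full set")
})

test_that("zero-epoch training returns the model unchanged", {
  ds <- tiny_two_class_ds()
  model <- build_network(tiny_spec(16L, 2L), seed = 1)
  before <- snapshot_params(model)
  model <- train(model, ds, train_config(epochs = 0))
  expect_identical(snapshot_params(model), before)
  expect_equal(nrow(model$history), 0)
})

test_that("training is reproducible and overfits a small separable set", {
  ds <- tiny_two_class_ds(n_per = 16)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 11)
  h1 <- train(build_network(tiny_spec(16L, 2L), seed = 5), ds, cfg)$history
  h2 <- train(build_network(tiny_spec(16L, 2L), seed = 5), ds, cfg)$history
  expect_identical(h1, h2)
  model <- build_network(tiny_spec(16L, 2L), seed = 5)
  model <- train(model, ds, train_config(epochs = 30, batch_size = 8, seed = 1))
  expect_equal(max(model$history$accuracy), 1)   # reaches 100% within budget
  expect_error(train(model, image_dataset(ds$x, ds$y,
                                          split = rep("test", length(ds$y))),
                     train_config(epochs = 1)),
               "empty")
})

test_that("a non-finite loss aborts training with a diagnostic", {
  ds <- tiny_two_class_ds(n_per = 8)
  ds$x[1, 1, 1, 1] <- NaN   # poisoned pixel propagates to the loss
  model <- build_network(tiny_spec(16L, 2L), seed = 2)
  expect_error(
    train(model, ds, train_config(epochs = 1, batch_size = 16,
                                  shuffle = FALSE, seed = 1)),
    "non-finite")
})
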