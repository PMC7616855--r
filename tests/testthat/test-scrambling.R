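test_that("global permutations are seeded bijections", {
  p <- make_global_permutation(28, 28, seed = 5)
  expect_identical(sort(p$mapping), seq_len(784L))
  expect_identical(p$mapping, make_global_permutation(28, 28, seed = 5)$mapping)
  expect_false(identical(p$mapping, make_global_permutation(28, 28, seed = 6)$mapping))
  expect_identical(make_global_permutation(1, 1, seed = 3)$mapping, 1L)
})

test_that("local permutations never cross their window tiles", {
  p <- make_local_permutation(4, 4, window = 2, seed = 1)
  expect_identical(sort(p$mapping), seq_len(16L))
  tile_of <- function(idx, h, w, win) {
    r <- (idx - 1L) %% h; c <- (idx - 1L) %/% h
    c(r %/% win, c %/% win)
  }
  for (i in seq_len(16))
    expect_identical(tile_of(p$mapping[i], 4, 4, 2), tile_of(i, 4, 4, 2))
  # remainder tiles at the edges of an odd grid stay closed too
  p5 <- make_local_permutation(5, 5, window = 2, seed = 2)
  expect_identical(sort(p5$mapping), seq_len(25L))
  disp <- function(p) {
    h <- p$grid_height
    r0 <- (seq_along(p$mapping) - 1L) %% h; c0 <- (seq_along(p$mapping) - 1L) %/% h
    r1 <- (p$mapping - 1L) %% h; c1 <- (p$mapping - 1L) %/% h
    pmax(abs(r1 - r0), abs(c1 - c0))
  }
  expect_true(all(disp(p5) <= 1))  # window 2 moves nothing farther than 1 cell
  expect_identical(make_local_permutation(6, 6, window = 1, seed = 1)$mapping,
                   seq_len(36L))
  expect_warning(pbig <- make_local_permutation(3, 3, window = 5, seed = 1),
                 "global")
  expect_identical(sort(pbig$mapping), seq_len(9L))
})

test_that("applying a permutation moves whole feature columns", {
  f <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  swap <- erfscope:::new_perm_map(c(4L, 3L, 2L, 1L), 2, 2, "global")
  g <- apply_permutation(f, swap)
  for (c in 1:3) {
    expect_equal(g[2, 2, c], f[1, 1, c])  # position 1 -> position 4
    expect_equal(g[1, 2, c], f[2, 1, c])  # position 2 -> position 3
  }
  idp <- erfscope:::identity_permutation(2, 2)
  expect_identical(apply_permutation(f, idp), f)
  p <- make_global_permutation(2, 2, seed = 9)
  expect_equal(apply_permutation(apply_permutation(f, p),
                                 erfscope:::invert_permutation(p)), f)
  expect_error(apply_permutation(array(0, c(3, 3, 1)), swap), "match")
})

test_that("permutation maps survive a JSON round trip", {
  p <- make_local_permutation(6, 4, window = 2, seed = 7)
  q <- perm_from_json(perm_to_json(p))
  expect_identical(q$mapping, p$mapping)
  expect_identical(q$scope, "local")
  expect_identical(q$window, p$window)
})

test_that("pooling-based heads are provably permutation invariant", {
  spec <- tiny_spec(input_size = 16L, n_classes = 3L)
  base <- build_network(spec, seed = 4)
  set.seed(5)
  x <- array(runif(16 * 16 * 1 * 100), c(16, 16, 1, 100))
  fw <- erfscope:::model_forward(base, x)
  g <- dim(fw$features)[1]
  perm <- make_global_permutation(g, g, seed = 1)
  # (a) base-only classifier: GAP ignores any spatial rearrangement
  hd0 <- erfscope:::head_forward(base$head, fw$features)
  hd1 <- erfscope:::head_forward(base$head, apply_permutation(fw$features, perm))
  expect_lt(max(abs(hd0$logits - hd1$logits)), 1e-4)
  # (b) pointwise follow-up: 1x1 convolutions cannot mix positions
  cm <- compose(base, followup_spec("pointwise"), seed = 2)
  p0 <- erfscope:::fu_forward(cm, fw$features)$logits
  p1 <- erfscope:::fu_forward(cm, apply_permutation(fw$features, perm))$logits
  expect_lt(max(abs(p0 - p1)), 1e-4)
  pl <- make_local_permutation(g, g, window = 2, seed = 3)
  p2 <- erfscope:::fu_forward(cm, apply_permutation(fw$features, pl))$logits
  expect_lt(max(abs(p0 - p2)), 1e-4)
})

test_that("composition freezes the base and keeps a train-time map constant", {
  ds <- tiny_two_class_ds()
  spec <- tiny_spec(input_size = 16L, n_classes = 2L)
  base <- build_network(spec, seed = 1)
  before <- snapshot_params(base)
  cm <- compose(base, followup_spec("aggregating"), train_time_scramble = TRUE,
                seed = 3)
  map_before <- perm_to_json(cm$perm)
  cm <- train(cm, ds, train_config(epochs = 2, batch_size = 8, seed = 1))
  expect_identical(snapshot_params(base), before)       # bit-identical base
  expect_identical(perm_to_json(cm$perm), map_before)   # fixed permutation
  expect_equal(nrow(cm$history), 2)
})

test_that("test-time scrambling is a no-op for pointwise and window-1 models", {
  spec <- tiny_spec(input_size = 16L, n_classes = 2L)
  base <- build_network(spec, seed = 6)
  set.seed(7)
  x <- array(runif(16 * 16 * 1 * 8), c(16, 16, 1, 8))
  pw <- compose(base, followup_spec("pointwise"), seed = 1)
  out <- test_time_scramble(pw, x, scope = "global", seed = 2)
  expect_equal(out$scrambled, out$clean, tolerance = 1e-10)
  agg <- compose(base, followup_spec("aggregating"), seed = 1)
  out1 <- test_time_scramble(agg, x, scope = "local", window = 1, seed = 2)
  expect_equal(out1$scrambled, out1$clean, tolerance = 1e-12)
  # per-image permutations are drawn from a seeded stream: reproducible
  out2 <- test_time_scramble(agg, x, scope = "global", seed = 9)
  out3 <- test_time_scramble(agg, x, scope = "global", seed = 9)
  expect_identical(out2$scrambled, out3$scrambled)
})

test_that("composed receptive field covers the full input for the smallest base", {
  spec <- make_erf_variant("erf11")  # input 224
  base_erf <- network_erf(spec)
  composed <- attr(compute_erf(spec, followup = followup_spec("aggregating")),
                   "network_erf")
  expect_identical(composed, 235)
  expect_gte(composed, spec$input_size)
  expect_lt(base_erf, spec$input_size)
})
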