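# Shared fixtures: tiny architectures, tiny datasets, closed-form oracles.

# small two-block architecture for fast structural tests
tiny_spec <- function(input_size = 16L, n_classes = 3L, in_channels = 1L) {
  arch_spec(list(list(n_units = 1L, width = 6L, stride = 2L, middle_kernels = 3L),
                 list(n_units = 1L, width = 8L, stride = 2L, middle_kernels = 3L)),
            n_classes = n_classes, input_size = input_size,
            in_channels = in_channels, stem_width = 4L)
}

# random small architecture whose ERF stays well inside `input_size`
random_tiny_spec <- function(input_size = 48L) {
  nb <- sample(1:2, 1)
  blocks <- lapply(seq_len(nb), function(b) {
    nu <- sample(1:2, 1)
    list(n_units = nu, width = sample(4:6, 1), stride = sample(1:2, 1),
         middle_kernels = sample(c(1, 3, 5), nu, replace = TRUE))
  })
  arch_spec(blocks, n_classes = 2L, input_size = input_size,
            in_channels = 1L, stem_width = 3L)
}

# trivially separable two-class image set (bright vs dark half-field)
tiny_two_class_ds <- function(n_per = 16L, size = 16L, seed = 1L) {
  n <- 2L * n_per
  x <- array(0, c(size, size, 1L, n))
  y <- integer(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    cl <- ifelse(i <= n_per, 1L, 2L)
    img <- matrix(stats::rnorm(size^2, sd = 0.1), size, size)
    if (cl == 1L) img[, seq_len(size / 2)] <- img[, seq_len(size / 2)] + 0.8
    else img[seq_len(size / 2), ] <- img[seq_len(size / 2), ] + 0.8
    x[, , 1L, i] <- pmin(1, pmax(0, img))
    y[i] <- cl
  }
  image_dataset(x, y, split = rep("train", n))
}

# closed-form expectation for a min-side >= threshold oracle classifier:
# returns list(level, count) of the MIRCs, or NULL when the root fails
expected_mirc_closed_form <- function(side, threshold, max_level = 10L) {
  if (side < threshold) return(NULL)
  s <- side
  lvl <- 0L
  while (lvl < max_level) {
    s_next <- max(1L, floor(0.75 * s))
    if (s_next < threshold) return(list(level = lvl, count = 4^lvl))
    if (s_next == s) return(list(level = lvl, count = 4^lvl))  # no progress
    s <- s_next
    lvl <- lvl + 1L
  }
  list(level = max_level, count = 4^max_level)  # capped
}

# oracle patch classifier: correct iff min(side) >= threshold
side_oracle <- function(threshold) {
  function(image, p, true_class)
    list(correct = min(p$height, p$width) >= threshold, probability = 0.5)
}

# deep-copy snapshot of all base parameters for freeze checks
snapshot_params <- function(model) {
  lapply(erfscope:::stack_cbns(model$stem, model$units),
         function(L) list(W = L$W + 0, gamma = L$gamma + 0, beta = L$beta + 0,
                          rmean = L$rmean + 0, rvar = L$rvar + 0))
}
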