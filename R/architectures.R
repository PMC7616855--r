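#' Middle filter sizes of the five canonical ERF variants
#'
#' Each entry lists, per block, the middle (k x k) filter size of every
#' bottleneck residual unit. The four blocks contain 2, 3, 3 and 2 units with
#' widths 128, 256, 512, 1024 and strides 2, 2, 2, 1; together with a 3x3
#' stride-1 stem these settings give networks whose last convolutional layer
#' has a theoretical effective receptive field of 11, 23, 47, 95 or 227 pixels.
#'
#' @format A named list of five kernel configurations; each configuration is a
#'   list of four integer vectors of lengths 2, 3, 3, 2.
#' @export
erf_variant_kernels <- list(
  erf11  = list(c(3, 3), c(1, 1, 1), c(1, 1, 1), c(1, 1)),
  erf23  = list(c(3, 5), c(3, 1, 1), c(1, 1, 1), c(1, 1)),
  erf47  = list(c(3, 5), c(3, 3, 5), c(1, 1, 1), c(1, 1)),
  erf95  = list(c(3, 5), c(3, 3, 5), c(3, 3, 3), c(1, 1)),
  erf227 = list(c(5, 5), c(5, 5, 5), c(5, 5, 5), c(5, 5))
)

CANON_UNITS <- c(2L, 3L, 3L, 2L)
CANON_WIDTHS <- c(128L, 256L, 512L, 1024L)
CANON_STRIDES <- c(2L, 2L, 2L, 1L)

#' Construct an architecture specification
#'
#' Low-level constructor describing a stem convolution followed by blocks of
#' bottleneck residual units (1x1 -> kxk -> 1x1, block stride applied on the
#' first 1x1 convolution of the block's first unit, identity or projection
#' shortcut). [make_erf_variant()] builds the canonical four-block family;
#' this constructor accepts arbitrary block layouts for small ad-hoc networks.
#'
#' @param blocks list of blocks, each a list with `n_units`, `width`, `stride`
#'   and `middle_kernels` (one odd kernel size per unit).
#' @param n_classes number of output classes.
#' @param input_size input image side in pixels (images are square).
#' @param in_channels number of input image channels.
#' @param stem_kernel,stem_width,stem_stride stem convolution geometry.
#' @param width_multiplier recorded multiplier (widths are stored already
#'   scaled; the field is metadata for reporting).
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(blocks, n_classes, input_size = 224L, in_channels = 3L,
                      stem_kernel = 3L, stem_width = 64L, stem_stride = 1L,
                      width_multiplier = 1) {
  for (b in blocks) {
    stopifnot(is.list(b), !is.null(b$n_units), !is.null(b$width),
              !is.null(b$stride), !is.null(b$middle_kernels))
    if (length(b$middle_kernels) != b$n_units)
      stop("middle_kernels length must equal n_units in every block")
    if (any(b$middle_kernels %% 2 == 0) || any(b$middle_kernels < 1))
      stop("middle kernels must be odd and >= 1")
  }
  structure(list(
    stem = list(kernel = as.integer(stem_kernel), stride = as.integer(stem_stride),
                width = as.integer(stem_width)),
    blocks = lapply(blocks, function(b)
      list(n_units = as.integer(b$n_units), width = as.integer(b$width),
           stride = as.integer(b$stride),
           middle_kernels = as.integer(b$middle_kernels))),
    n_classes = as.integer(n_classes),
    input_size = as.integer(input_size),
    in_channels = as.integer(in_channels),
    width_multiplier = width_multiplier
  ), class = "arch_spec")
}

#' Build a canonical ERF-variant architecture specification
#'
#' Instantiates the four-block bottleneck-residual family: blocks of
#' (2, 3, 3, 2) units with widths (128, 256, 512, 1024) scaled by
#' `width_multiplier`, block strides (2, 2, 2, 1) applied on the first 1x1
#' convolution of each block's first unit, and a 3x3 stride-1 stem. The
#' theoretical ERF of the resulting network is set purely by
#' `variant_kernels`, the per-block middle filter sizes.
#'
#' @param variant_kernels either a name from [erf_variant_kernels]
#'   (`"erf11"` ... `"erf227"`) or a list of four kernel vectors of lengths
#'   (2, 3, 3, 2) with entries in {1, 3, 5}.
#' @param width_multiplier positive scaling of all block widths (and the stem),
#'   rounded to the nearest channel; multiplier 1 keeps the canonical widths.
#'   Used for parameter-matched wide/small-ERF control networks.
#' @param n_classes,input_size,in_channels see [arch_spec()].
#' @return An `arch_spec`.
#' @examples
#' spec <- make_erf_variant("erf11", n_classes = 10, input_size = 64,
#'                          in_channels = 1, width_multiplier = 1 / 16)
#' network_erf(spec)  # 11
#' @export
make_erf_variant <- function(variant_kernels, width_multiplier = 1,
                             n_classes = 1000L, input_size = 224L,
                             in_channels = 3L) {
  if (is.character(variant_kernels)) {
    variant_kernels <- match.arg(variant_kernels, names(erf_variant_kernels))
    variant_kernels <- erf_variant_kernels[[variant_kernels]]
  }
  if (!is.list(variant_kernels) || length(variant_kernels) != 4L)
    stop("variant_kernels must be a list of 4 kernel vectors (one per block)")
  lens <- vapply(variant_kernels, length, integer(1))
  if (!identical(lens, CANON_UNITS))
    stop("kernel vectors must have lengths (2, 3, 3, 2)")
  ks <- unlist(variant_kernels)
  if (any(!ks %in% c(1, 3, 5)))
    warning("kernel size outside {1, 3, 5}: non-canonical variant")
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  widths <- pmax(1L, as.integer(round(CANON_WIDTHS * width_multiplier)))
  stem_w <- max(1L, as.integer(round(64 * width_multiplier)))
  blocks <- lapply(seq_len(4L), function(i)
    list(n_units = CANON_UNITS[i], width = widths[i], stride = CANON_STRIDES[i],
         middle_kernels = variant_kernels[[i]]))
  arch_spec(blocks, n_classes = n_classes, input_size = input_size,
            in_channels = in_channels, stem_width = stem_w,
            width_multiplier = width_multiplier)
}

# flat per-convolution layer table of a spec (main path only), in forward order
spec_layer_seq <- function(spec) {
  rows <- list(list(layer = "stem", kernel = spec$stem$kernel,
                    stride = spec$stem$stride))
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    for (ui in seq_len(b$n_units)) {
      s <- if (ui == 1L) b$stride else 1L
      id <- sprintf("b%du%d", bi, ui)
      rows <- c(rows,
                list(list(layer = paste0(id, "c1"), kernel = 1L, stride = s),
                     list(layer = paste0(id, "c2"), kernel = b$middle_kernels[ui],
                          stride = 1L),
                     list(layer = paste0(id, "c3"), kernel = 1L, stride = 1L)))
    }
  }
  rows
}

followup_layer_seq <- function(fu) {
  rows <- list()
  for (ui in seq_along(fu$strides)) {
    id <- sprintf("fu%d", ui)
    rows <- c(rows,
              list(list(layer = paste0(id, "c1"), kernel = 1L,
                        stride = fu$strides[ui]),
                   list(layer = paste0(id, "c2"), kernel = fu$middle_kernel,
                        stride = 1L),
                   list(layer = paste0(id, "c3"), kernel = 1L, stride = 1L)))
  }
  rows
}

#' Analytic effective receptive field of every layer
#'
#' Standard receptive-field arithmetic applied in forward layer order (stem,
#' then the three convolutions of every residual unit): each layer grows the
#' receptive field by `(k - 1) * jump` where `jump` is the input-pixel spacing
#' of adjacent units, and multiplies `jump` by its stride. The ERF of the
#' network is the value at the last convolutional layer.
#'
#' @param spec an `arch_spec`.
#' @param followup optionally a [followup_spec()] appended after the last base
#'   layer, for the composed base + follow-up receptive field.
#' @return A data frame (class `erf_table`) with one row per convolution:
#'   `layer`, `kernel`, `stride`, `erf`, `jump` (product of strides up to and
#'   including the layer) and `grid` (feature-map side). The network ERF is
#'   available through [network_erf()].
#' @examples
#' tab <- compute_erf(make_erf_variant("erf227"))
#' network_erf(tab)  # 227
#' @export
compute_erf <- function(spec, followup = NULL) UseMethod("compute_erf")

#' @export
compute_erf.arch_spec <- function(spec, followup = NULL) {
  seq <- spec_layer_seq(spec)
  if (!is.null(followup)) seq <- c(seq, followup_layer_seq(followup))
  n <- length(seq)
  erf <- jump <- grid <- numeric(n)
  e <- 1; j <- 1; g <- spec$input_size
  for (i in seq_len(n)) {
    l <- seq[[i]]
    e <- e + (l$kernel - 1) * j
    j <- j * l$stride
    g <- ceiling(g / l$stride)
    erf[i] <- e; jump[i] <- j; grid[i] <- g
  }
  out <- data.frame(
    layer = vapply(seq, `[[`, character(1), "layer"),
    kernel = vapply(seq, `[[`, numeric(1), "kernel"),
    stride = vapply(seq, `[[`, numeric(1), "stride"),
    erf = erf, jump = jump, grid = grid,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("erf_table", "data.frame"), network_erf = e)
}

#' Network-level effective receptive field
#'
#' @param x an `arch_spec` or an `erf_table` from [compute_erf()].
#' @return The ERF (pixels) of the last convolutional layer.
#' @export
network_erf <- function(x) {
  if (inherits(x, "erf_table")) return(attr(x, "network_erf"))
  attr(compute_erf(x), "network_erf")
}

#' Count trainable parameters of an architecture
#'
#' Closed-form count over all convolutions (no biases), batch-normalization
#' affine terms (two per channel) and the fully connected classifier layer
#' (weights plus biases). Projection shortcuts (strided or width-changing
#' units) are included. For a built network the parameters are enumerated
#' from its weight arrays; both routes must agree.
#'
#' @param x an `arch_spec` or an `erf_model`.
#' @return Integer-valued parameter count.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.arch_spec <- function(x) {
  total <- x$stem$kernel^2 * x$in_channels * x$stem$width + 2 * x$stem$width
  cin <- x$stem$width
  for (b in x$blocks) {
    for (ui in seq_len(b$n_units)) {
      s <- if (ui == 1L) b$stride else 1L
      k <- b$middle_kernels[ui]
      w <- b$width
      total <- total +
        1 * cin * w + 2 * w +        # first 1x1 + BN
        k^2 * w * w + 2 * w +        # middle kxk + BN
        1 * w * w + 2 * w            # last 1x1 + BN
      if (s != 1L || cin != w) total <- total + cin * w + 2 * w  # projection
      cin <- w
    }
  }
  total + cin * x$n_classes + x$n_classes
}

#' @export
count_parameters.erf_model <- function(x) {
  n <- 0
  for (L in stack_cbns(x$stem, x$units))
    n <- n + length(L$W) + length(L$gamma) + length(L$beta)
  n + length(x$head$W) + length(x$head$b)
}

#' Find a width multiplier matching a target parameter count
#'
#' Parameter-matched control: searches for the width multiplier at which a
#' (typically small-ERF) variant has as many trainable parameters as a
#' reference network, e.g. the largest-ERF variant at multiplier 1.
#'
#' @param variant_kernels kernel configuration (name or list) of the variant
#'   to widen, as in [make_erf_variant()].
#' @param target_params parameter count to match.
#' @param n_classes,input_size,in_channels forwarded to [make_erf_variant()].
#' @param interval multiplier search interval.
#' @return The multiplier (numeric); its achieved count and relative error are
#'   attached as attributes `params` and `rel_error`.
#' @export
match_width_multiplier <- function(variant_kernels, target_params,
                                   n_classes = 1000L, input_size = 224L,
                                   in_channels = 3L, interval = c(0.1, 8)) {
  count_at <- function(m)
    count_parameters(make_erf_variant(variant_kernels, width_multiplier = m,
                                      n_classes = n_classes,
                                      input_size = input_size,
                                      in_channels = in_channels))
  root <- stats::uniroot(function(m) count_at(m) - target_params,
                         interval = interval, tol = 1e-6)$root
  achieved <- count_at(root)
  structure(root, params = achieved,
            rel_error = abs(achieved - target_params) / target_params)
}

#' Build a trainable network from an architecture specification
#'
#' Instantiates the stem, every bottleneck residual unit (batch normalization
#' after each convolution, ReLU nonlinearities, identity or projection
#' shortcuts) and the GAP + fully connected + softmax head, with seeded
#' He-uniform weight initialization.
#'
#' @param spec an `arch_spec`.
#' @param seed integer seed for weight initialization.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @return An object of class `erf_model`.
#' @export
build_network <- function(spec, seed = 1L, bn_momentum = 0.9) {
  stopifnot(inherits(spec, "arch_spec"))
  with_seed(seed, {
    stem <- new_conv_bn(spec$stem$kernel, spec$in_channels, spec$stem$width,
                        spec$stem$stride)
    units <- list()
    cin <- spec$stem$width
    for (b in spec$blocks) {
      for (ui in seq_len(b$n_units)) {
        s <- if (ui == 1L) b$stride else 1L
        units[[length(units) + 1L]] <-
          new_unit(cin, b$width, b$width, b$middle_kernels[ui], s)
        cin <- b$width
      }
    }
    head <- new_head(cin, spec$n_classes)
    structure(list(spec = spec, stem = stem, units = units, head = head,
                   bn_momentum = bn_momentum, out_width = cin, seed = seed),
              class = "erf_model")
  })
}

# Full forward pass. Returns logits/probs, the last-conv feature grid and,
# on request, per-unit activations (capture) or backward caches (train).
# batch_stats uses batch normalization statistics without updating the
# running ones (probing untrained or uncalibrated networks).
model_forward <- function(model, x, train = FALSE, capture = FALSE,
                          batch_stats = train) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  if (d[1] != d[2]) stop("input images must be square")
  if (d[1] != model$spec$input_size)
    stop(sprintf("input size %d does not match spec input_size %d",
                 d[1], model$spec$input_size))
  bnm <- model$bn_momentum
  st <- cbn_forward(model$stem, x, batch_stats, bnm, update = train)
  h <- relu_fwd(st$out)
  caches <- if (train) list(stem = st$cache, stem_out = h)
  acts <- if (capture) list()
  ucaches <- if (train) vector("list", length(model$units))
  for (i in seq_along(model$units)) {
    uf <- unit_forward(model$units[[i]], h, batch_stats, bnm, update = train)
    h <- uf$out
    if (train) ucaches[[i]] <- uf$cache
    if (capture) acts[[sprintf("unit%02d", i)]] <- h
  }
  hd <- head_forward(model$head, h)
  probs <- softmax_cols(hd$logits)
  if (capture) {
    acts$gap <- hd$g
    acts$softmax <- probs
  }
  list(logits = hd$logits, probs = probs, features = h, g = hd$g,
       caches = caches, ucaches = ucaches, acts = acts, feat_dim = dim(h))
}

# Backward pass from logit gradients; fills layer gradients, returns d(input).
model_backward <- function(model, fw, dlogits, train = TRUE) {
  dh <- head_backward(model$head, fw$g, dlogits, fw$feat_dim)
  for (i in rev(seq_along(model$units)))
    dh <- unit_backward(model$units[[i]], fw$ucaches[[i]], dh, train)
  dh <- dh * (fw$caches$stem_out > 0)
  cbn_backward(model$stem, fw$caches$stem, dh, train)
}

model_sgd_step <- function(model, lr, mom) {
  for (L in stack_cbns(model$stem, model$units)) sgd_step_cbn(L, lr, mom)
  sgd_step_head(model$head, lr, mom)
  invisible(model)
}

#' Class probabilities for a batch of images
#'
#' @param object an `erf_model`.
#' @param x array `[H, W, C, N]` (or `[H, W, C]` for a single image).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Matrix of softmax probabilities, classes x images.
#' @export
predict.erf_model <- function(object, x, batch_size = 64L, ...) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  out <- matrix(0, object$spec$n_classes, n)
  for (i0 in seq(1L, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1L, n)
    out[, idx] <- model_forward(object, x[, , , idx, drop = FALSE])$probs
  }
  out
}

# Last-conv feature grids for a batch, eval mode, batched.
extract_features <- function(model, x, batch_size = 64L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  first <- model_forward(model, x[, , , 1, drop = FALSE])
  fd <- first$feat_dim
  out <- array(0, c(fd[1], fd[2], fd[3], n))
  out[, , , 1] <- first$features
  if (n > 1L) {
    for (i0 in seq(2L, n, by = batch_size)) {
      idx <- i0:min(i0 + batch_size - 1L, n)
      out[, , , idx] <- model_forward(model, x[, , , idx, drop = FALSE])$features
    }
  }
  out
}

#' Empirical receptive field by gradient support
#'
#' Cross-check for [compute_erf()]: the built network is put into a positive
#' mode (absolute weights, positively shifted batch-norm output) so that no
#' ReLU can cut an active path, the gradient of a centered last-layer unit is
#' propagated back to the input, and the side of the bounding box of non-zero
#' input-gradient support is returned. For a centered unit whose receptive
#' field lies inside the image this equals the analytic ERF exactly.
#'
#' @param spec an `arch_spec`; `spec$input_size` must exceed the analytic ERF
#'   so that the probed unit is unclipped.
#' @param seed weight-initialization seed.
#' @return Integer side length of the gradient-support bounding box.
#' @export
erf_empirical <- function(spec, seed = 1L) {
  model <- build_network(spec, seed = seed)
  for (L in stack_cbns(model$stem, model$units)) {
    L$W <- abs(L$W) + 1e-3
    L$gamma <- rep(1, L$cout)
    L$beta <- rep(0.1, L$cout)
    L$rmean <- rep(0, L$cout)
    L$rvar <- rep(1, L$cout)
  }
  sz <- spec$input_size
  x <- array(1, c(sz, sz, spec$in_channels, 1L))
  # frozen statistics (mean 0, var 1) keep every activation strictly positive,
  # so no ReLU cuts a path and the gradient support is the full receptive field
  fw <- model_forward_frozen_with_cache(model, x)
  fd <- fw$feat_dim
  ctr <- max(1L, fd[1] %/% 2L)
  dfeat <- array(0, fd)
  dfeat[ctr, ctr, , 1] <- 1
  dh <- dfeat * (fw$features > 0)
  for (i in rev(seq_along(model$units)))
    dh <- unit_backward(model$units[[i]], fw$ucaches[[i]], dh, train = FALSE)
  dh <- dh * (fw$caches$stem_out > 0)
  dx <- cbn_backward(model$stem, fw$caches$stem, dh, train = FALSE)
  supp <- apply(abs(dx[, , , 1, drop = FALSE]), c(1, 2), max) > 1e-12
  rows <- which(rowSums(supp) > 0)
  cols <- which(colSums(supp) > 0)
  if (!length(rows)) return(0L)
  as.integer(max(max(rows) - min(rows), max(cols) - min(cols)) + 1L)
}

# forward pass with frozen (eval) batch-norm statistics but caches retained
model_forward_frozen_with_cache <- function(model, x) {
  bnm <- model$bn_momentum
  st <- cbn_forward(model$stem, x, train = FALSE, bnm)
  h <- relu_fwd(st$out)
  caches <- list(stem = st$cache, stem_out = h)
  ucaches <- vector("list", length(model$units))
  for (i in seq_along(model$units)) {
    uf <- unit_forward(model$units[[i]], h, train = FALSE, bnm)
    h <- uf$out
    ucaches[[i]] <- uf$cache
  }
  list(features = h, caches = caches, ucaches = ucaches, feat_dim = dim(h))
}

#' Serialize / restore architecture specifications as JSON
#'
#' @param spec an `arch_spec`.
#' @param path file path; when `NULL`, `arch_to_json` returns the JSON string.
#' @return `arch_to_json` a JSON string (invisibly the path when written);
#'   `arch_from_json` an `arch_spec`.
#' @export
arch_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname arch_to_json
#' @param json JSON string or path to a JSON file.
#' @export
arch_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  blocks <- lapply(seq_len(nrow(x$blocks)), function(i)
    list(n_units = x$blocks$n_units[i], width = x$blocks$width[i],
         stride = x$blocks$stride[i],
         middle_kernels = x$blocks$middle_kernels[[i]]))
  arch_spec(blocks, n_classes = x$n_classes, input_size = x$input_size,
            in_channels = x$in_channels, stem_kernel = x$stem$kernel,
            stem_width = x$stem$width, stem_stride = x$stem$stride,
            width_multiplier = x$width_multiplier)
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> input %dx%dx%d, %d classes, ERF %d px\n",
              x$input_size, x$input_size, x$in_channels, x$n_classes,
              network_erf(x)))
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat(sprintf("  block %d: %d units, width %d, stride %d, kernels (%s)\n",
                i, b$n_units, b$width, b$stride,
                paste(b$middle_kernels, collapse = ",")))
  }
  cat(sprintf("  parameters: %s\n", format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.erf_model <- function(x, ...) {
  cat(sprintf("<erf_model> %d residual units, %s parameters, ERF %d px\n",
              length(x$units), format(count_parameters(x), big.mark = ","),
              network_erf(x$spec)))
  invisible(x)
}
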