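# Spatial feature scrambling: permutation maps over a feature grid, and the
# frozen-base / trainable-follow-up model composition that the scrambling
# probe is applied to.

new_perm_map <- function(mapping, h, w, scope, window = NA_integer_, seed = NA_integer_) {
  structure(list(mapping = as.integer(mapping), grid_height = as.integer(h),
                 grid_width = as.integer(w), scope = scope,
                 window = as.integer(window), seed = as.integer(seed)),
            class = "perm_map")
}

#' Global spatial permutation of a feature grid
#'
#' Draws a uniformly random bijection over all `h * w` spatial positions of a
#' feature grid, reproducible from the seed. Feature vectors (whole channel
#' columns) at position `i` move to position `mapping[i]`.
#'
#' @param h,w grid height and width in cells (`w` defaults to `h`).
#' @param seed integer seed.
#' @return A `perm_map` with scope `"global"`.
#' @export
make_global_permutation <- function(h, w = h, seed = 1L) {
  stopifnot(h >= 1, w >= 1)
  mapping <- with_seed(seed, sample.int(h * w))
  new_perm_map(mapping, h, w, "global", seed = seed)
}

#' Local spatial permutation within non-overlapping windows
#'
#' Partitions the grid into non-overlapping square tiles of side `window`
#' (remainder tiles at the right/bottom edges are smaller and permuted among
#' themselves) and draws an independent uniform permutation inside each tile.
#' No feature crosses a tile boundary, so no feature moves farther than
#' `(window - 1)` cells in either grid direction.
#'
#' @param h,w grid dimensions in cells.
#' @param window tile side in cells; `window = 1` yields the identity, a
#'   window covering the whole grid is equivalent in law to a global
#'   permutation, and a window larger than the grid falls back to global with
#'   a warning.
#' @param seed integer seed.
#' @return A `perm_map` with scope `"local"`.
#' @export
make_local_permutation <- function(h, w = h, window = 2L, seed = 1L) {
  stopifnot(h >= 1, w >= 1, window >= 1)
  if (window > max(h, w)) {
    warning("window exceeds grid size; falling back to a global permutation")
    p <- make_global_permutation(h, w, seed)
    p$scope <- "local"
    p$window <- as.integer(window)
    return(p)
  }
  mapping <- integer(h * w)
  with_seed(seed, {
    for (c0 in seq(1L, w, by = window)) {
      cs <- c0:min(c0 + window - 1L, w)
      for (r0 in seq(1L, h, by = window)) {
        rs <- r0:min(r0 + window - 1L, h)
        cells <- as.integer(outer(rs, (cs - 1L) * h, `+`))  # column-major ids
        mapping[cells] <- cells[sample.int(length(cells))]
      }
    }
  })
  new_perm_map(mapping, h, w, "local", window = window, seed = seed)
}

identity_permutation <- function(h, w = h)
  new_perm_map(seq_len(h * w), h, w, "global")

invert_permutation <- function(perm) {
  inv <- integer(length(perm$mapping))
  inv[perm$mapping] <- seq_along(inv)
  p <- perm
  p$mapping <- inv
  p
}

#' Apply a spatial permutation to a feature grid
#'
#' Moves whole feature columns: the output column at position `mapping[i]`
#' equals the input column at position `i`; channel order within a column is
#' unchanged. Positions are column-major cell indices of the `H x W` grid.
#'
#' @param features array `[H, W, C]` or `[H, W, C, N]` (the same permutation
#'   is applied to every sample of a batch).
#' @param perm a `perm_map` with matching grid dimensions.
#' @return The permuted array, same shape.
#' @export
apply_permutation <- function(features, perm) {
  d <- dim(features)
  if (d[1] != perm$grid_height || d[2] != perm$grid_width)
    stop(sprintf("permutation grid %dx%d does not match features %dx%d",
                 perm$grid_height, perm$grid_width, d[1], d[2]))
  hw <- d[1] * d[2]
  m <- matrix(features, nrow = hw)
  out <- m
  out[perm$mapping, ] <- m
  array(out, dim = d)
}

#' Serialize / restore permutation maps as JSON
#'
#' The mapping is written 0-based for interoperability.
#'
#' @param perm a `perm_map`.
#' @param path optional file path.
#' @return `perm_to_json` a JSON string; `perm_from_json` a `perm_map`.
#' @export
perm_to_json <- function(perm, path = NULL) {
  x <- list(grid_height = perm$grid_height, grid_width = perm$grid_width,
            mapping = perm$mapping - 1L, scope = perm$scope,
            window = perm$window, seed = perm$seed)
  js <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, na = "null"))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname perm_to_json
#' @param json JSON string or file path.
#' @export
perm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_perm_map(x$mapping + 1L, x$grid_height, x$grid_width, x$scope,
               window = x$window %||% NA_integer_, seed = x$seed %||% NA_integer_)
}

#' Follow-up network specification
#'
#' A follow-up network is a stack of four bottleneck residual units appended
#' to a frozen base network. The aggregating mode integrates across space
#' (3x3 middle filters, stride 2 on the first 1x1 convolution of the first
#' two units); the pointwise mode uses only 1x1 convolutions with no
#' down-sampling and therefore cannot combine information across grid
#' positions, making its predictions provably invariant to any spatial
#' permutation of its input.
#'
#' @param mode `"aggregating"` or `"pointwise"`.
#' @param width channel width of the follow-up units; `NULL` (default) matches
#'   the base network's last-layer width.
#' @param n_units number of residual units.
#' @return A `followup_spec`.
#' @export
followup_spec <- function(mode = c("aggregating", "pointwise"), width = NULL,
                          n_units = 4L) {
  mode <- match.arg(mode)
  strides <- if (mode == "aggregating") c(2L, 2L, rep(1L, n_units - 2L))
             else rep(1L, n_units)
  structure(list(mode = mode, n_units = as.integer(n_units),
                 strides = strides,
                 middle_kernel = if (mode == "aggregating") 3L else 1L,
                 width = width),
            class = "followup_spec")
}

#' Compose a frozen base network with a trainable follow-up network
#'
#' The base network's classifier head is detached; its last convolutional
#' feature grid is fed (optionally through a spatial permutation) into a
#' freshly initialized follow-up stack with its own GAP + softmax head. Only
#' the follow-up and head are ever updated by training; the base weights stay
#' frozen.
#'
#' @param base a trained `erf_model`.
#' @param followup a [followup_spec()].
#' @param perm optional fixed `perm_map` applied between base and follow-up.
#' @param train_time_scramble when `TRUE` and `perm` is `NULL`, a fixed global
#'   permutation is drawn once from `seed` and used at every training step
#'   (and at evaluation).
#' @param seed follow-up initialization (and permutation) seed.
#' @return An object of class `composed_model`.
#' @export
compose <- function(base, followup, perm = NULL, train_time_scramble = FALSE,
                    seed = 1L) {
  stopifnot(inherits(base, "erf_model"), inherits(followup, "followup_spec"))
  grid <- tail_grid(base)
  if (train_time_scramble && is.null(perm))
    perm <- make_global_permutation(grid[1], grid[2], seed = seed)
  if (!is.null(perm) &&
      (perm$grid_height != grid[1] || perm$grid_width != grid[2]))
    stop("permutation grid does not match the base feature grid")
  width <- followup$width %||% base$out_width
  with_seed(seed + 1L, {
    units <- list()
    cin <- base$out_width
    for (i in seq_len(followup$n_units)) {
      units[[i]] <- new_unit(cin, width, width, followup$middle_kernel,
                             followup$strides[i])
      cin <- width
    }
    head <- new_head(cin, base$spec$n_classes)
  })
  structure(list(base = base, followup = followup, fu_units = units,
                 head = head, perm = perm,
                 train_time_scramble = isTRUE(train_time_scramble),
                 bn_momentum = base$bn_momentum, seed = seed),
            class = "composed_model")
}

# spatial grid (h, w) of the base's last conv layer
tail_grid <- function(base) {
  tab <- compute_erf(base$spec)
  g <- tab$grid[nrow(tab)]
  c(g, g)
}

#' @export
compute_erf.composed_model <- function(spec, followup = NULL) {
  compute_erf(spec$base$spec, followup = spec$followup)
}

# forward of the follow-up stack from (already permuted) features
fu_forward <- function(cm, feats, train = FALSE) {
  bnm <- cm$bn_momentum
  h <- feats
  ucaches <- if (train) vector("list", length(cm$fu_units))
  for (i in seq_along(cm$fu_units)) {
    uf <- unit_forward(cm$fu_units[[i]], h, train, bnm)
    h <- uf$out
    if (train) ucaches[[i]] <- uf$cache
  }
  hd <- head_forward(cm$head, h)
  list(logits = hd$logits, probs = softmax_cols(hd$logits), g = hd$g,
       ucaches = ucaches, feat_dim = dim(h))
}

fu_backward <- function(cm, fw, dlogits) {
  dh <- head_backward(cm$head, fw$g, dlogits, fw$feat_dim)
  for (i in rev(seq_along(cm$fu_units)))
    dh <- unit_backward(cm$fu_units[[i]], fw$ucaches[[i]], dh, train = TRUE)
  invisible(dh)
}

fu_sgd_step <- function(cm, lr, mom) {
  for (L in stack_cbns(NULL, cm$fu_units)) sgd_step_cbn(L, lr, mom)
  sgd_step_head(cm$head, lr, mom)
  invisible(cm)
}

composed_features <- function(model, x, batch_size = 64L) {
  base <- if (inherits(model, "composed_model")) model$base else model
  extract_features(base, x, batch_size = batch_size)
}

#' @rdname predict.erf_model
#' @param features optionally, precomputed base feature grids `[h, w, C, N]`
#'   (skips the frozen base forward pass).
#' @export
predict.composed_model <- function(object, x = NULL, features = NULL,
                                   batch_size = 64L, ...) {
  if (is.null(features)) features <- composed_features(object, x, batch_size)
  if (!is.null(object$perm)) features <- apply_permutation(features, object$perm)
  n <- dim(features)[4]
  out <- matrix(0, object$base$spec$n_classes, n)
  for (i0 in seq(1L, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1L, n)
    out[, idx] <- fu_forward(object, features[, , , idx, drop = FALSE])$probs
  }
  out
}

#' Paired predictions with and without test-time feature scrambling
#'
#' For a composed model trained without scrambling, draws a fresh permutation
#' per image from a seeded stream, applies it to the base feature grid, and
#' returns predictions with and without scrambling for paired comparison.
#'
#' @param model a `composed_model` (its own `perm` must be `NULL`).
#' @param images array `[H, W, C, N]`; alternatively pass precomputed
#'   `features`.
#' @param scope `"global"` or `"local"`.
#' @param window tile side for local scrambling.
#' @param seed seed of the per-image permutation stream.
#' @param features optional precomputed base features.
#' @return A list with `clean` and `scrambled` class-probability matrices
#'   (classes x images) and the per-image permutations used.
#' @export
test_time_scramble <- function(model, images = NULL, scope = c("global", "local"),
                               window = 2L, seed = 1L, features = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(model, "composed_model"))
  if (!is.null(model$perm))
    warning("model carries a fixed permutation; test-time scrambling is ",
            "intended for models trained without scrambling")
  if (is.null(features)) features <- composed_features(model, images)
  d <- dim(features)
  n <- d[4]
  perms <- lapply(seq_len(n), function(i) {
    s <- seed + i - 1L
    if (scope == "global") make_global_permutation(d[1], d[2], seed = s)
    else make_local_permutation(d[1], d[2], window = window, seed = s)
  })
  scr <- features
  for (i in seq_len(n))
    scr[, , , i] <- apply_permutation(features[, , , i, drop = FALSE], perms[[i]])
  list(clean = predict(model, features = features),
       scrambled = predict(model, features = scr),
       perms = perms, scope = scope, window = window, seed = seed)
}

#' @export
print.composed_model <- function(x, ...) {
  cat(sprintf("<composed_model> frozen base (ERF %d) + %s follow-up%s\n",
              network_erf(x$base$spec), x$followup$mode,
              if (!is.null(x$perm)) sprintf(" [fixed %s scrambling]", x$perm$scope)
              else ""))
  cat(sprintf("  composed ERF: %d px\n", network_erf(compute_erf(x))))
  invisible(x)
}
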