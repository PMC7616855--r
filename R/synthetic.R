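# Seeded synthetic image datasets with controlled class-defining cues.
#
# Two regimes mirror the texture-vs-arrangement contrast the scrambling probe
# is designed to detect: texture classes are separable by local surface
# statistics anywhere in the image (scrambling-insensitive by construction),
# arrangement classes share one part inventory and differ only in the spatial
# layout of those parts (separable only through spatial configuration). A
# sketch rendering mode reduces images to binary contours.

#' Synthetic dataset specification
#'
#' @param cue_type `"texture"`, `"arrangement"` or `"sketch"` (sketch renders
#'   an arrangement dataset as binary contours).
#' @param n_classes number of classes (texture: at most 12 distinguishable
#'   orientations).
#' @param images_per_class images generated per class.
#' @param image_size square image side in pixels.
#' @param part_inventory named list of glyph matrices (values in `[0, 1]`)
#'   shared by all arrangement classes; defaults to [default_parts()].
#' @param part_spacing center-to-center distance of adjacent parts along an
#'   arrangement chain, in pixels (must exceed the glyph side so parts never
#'   collide).
#' @param part_jitter independent per-part jitter, in pixels. (The global
#'   layout translation is uniform over the toroidal canvas.)
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units).
#' @param train_frac fraction of each class assigned to the training split.
#' @param stripe_period texture stripe period in pixels.
#' @param seed generation seed; (spec, seed) regenerate bit-identical data.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(cue_type = c("texture", "arrangement", "sketch"),
                       n_classes = 4L, images_per_class = 200L,
                       image_size = 64L, part_inventory = NULL,
                       part_spacing = 16L, part_jitter = 2L, noise_sd = 0.08,
                       train_frac = 0.75, stripe_period = 8, seed = 1L) {
  cue_type <- match.arg(cue_type)
  structure(list(cue_type = cue_type, n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 part_inventory = part_inventory %||% default_parts(),
                 part_spacing = as.integer(part_spacing),
                 part_jitter = as.integer(part_jitter),
                 noise_sd = noise_sd, train_frac = train_frac,
                 stripe_period = stripe_period, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default part inventory: three parametric glyphs
#'
#' A bar, a disk and a cross, rendered as anti-aliased grayscale matrices.
#' All arrangement classes share this inventory; only its layout differs.
#'
#' @param size glyph side in pixels.
#' @return Named list of `size x size` matrices.
#' @export
default_parts <- function(size = 13L) {
  s <- size
  ctr <- (s + 1) / 2
  xy <- expand.grid(r = seq_len(s), c = seq_len(s))
  soft <- function(d, edge = 0.8) pmin(1, pmax(0, (edge - d) / edge + 0.5))
  bar <- matrix(0, s, s)
  bar[abs(seq_len(s) - ctr) <= s %/% 6, ] <- 1
  disk <- matrix(soft(sqrt((xy$r - ctr)^2 + (xy$c - ctr)^2) - (s / 2 - 1.5)),
                 s, s)
  cross <- matrix(0, s, s)
  w <- s %/% 6
  cross[abs(seq_len(s) - ctr) <= w, ] <- 1
  cross[, abs(seq_len(s) - ctr) <= w] <- 1
  list(bar = bar, disk = disk, cross = cross)
}

# chain directions of the arrangement classes: parts are laid out along a
# line whose orientation (horizontal, vertical, diagonal, anti-diagonal)
# defines the class
chain_directions <- list(c(0, 1), c(1, 0),
                         c(1, 1) / sqrt(2), c(1, -1) / sqrt(2))

# glyph placement with toroidal wrap-around (max composition)
place_part_torus <- function(canvas, glyph, r0, c0) {
  rs <- ((r0 + seq_len(nrow(glyph)) - 2L) %% nrow(canvas)) + 1L
  cs <- ((c0 + seq_len(ncol(glyph)) - 2L) %% ncol(canvas)) + 1L
  canvas[rs, cs] <- pmax(canvas[rs, cs], glyph)
  canvas
}

#' Generate a texture-defined synthetic dataset
#'
#' Each class is a distinct oriented stripe pattern filling the whole image
#' (orientations evenly spaced over 180 degrees), with a random per-image
#' phase and additive Gaussian noise. Any image patch larger than one stripe
#' period is class-diagnostic, so these classes are scrambling-insensitive
#' by construction.
#'
#' @param spec a [synth_spec()] with `cue_type = "texture"`.
#' @return An `image_dataset` with a `synth_spec` attribute.
#' @export
generate_texture_classes <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$cue_type == "texture")
  if (spec$n_classes > 12L)
    stop("more texture classes than distinguishable stripe orientations")
  sz <- spec$image_size
  n <- spec$n_classes * spec$images_per_class
  x <- array(0, c(sz, sz, 1L, n))
  y <- integer(n)
  thetas <- (seq_len(spec$n_classes) - 1L) * pi / spec$n_classes
  coords <- expand.grid(r = seq_len(sz), c = seq_len(sz))
  with_seed(spec$seed, {
    i <- 0L
    for (cl in seq_len(spec$n_classes)) {
      u <- cos(thetas[cl]); v <- sin(thetas[cl])
      proj <- matrix(coords$r * u + coords$c * v, sz, sz)
      for (im in seq_len(spec$images_per_class)) {
        i <- i + 1L
        phase <- stats::runif(1, 0, 2 * pi)
        img <- 0.5 + 0.4 * sin(2 * pi * proj / spec$stripe_period + phase)
        img <- img + stats::rnorm(sz * sz, sd = spec$noise_sd)
        x[, , 1L, i] <- pmin(1, pmax(0, img))
        y[i] <- cl
      }
    }
    split <- make_split(y, spec$train_frac)
  })
  ds <- image_dataset(x, y, classes = paste0("tex", seq_len(spec$n_classes)),
                      split = split)
  attr(ds, "synth_spec") <- spec
  ds
}

#' Generate an arrangement-defined synthetic dataset
#'
#' Every image places the SAME multiset of parts (the shared inventory, one
#' occurrence of each glyph) along a chain whose orientation — horizontal,
#' vertical, diagonal or anti-diagonal — defines the class. The order of the
#' parts along the chain is random per image, the whole layout is translated
#' uniformly over the toroidal canvas (glyphs wrap around the edges), and
#' each part receives an additional small independent jitter. Per-class
#' part-occurrence histograms are therefore identical by construction, every
#' part appears at every image position with equal probability, and only the
#' relative spatial configuration of the parts carries class identity.
#'
#' @param spec a [synth_spec()] with `cue_type = "arrangement"`; at most 4
#'   classes (one per chain orientation). `spec$jitter` is ignored in favour
#'   of full toroidal translation; `spec$part_jitter` is the per-part jitter.
#' @return An `image_dataset` with `synth_spec` and `part_truth` attributes
#'   (the latter: per-class part-count table, constant by construction).
#' @export
generate_arrangement_classes <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"),
            spec$cue_type %in% c("arrangement", "sketch"))
  parts <- spec$part_inventory
  if (length(parts) < 3L) stop("part inventory must contain at least 3 glyphs")
  if (spec$n_classes > length(chain_directions))
    stop(sprintf("at most %d arrangement classes (chain orientations)",
                 length(chain_directions)))
  sz <- spec$image_size
  np <- length(parts)
  spacing <- spec$part_spacing
  n <- spec$n_classes * spec$images_per_class
  x <- array(0, c(sz, sz, 1L, n))
  y <- integer(n)
  with_seed(spec$seed, {
    i <- 0L
    for (cl in seq_len(spec$n_classes)) {
      dir <- chain_directions[[cl]]
      for (im in seq_len(spec$images_per_class)) {
        i <- i + 1L
        canvas <- matrix(0, sz, sz)
        gj <- sample(0:(sz - 1L), 2L, replace = TRUE)
        ord <- sample.int(np)
        for (s in seq_len(np)) {
          glyph <- parts[[ord[s]]]
          off <- (s - (np + 1) / 2) * spacing * dir
          pj <- sample(-spec$part_jitter:spec$part_jitter, 2L, replace = TRUE)
          r0 <- as.integer(round(sz / 2 + off[1] - nrow(glyph) / 2)) + gj[1] + pj[1]
          c0 <- as.integer(round(sz / 2 + off[2] - ncol(glyph) / 2)) + gj[2] + pj[2]
          canvas <- place_part_torus(canvas, glyph, r0, c0)
        }
        canvas <- canvas + stats::rnorm(sz * sz, sd = spec$noise_sd)
        x[, , 1L, i] <- pmin(1, pmax(0, canvas))
        y[i] <- cl
      }
    }
    split <- make_split(y, spec$train_frac)
  })
  ds <- image_dataset(x, y, classes = paste0("arr", seq_len(spec$n_classes)),
                      split = split)
  attr(ds, "synth_spec") <- spec
  counts <- matrix(1L, spec$n_classes, length(parts),
                   dimnames = list(paste0("arr", seq_len(spec$n_classes)),
                                   names(parts)))
  attr(ds, "part_truth") <- counts  # one occurrence of every part per image
  ds
}

#' Concatenate two image datasets into one labeled task
#'
#' Classes of `b` are appended after those of `a` (class indices of `b` are
#' shifted); image shapes must match. Used to build heterogeneous tasks that
#' mix texture-defined and arrangement-defined classes, mirroring per-class
#' analyses on heterogeneous natural datasets.
#'
#' @param a,b `image_dataset`s with identical image dimensions.
#' @return An `image_dataset` with `length(a$classes) + length(b$classes)`
#'   classes.
#' @export
combine_datasets <- function(a, b) {
  da <- dim(a$x); db <- dim(b$x)
  stopifnot(identical(da[1:3], db[1:3]))
  x <- array(0, c(da[1:3], da[4] + db[4]))
  x[, , , seq_len(da[4])] <- a$x
  x[, , , da[4] + seq_len(db[4])] <- b$x
  image_dataset(x, c(a$y, b$y + length(a$classes)),
                classes = c(a$classes, b$classes),
                split = c(a$split, b$split))
}

#' Generate a synthetic dataset from a specification
#'
#' Dispatches on `cue_type`; `"sketch"` generates an arrangement dataset and
#' renders it in sketch style.
#'
#' @param spec a [synth_spec()].
#' @return An `image_dataset`.
#' @export
generate_synthetic <- function(spec) {
  switch(spec$cue_type,
         texture = generate_texture_classes(spec),
         arrangement = generate_arrangement_classes(spec),
         sketch = render_sketch_style(generate_arrangement_classes(
           within_spec(spec, cue_type = "arrangement"))))
}

within_spec <- function(spec, ...) {
  mod <- list(...)
  spec[names(mod)] <- mod
  spec
}

#' Render a dataset in sketch style (binary contours)
#'
#' Replaces every image by a binarized black-on-white contour rendering:
#' images are lightly blurred, the gradient magnitude is thresholded, and
#' edges are drawn black on a white background. Surface fill is removed, so
#' a filled disk becomes an annulus.
#'
#' @param dataset an `image_dataset`.
#' @param threshold gradient-magnitude threshold for an edge pixel.
#' @return The sketch-rendered `image_dataset` (binary-valued images).
#' @export
render_sketch_style <- function(dataset, threshold = 0.15) {
  x <- dataset$x
  for (i in seq_len(dim(x)[4]))
    x[, , 1L, i] <- sketch_render_one(x[, , 1L, i], threshold)
  out <- image_dataset(x, dataset$y, classes = dataset$classes,
                       split = dataset$split)
  sp <- attr(dataset, "synth_spec")
  if (!is.null(sp)) {
    sp$cue_type <- "sketch"
    attr(out, "synth_spec") <- sp
  }
  attr(out, "part_truth") <- attr(dataset, "part_truth")
  out
}

sketch_render_one <- function(img, threshold) {
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 0.8))
  gr <- img * 0
  gc <- img * 0
  n <- nrow(sm)
  gr[2:(n - 1), ] <- (sm[3:n, ] - sm[1:(n - 2), ]) / 2
  gc[, 2:(n - 1)] <- (sm[, 3:n] - sm[, 1:(n - 2)]) / 2
  edge <- sqrt(gr^2 + gc^2) > threshold
  1 - edge * 1  # black contours on white
}

make_split <- function(y, train_frac) {
  split <- rep("test", length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(length(idx) * train_frac)
    split[sample(idx, n_tr)] <- "train"
  }
  split
}

# ---- dataset I/O: directory-per-class PNGs + CSV manifest + JSON spec ----

#' Write a dataset as directory-per-class PNG files
#'
#' Creates `dir/<class>/img_XXXX.png`, a `manifest.csv` (path, label, split)
#' and, for synthetic datasets, a `spec.json` echo of the generation spec.
#'
#' @param dataset an `image_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$y)
  paths <- character(n)
  counters <- integer(length(dataset$classes))
  for (i in seq_len(n)) {
    cl <- dataset$classes[dataset$y[i]]
    cldir <- file.path(dir, cl)
    if (!dir.exists(cldir)) dir.create(cldir)
    counters[dataset$y[i]] <- counters[dataset$y[i]] + 1L
    paths[i] <- file.path(cl, sprintf("img_%04d.png", counters[dataset$y[i]]))
    png::writePNG(dataset$x[, , 1L, i], file.path(dir, paths[i]))
  }
  utils::write.csv(data.frame(path = paths,
                              label = dataset$classes[dataset$y],
                              split = dataset$split),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  sp <- attr(dataset, "synth_spec")
  if (!is.null(sp)) {
    sp$part_inventory <- lapply(sp$part_inventory, unclass)
    writeLines(as.character(jsonlite::toJSON(unclass(sp), auto_unbox = TRUE,
                                             digits = NA)),
               file.path(dir, "spec.json"))
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return An `image_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  classes <- sort(unique(man$label))
  img1 <- png::readPNG(file.path(dir, man$path[1]))
  sz <- dim(img1)[1:2]
  x <- array(0, c(sz[1], sz[2], 1L, nrow(man)))
  for (i in seq_len(nrow(man))) {
    im <- png::readPNG(file.path(dir, man$path[i]))
    if (length(dim(im)) == 3L) im <- im[, , 1]
    x[, , 1L, i] <- im
  }
  image_dataset(x, match(man$label, classes), classes = classes,
                split = man$split)
}

# ---- certification baselines ----

#' Patch-statistics baseline classifier (texture certification)
#'
#' Featurizes every image by the mean absolute gradient energy along four
#' orientations over `patch x patch` tiles, then classifies by nearest class
#' centroid (centroids from the training split). High accuracy certifies
#' that local surface statistics alone separate the classes.
#'
#' @param dataset an `image_dataset`.
#' @param patch tile side in pixels.
#' @return Test-split accuracy, with the per-image features attached.
#' @export
texture_patch_baseline <- function(dataset, patch = 8L) {
  feat <- function(img) {
    n <- nrow(img)
    gr <- img * 0; gc <- img * 0
    gr[2:(n - 1), ] <- (img[3:n, ] - img[1:(n - 2), ]) / 2
    gc[, 2:(n - 1)] <- (img[, 3:n] - img[, 1:(n - 2)]) / 2
    c(mean(abs(gr)), mean(abs(gc)),
      mean(abs(gr + gc)) / sqrt(2), mean(abs(gr - gc)) / sqrt(2))
  }
  feats <- t(vapply(seq_len(dim(dataset$x)[4]),
                    function(i) feat(dataset$x[, , 1L, i]), numeric(4)))
  nearest_centroid_accuracy(feats, dataset)
}

#' Bag-of-parts baseline classifier (arrangement certification)
#'
#' Counts part detections per image by normalized cross-correlation with each
#' inventory glyph (peaks above `ncc_threshold`, greedy non-maximum
#' suppression at glyph scale) and classifies on the count vector alone — no
#' position information. Chance-level accuracy certifies that part
#' occurrence statistics carry no class information, i.e. that class
#' identity lives solely in the spatial arrangement.
#'
#' @param dataset an `image_dataset` (arrangement or sketch).
#' @param parts glyph inventory; defaults to the dataset's generation spec.
#' @param ncc_threshold detection threshold on normalized cross-correlation.
#'   The default is strict: partial matches across part junctions score well
#'   below it, so false positives (which would be orientation-correlated) are
#'   suppressed, while whole-glyph matches score close to 1 even under pixel
#'   noise. Missed detections (e.g. glyphs wrapped across the canvas edge)
#'   are translation-driven and therefore class-independent.
#' @return Test-split accuracy with attribute `counts` (image x part
#'   detection counts).
#' @export
bag_of_parts_baseline <- function(dataset, parts = NULL, ncc_threshold = 0.85) {
  sp <- attr(dataset, "synth_spec")
  parts <- parts %||% sp$part_inventory
  if (!is.null(sp) && sp$cue_type == "sketch")
    parts <- lapply(parts, function(g) sketch_render_one(g, 0.15))
  n <- dim(dataset$x)[4]
  counts <- matrix(0L, n, length(parts))
  for (i in seq_len(n))
    counts[i, ] <- vapply(parts, function(g)
      count_part_detections(dataset$x[, , 1L, i], g, ncc_threshold), integer(1))
  acc <- nearest_centroid_accuracy(counts, dataset)
  attr(acc, "counts") <- counts
  acc
}

# ZNCC template matching with greedy peak suppression
count_part_detections <- function(img, glyph, threshold) {
  gh <- nrow(glyph); gw <- ncol(glyph)
  g0 <- glyph - mean(glyph)
  gnorm <- sqrt(sum(g0^2))
  if (gnorm == 0) return(0L)
  xi <- array(img, c(dim(img), 1L, 1L))
  corr <- conv2d_forward_cpp(xi, array(g0, c(gh, gw, 1L, 1L)), 1L, 0L)[, , 1L, 1L]
  s1 <- conv2d_forward_cpp(xi, array(1, c(gh, gw, 1L, 1L)), 1L, 0L)[, , 1L, 1L]
  s2 <- conv2d_forward_cpp(array(img^2, c(dim(img), 1L, 1L)),
                           array(1, c(gh, gw, 1L, 1L)), 1L, 0L)[, , 1L, 1L]
  npx <- gh * gw
  denom <- sqrt(pmax(s2 - s1^2 / npx, 1e-9)) * gnorm
  ncc <- corr / denom
  cnt <- 0L
  repeat {
    m <- which.max(ncc)
    if (ncc[m] < threshold) break
    cnt <- cnt + 1L
    mr <- (m - 1L) %% nrow(ncc) + 1L
    mc <- (m - 1L) %/% nrow(ncc) + 1L
    rs <- max(1L, mr - gh %/% 2L):min(nrow(ncc), mr + gh %/% 2L)
    cs <- max(1L, mc - gw %/% 2L):min(ncol(ncc), mc + gw %/% 2L)
    ncc[rs, cs] <- -Inf
  }
  cnt
}

nearest_centroid_accuracy <- function(feats, dataset) {
  tr <- dataset$split == "train"
  te <- dataset$split == "test"
  k <- length(dataset$classes)
  centroids <- t(vapply(seq_len(k), function(cl)
    colMeans(feats[tr & dataset$y == cl, , drop = FALSE]),
    numeric(ncol(feats))))
  d2 <- outer(rowSums(feats[te, , drop = FALSE]^2), rep(1, k)) -
    2 * feats[te, , drop = FALSE] %*% t(centroids) +
    outer(rep(1, sum(te)), rowSums(centroids^2))
  pred <- max.col(-d2, ties.method = "first")
  structure(mean(pred == dataset$y[te]), names = NULL)
}
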