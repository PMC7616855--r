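# Minimal recognizable configuration (MIRC) search: recursive expansion of
# corner-anchored 75% crops, stopping where classification fails.

#' Corner-anchored image patch
#'
#' Bounding boxes are in original-image pixel coordinates, 0-based,
#' half-open: the patch covers rows `row .. row + height - 1` (1-based
#' `row + 1 .. row + height`).
#'
#' @param row,col top-left corner (0-based).
#' @param height,width patch extent in pixels (>= 1).
#' @param level recursion level (0 = full image).
#' @return A `patch`.
#' @export
patch <- function(row, col, height, width, level = 0L) {
  stopifnot(height >= 1, width >= 1, row >= 0, col >= 0)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width),
                 level = as.integer(level)),
            class = "patch")
}

full_image_patch <- function(image)
  patch(0L, 0L, dim(image)[1], dim(image)[2], level = 0L)

#' Four corner-anchored descendants of a patch
#'
#' Each descendant spans 75% of the height and width of its parent
#' (`floor(0.75 * side)`, clamped to >= 1 pixel) and is anchored at one of
#' the four corners; levels are incremented.
#'
#' @param p a [patch()].
#' @return List of 4 patches (top-left, top-right, bottom-left, bottom-right).
#' @export
descendants <- function(p) {
  h2 <- max(1L, as.integer(floor(0.75 * p$height)))
  w2 <- max(1L, as.integer(floor(0.75 * p$width)))
  lv <- p$level + 1L
  list(
    patch(p$row, p$col, h2, w2, lv),
    patch(p$row, p$col + p$width - w2, h2, w2, lv),
    patch(p$row + p$height - h2, p$col, h2, w2, lv),
    patch(p$row + p$height - h2, p$col + p$width - w2, h2, w2, lv)
  )
}

crop_patch <- function(image, p) {
  d <- dim(image)
  if (p$row + p$height > d[1] || p$col + p$width > d[2])
    stop("patch extends outside the image")
  if (length(d) == 2L)
    image[p$row + seq_len(p$height), p$col + seq_len(p$width), drop = FALSE]
  else
    image[p$row + seq_len(p$height), p$col + seq_len(p$width), , drop = FALSE]
}

#' Classify one image patch with a model
#'
#' Crops the patch, upsamples it with bilinear interpolation to the model's
#' input size and runs a forward pass; the classification is correct iff the
#' top-1 prediction equals `true_class`.
#'
#' @param model an `erf_model` or `composed_model`.
#' @param image array `[H, W]` or `[H, W, C]`.
#' @param p a [patch()] inside the image.
#' @param true_class integer class index.
#' @return List `(correct, probability, pred)`; `probability` is the softmax
#'   mass on `true_class`.
#' @export
classify_patch <- function(model, image, p, true_class) {
  spec <- if (inherits(model, "composed_model")) model$base$spec else model$spec
  x <- resize_bilinear(crop_patch(image, p), spec$input_size)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  probs <- predict(model, x)
  pred <- which.max(probs[, 1])
  list(correct = pred == true_class, probability = probs[true_class, 1],
       pred = pred)
}

# classifier closure from a model or a user function(image, p, true_class)
as_patch_classifier <- function(classifier) {
  if (is.function(classifier)) return(classifier)
  function(image, p, true_class) classify_patch(classifier, image, p, true_class)
}

#' Recursive MIRC search on one image
#'
#' Starting from the full (correctly classified) image, recursively expands
#' the four 75% corner crops of every correctly classified patch. A patch is
#' a MIRC when it is correctly classified but none of its four descendants
#' is; recursion also halts (leaves flagged `capped`) at `max_level` or when
#' subdivision makes no progress (1-pixel patches). Misclassified patches are
#' never expanded. Duplicate bounding boxes arising from overlapping
#' descendants are evaluated once (memoized) but counted as distinct leaves.
#'
#' @param classifier an `erf_model`/`composed_model`, or a function
#'   `(image, patch, true_class) -> list(correct, probability)` (useful for
#'   closed-form oracle classifiers).
#' @param image array `[H, W]` or `[H, W, C]`.
#' @param true_class integer class index.
#' @param max_level recursion cap (default 10).
#' @return A `mirc_tree`: list with `root` (nested nodes carrying `patch`,
#'   `correct`, `probability`, `children`, `mirc`, `capped`), a flat `mircs`
#'   list, `max_level`, and `reason` (`"ok"` or `"misclassified_root"` for
#'   the empty tree).
#' @export
mirc_search <- function(classifier, image, true_class, max_level = 10L) {
  cls <- as_patch_classifier(classifier)
  memo <- new.env(parent = emptyenv())
  eval_patch <- function(p) {
    key <- sprintf("%d_%d_%d_%d", p$row, p$col, p$height, p$width)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- cls(image, p, true_class)
    memo[[key]] <- res
    res
  }
  mircs <- list()
  expand <- function(p) {
    res <- eval_patch(p)
    node <- list(patch = p, correct = isTRUE(res$correct),
                 probability = res$probability, children = NULL,
                 mirc = FALSE, capped = FALSE)
    if (!node$correct) return(node)
    kids <- descendants(p)
    no_progress <- kids[[1]]$height == p$height && kids[[1]]$width == p$width
    if (p$level >= max_level || no_progress) {
      node$mirc <- TRUE
      node$capped <- TRUE
    } else {
      node$children <- lapply(kids, expand)
      node$mirc <- !any(vapply(node$children, `[[`, logical(1), "correct"))
    }
    if (node$mirc)
      mircs[[length(mircs) + 1L]] <<- list(patch = p,
                                           probability = res$probability,
                                           capped = node$capped)
    node
  }
  root_patch <- full_image_patch(image)
  root_res <- eval_patch(root_patch)
  if (!isTRUE(root_res$correct)) {
    return(structure(list(root = NULL, mircs = list(),
                          max_level = as.integer(max_level),
                          reason = "misclassified_root"),
                     class = "mirc_tree"))
  }
  root <- expand(root_patch)
  structure(list(root = root, mircs = mircs,
                 max_level = as.integer(max_level), reason = "ok"),
            class = "mirc_tree")
}

#' Histogram of per-image maximum MIRC levels
#'
#' @param trees list of `mirc_tree`s (empty trees are skipped).
#' @return Named integer vector of counts over levels `0..max_level`; empty
#'   when no tree has MIRCs.
#' @export
mirc_level_hist <- function(trees) {
  deepest <- vapply(trees, function(tr) {
    if (length(tr$mircs) == 0L) return(NA_integer_)
    max(vapply(tr$mircs, function(m) m$patch$level, integer(1)))
  }, integer(1))
  deepest <- deepest[!is.na(deepest)]
  if (length(deepest) == 0L) return(integer(0))
  mx <- max(vapply(trees, `[[`, integer(1), "max_level"))
  counts <- tabulate(deepest + 1L, nbins = mx + 1L)
  names(counts) <- 0:mx
  counts
}

#' Deepest (and highest-probability) MIRC of a tree
#'
#' @param tree a `mirc_tree`.
#' @return The MIRC record at the deepest level, ties broken by probability;
#'   `NULL` for an empty tree.
#' @export
deepest_mirc <- function(tree) {
  if (length(tree$mircs) == 0L) return(NULL)
  lv <- vapply(tree$mircs, function(m) m$patch$level, integer(1))
  cand <- tree$mircs[lv == max(lv)]
  pr <- vapply(cand, function(m) m$probability %||% NA_real_, numeric(1))
  cand[[if (all(is.na(pr))) 1L else which.max(pr)]]
}

# recursively assert the structural MIRC-tree invariants; errors on violation
validate_mirc_tree <- function(tree) {
  walk <- function(node) {
    if (!is.null(node$children)) {
      if (!node$correct) stop("incorrect node has children")
      for (ch in node$children) walk(ch)
      kids_ok <- vapply(node$children, `[[`, logical(1), "correct")
      if (node$mirc && any(kids_ok))
        stop("MIRC leaf has a correctly classified descendant")
      if (!node$mirc && !any(kids_ok))
        stop("non-MIRC expanded node with no correct child")
    }
    invisible(TRUE)
  }
  if (!is.null(tree$root)) walk(tree$root)
  invisible(TRUE)
}

#' Serialize a MIRC tree to JSON
#'
#' @param tree a `mirc_tree`.
#' @param path optional output file.
#' @return JSON string (invisibly the path when written).
#' @export
mirc_tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (is.null(node)) return(NULL)
    list(bbox = c(node$patch$row, node$patch$col, node$patch$height,
                  node$patch$width),
         level = node$patch$level, correct = node$correct,
         probability = node$probability, mirc = node$mirc,
         capped = node$capped,
         children = if (!is.null(node$children)) lapply(node$children, strip))
  }
  js <- as.character(jsonlite::toJSON(
    list(reason = tree$reason, max_level = tree$max_level,
         root = strip(tree$root)),
    auto_unbox = TRUE, digits = NA, null = "null"))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Cluster the MIRCs of one class by their latent representations
#'
#' Each MIRC patch is upsampled to the model input size, its GAP vector taken
#' as latent representation, and k-means (seeded) groups the latents into `k`
#' clusters. Per cluster the `n_exemplars` MIRCs closest to the cluster
#' center (Euclidean distance) and originating from distinct source images
#' are reported.
#'
#' @param model the model providing latent representations.
#' @param trees list of `mirc_tree`s of one class; names or the `image`
#'   attribute identify source images (defaults to list position).
#' @param images list of the source images (same order as `trees`).
#' @param k number of clusters (reduced with a warning when there are fewer
#'   MIRCs).
#' @param n_exemplars exemplars reported per cluster.
#' @param seed k-means seed.
#' @return List with `assignment` data frame (image, level, cluster, distance
#'   to own center), `centers`, and `exemplars` (per cluster, rows of the
#'   assignment table with distinct source images).
#' @export
cluster_mircs <- function(model, trees, images, k = 5L, n_exemplars = 8L,
                          seed = 1L) {
  recs <- list()
  for (ti in seq_along(trees)) {
    for (m in trees[[ti]]$mircs)
      recs[[length(recs) + 1L]] <- list(image = ti, patch = m$patch)
  }
  if (length(recs) == 0L) stop("no MIRCs to cluster")
  if (length(recs) < k) {
    warning(sprintf("only %d MIRCs; reducing k from %d", length(recs), k))
    k <- length(recs)
  }
  spec <- if (inherits(model, "composed_model")) model$base$spec else model$spec
  extract <- gap_extractor(model)
  lat <- t(vapply(recs, function(r) {
    x <- resize_bilinear(crop_patch(images[[r$image]], r$patch),
                         spec$input_size)
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
    extract(array(x, c(dim(x), 1L)))[1, ]
  }, numeric(latent_dim(model))))
  n_distinct <- nrow(unique(round(lat, 10)))
  if (n_distinct < k) {
    warning(sprintf("only %d distinct latents; reducing k from %d", n_distinct, k))
    k <- n_distinct
  }
  km <- with_seed(seed, stats::kmeans(lat, centers = k, nstart = 5L))
  dist_to_center <- sqrt(rowSums((lat - km$centers[km$cluster, , drop = FALSE])^2))
  assign_df <- data.frame(
    image = vapply(recs, `[[`, integer(1), "image"),
    level = vapply(recs, function(r) r$patch$level, integer(1)),
    cluster = km$cluster, distance = dist_to_center)
  exemplars <- lapply(seq_len(k), function(cl) {
    rows <- which(assign_df$cluster == cl)
    rows <- rows[order(assign_df$distance[rows])]
    seen <- integer(0)
    keep <- integer(0)
    for (r in rows) {
      if (assign_df$image[r] %in% seen) next
      keep <- c(keep, r)
      seen <- c(seen, assign_df$image[r])
      if (length(keep) >= n_exemplars) break
    }
    cbind(assign_df[keep, , drop = FALSE],
          patch_row = vapply(recs[keep], function(r) r$patch$row, integer(1)),
          patch_col = vapply(recs[keep], function(r) r$patch$col, integer(1)),
          patch_height = vapply(recs[keep], function(r) r$patch$height, integer(1)),
          patch_width = vapply(recs[keep], function(r) r$patch$width, integer(1)))
  })
  list(assignment = assign_df, centers = km$centers, exemplars = exemplars,
       inertia = km$tot.withinss, k = k)
}

latent_dim <- function(model) {
  if (inherits(model, "composed_model")) nrow(model$head$W)
  else model$out_width
}
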