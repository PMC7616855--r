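# Representational similarity analysis: first- and second-order
# dissimilarity matrices, explained variance between RDMs, classical MDS,
# and the repeated-sampling scrambling-sensitivity contrast.

new_rdm <- function(m, labels = NULL, provenance = NULL) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  structure(m, class = c("rdm", "matrix"), provenance = provenance)
}

#' Representational dissimilarity matrix
#'
#' Entry (i, j) is the correlation distance `1 - Pearson(r_i, r_j)` between
#' the activation vectors of stimuli i and j. Entries lie in `[0, 2]`, the
#' diagonal is zero and the matrix is symmetric.
#'
#' @param activations stimuli x features matrix (>= 2 stimuli; activations
#'   with spatial extent must be flattened to one vector per stimulus).
#' @param labels optional stimulus labels.
#' @param provenance optional free-form provenance (model, layer, ...).
#' @return An `rdm` matrix.
#' @export
compute_rdm <- function(activations, labels = NULL, provenance = NULL) {
  activations <- as.matrix(activations)
  if (nrow(activations) < 2L) stop("need at least 2 stimuli")
  v <- apply(activations, 1, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)[1]
    nm <- rownames(activations)[bad] %||% as.character(bad)
    stop(sprintf("activation vector of stimulus %s has zero variance", nm))
  }
  new_rdm(1 - stats::cor(t(activations)), labels = labels,
          provenance = provenance)
}

#' Upper-triangle vector of an RDM (diagonal excluded)
#'
#' @param rdm a square symmetric matrix.
#' @return Numeric vector of the strictly-upper-triangular entries.
#' @export
upper_tri <- function(rdm) rdm[upper.tri(rdm)]

#' Second-order RDM over a list of layer RDMs
#'
#' Entry (a, b) is the correlation distance between the vectorized upper
#' triangles of RDMs a and b. With 5 models and 12 extracted layers per model
#' this is the 60 x 60 layer-dissimilarity matrix.
#'
#' @param rdms list of `rdm` matrices with identical side and stimulus order.
#' @param labels optional layer labels (defaults to list names).
#' @return An `rdm` over layers.
#' @export
second_order_rdm <- function(rdms, labels = NULL) {
  sides <- vapply(rdms, nrow, integer(1))
  if (length(unique(sides)) != 1L) stop("all RDMs must have the same side")
  tri <- vapply(rdms, upper_tri, numeric(sides[1] * (sides[1] - 1) / 2))
  new_rdm(1 - stats::cor(tri), labels = labels %||% names(rdms))
}

#' Element-wise average of RDMs (e.g. across initialization seeds)
#'
#' @param rdms list of same-side `rdm` matrices.
#' @return The averaged `rdm`.
#' @export
average_rdms <- function(rdms) {
  new_rdm(Reduce(`+`, lapply(rdms, unclass)) / length(rdms),
          labels = rownames(rdms[[1]]))
}

#' Explained variance between two RDMs
#'
#' Squared Pearson correlation of the vectorized upper triangles.
#'
#' @param a,b same-side RDMs over the same stimuli.
#' @return R-squared in `[0, 1]`.
#' @export
rdm_r2 <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("RDM sides differ")
  ta <- upper_tri(a)
  tb <- upper_tri(b)
  if (stats::var(ta) == 0 || stats::var(tb) == 0)
    stop("constant upper triangle: R^2 undefined")
  stats::cor(ta, tb)^2
}

#' Metric multidimensional scaling of an RDM
#'
#' Classical (Torgerson) metric scaling of the dissimilarities, deterministic,
#' exact for Euclidean-embeddable inputs. The residual stress
#' `sqrt(sum((d_hat - d)^2) / sum(d^2))` of the embedding is attached.
#'
#' @param rdm an `rdm` (or any symmetric dissimilarity matrix).
#' @param dims embedding dimensionality (default 2).
#' @return n x dims coordinate matrix with attribute `stress`.
#' @export
mds_embed <- function(rdm, dims = 2L) {
  n <- nrow(rdm)
  d <- as.matrix(rdm)
  if (all(d == 0)) {
    coords <- matrix(0, n, dims)
    return(structure(coords, stress = 0))
  }
  coords <- suppressWarnings(stats::cmdscale(d, k = dims))
  if (ncol(coords) < dims)
    coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
  emb <- as.matrix(stats::dist(coords))
  structure(coords, stress = sqrt(sum((emb - d)^2) / sum(d^2)))
}

#' Extract flattened layer activations of a model
#'
#' Runs a batch of images through an `erf_model` and returns, per probed
#' layer, a stimuli x features matrix: the output grid of each residual unit
#' (flattened), the GAP vector and the softmax output — 12 layers for the
#' canonical 10-unit architectures.
#'
#' @param model an `erf_model`.
#' @param x image array `[H, W, C, N]`.
#' @param batch_stats normalize with batch statistics instead of the stored
#'   running statistics (without updating them). Use for untrained or
#'   otherwise uncalibrated networks, whose running statistics would let
#'   activations saturate.
#' @return Named list of activation matrices.
#' @export
layer_activations <- function(model, x, batch_stats = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  fw <- model_forward(model, x, capture = TRUE, batch_stats = batch_stats)
  lapply(fw$acts, function(a) {
    if (is.matrix(a)) t(a)                     # gap / softmax: C x N
    else t(matrix(a, ncol = dim(a)[4]))        # grid: flatten per stimulus
  })
}

#' Layer RDMs of a model
#'
#' @inheritParams layer_activations
#' @param labels optional stimulus labels.
#' @return Named list of `rdm` matrices, one per probed layer.
#' @export
layer_rdms <- function(model, x, labels = NULL, batch_stats = FALSE) {
  acts <- layer_activations(model, x, batch_stats = batch_stats)
  out <- lapply(names(acts), function(nm)
    compute_rdm(acts[[nm]], labels = labels, provenance = nm))
  names(out) <- names(acts)
  out
}

#' Scrambling-sensitivity contrast of representational similarity
#'
#' Tests whether a small-ERF model explains the representations of a
#' large-ERF model worse for scrambling-sensitive classes than for
#' scrambling-insensitive ones. Per repetition, `n_images` images are sampled
#' from each class of each condition, both models' features are extracted,
#' RDMs are built per model and condition, and the explained variance
#' R^2(small -> large) is computed per condition; the statistic is the
#' difference `R^2_sensitive - R^2_insensitive`.
#'
#' @param extract_small,extract_large functions mapping an image array
#'   `[H, W, C, n]` to a stimuli x features activation matrix (e.g.
#'   [gap_extractor()]).
#' @param dataset an `image_dataset` pooling the candidate images.
#' @param sensitive,insensitive class-name vectors defining the conditions.
#' @param reps number of repetitions (default 100).
#' @param n_images images sampled per class and repetition; classes with
#'   fewer images are sampled with replacement, with a warning.
#' @param split dataset split to sample from.
#' @param seed seed of the sampling stream.
#' @return Data frame (rep, r2_sensitive, r2_insensitive, delta).
#' @export
sensitivity_contrast <- function(extract_small, extract_large, dataset,
                                 sensitive, insensitive, reps = 100L,
                                 n_images = 20L, split = "test", seed = 1L) {
  ds <- dataset_split(dataset, split)
  cls_idx <- function(cls) which(ds$classes[ds$y] == cls)
  pool <- lapply(c(sensitive, insensitive), cls_idx)
  names(pool) <- c(sensitive, insensitive)
  short <- vapply(pool, length, integer(1)) < n_images
  if (any(short))
    warning("classes with fewer than n_images images; sampling with replacement: ",
            paste(names(pool)[short], collapse = ", "))
  one_cond <- function(cls_set) {
    idx <- unlist(lapply(cls_set, function(cl) {
      p <- pool[[cl]]
      sample(p, n_images, replace = length(p) < n_images)
    }))
    xb <- ds$x[, , , idx, drop = FALSE]
    a <- extract_small(xb)
    b <- extract_large(xb)
    rdm_r2(compute_rdm(a), compute_rdm(b))
  }
  with_seed(seed, {
    out <- lapply(seq_len(reps), function(r) {
      r2s <- one_cond(sensitive)
      r2i <- one_cond(insensitive)
      data.frame(rep = r, r2_sensitive = r2s, r2_insensitive = r2i,
                 delta = r2s - r2i)
    })
  })
  do.call(rbind, out)
}

#' Feature extractors for RSA
#'
#' `gap_extractor` returns the global-average-pooled feature vector per
#' stimulus; `softmax_extractor` the class-probability vector.
#'
#' @param model an `erf_model` or `composed_model`.
#' @return A function mapping an image array to a stimuli x features matrix.
#' @export
gap_extractor <- function(model) {
  if (inherits(model, "composed_model")) {
    function(x) {
      feats <- composed_features(model, x)
      if (!is.null(model$perm)) feats <- apply_permutation(feats, model$perm)
      t(fu_forward(model, feats)$g)
    }
  } else {
    function(x) t(model_forward(model, x)$g)
  }
}

#' @rdname gap_extractor
#' @export
softmax_extractor <- function(model) function(x) t(predict(model, x))
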