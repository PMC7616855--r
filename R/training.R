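# Training schedule, preprocessing, per-class metrics and the
# scrambling-ratio statistic.

#' Training configuration
#'
#' SGD with momentum 0.9 and a learning rate held at `lr_initial` for the
#' first 10 epochs, then decayed exponentially by `decay_rate` per epoch:
#' `lr(t) = lr_initial` for `t <= 10`, `lr_initial * decay_rate^(t - 10)`
#' afterwards.
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr_initial initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param decay_rate per-epoch exponential decay factor after epoch 10.
#' @param seed seed controlling shuffling (and any preprocessing randomness).
#' @param bn_momentum batch-norm running-statistics momentum.
#' @param shuffle shuffle training examples each epoch.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 128L, lr_initial = 0.01,
                         momentum = 0.9, decay_rate = 0.94, seed = 1L,
                         bn_momentum = 0.9, shuffle = TRUE) {
  stopifnot(lr_initial > 0, decay_rate > 0, epochs >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, momentum = momentum,
                 decay_rate = decay_rate, seed = as.integer(seed),
                 bn_momentum = bn_momentum, shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param config a [train_config()].
#' @param epoch epoch number (1-based).
#' @return The learning rate.
#' @export
lr_at <- function(config, epoch) {
  if (epoch <= 10) config$lr_initial
  else config$lr_initial * config$decay_rate^(epoch - 10)
}

center_square_crop <- function(image) {
  d <- dim(image)
  side <- min(d[1], d[2])
  r0 <- (d[1] - side) %/% 2L
  c0 <- (d[2] - side) %/% 2L
  if (length(d) == 2L) image[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
  else image[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
}

resize_bilinear <- function(image, h, w = h) {
  d <- dim(image)
  if (d[1] == h && d[2] == w) return(image)
  out <- EBImage::resize(EBImage::Image(image), w = h, h = w,
                         filter = "bilinear")
  as.array(out)
}

#' Training-time preprocessing
#'
#' Central square crop (side = shortest image dimension), bilinear resize to
#' `resize_to`, random horizontal flip with probability 1/2, then a random
#' `crop_to` crop. Randomness is drawn from the caller's RNG stream; seed it
#' (e.g. via the training config) for reproducibility.
#'
#' @param image array `[H, W]` or `[H, W, C]` with values in `[0, 1]`.
#' @param resize_to intermediate square size (default 256).
#' @param crop_to final square size (default 224).
#' @param flip allow the random horizontal flip.
#' @param random_crop when `FALSE` the crop is pinned to the top-left corner
#'   (deterministic regression mode).
#' @return Array `crop_to x crop_to (x C)`.
#' @export
preprocess_train <- function(image, resize_to = 256L, crop_to = 224L,
                             flip = TRUE, random_crop = TRUE) {
  x <- resize_bilinear(center_square_crop(image), resize_to)
  has_c <- length(dim(x)) == 3L
  if (flip && stats::runif(1) < 0.5) {
    x <- if (has_c) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
         else x[, rev(seq_len(dim(x)[2])), drop = FALSE]
  }
  mx <- resize_to - crop_to
  r0 <- if (random_crop) sample.int(mx + 1L, 1L) - 1L else 0L
  c0 <- if (random_crop) sample.int(mx + 1L, 1L) - 1L else 0L
  if (has_c) x[r0 + seq_len(crop_to), c0 + seq_len(crop_to), , drop = FALSE]
  else x[r0 + seq_len(crop_to), c0 + seq_len(crop_to), drop = FALSE]
}

#' Test-time preprocessing
#'
#' Central square crop, bilinear resize to `resize_to`, then the central
#' `crop_to` patch. Fully deterministic.
#'
#' @inheritParams preprocess_train
#' @return Array `crop_to x crop_to (x C)`.
#' @export
preprocess_eval <- function(image, resize_to = 256L, crop_to = 224L) {
  x <- resize_bilinear(center_square_crop(image), resize_to)
  off <- (resize_to - crop_to) %/% 2L
  if (length(dim(x)) == 3L)
    x[off + seq_len(crop_to), off + seq_len(crop_to), , drop = FALSE]
  else x[off + seq_len(crop_to), off + seq_len(crop_to), drop = FALSE]
}

# ---- in-memory datasets ----

#' Assemble an in-memory labeled image dataset
#'
#' @param x array `[H, W, C, N]` of images in `[0, 1]`.
#' @param y integer class labels in `1..K` (or a factor).
#' @param classes class names (defaults to factor levels or `class1..K`).
#' @param split character vector (`"train"`/`"test"`) per image.
#' @return An object of class `image_dataset`.
#' @export
image_dataset <- function(x, y, classes = NULL, split = NULL) {
  if (is.factor(y)) {
    classes <- classes %||% levels(y)
    y <- as.integer(y)
  }
  classes <- classes %||% paste0("class", seq_len(max(y)))
  split <- split %||% rep("train", length(y))
  stopifnot(dim(x)[4] == length(y), length(split) == length(y))
  structure(list(x = x, y = as.integer(y), classes = classes, split = split),
            class = "image_dataset")
}

#' Subset a dataset to one split
#'
#' @param dataset an `image_dataset`.
#' @param split `"train"` or `"test"`.
#' @return An `image_dataset` containing only that split.
#' @export
dataset_split <- function(dataset, split = "train") {
  keep <- dataset$split == split
  image_dataset(dataset$x[, , , keep, drop = FALSE], dataset$y[keep],
                classes = dataset$classes, split = dataset$split[keep])
}

# ---- training ----

#' Train a model with SGD + momentum
#'
#' Minimizes cross-entropy with the schedule of [train_config()]. For a
#' standalone `erf_model` all layers are updated. For a `composed_model` the
#' base is frozen: its feature grids are computed once in evaluation mode
#' (optionally scrambled by the model's fixed permutation) and only the
#' follow-up stack and head are updated.
#'
#' @param model an `erf_model` or `composed_model`.
#' @param dataset an `image_dataset`; only its `"train"` split is used.
#' @param config a [train_config()].
#' @param verbose print per-epoch loss/accuracy.
#' @return The trained model with a per-epoch `history` data frame attached
#'   (`model$history`: epoch, lr, loss, accuracy).
#' @export
train <- function(model, dataset, config = train_config(), verbose = FALSE)
  UseMethod("train")

run_sgd_epochs <- function(forward_backward_step, n, config, verbose) {
  hist <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                     accuracy = numeric(0))
  if (config$epochs == 0L) return(hist)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at(config, epoch)
      idx <- if (config$shuffle) sample.int(n) else seq_len(n)
      tot_loss <- 0
      tot_correct <- 0L
      for (i0 in seq(1L, n, by = config$batch_size)) {
        bidx <- idx[i0:min(i0 + config$batch_size - 1L, n)]
        res <- forward_backward_step(bidx, lr)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite loss at epoch %d (lr %.4g); aborting",
                       epoch, lr))
        tot_loss <- tot_loss + res$loss * length(bidx)
        tot_correct <- tot_correct + res$correct
      }
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     loss = tot_loss / n,
                                     accuracy = tot_correct / n))
      if (verbose)
        message(sprintf("epoch %3d  lr %.4g  loss %.4f  acc %.3f",
                        epoch, lr, tot_loss / n, tot_correct / n))
    }
  })
  hist
}

#' @export
train.erf_model <- function(model, dataset, config = train_config(),
                            verbose = FALSE) {
  ds <- dataset_split(dataset, "train")
  n <- length(ds$y)
  if (n == 0L) stop("training split is empty")
  model$bn_momentum <- config$bn_momentum
  step <- function(bidx, lr) {
    xb <- ds$x[, , , bidx, drop = FALSE]
    yb <- ds$y[bidx]
    fw <- model_forward(model, xb, train = TRUE)
    ce <- xent_loss(fw$logits, yb)
    model_backward(model, fw, ce$dlogits)
    model_sgd_step(model, lr, config$momentum)
    list(loss = ce$loss,
         correct = sum(max.col(t(ce$probs), ties.method = "first") == yb))
  }
  model$history <- run_sgd_epochs(step, n, config, verbose)
  model
}

#' @export
train.composed_model <- function(model, dataset, config = train_config(),
                                 verbose = FALSE) {
  ds <- dataset_split(dataset, "train")
  n <- length(ds$y)
  if (n == 0L) stop("training split is empty")
  feats <- composed_features(model, ds$x)
  if (!is.null(model$perm)) feats <- apply_permutation(feats, model$perm)
  step <- function(bidx, lr) {
    fb <- feats[, , , bidx, drop = FALSE]
    yb <- ds$y[bidx]
    fw <- fu_forward(model, fb, train = TRUE)
    ce <- xent_loss(fw$logits, yb)
    fu_backward(model, fw, ce$dlogits)
    fu_sgd_step(model, lr, config$momentum)
    list(loss = ce$loss,
         correct = sum(max.col(t(ce$probs), ties.method = "first") == yb))
  }
  model$history <- run_sgd_epochs(step, n, config, verbose)
  model
}

# ---- metrics ----

#' Per-class precision/recall/F1 from predictions
#'
#' One-vs-rest counts from top-1 predictions. F1 is the harmonic mean of
#' precision and recall and is set to 0 when both are 0; a class absent from
#' the truth vector gets `NA` metrics and is flagged.
#'
#' @param pred integer predicted labels.
#' @param truth integer true labels.
#' @param classes class names (length = number of classes).
#' @return A `class_metrics` data frame (class, tp, fp, fn, precision, recall,
#'   f1, present) with the overall top-1 accuracy in `attr(, "accuracy")`.
#' @export
class_metrics <- function(pred, truth, classes) {
  k <- length(classes)
  stopifnot(length(pred) == length(truth))
  tp <- fp <- fn <- integer(k)
  for (c in seq_len(k)) {
    tp[c] <- sum(pred == c & truth == c)
    fp[c] <- sum(pred == c & truth != c)
    fn[c] <- sum(pred != c & truth == c)
  }
  present <- tabulate(truth, k) > 0L
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  precision[!present] <- recall[!present] <- f1[!present] <- NA_real_
  out <- data.frame(class = classes, tp = tp, fp = fp, fn = fn,
                    precision = precision, recall = recall, f1 = f1,
                    present = present, stringsAsFactors = FALSE)
  structure(out, class = c("class_metrics", "data.frame"),
            accuracy = mean(pred == truth))
}

#' Evaluate a model on a labeled dataset split
#'
#' @param model an `erf_model` or `composed_model`.
#' @param dataset an `image_dataset`.
#' @param split which split to evaluate (default `"test"`).
#' @param features optional precomputed base features (composed models only).
#' @return A [class_metrics()] data frame.
#' @export
evaluate <- function(model, dataset, split = "test", features = NULL) {
  ds <- dataset_split(dataset, split)
  if (length(ds$y) == 0L) stop(sprintf("split '%s' is empty", split))
  probs <- if (inherits(model, "composed_model") && !is.null(features))
    predict(model, features = features)
  else predict(model, ds$x)
  pred <- max.col(t(probs), ties.method = "first")
  class_metrics(pred, ds$y, ds$classes)
}

#' Per-class scrambling-sensitivity report
#'
#' For every class reliably classified before scrambling (`f1_before >
#' threshold`), computes the scrambling ratio `f1_after / f1_before` and
#' ranks classes ascending by ratio (most scrambling-sensitive first). A low
#' ratio marks a class whose recognition depends on the global spatial
#' configuration of features.
#'
#' @param before,after [class_metrics()] over the same class list, computed
#'   without and with feature scrambling.
#' @param threshold eligibility threshold on `f1_before` (default 0.75).
#' @return A `scrambling_report` data frame (class, f1_before, f1_after,
#'   ratio, eligible) ordered as the input classes, with ranked eligible class
#'   names in `attr(, "ranking")` (ascending ratio).
#' @export
scrambling_ratio <- function(before, after, threshold = 0.75) {
  stopifnot(identical(before$class, after$class))
  ratio <- ifelse(before$f1 > 0, after$f1 / before$f1, NA_real_)
  eligible <- !is.na(before$f1) & before$f1 > threshold
  if (!any(eligible))
    warning("no class exceeds the f1 eligibility threshold; empty report")
  ratio[!eligible] <- NA_real_
  out <- data.frame(class = before$class, f1_before = before$f1,
                    f1_after = after$f1, ratio = ratio, eligible = eligible,
                    stringsAsFactors = FALSE)
  ranking <- out$class[eligible][order(out$ratio[eligible])]
  structure(out, class = c("scrambling_report", "data.frame"),
            ranking = ranking, threshold = threshold)
}

#' Overlap of scrambling-sensitivity rankings across models
#'
#' Pairwise intersection counts of the k most (and k least)
#' scrambling-sensitive classes between models.
#'
#' @param rankings named list; each element is either a `scrambling_report`
#'   or a character vector of eligible classes ranked ascending by ratio.
#' @param k list depth (default 20); truncated with a warning when a ranking
#'   is shorter.
#' @return A list with symmetric integer matrices `most` and `least`.
#' @export
class_set_overlap <- function(rankings, k = 20L) {
  rank_of <- function(r) if (inherits(r, "scrambling_report")) attr(r, "ranking") else r
  rks <- lapply(rankings, rank_of)
  if (any(vapply(rks, length, integer(1)) < k)) {
    warning("k exceeds an eligible set; using the full set for that model")
  }
  m <- length(rks)
  nms <- names(rks) %||% paste0("model", seq_len(m))
  most <- least <- matrix(0L, m, m, dimnames = list(nms, nms))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    ri <- rks[[i]]; rj <- rks[[j]]
    most[i, j] <- length(intersect(head(ri, min(k, length(ri))),
                                   head(rj, min(k, length(rj)))))
    least[i, j] <- length(intersect(head(rev(ri), min(k, length(ri))),
                                    head(rev(rj), min(k, length(rj)))))
  }
  list(most = most, least = least, k = as.integer(k))
}
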