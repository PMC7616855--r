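# End-to-end experiment orchestration: the ERF survey and the
# base/follow-up scrambling study, with seeded reproducibility and a
# manifest sufficient to reproduce every output.

#' Experiment configuration
#'
#' @param dataset an `image_dataset`, a [synth_spec()] (generated in-run), or
#'   a directory written by [write_dataset()].
#' @param variants named list of kernel configurations (names from
#'   [erf_variant_kernels] or explicit kernel lists) surveyed / used as base.
#' @param width_multiplier width scaling of every built network.
#' @param base_config,followup_config [train_config()]s for the standalone
#'   base networks and the follow-up stacks.
#' @param window local-scrambling window in grid cells.
#' @param include_pointwise also train the pointwise (1x1) follow-up control
#'   in [run_scrambling_study()].
#' @param seed global experiment seed (model init, permutations, sampling).
#' @param out_dir optional output directory (`results.csv`, `manifest.json`).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(dataset, variants = list(erf11 = "erf11"),
                              width_multiplier = 1 / 16,
                              base_config = train_config(epochs = 8L,
                                                         batch_size = 32L),
                              followup_config = train_config(epochs = 25L,
                                                             batch_size = 32L),
                              window = 2L, include_pointwise = TRUE,
                              seed = 1L, out_dir = NULL) {
  structure(list(dataset = dataset, variants = variants,
                 width_multiplier = width_multiplier,
                 base_config = base_config, followup_config = followup_config,
                 window = as.integer(window),
                 include_pointwise = isTRUE(include_pointwise),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

resolve_dataset <- function(dataset) {
  if (inherits(dataset, "image_dataset")) return(dataset)
  if (inherits(dataset, "synth_spec")) return(generate_synthetic(dataset))
  if (is.character(dataset)) return(read_dataset(dataset))
  stop("dataset must be an image_dataset, synth_spec or directory path")
}

config_spec_for <- function(config, ds, kernels) {
  d <- dim(ds$x)
  make_erf_variant(kernels, width_multiplier = config$width_multiplier,
                   n_classes = length(ds$classes), input_size = d[1],
                   in_channels = d[3])
}

write_run_outputs <- function(config, results) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)
  cfg <- config
  cfg$dataset <- if (is.character(cfg$dataset)) cfg$dataset
                 else class(cfg$dataset)[1]
  js <- as.character(jsonlite::toJSON(
    list(config = lapply(unclass(cfg), unclass), seed = config$seed,
         package_version = as.character(utils::packageVersion("erfscope"))),
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null"))
  manifest <- file.path(config$out_dir, "manifest.json")
  writeLines(js, manifest)
  writeLines(sprintf("%s  manifest.json", unname(tools::md5sum(manifest))),
             file.path(config$out_dir, "manifest.md5"))
  invisible(config$out_dir)
}

#' Survey test accuracy as a function of the ERF variant
#'
#' Trains every configured variant on the dataset and reports its theoretical
#' ERF, parameter count and test accuracy.
#'
#' @param config an [experiment_config()] with at least one variant.
#' @return Data frame (variant, erf, params, accuracy), one row per variant,
#'   also written to `out_dir/results.csv` when configured.
#' @export
run_erf_survey <- function(config) {
  ds <- resolve_dataset(config$dataset)
  rows <- lapply(seq_along(config$variants), function(i) {
    kernels <- config$variants[[i]]
    spec <- config_spec_for(config, ds, kernels)
    model <- build_network(spec, seed = config$seed)
    cfg <- config$base_config
    cfg$seed <- config$seed
    model <- train(model, ds, cfg)
    met <- evaluate(model, ds, "test")
    data.frame(variant = names(config$variants)[i] %||% paste0("v", i),
               erf = network_erf(spec), params = count_parameters(spec),
               accuracy = attr(met, "accuracy"))
  })
  results <- do.call(rbind, rows)
  write_run_outputs(config, results)
  results
}

#' Run the full base/follow-up scrambling study
#'
#' Produces the four model conditions of the scrambling probe — the
#' standalone base, base + aggregating follow-up, base + pointwise (1x1)
#' follow-up, and base + follow-up trained on features scrambled by a fixed
#' permutation — plus test-time global and local scrambling of the
#' unscrambled aggregating model.
#'
#' @param config an [experiment_config()]; the first variant is the base.
#' @return List with `results` (condition/accuracy data frame), `report`
#'   (the [scrambling_ratio()] before/after test-time global scrambling of
#'   the aggregating model), and the trained models.
#' @export
run_scrambling_study <- function(config) {
  ds <- resolve_dataset(config$dataset)
  spec <- config_spec_for(config, ds, config$variants[[1]])
  base_cfg <- config$base_config
  base_cfg$seed <- config$seed
  fu_cfg <- config$followup_config
  fu_cfg$seed <- config$seed + 1L

  base <- train(build_network(spec, seed = config$seed), ds, base_cfg)
  test <- dataset_split(ds, "test")
  feats_te <- composed_features(base, test$x)
  met_base <- evaluate(base, ds, "test")

  agg <- compose(base, followup_spec("aggregating"), seed = config$seed)
  agg <- train(agg, ds, fu_cfg)
  met_agg <- evaluate(agg, ds, "test", features = feats_te)

  tts_g <- test_time_scramble(agg, scope = "global", seed = config$seed,
                              features = feats_te)
  tts_l <- test_time_scramble(agg, scope = "local", window = config$window,
                              seed = config$seed, features = feats_te)
  pred_of <- function(probs) max.col(t(probs), ties.method = "first")
  acc_of <- function(probs) mean(pred_of(probs) == test$y)
  met_of <- function(probs) class_metrics(pred_of(probs), test$y, test$classes)
  met_scr_g <- met_of(tts_g$scrambled)
  met_scr_l <- met_of(tts_l$scrambled)

  if (config$include_pointwise) {
    pw <- compose(base, followup_spec("pointwise"), seed = config$seed)
    pw <- train(pw, ds, fu_cfg)
    met_pw <- evaluate(pw, ds, "test", features = feats_te)
    tts_pw <- test_time_scramble(pw, scope = "global", seed = config$seed,
                                 features = feats_te)
  }

  ts <- compose(base, followup_spec("aggregating"),
                train_time_scramble = TRUE, seed = config$seed)
  ts <- train(ts, ds, fu_cfg)
  met_ts <- evaluate(ts, ds, "test", features = feats_te)

  conditions <- c("base", "base+followup", "base+followup/test-global",
                  "base+followup/test-local")
  accs <- c(attr(met_base, "accuracy"), attr(met_agg, "accuracy"),
            acc_of(tts_g$scrambled), acc_of(tts_l$scrambled))
  if (config$include_pointwise) {
    conditions <- c(conditions, "base+1x1-followup",
                    "base+1x1-followup/test-global")
    accs <- c(accs, attr(met_pw, "accuracy"), acc_of(tts_pw$scrambled))
  }
  conditions <- c(conditions, "base+followup/train-scrambled")
  accs <- c(accs, attr(met_ts, "accuracy"))
  results <- data.frame(condition = conditions, accuracy = accs)
  report <- suppressWarnings(scrambling_ratio(met_agg, met_scr_g))
  write_run_outputs(config, results)
  metrics <- list(base = met_base, followup = met_agg,
                  followup_test_global = met_scr_g,
                  followup_test_local = met_scr_l,
                  train_scrambled = met_ts)
  models <- list(base = base, aggregating = agg, train_scrambled = ts)
  if (config$include_pointwise) {
    metrics$pointwise <- met_pw
    models$pointwise <- pw
  }
  list(results = results, report = report, metrics = metrics, models = models)
}

#' Mean recall over a subset of classes
#'
#' Convenience for cue-group summaries: the mean per-class recall (top-1
#' sensitivity) of the named classes.
#'
#' @param metrics a [class_metrics()] data frame.
#' @param classes class names to average over.
#' @return Mean recall.
#' @export
mean_recall <- function(metrics, classes) {
  mean(metrics$recall[match(classes, metrics$class)])
}
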