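#' Configuration of the wrapped selection pipeline
#'
#' Bundles the data source (simulation spec or trial directory), feature
#' configuration, holdout split, cross-validation plan, and solver settings
#' of the end-to-end pipeline.
#'
#' @param sim_spec An [eeg_sim_spec()] generating the trials; ignored when
#'   `input_dir` is given.
#' @param input_dir Directory of trials readable by [read_trials()].
#' @param feature_cfg A [feature_config()].
#' @param resample_to Target sampling frequency in Hz (`NULL` = no
#'   resampling).
#' @param holdout_fraction Fraction of trials held out for testing (default
#'   0.3, stratified).
#' @param split_seed Seed of the train/test split (default 0).
#' @param alpha_grid,n_lambda,lambda_min_ratio,folds,fold_seed
#'   Cross-validation plan, see [sgl_cv()].
#' @param settings A [solver_settings()].
#' @param out_prefix Optional output prefix; when given, [write_report()]
#'   artifacts are written.
#' @param verbose Print stage progress (default FALSE).
#'
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim_spec = eeg_sim_spec(), input_dir = NULL,
                            feature_cfg = feature_config(),
                            resample_to = NULL, holdout_fraction = 0.3,
                            split_seed = 0L,
                            alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                            n_lambda = 50L, lambda_min_ratio = 0.01,
                            folds = 10L, fold_seed = 0L,
                            settings = solver_settings(),
                            out_prefix = NULL, verbose = FALSE) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  structure(
    list(sim_spec = sim_spec, input_dir = input_dir,
         feature_cfg = feature_cfg, resample_to = resample_to,
         holdout_fraction = holdout_fraction,
         split_seed = as.integer(split_seed), alpha_grid = alpha_grid,
         n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio, folds = as.integer(folds),
         fold_seed = as.integer(fold_seed), settings = settings,
         out_prefix = out_prefix, verbose = verbose),
    class = "pipeline_config"
  )
}

#' Run the wrapped channel/feature selection pipeline
#'
#' Resample (optionally) -> extract fused features -> stratified train/test
#' split -> cross-validated Sparse Group Lasso selection on the training
#' trials -> refit -> holdout evaluation. Fully deterministic given the
#' configuration seeds; test trials never influence standardization, the
#' lambda path, or the CV choice.
#'
#' @param config A [pipeline_config()].
#' @return List of class `sgl_pipeline_result`: the fitted `model`,
#'   `test_error`, `selection`, the index sets of the split, and the fused
#'   feature dimensions.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)

  say("stage 1/5: data")
  trials <- if (!is.null(config$input_dir)) read_trials(config$input_dir)
            else gen_eeg_trials(config$sim_spec)
  if (!is.null(config$resample_to) && config$resample_to != trials$fs) {
    say("  resampling ", trials$fs, " -> ", config$resample_to, " Hz")
    trials <- trial_set(
      lapply(trials$trials, resample_trial, fs_in = trials$fs,
             fs_out = config$resample_to),
      trials$labels, config$resample_to, trials$channel_names)
  }

  say("stage 2/5: feature extraction (", length(trials$trials), " trials)")
  ff <- extract_fused(trials, config$feature_cfg)

  say("stage 3/5: train/test split")
  y <- ff$labels
  test_idx <- with_seed(config$split_seed, {
    idx <- integer(0)
    for (cl in sort(unique(y))) {
      cl_idx <- which(y == cl)
      n_te <- max(1L, round(config$holdout_fraction * length(cl_idx)))
      idx <- c(idx, sample(cl_idx, n_te))
    }
    sort(idx)
  })
  train_idx <- setdiff(seq_along(y), test_idx)

  say("stage 4/5: cross-validated selection (", length(train_idx),
      " training trials)")
  model <- sgl_cv(ff$values[train_idx, , drop = FALSE], y[train_idx],
                  ff$group_index, alpha_grid = config$alpha_grid,
                  n_lambda = config$n_lambda,
                  lambda_min_ratio = config$lambda_min_ratio,
                  folds = config$folds, fold_seed = config$fold_seed,
                  settings = config$settings,
                  channel_names = ff$channel_names,
                  feature_labels = ff$feature_labels)

  say("stage 5/5: holdout evaluation (", length(test_idx), " trials)")
  test_error <- evaluate_model(model, ff$values[test_idx, , drop = FALSE],
                               y[test_idx])
  if (!is.null(config$out_prefix))
    write_report(model, config$out_prefix, test_error)
  structure(
    list(model = model, test_error = test_error,
         selection = model$selection, train_idx = train_idx,
         test_idx = test_idx, n_features = ncol(ff$values),
         d = ff$d, n_channels = ff$n_channels),
    class = "sgl_pipeline_result"
  )
}

#' @export
print.sgl_pipeline_result <- function(x, ...) {
  print(x$model)
  cat(sprintf("  holdout error rate: %.4f (%d test trials)\n",
              x$test_error, length(x$test_idx)))
  invisible(x)
}
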