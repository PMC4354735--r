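#' Write a trial set to a directory of delimited-text files
#'
#' One CSV per trial (rows = channels, columns = samples, no header), a
#' `manifest.csv` with columns `file,label`, and a `meta.json` holding the
#' sampling frequency and channel names.
#'
#' @param trials A [trial_set()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_trials <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trial_%04d.csv", seq_along(trials$trials))
  for (i in seq_along(trials$trials))
    utils::write.table(trials$trials[[i]], file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(file = files, label = trials$labels),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fs = trials$fs, channel_names = trials$channel_names),
    file.path(dir, "meta.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a trial set from a directory of delimited-text files
#'
#' Expects the layout written by [write_trials()]: per-trial channel x sample
#' matrices, a `manifest.csv` (`file,label`), and a `meta.json` with `fs`.
#'
#' @param dir Directory path.
#' @param fs Sampling frequency override; required if no `meta.json` exists.
#' @return A [trial_set()].
#' @export
read_trials <- function(dir, fs = NULL) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(man)))
    stop("manifest must have columns 'file' and 'label'")
  meta_path <- file.path(dir, "meta.json")
  ch_names <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(fs)) fs <- meta$fs
    ch_names <- meta$channel_names
    if (length(ch_names) == 0L) ch_names <- NULL
  }
  if (is.null(fs)) stop("sampling frequency unknown: no meta.json, pass 'fs'")
  trials <- lapply(seq_len(nrow(man)), function(i) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f))
      stop("trial file listed in manifest is missing: ", man$file[i])
    as.matrix(utils::read.table(f, sep = ",", header = FALSE))
  })
  p <- nrow(trials[[1]])
  ragged <- which(vapply(trials, nrow, integer(1)) != p)
  if (length(ragged))
    stop("ragged channel count in ", man$file[ragged[1]])
  trials <- lapply(trials, function(m) {
    dimnames(m) <- NULL
    m
  })
  trial_set(trials, man$label, fs, ch_names)
}

#' Write a fused feature matrix
#'
#' Emits `<prefix>_features.csv` (header = feature labels, one row per trial,
#' with a leading `label` column) and `<prefix>_groups.json` (channel-group
#' map).
#'
#' @param ff A `fused_features` object from [extract_fused()].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_features <- function(ff, prefix) {
  stopifnot(inherits(ff, "fused_features"))
  fcsv <- paste0(prefix, "_features.csv")
  fjson <- paste0(prefix, "_groups.json")
  df <- data.frame(label = ff$labels, ff$values, check.names = FALSE)
  utils::write.csv(df, fcsv, row.names = FALSE)
  jsonlite::write_json(
    list(group_index = ff$group_index, d = ff$d,
         n_channels = ff$n_channels, channel_names = ff$channel_names,
         feature_labels = ff$feature_labels, fs = ff$fs),
    fjson, auto_unbox = TRUE)
  invisible(c(fcsv, fjson))
}

#' Read a fused feature matrix written by [write_features()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `fused_features` object.
#' @export
read_features <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, "_features.csv"), check.names = FALSE)
  g <- jsonlite::read_json(paste0(prefix, "_groups.json"),
                           simplifyVector = TRUE)
  X <- as.matrix(df[, -1, drop = FALSE])
  dimnames(X) <- list(NULL, g$feature_labels)
  structure(
    list(values = X, group_index = as.integer(g$group_index), d = g$d,
         n_channels = g$n_channels, channel_names = g$channel_names,
         feature_labels = g$feature_labels, labels = as.integer(df$label),
         fs = g$fs),
    class = "fused_features"
  )
}

#' Serialize a fitted model to JSON
#'
#' Stores coefficients, intercepts, the group map, standardization
#' parameters, the chosen penalty, and convergence metadata.
#'
#' @param model An `sgl_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sgl_model"))
  doc <- list(
    beta = apply(model$beta, 2L, identity, simplify = FALSE),
    intercepts = model$intercepts,
    center = as.numeric(model$center), scale = as.numeric(model$scale),
    group_index = model$group_index, classes = model$classes,
    chosen = model$chosen, cv_accuracy = model$cv_accuracy,
    alpha_grid = model$alpha_grid, folds = model$folds,
    fold_seed = model$fold_seed,
    channel_names = model$channel_names,
    feature_labels = model$feature_labels,
    converged = model$fit$converged, kkt = model$fit$kkt,
    iterations = model$fit$iterations)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON file path.
#' @return An `sgl_model` (sufficient for prediction and reporting).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  # beta was serialized as a list of class columns; simplification yields a
  # (M-1) x (p*d) matrix (rows = columns of beta) or a list when ragged-safe
  beta <- if (is.matrix(doc$beta)) t(doc$beta)
          else if (is.list(doc$beta)) do.call(cbind, doc$beta)
          else matrix(doc$beta, ncol = 1L)
  gi <- as.integer(doc$group_index)
  structure(
    list(beta = beta, intercepts = doc$intercepts,
         center = doc$center, scale = doc$scale, group_index = gi,
         classes = doc$classes,
         chosen = as.list(doc$chosen), cv_accuracy = doc$cv_accuracy,
         cv_table = NULL, selection = sgl_select(beta, gi),
         alpha_grid = doc$alpha_grid, folds = doc$folds,
         fold_seed = doc$fold_seed, channel_names = doc$channel_names,
         feature_labels = doc$feature_labels,
         fit = list(converged = doc$converged, kkt = doc$kkt,
                    iterations = doc$iterations)),
    class = "sgl_model"
  )
}

#' Write the selection report of a fitted model
#'
#' Emits `<prefix>_model.json`, `<prefix>_selection.csv` (per selected
#' channel: id, name, selected feature count, proportion of the channel's
#' features in %), `<prefix>_summary.csv` (totals and proportions),
#' `<prefix>_cv_table.csv`, and a human-readable `<prefix>_log.txt`
#' (timestamp-free so reruns are byte-identical).
#'
#' @param model An `sgl_model`.
#' @param prefix Output path prefix.
#' @param test_error Optional holdout error rate to include.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(model, prefix, test_error = NULL) {
  stopifnot(inherits(model, "sgl_model"))
  sel <- model$selection
  d_per <- table(model$group_index)
  ch_names <- model$channel_names
  if (is.null(ch_names))
    ch_names <- paste0("ch", sort(unique(model$group_index)))
  sel_df <- data.frame(
    channel = sel$per_channel$channel,
    channel_name = ch_names[sel$per_channel$channel],
    n_features_selected = sel$per_channel$n_features,
    prop_channel_features =
      100 * sel$per_channel$n_features /
      as.integer(d_per[as.character(sel$per_channel$channel)]))
  if (nrow(sel_df) == 0L)
    sel_df <- sel_df[0, ]
  sum_df <- data.frame(
    n_channels_selected = sel$n_channels,
    prop_channels = sel$prop_channels,
    n_features_selected = sel$n_features,
    prop_features = sel$prop_features,
    alpha = model$chosen$alpha, lambda = model$chosen$lambda,
    cv_accuracy = model$cv_accuracy,
    test_error = if (is.null(test_error)) NA_real_ else test_error)
  paths <- c(model = paste0(prefix, "_model.json"),
             selection = paste0(prefix, "_selection.csv"),
             summary = paste0(prefix, "_summary.csv"),
             cv = paste0(prefix, "_cv_table.csv"),
             log = paste0(prefix, "_log.txt"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  write_model(model, paths["model"])
  utils::write.csv(sel_df, paths["selection"], row.names = FALSE)
  utils::write.csv(sum_df, paths["summary"], row.names = FALSE)
  if (!is.null(model$cv_table))
    utils::write.csv(model$cv_table, paths["cv"], row.names = FALSE)
  log_lines <- c(
    "sparse group lasso channel/feature selection report",
    sprintf("chosen alpha=%.4g lambda=%.6g (mean CV accuracy %.4f)",
            model$chosen$alpha, model$chosen$lambda, model$cv_accuracy),
    sprintf("selected channels: %d (%.2f%%)", sel$n_channels,
            sel$prop_channels),
    sprintf("selected features: %d (%.2f%%)", sel$n_features,
            sel$prop_features),
    if (!is.null(test_error))
      sprintf("holdout error rate: %.4f", test_error))
  writeLines(log_lines, paths["log"])
  invisible(paths)
}
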