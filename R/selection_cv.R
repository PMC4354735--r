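#' Geometric lambda path
#'
#' Builds a descending geometric grid of penalty weights from
#' [kkt_lambda_max()] down to `lambda_min_ratio * lambda_max`.
#'
#' @inheritParams sgl_fit
#' @param n_lambda Path length (default 50).
#' @param lambda_min_ratio Ratio of the smallest to the largest value
#'   (default 0.01).
#' @return Descending numeric vector of length `n_lambda` (length 1 returns
#'   `lambda_max` alone).
#' @export
build_lambda_path <- function(X, y = NULL, alpha = 0.5, group_index,
                              Y = NULL, n_lambda = 50L,
                              lambda_min_ratio = 0.01, weights = NULL,
                              intercept = TRUE,
                              group_weight_mode = c("unit", "sqrt_size")) {
  group_weight_mode <- match.arg(group_weight_mode)
  stopifnot(n_lambda >= 1, lambda_min_ratio > 0, lambda_min_ratio < 1)
  lmax <- kkt_lambda_max(X, y, alpha, group_index, Y, weights, intercept,
                         group_weight_mode)
  if (n_lambda == 1L) return(lmax)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt to folds round-robin under a fold-local seed.
make_folds <- function(y, folds = 10L, seed = 0L, stratified = TRUE) {
  n <- length(y)
  if (n < folds) stop("need at least as many samples as folds")
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(folds), n))
    }
    fold
  })
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1   # constant columns pass through
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}

#' Cross-validated selection of the penalty parameters
#'
#' Wrapped channel/feature selection: for every `alpha` on the grid a
#' warm-started lambda path is fitted on each training fold (standardized
#' with training-fold statistics only) and scored by held-out classification
#' accuracy. The `(alpha, lambda)` pair with the highest mean CV accuracy is
#' chosen, with ties broken toward larger lambda (sparser models) and then
#' larger alpha; the final model is refit on the full data at the chosen
#' pair.
#'
#' Under the default `selection_rule = "1se"`, all pairs whose mean CV
#' accuracy is within one standard error (across folds) of the best are
#' treated as statistically tied, and the tie-break picks the sparsest of
#' them. `"best"` uses the raw argmax (ties still broken toward sparser);
#' the raw argmax of a CV curve is known to over-select, so `"1se"` is the
#' default for support recovery.
#'
#' @param X N x (p*d) feature matrix (unstandardized).
#' @param y Integer class labels `1..M`.
#' @param group_index Channel id per column of `X`.
#' @param alpha_grid Mixing parameters to search (default
#'   `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param n_lambda,lambda_min_ratio Lambda-path construction, see
#'   [build_lambda_path()].
#' @param folds Number of CV folds (default 10).
#' @param stratified Stratify folds by class (default TRUE).
#' @param fold_seed Seed of the fold assignment (default 0).
#' @param settings A [solver_settings()].
#' @param intercept Fit unpenalized intercepts (default TRUE).
#' @param selection_rule `"1se"` (default) or `"best"`, see Details.
#' @param channel_names,feature_labels Optional identifiers carried into the
#'   fitted model.
#'
#' @return Object of class `sgl_model`: final `beta`, `intercepts`,
#'   standardization parameters, `chosen` `(alpha, lambda)`, `cv_table`
#'   (data frame: alpha, lambda, mean_accuracy), `cv_accuracy` of the chosen
#'   pair, and the selection (see [sgl_select()]).
#' @export
sgl_cv <- function(X, y, group_index,
                   alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                   n_lambda = 50L, lambda_min_ratio = 0.01, folds = 10L,
                   stratified = TRUE, fold_seed = 0L,
                   settings = solver_settings(), intercept = TRUE,
                   selection_rule = c("1se", "best"),
                   channel_names = NULL, feature_labels = NULL) {
  selection_rule <- match.arg(selection_rule)
  X <- as.matrix(X)
  y <- as.integer(y)
  M <- max(y)
  if (length(unique(y)) < 2L) stop("need at least two classes")
  if (length(alpha_grid) == 0L) stop("alpha_grid must be nonempty")
  if (folds < 2L) stop("folds must be >= 2")
  fold <- make_folds(y, folds, fold_seed, stratified)
  for (k in seq_len(folds))
    if (length(unique(y[fold != k])) < M)
      stop("a class is absent from training fold ", k,
           "; use fewer folds or more data")

  std_full <- standardize_fit(X)
  Xs_full <- standardize_apply(X, std_full)
  # common lambda grid per alpha, built on the full standardized data
  paths <- lapply(alpha_grid, function(a)
    build_lambda_path(Xs_full, y, a, group_index, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio,
                      intercept = intercept,
                      group_weight_mode = settings$group_weight_mode))

  acc <- array(0, c(length(alpha_grid), n_lambda, folds))
  for (k in seq_len(folds)) {
    tr <- fold != k
    std <- standardize_fit(X[tr, , drop = FALSE])
    Xtr <- standardize_apply(X[tr, , drop = FALSE], std)
    Xte <- standardize_apply(X[!tr, , drop = FALSE], std)
    yte <- y[!tr]
    # per-observation penalty strength: a path value lambda earned on the
    # full N-sample design corresponds to lambda * n_train / N on a fold
    lam_scale <- sum(tr) / length(y)
    for (a in seq_along(alpha_grid)) {
      beta0 <- NULL; b00 <- NULL
      for (l in seq_len(n_lambda)) {
        fit <- sgl_fit(Xtr, y[tr], lambda = paths[[a]][l] * lam_scale,
                       alpha = alpha_grid[a], group_index = group_index,
                       intercept = intercept, settings = settings,
                       beta0 = beta0, b0 = b00)
        beta0 <- fit$beta; b00 <- fit$intercepts
        pred <- predict_classes(Xte, fit$beta, fit$intercepts)
        acc[a, l, k] <- mean(pred == yte)
      }
    }
  }
  mean_acc <- apply(acc, c(1, 2), mean)
  se_acc <- apply(acc, c(1, 2), stats::sd) / sqrt(folds)
  best_raw <- which(mean_acc == max(mean_acc), arr.ind = TRUE)
  best_raw <- best_raw[order(best_raw[, 2], -best_raw[, 1]), ,
                       drop = FALSE][1, ]
  tie_level <- if (selection_rule == "1se")
    max(mean_acc) - se_acc[best_raw[1], best_raw[2]]
  else max(mean_acc)
  # sparsest among the (near-)ties: larger lambda first, then larger alpha
  best <- which(mean_acc >= tie_level, arr.ind = TRUE)
  best <- best[order(best[, 2], -best[, 1]), , drop = FALSE][1, ]
  a_star <- alpha_grid[best[1]]
  l_star <- paths[[best[1]]][best[2]]

  # refit on the full (standardized) data, warm-started along the path
  beta0 <- NULL; b00 <- NULL
  for (l in seq_len(best[2])) {
    fit <- sgl_fit(Xs_full, y, lambda = paths[[best[1]]][l], alpha = a_star,
                   group_index = group_index, intercept = intercept,
                   settings = settings, beta0 = beta0, b0 = b00)
    beta0 <- fit$beta; b00 <- fit$intercepts
  }
  sel <- sgl_select(fit$beta, group_index)
  cv_table <- data.frame(
    alpha = rep(alpha_grid, each = n_lambda),
    lambda = unlist(paths),
    mean_accuracy = as.numeric(t(mean_acc)),
    se_accuracy = as.numeric(t(se_acc)))
  structure(
    list(beta = fit$beta, intercepts = fit$intercepts, fit = fit,
         center = std_full$center, scale = std_full$scale,
         group_index = group_index, classes = M,
         chosen = list(alpha = a_star, lambda = l_star),
         cv_accuracy = mean_acc[best[1], best[2]],
         cv_table = cv_table, selection = sel,
         selection_rule = selection_rule,
         alpha_grid = alpha_grid, folds = folds, fold_seed = fold_seed,
         channel_names = channel_names, feature_labels = feature_labels),
    class = "sgl_model"
  )
}

predict_classes <- function(X, beta, intercepts) {
  P <- class_probabilities(X, beta, intercepts)
  apply(P, 1L, which.max)                # ties break toward the lower class
}

#' Selected channels and features of a coefficient matrix
#'
#' A feature (row) is selected iff any of its free-class coefficients is
#' nonzero; a channel is selected iff any feature in its block is selected.
#'
#' @param beta (p*d) x (M-1) coefficient matrix.
#' @param group_index Channel id per row.
#' @return List: `features` (selected row indices), `channels` (selected
#'   group ids), `n_features`, `n_channels`, `prop_features`,
#'   `prop_channels` (percentages of the respective totals), and
#'   `per_channel` (data frame of per-channel selected-feature counts).
#' @export
sgl_select <- function(beta, group_index) {
  beta <- as.matrix(beta)
  nz_row <- rowSums(abs(beta)) > 0
  features <- which(nz_row)
  channels <- sort(unique(group_index[features]))
  all_ch <- unique(group_index)
  per_channel <- data.frame(
    channel = channels,
    n_features = vapply(channels, function(g)
      sum(nz_row[group_index == g]), integer(1)))
  list(features = features, channels = channels,
       n_features = length(features), n_channels = length(channels),
       prop_features = 100 * length(features) / nrow(beta),
       prop_channels = 100 * length(channels) / length(all_ch),
       per_channel = per_channel)
}

#' Predict from a cross-validated Sparse Group Lasso model
#'
#' Applies the stored standardization and returns argmax-probability classes
#' (ties toward the lower class index) or the probability matrix.
#'
#' @param object An `sgl_model` from [sgl_cv()].
#' @param newdata Feature matrix on the original (unstandardized) scale.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Integer class vector or N x M probability matrix.
#' @export
predict.sgl_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  Xs <- standardize_apply(as.matrix(newdata),
                          list(center = object$center,
                               scale = object$scale))
  if (type == "prob")
    return(class_probabilities(Xs, object$beta, object$intercepts))
  predict_classes(Xs, object$beta, object$intercepts)
}

#' @export
print.sgl_model <- function(x, ...) {
  cat(sprintf(
    "sgl_model: chosen alpha=%.2f lambda=%.4g (mean CV accuracy %.3f)\n",
    x$chosen$alpha, x$chosen$lambda, x$cv_accuracy))
  cat(sprintf("  selected %d/%d channels (%.1f%%), %d/%d features (%.1f%%)\n",
              x$selection$n_channels, length(unique(x$group_index)),
              x$selection$prop_channels, x$selection$n_features,
              length(x$group_index), x$selection$prop_features))
  invisible(x)
}

#' Holdout misclassification rate of a fitted model
#'
#' @param model An `sgl_model`.
#' @param X_test,y_test Holdout features (original scale) and labels.
#' @return Misclassification fraction in `[0, 1]`.
#' @export
evaluate_model <- function(model, X_test, y_test) {
  pred <- predict(model, X_test)
  mean(pred != as.integer(y_test))
}
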