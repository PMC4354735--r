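#' Extract the fused, grouped feature matrix from a trial set
#'
#' For every channel of every trial, concatenates band powers, time-domain
#' statistics, AR coefficients and wavelet features (in that fixed order) into
#' one row per trial. The columns of each channel form one contiguous group,
#' the unit on which the group penalty acts. Under the default configuration
#' each channel contributes d = 5 + 4 + 6 + 55 = 70 columns.
#'
#' @param trials A [trial_set()].
#' @param config A [feature_config()].
#'
#' @return An object of class `fused_features`: list with `values`
#'   (N x (p*d) matrix), `group_index` (channel id per column),
#'   `feature_labels`, `d`, `n_channels`, `channel_names`, `labels` (trial
#'   class labels carried through), and `fs`.
#' @export
extract_fused <- function(trials, config = feature_config()) {
  if (!inherits(trials, "trial_set")) stop("'trials' must be a trial_set")
  if (!inherits(config, "feature_config"))
    stop("'config' must be a feature_config")
  if (length(trials$trials) == 0L) stop("empty trial list")
  p <- trials$n_channels
  fs <- trials$fs
  if (any(config$bands[, 2] > fs / 2))
    stop("configured band edge above Nyquist (", fs / 2, " Hz)")

  ch1 <- channel_features(trials$trials[[1]][1, ], fs, config)
  d <- length(ch1)
  if (d != config$d)
    stop("internal dimension mismatch: got ", d, ", expected ", config$d)
  N <- length(trials$trials)
  X <- matrix(NA_real_, N, p * d)
  for (i in seq_len(N)) {
    tr <- trials$trials[[i]]
    for (ch in seq_len(p)) {
      f <- tryCatch(channel_features(tr[ch, ], fs, config),
                    error = function(e)
                      stop("trial ", i, ", channel ", ch, ": ",
                           conditionMessage(e), call. = FALSE))
      X[i, ((ch - 1L) * d + 1L):(ch * d)] <- f
    }
  }
  ch_names <- trials$channel_names
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(p))
  labels <- paste0(rep(ch_names, each = d), ".", rep(names(ch1), p))
  colnames(X) <- labels
  structure(
    list(values = X, group_index = rep(seq_len(p), each = d),
         feature_labels = labels, d = d, n_channels = p,
         channel_names = ch_names, labels = trials$labels, fs = fs),
    class = "fused_features"
  )
}

channel_features <- function(x, fs, config) {
  bp <- band_power(x, fs, config$bands, config$psd_method,
                   config$psd_window_sec)
  names(bp) <- paste0("bp_", config$bands[, 1], "_", config$bands[, 2])
  ts <- time_stats(x)
  names(ts) <- paste0("ts_", names(ts))
  ar <- ar_coefficients(x, config$ar_order, config$ar_method)
  names(ar) <- paste0("ar_", seq_along(ar))
  wv <- wavelet_features(x, config$wavelet_levels, config$entropy_epsilon,
                         config$wavelet_convention)
  names(wv) <- paste0("wv_", names(wv))
  c(bp, ts, ar, wv)
}

#' @export
print.fused_features <- function(x, ...) {
  cat("fused_features:", nrow(x$values), "trials x", ncol(x$values),
      "columns (", x$n_channels, "channels x", x$d, "features )\n")
  invisible(x)
}
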