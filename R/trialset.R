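#' Labeled multichannel trial set
#'
#' Container for a set of EEG trials. Each trial is a channels x samples
#' matrix; all trials must share the same channel count and sample count.
#'
#' @param trials List of numeric matrices, one per trial, rows = channels,
#'   columns = time samples (channel-major convention).
#' @param labels Integer class labels, one per trial, coded `1..M`. At least
#'   two distinct classes are required.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param channel_names Optional character vector of channel identifiers.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, fs, channel_names = NULL) {
  if (!is.list(trials) || length(trials) == 0L)
    stop("'trials' must be a non-empty list of channel x sample matrices")
  if (!all(vapply(trials, is.matrix, logical(1))))
    stop("every trial must be a numeric matrix (rows = channels)")
  dims <- vapply(trials, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all trials must share the same channel and sample counts; trial ",
         which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1],
         " differs")
  labels <- as.integer(labels)
  if (length(labels) != length(trials))
    stop("need exactly one label per trial")
  if (any(is.na(labels)) || any(labels < 1L))
    stop("labels must be positive integers 1..M")
  if (length(unique(labels)) < 2L)
    stop("labels must take at least two distinct values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar (Hz)")
  p <- dims[1, 1]
  if (!is.null(channel_names) && length(channel_names) != p)
    stop("channel_names length must equal the channel count (", p, ")")
  structure(
    list(trials = trials, labels = labels, fs = fs,
         channel_names = channel_names, n_channels = p,
         n_samples = dims[2, 1]),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat("trial_set:", length(x$trials), "trials,", x$n_channels, "channels x",
      x$n_samples, "samples @", x$fs, "Hz\n")
  cat("  classes:", paste(sprintf("%d (n=%d)", sort(unique(x$labels)),
                                  tabulate(x$labels)[sort(unique(x$labels))]),
                          collapse = ", "), "\n")
  invisible(x)
}
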