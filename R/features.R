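#' Feature-extraction configuration
#'
#' Defaults reproduce the standard motor-imagery fusion setup: band powers in
#' five rhythm bands (2-4, 4-8, 8-12, 12-18, 18-30 Hz), four time-domain
#' statistics, a sixth-order AR model, and a 6-level Db4 wavelet decomposition
#' (55 features per channel under the per-level entropy convention), for a
#' fused per-channel dimension of 70.
#'
#' @param bands Numeric 2-column matrix (or list of pairs) of band edges in Hz;
#'   edges must be strictly increasing and below the Nyquist frequency.
#' @param ar_order Order of the autoregressive model (default 6).
#' @param ar_method `"burg"` (default, suited to short EEG segments) or
#'   `"yule_walker"`.
#' @param wavelet Mother wavelet; only `"db4"` is implemented.
#' @param wavelet_levels Number of decomposition levels (default 6).
#' @param wavelet_convention `"per_level"` (default): energies of the 7
#'   terminal coefficient sets plus Shannon entropy, log-energy entropy and
#'   Teager-Kaiser mean/variance of each of the 12 per-level approximation and
#'   detail vectors (55 features). `"terminal"`: the same 4 statistics on the
#'   7 terminal sets only (35 features).
#' @param psd_method `"welch"` (default: 1-s Hann windows, 50% overlap) or
#'   `"periodogram"`.
#' @param psd_window_sec Welch window length in seconds (default 1).
#' @param entropy_epsilon Guard added inside the log of the log-energy entropy
#'   (default 1e-12).
#'
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(bands = cbind(c(2, 4, 8, 12, 18),
                                         c(4, 8, 12, 18, 30)),
                           ar_order = 6L,
                           ar_method = c("burg", "yule_walker"),
                           wavelet = "db4",
                           wavelet_levels = 6L,
                           wavelet_convention = c("per_level", "terminal"),
                           psd_method = c("welch", "periodogram"),
                           psd_window_sec = 1,
                           entropy_epsilon = 1e-12) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  bands <- as.matrix(bands)
  if (ncol(bands) != 2L || any(bands[, 1] >= bands[, 2]))
    stop("each band must be a (low, high) pair with low < high")
  ar_method <- match.arg(ar_method)
  wavelet_convention <- match.arg(wavelet_convention)
  psd_method <- match.arg(psd_method)
  if (!identical(wavelet, "db4")) stop("only the db4 wavelet is implemented")
  ar_order <- as.integer(ar_order)
  wavelet_levels <- as.integer(wavelet_levels)
  if (ar_order < 1L) stop("ar_order must be >= 1")
  if (wavelet_levels < 1L) stop("wavelet_levels must be >= 1")
  if (entropy_epsilon <= 0) stop("entropy_epsilon must be > 0")
  n_wavelet <- if (wavelet_convention == "per_level")
    (wavelet_levels + 1L) + 4L * 2L * wavelet_levels
  else
    (wavelet_levels + 1L) * 5L
  structure(
    list(bands = bands, ar_order = ar_order, ar_method = ar_method,
         wavelet = wavelet, wavelet_levels = wavelet_levels,
         wavelet_convention = wavelet_convention, psd_method = psd_method,
         psd_window_sec = psd_window_sec, entropy_epsilon = entropy_epsilon,
         d = nrow(bands) + 4L + ar_order + n_wavelet),
    class = "feature_config"
  )
}

# One-sided PSD estimate; Welch averages Hann-windowed 50%-overlap segments,
# the periodogram uses a single rectangular window over the whole signal.
psd_estimate <- function(x, fs, method = "welch", window_sec = 1) {
  n <- length(x)
  if (method == "welch") {
    L <- round(fs * window_sec)
    if (L < 8) L <- min(n, 8L)
    if (n < L)
      stop("signal too short for Welch PSD: length ", n,
           " < window length ", L, " (minimum ", L, " samples)")
    win <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
    step <- max(1L, L - floor(L / 2))
    starts <- seq(1L, n - L + 1L, by = step)
  } else {
    if (n < 8) stop("signal too short for a periodogram: length ", n,
                    " < minimum 8 samples")
    L <- n
    win <- rep(1, L)
    starts <- 1L
  }
  scale <- fs * sum(win^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * win
    P <- Mod(fft(seg))^2 / scale
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything but DC and (for even L) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd * dbl, df = fs / L)
}

#' Band power of a single-channel signal
#'
#' Integrates a power spectral density estimate over each configured frequency
#' band, capturing the rhythm-power modulation (ERD/ERS) that separates
#' imagined-movement classes. Bands are treated as half-open intervals
#' `(low, high]` so adjacent bands sharing an edge partition the spectrum.
#'
#' @param x Numeric signal vector (length >= 8).
#' @param fs Sampling frequency in Hz.
#' @param bands 2-column matrix of (low, high) band edges in Hz.
#' @param method `"welch"` or `"periodogram"`.
#' @param window_sec Welch window length in seconds.
#'
#' @return Nonnegative numeric vector with one power value per band.
#' @export
band_power <- function(x, fs, bands = feature_config()$bands,
                       method = c("welch", "periodogram"), window_sec = 1) {
  method <- match.arg(method)
  if (is.list(bands)) bands <- do.call(rbind, bands)
  bands <- as.matrix(bands)
  if (any(bands[, 2] > fs / 2))
    stop("band edge ", max(bands[, 2]), " Hz is above the Nyquist frequency ",
         fs / 2, " Hz")
  if (any(bands[, 1] >= bands[, 2]) || any(bands < 0))
    stop("band edges must satisfy 0 <= low < high")
  est <- psd_estimate(x, fs, method, window_sec)
  # half-open intervals (low, high]: adjacent bands share an edge without
  # counting its power twice, and DC is never attributed to a band
  apply(bands, 1L, function(b) {
    sel <- est$freq > b[1] & est$freq <= b[2]
    sum(est$psd[sel]) * est$df
  })
}

#' Time-domain statistics of a signal
#'
#' @param x Numeric vector of length >= 3.
#'
#' @return Numeric 4-vector: mean, standard deviation, mean absolute first
#'   difference, mean absolute second difference.
#' @export
time_stats <- function(x) {
  if (length(x) < 3L)
    stop("time_stats needs at least 3 samples (second difference undefined)")
  c(mean = mean(x), sd = stats::sd(x),
    mad1 = mean(abs(diff(x))),
    mad2 = mean(abs(diff(x, differences = 2L))))
}

#' Autoregressive model coefficients
#'
#' Fits an AR(`order`) model to the signal and returns the coefficient vector
#' (excluding the innovation variance).
#'
#' @param x Numeric signal vector, length > 2 * order, non-constant.
#' @param order AR order (default 6).
#' @param method `"burg"` (default) or `"yule_walker"`.
#'
#' @return Numeric vector of length `order`.
#' @export
ar_coefficients <- function(x, order = 6L,
                            method = c("burg", "yule_walker")) {
  method <- match.arg(method)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (length(x) <= 2L * order)
    stop("signal length ", length(x), " too short for AR(", order,
         "): need > ", 2L * order, " samples")
  if (stats::sd(x) == 0)
    stop("degenerate input: constant signal has no AR representation")
  fit <- if (method == "burg")
    stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  else
    stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
  as.numeric(fit$ar)
}

#' Resample a multichannel trial to a lower sampling rate
#'
#' Fourier-method resampling: the spectrum is truncated to the new bandwidth
#' and inverted, so band-limited content (including DC) is preserved exactly.
#' Only downsampling (or the identity) is supported.
#'
#' @param x Numeric matrix, rows = channels, columns = samples (a plain vector
#'   is treated as one channel).
#' @param fs_in Input sampling frequency in Hz.
#' @param fs_out Output sampling frequency in Hz; must be <= `fs_in`.
#'
#' @return Matrix with the same channel count and
#'   `round(ncol(x) * fs_out / fs_in)` samples.
#' @export
resample_trial <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in)
    stop("fs_out > fs_in: upsampling is out of scope")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (fs_out == fs_in) return(if (vec) drop(x) else x)
  n <- ncol(x)
  m <- as.integer(round(n * fs_out / fs_in))
  if (m < 2L) stop("output would have fewer than 2 samples")
  out <- t(apply(x, 1L, resample_fft, m = m))
  if (vec) drop(out) else out
}

resample_fft <- function(x, m) {
  n <- length(x)
  X <- fft(x)
  Y <- complex(m)
  npos <- ceiling(m / 2) - 1L            # positive-frequency bins kept
  Y[1] <- X[1]
  if (npos > 0) {
    Y[1 + seq_len(npos)] <- X[1 + seq_len(npos)]
    Y[m + 1 - seq_len(npos)] <- X[n + 1 - seq_len(npos)]
  }
  if (m %% 2 == 0)                        # fold the conjugate pair at Nyquist
    Y[m / 2 + 1] <- X[m / 2 + 1] + Conj(X[m / 2 + 1])
  Re(fft(Y, inverse = TRUE)) / n
}
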