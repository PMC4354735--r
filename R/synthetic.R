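#' Specification for simulated multichannel EEG trials
#'
#' Emulates the shape of a motor-imagery recording: 59 channels, 400 samples
#' at 100 Hz, two classes. A subset of "active" channels carries a band-limited
#' oscillation whose amplitude depends on the trial's class (an ERD/ERS-like
#' band-power modulation); every channel carries 1/f-colored background noise.
#' Oscillation phase and exact frequency are randomized per trial so band
#' power, not phase, carries the class information.
#'
#' @param n_channels Number of channels (default 59).
#' @param n_samples Samples per trial (default 400).
#' @param fs Sampling frequency in Hz (default 100).
#' @param n_trials_per_class Trials per class (default 100).
#' @param active_channels Channel ids carrying the class-dependent rhythm.
#' @param rhythm_band `(low, high)` Hz of the planted rhythm (default 8-12).
#' @param amplitude_by_class Rhythm amplitude per class on active channels
#'   (default `c(2, 0.5)`; must not be all equal).
#' @param noise_exponent Spectral exponent of the 1/f background (default 1).
#' @param noise_scale Background noise standard deviation (default 1).
#' @param seed RNG seed; generation is deterministic given the spec.
#'
#' @return List of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(n_channels = 59L, n_samples = 400L, fs = 100,
                         n_trials_per_class = 100L,
                         active_channels = c(10L, 13L, 27L, 29L, 31L, 44L),
                         rhythm_band = c(8, 12),
                         amplitude_by_class = c(2, 0.5),
                         noise_exponent = 1, noise_scale = 1, seed = 1L) {
  stopifnot(n_channels >= 1, n_samples >= 16, fs > 0,
            n_trials_per_class >= 1, length(rhythm_band) == 2,
            rhythm_band[1] < rhythm_band[2], rhythm_band[2] <= fs / 2,
            all(amplitude_by_class >= 0), noise_scale > 0)
  active_channels <- as.integer(active_channels)
  if (any(active_channels < 1L) || any(active_channels > n_channels))
    stop("active_channels must lie in 1..n_channels")
  if (length(active_channels) == 0L &&
      length(unique(amplitude_by_class)) > 1L)
    stop("class-dependent amplitudes require a non-empty active channel set")
  structure(
    list(n_channels = as.integer(n_channels),
         n_samples = as.integer(n_samples), fs = fs,
         n_trials_per_class = as.integer(n_trials_per_class),
         active_channels = active_channels, rhythm_band = rhythm_band,
         amplitude_by_class = amplitude_by_class,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         seed = as.integer(seed)),
    class = "eeg_sim_spec"
  )
}

# Spectrally shaped white noise with power spectrum ~ 1/f^exponent,
# normalized to unit standard deviation. A simple stand-in for EEG
# background activity, not a physiological model.
colored_noise <- function(n, exponent = 1) {
  w <- rnorm(n)
  W <- fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)                    # two-sided frequency index
  s <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(fft(W * s, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate simulated EEG trials
#'
#' @param spec An [eeg_sim_spec()].
#' @return A [trial_set()] with `n_classes * n_trials_per_class` trials
#'   (class labels `1..M` in block order).
#' @export
gen_eeg_trials <- function(spec = eeg_sim_spec()) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  M <- length(spec$amplitude_by_class)
  tsec <- (seq_len(spec$n_samples) - 1) / spec$fs
  with_seed(spec$seed, {
    trials <- list()
    labels <- integer(0)
    for (m in seq_len(M)) {
      for (i in seq_len(spec$n_trials_per_class)) {
        mat <- matrix(0, spec$n_channels, spec$n_samples)
        for (ch in seq_len(spec$n_channels))
          mat[ch, ] <- spec$noise_scale *
            colored_noise(spec$n_samples, spec$noise_exponent)
        for (ch in spec$active_channels) {
          f0 <- runif(1, spec$rhythm_band[1], spec$rhythm_band[2])
          ph <- runif(1, 0, 2 * pi)
          mat[ch, ] <- mat[ch, ] +
            spec$amplitude_by_class[m] * sin(2 * pi * f0 * tsec + ph)
        }
        trials[[length(trials) + 1L]] <- mat
        labels <- c(labels, m)
      }
    }
    trial_set(trials, labels, spec$fs,
              paste0("ch", seq_len(spec$n_channels)))
  })
}

#' Specification for a grouped sparse design simulation
#'
#' Testbed for solver support recovery: standard-normal design with known
#' group-sparse coefficients and labels drawn from the multinomial logistic
#' law at those coefficients.
#'
#' @param n Number of observations (default 400).
#' @param p_groups Number of groups (default 20).
#' @param d Features per group (default 5).
#' @param M Number of classes (default 2).
#' @param active_groups Ids of groups with nonzero coefficients (default 1:3).
#' @param within_group_density Fraction of rows nonzero inside an active group
#'   (default 0.6).
#' @param magnitude Absolute value of nonzero coefficients (default 1.5).
#' @param noise_sd Standard deviation of additive noise on the linear
#'   predictor (default 0: labels are noiseless draws from the model).
#' @param seed RNG seed.
#'
#' @return List of class `design_sim_spec`.
#' @export
design_sim_spec <- function(n = 400L, p_groups = 20L, d = 5L, M = 2L,
                            active_groups = 1:3,
                            within_group_density = 0.6, magnitude = 1.5,
                            noise_sd = 0, seed = 1L) {
  stopifnot(n >= 1, p_groups >= 1, d >= 1, M >= 2,
            within_group_density > 0, within_group_density <= 1,
            magnitude >= 0, noise_sd >= 0)
  active_groups <- as.integer(active_groups)
  if (any(active_groups < 1L) || any(active_groups > p_groups))
    stop("active_groups must lie in 1..p_groups")
  structure(
    list(n = as.integer(n), p_groups = as.integer(p_groups),
         d = as.integer(d), M = as.integer(M),
         active_groups = active_groups,
         within_group_density = within_group_density,
         magnitude = magnitude, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "design_sim_spec"
  )
}

#' Generate a grouped sparse design with labels from the logistic model
#'
#' @param spec A [design_sim_spec()].
#' @return List: `X` (n x p_groups*d), `y` (labels `1..M`), `Y` (indicator
#'   matrix), `beta_true` ((p_groups*d) x (M-1)), `group_index`,
#'   `active_groups`, `active_rows` (row indices of nonzero coefficients).
#' @export
gen_design <- function(spec = design_sim_spec()) {
  stopifnot(inherits(spec, "design_sim_spec"))
  pd <- spec$p_groups * spec$d
  K <- spec$M - 1L
  with_seed(spec$seed, {
    X <- matrix(rnorm(spec$n * pd), spec$n, pd)
    beta <- matrix(0, pd, K)
    k_nz <- max(1L, round(spec$within_group_density * spec$d))
    active_rows <- integer(0)
    for (g in spec$active_groups) {
      rows <- (g - 1L) * spec$d + sort(sample.int(spec$d, k_nz))
      active_rows <- c(active_rows, rows)
      signs <- matrix(sample(c(-1, 1), length(rows) * K, replace = TRUE),
                      length(rows), K)
      beta[rows, ] <- spec$magnitude * signs
    }
    eta <- X %*% beta
    if (spec$noise_sd > 0)
      eta <- eta + matrix(rnorm(length(eta), sd = spec$noise_sd),
                          nrow(eta), ncol(eta))
    eta <- cbind(eta, 0)
    P <- exp(eta - apply(eta, 1L, max))
    P <- P / rowSums(P)
    y <- vapply(seq_len(spec$n),
                function(i) sample.int(spec$M, 1L, prob = P[i, ]),
                integer(1))
    # degenerate draws: ensure both the fit and CV see every class
    if (length(unique(y)) < spec$M)
      y[seq_len(spec$M)] <- seq_len(spec$M)
    list(X = X, y = y, Y = indicator_matrix(y, spec$M), beta_true = beta,
         group_index = rep(seq_len(spec$p_groups), each = spec$d),
         active_groups = spec$active_groups,
         active_rows = sort(active_rows))
  })
}
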