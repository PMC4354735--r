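# Daubechies-4 (8-tap) decomposition filters.
db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)

# One analysis step: half-point symmetric extension by (filter length - 1) on
# each side, valid convolution, keep every second output.  Output length is
# floor((n + 7) / 2) for the 8-tap filter.
dwt_step <- function(x) {
  L <- 8L
  pad <- L - 1L
  n <- length(x)
  xe <- c(rev(x[seq_len(min(pad, n))]), x, rev(x)[seq_len(min(pad, n))])
  while (length(xe) < n + 2L * pad)      # tiny signals: re-reflect
    xe <- c(rev(xe[seq_len(pad)]), xe, rev(xe)[seq_len(pad)])[
      seq_len(n + 2L * pad)]
  nv <- length(xe) - L + 1L
  idx <- seq(2L, nv, by = 2L)
  lo <- rev(db4_dec_lo)
  hi <- rev(db4_dec_hi)
  cA <- vapply(idx, function(k) sum(lo * xe[k:(k + L - 1L)]), numeric(1))
  cD <- vapply(idx, function(k) sum(hi * xe[k:(k + L - 1L)]), numeric(1))
  list(cA = cA, cD = cD)
}

#' Multilevel Db4 wavelet decomposition
#'
#' @param x Numeric signal vector.
#' @param levels Number of decomposition levels.
#'
#' @return List with elements `cA` and `cD`, each a list of per-level
#'   coefficient vectors (level 1 first).
#' @export
dwt_db4 <- function(x, levels = 6L) {
  cA <- vector("list", levels)
  cD <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    if (length(cur) < 3L)
      stop("signal too short for a ", levels, "-level Db4 decomposition: ",
           "level ", l, " input has ", length(cur), " samples (need >= 3); ",
           "minimum original length is ", min_dwt_length(levels))
    s <- dwt_step(cur)
    cA[[l]] <- s$cA
    cD[[l]] <- s$cD
    cur <- s$cA
  }
  list(cA = cA, cD = cD)
}

min_dwt_length <- function(levels) {
  n <- 3L
  repeat {
    len <- n
    ok <- TRUE
    for (l in seq_len(levels)) {
      if (len < 3L) { ok <- FALSE; break }
      len <- (len + 7L) %/% 2L
    }
    if (ok) return(n)
    n <- n + 1L
  }
}

#' Shannon entropy of a coefficient vector
#'
#' Entropy of the normalized squared coefficients `q_i = c_i^2 / sum(c^2)`,
#' with the `0 * log(0) = 0` convention; a zero vector has entropy 0.
#'
#' @param v Numeric vector.
#' @return Nonnegative scalar (natural log).
#' @export
shannon_entropy <- function(v) {
  e <- v^2
  s <- sum(e)
  if (s == 0) return(0)
  q <- e / s
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Log-energy entropy of a coefficient vector
#'
#' `sum(log(c_i^2 + epsilon))`; the epsilon guard keeps zero coefficients
#' finite.
#'
#' @param v Numeric vector.
#' @param epsilon Positive guard (default 1e-12).
#' @return Scalar.
#' @export
log_energy_entropy <- function(v, epsilon = 1e-12) {
  sum(log(v^2 + epsilon))
}

#' Teager-Kaiser energy operator
#'
#' `psi(x_n) = x_n^2 - x_{n-1} * x_{n+1}`, evaluated at the interior samples.
#'
#' @param v Numeric vector of length >= 3.
#' @return Numeric vector of length `length(v) - 2`.
#' @export
teager_kaiser <- function(v) {
  n <- length(v)
  if (n < 3L) stop("Teager-Kaiser operator needs at least 3 samples")
  v[2:(n - 1L)]^2 - v[1:(n - 2L)] * v[3:n]
}

#' Wavelet feature vector of a single-channel signal
#'
#' Six-level Db4 decomposition summarized as (default `per_level` convention):
#' energies of the 7 terminal coefficient sets (cA6, cD6, ..., cD1), then for
#' each of the 12 per-level vectors (cA1..cA6, cD1..cD6) the Shannon entropy,
#' log-energy entropy, and Teager-Kaiser mean and variance - 55 features.
#' The `terminal` convention computes the 4 statistics on the 7 terminal sets
#' only (35 features).
#'
#' @param x Numeric signal vector.
#' @param levels Number of decomposition levels (default 6).
#' @param epsilon Log-energy entropy guard.
#' @param convention `"per_level"` (default) or `"terminal"`.
#'
#' @return Named numeric vector (length 55 for the default configuration).
#' @export
wavelet_features <- function(x, levels = 6L, epsilon = 1e-12,
                             convention = c("per_level", "terminal")) {
  convention <- match.arg(convention)
  dec <- dwt_db4(x, levels)
  terminal <- c(dec$cA[levels], rev(dec$cD))      # cA_L, cD_L, ..., cD_1
  names(terminal) <- c(paste0("cA", levels), paste0("cD", levels:1))
  energies <- vapply(terminal, function(v) sum(v^2), numeric(1))
  names(energies) <- paste0("en_", names(terminal))
  stats4 <- function(v) {
    tk <- teager_kaiser(v)
    c(sh = shannon_entropy(v), le = log_energy_entropy(v, epsilon),
      tkm = mean(tk),
      tkv = if (length(tk) >= 2L) stats::var(tk) else 0)
  }
  if (convention == "per_level") {
    vecs <- c(dec$cA, dec$cD)
    names(vecs) <- c(paste0("cA", seq_len(levels)),
                     paste0("cD", seq_len(levels)))
  } else {
    vecs <- terminal
  }
  extra <- unlist(lapply(seq_along(vecs), function(i) {
    s <- stats4(vecs[[i]])
    names(s) <- paste0(names(s), "_", names(vecs)[i])
    s
  }))
  c(energies, extra)
}
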