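#' Multinomial class probabilities under the reference-class logistic model
#'
#' Computes `p_im = exp(eta_im) / sum_l exp(eta_il)` where
#' `eta_im = x_i' beta_m + b0_m` for the M-1 free classes and `eta_iM = 0`
#' for the reference class, with log-sum-exp stabilization.
#'
#' @param X N x (p*d) design matrix.
#' @param beta (p*d) x (M-1) coefficient matrix of the free classes.
#' @param intercepts Optional numeric (M-1)-vector of unpenalized intercepts.
#'
#' @return N x M matrix of probabilities; rows sum to 1, reference class last.
#' @export
class_probabilities <- function(X, beta, intercepts = NULL) {
  beta <- as.matrix(beta)
  if (ncol(X) != nrow(beta))
    stop("dimension mismatch: X has ", ncol(X), " columns but beta has ",
         nrow(beta), " rows")
  eta <- linear_predictor(X, beta, intercepts)
  mx <- row_max(eta)
  ex <- exp(eta - mx)
  ex / rowSums(ex)
}

linear_predictor <- function(X, beta, intercepts = NULL) {
  K <- ncol(beta)
  eta <- X %*% beta
  if (!is.null(intercepts)) {
    if (length(intercepts) != K)
      stop("intercepts must have length ncol(beta)")
    eta <- eta + rep(intercepts, each = nrow(eta))
  }
  cbind(eta, 0)                          # reference class fixed at zero
}

row_max <- function(m) {
  mx <- m[, 1L]
  for (k in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, k])
  mx
}

#' Indicator matrix of class labels
#'
#' @param y Integer labels in `1..M`.
#' @param M Number of classes (default `max(y)`).
#' @return N x M zero/one matrix with one 1 per row.
#' @export
indicator_matrix <- function(y, M = max(y)) {
  y <- as.integer(y)
  if (any(y < 1L) || any(y > M)) stop("labels must lie in 1..M")
  Y <- matrix(0, length(y), M)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

check_indicator <- function(Y) {
  if (!all(Y %in% c(0, 1)) || any(abs(rowSums(Y) - 1) > 1e-12))
    stop("Y must be a zero/one indicator matrix with exactly one 1 per row")
}

#' Multinomial log-likelihood
#'
#' `l(beta) = sum_i sum_m y_im * (eta_im - log sum_l exp(eta_il))`; always
#' nonpositive.
#'
#' @inheritParams class_probabilities
#' @param Y N x M indicator matrix (see [indicator_matrix()]).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(X, Y, beta, intercepts = NULL) {
  check_indicator(Y)
  eta <- linear_predictor(X, beta, intercepts)
  mx <- row_max(eta)
  lse <- mx + log(rowSums(exp(eta - mx)))
  sum(Y * eta) - sum(lse)
}

#' Sparse Group Lasso penalty
#'
#' `lambda * ((1 - alpha) * sum_J w_J ||beta^(J)||_2 + alpha * sum_j |beta_j|)`
#' where a group J is the block of all free-class coefficients of one channel.
#' `alpha = 1` gives the Lasso, `alpha = 0` the (weighted) Group Lasso.
#'
#' @param beta (p*d) x (M-1) coefficient matrix.
#' @param lambda Nonnegative penalty weight.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param group_index Integer channel id per row of `beta` (contiguous
#'   blocks).
#' @param weights Per-group nonnegative weights (default 1).
#' @return Scalar penalty value.
#' @export
sgl_penalty <- function(beta, lambda, alpha, group_index, weights = NULL) {
  beta <- as.matrix(beta)
  check_penalty(lambda, alpha)
  gi <- check_groups(group_index, nrow(beta))
  w <- resolve_weights(weights, gi)
  ssq <- rowsum(rowSums(beta * beta), group_index, reorder = FALSE)
  gnorm <- sqrt(as.numeric(ssq))         # in first-appearance (block) order
  lambda * ((1 - alpha) * sum(w * gnorm) + alpha * sum(abs(beta)))
}

check_penalty <- function(lambda, alpha) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
}

# Validates contiguity and returns ids/starts/lengths (in row order).
check_groups <- function(group_index, n_rows) {
  if (length(group_index) != n_rows)
    stop("group_index length must match the coefficient row count")
  r <- rle(as.integer(group_index))
  if (anyDuplicated(r$values))
    stop("group blocks must be contiguous")
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  list(ids = r$values, starts = starts, lengths = r$lengths)
}

resolve_weights <- function(weights, gi, mode = "unit", K = 1L) {
  if (!is.null(weights)) {
    if (length(weights) != length(gi$ids))
      stop("need one weight per group")
    if (any(weights < 0)) stop("group weights must be >= 0")
    return(as.numeric(weights))
  }
  if (mode == "sqrt_size") sqrt(gi$lengths * K) else rep(1, length(gi$ids))
}

#' Gradient of the negative log-likelihood
#'
#' `q = X' (P_free - Y_free)`, the exact gradient of `-l(beta)` with respect
#' to the free-class coefficients.
#'
#' @inheritParams log_likelihood
#' @return (p*d) x (M-1) matrix.
#' @export
sgl_gradient <- function(X, Y, beta, intercepts = NULL) {
  P <- class_probabilities(X, beta, intercepts)
  K <- ncol(P) - 1L
  crossprod(X, P[, seq_len(K), drop = FALSE] - Y[, seq_len(K), drop = FALSE])
}

#' Per-feature curvature blocks of the negative log-likelihood
#'
#' Block-diagonal restriction of the multinomial Hessian: for feature row j,
#' `H_jj = sum_i x_ij^2 * (diag(p_i) - p_i p_i')` over the free classes.
#' Cross-feature blocks are treated as zero; this is the curvature the
#' blockwise subproblem uses, and each block is symmetric PSD.
#'
#' @inheritParams class_probabilities
#' @return Array of dimension (M-1) x (M-1) x (p*d).
#' @export
hessian_blocks <- function(X, beta, intercepts = NULL) {
  P <- class_probabilities(X, beta, intercepts)
  K <- ncol(P) - 1L
  pd <- ncol(X)
  X2 <- X * X
  H <- array(0, c(K, K, pd))
  for (m1 in seq_len(K))
    for (m2 in m1:K) {
      wv <- if (m1 == m2) P[, m1] * (1 - P[, m1]) else -P[, m1] * P[, m2]
      v <- as.numeric(crossprod(X2, wv))
      H[m1, m2, ] <- v
      H[m2, m1, ] <- v
    }
  H
}

#' Penalized objective
#'
#' `-l(beta) + lambda * Phi(beta)`: the convex criterion the solver minimizes.
#'
#' @inheritParams log_likelihood
#' @inheritParams sgl_penalty
#' @return Scalar objective value.
#' @export
sgl_objective <- function(X, Y, beta, lambda, alpha, group_index,
                          weights = NULL, intercepts = NULL) {
  -log_likelihood(X, Y, beta, intercepts) +
    sgl_penalty(beta, lambda, alpha, group_index, weights)
}
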