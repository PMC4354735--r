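# Independent oracles used across the suite. These deliberately share no code
# with the package's solver: a long-run FISTA proximal-gradient route for the
# penalized logistic problem, a proximal-gradient route for the quadratic
# subproblem, and golden-section search for the one-dimensional inner problem.

# Penalized multinomial objective, computed from scratch (reference class 0).
oracle_objective <- function(X, Y, beta, lam, alpha, gi,
                             w = rep(1, length(unique(gi))),
                             intercepts = NULL) {
  eta <- X %*% beta
  if (!is.null(intercepts)) eta <- eta + rep(intercepts, each = nrow(eta))
  eta <- cbind(eta, 0)
  mx <- apply(eta, 1, max)
  ll <- sum(Y * eta) - sum(mx + log(rowSums(exp(eta - mx))))
  gids <- unique(gi)
  gl <- sum(vapply(seq_along(gids), function(g)
    w[g] * sqrt(sum(beta[gi == gids[g], , drop = FALSE]^2)), numeric(1)))
  -ll + lam * ((1 - alpha) * gl + alpha * sum(abs(beta)))
}

# FISTA on -loglik + lambda*Phi with the closed-form sparse-group-lasso prox
# (soft-threshold then group shrinkage). Run long enough to serve as a
# high-precision optimum on small instances.
fista_sgl <- function(X, Y, lam, alpha, gi,
                      w = rep(1, length(unique(gi))),
                      iters = 30000, intercept = TRUE) {
  n <- nrow(X); K <- ncol(Y) - 1L; pd <- ncol(X)
  Xa <- if (intercept) cbind(1, X) else X
  off <- if (intercept) 1L else 0L
  L <- 0.5 * (svd(Xa, nu = 0, nv = 0)$d[1])^2
  gids <- unique(gi)
  th <- matrix(0, pd + off, K); z <- th; tk <- 1
  for (it in seq_len(iters)) {
    eta <- cbind(Xa %*% z, 0)
    mx <- apply(eta, 1, max)
    P <- exp(eta - mx); P <- P / rowSums(P)
    G <- crossprod(Xa, P[, 1:K, drop = FALSE] - Y[, 1:K, drop = FALSE])
    v <- z - G / L
    b <- v
    bp <- v[(off + 1):nrow(v), , drop = FALSE]
    bp <- sign(bp) * pmax(abs(bp) - lam * alpha / L, 0)
    for (g in seq_along(gids)) {
      rows <- which(gi == gids[g])
      nr <- sqrt(sum(bp[rows, ]^2))
      sc <- if (nr > 0) max(0, 1 - lam * (1 - alpha) * w[g] / (L * nr)) else 0
      bp[rows, ] <- sc * bp[rows, ]
    }
    b[(off + 1):nrow(b), ] <- bp
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b + ((tk - 1) / tk1) * (b - th)
    th <- b; tk <- tk1
  }
  beta <- th[(off + 1):nrow(th), , drop = FALSE]
  ints <- if (intercept) th[1, ] else NULL
  list(beta = beta, intercepts = ints,
       obj = oracle_objective(X, Y, beta, lam, alpha, gi, w, ints))
}

# Proximal gradient on the penalized quadratic model
# Q(b) = q'(b - bt) + 0.5 (b - bt)' H (b - bt), H block-diagonal per row.
prox_quad_sgl <- function(q, H, beta_tilde, lam, alpha, gi,
                          w = rep(1, length(unique(gi))), iters = 50000) {
  pd <- nrow(q); K <- ncol(q)
  gids <- unique(gi)
  Hmul <- function(b) {
    out <- matrix(0, pd, K)
    for (j in seq_len(pd))
      out[j, ] <- H[, , j] %*% b[j, ]
    out
  }
  L <- max(vapply(seq_len(pd), function(j)
    max(abs(eigen(H[, , j], symmetric = TRUE,
                  only.values = TRUE)$values)), numeric(1)))
  L <- max(L, 1e-8)
  b <- beta_tilde; z <- b; tk <- 1
  for (it in seq_len(iters)) {
    G <- q + Hmul(z - beta_tilde)
    v <- z - G / L
    v <- sign(v) * pmax(abs(v) - lam * alpha / L, 0)
    for (g in seq_along(gids)) {
      rows <- which(gi == gids[g])
      nr <- sqrt(sum(v[rows, ]^2))
      sc <- if (nr > 0) max(0, 1 - lam * (1 - alpha) * w[g] / (L * nr)) else 0
      v[rows, ] <- sc * v[rows, ]
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- v + ((tk - 1) / tk1) * (v - b)
    b <- v; tk <- tk1
  }
  b
}

quad_penalized_value <- function(b, q, H, beta_tilde, lam, alpha, gi,
                                 w = rep(1, length(unique(gi)))) {
  d <- b - beta_tilde
  quad <- 0
  for (j in seq_len(nrow(q)))
    quad <- quad + 0.5 * sum(d[j, ] * (H[, , j] %*% d[j, ]))
  gids <- unique(gi)
  gl <- sum(vapply(seq_along(gids), function(g)
    w[g] * sqrt(sum(b[gi == gids[g], , drop = FALSE]^2)), numeric(1)))
  sum(q * d) + quad + lam * ((1 - alpha) * gl + alpha * sum(abs(b)))
}

# Golden-section minimization of the inner one-dimensional function
# w(b) = c*b + h*b^2/2 + gamma*sqrt(b^2+r) + xi*|b| (convex, unimodal).
omega_fn <- function(b, cc, h, gamma, r, xi) {
  cc * b + 0.5 * h * b^2 + gamma * sqrt(b^2 + r) + xi * abs(b)
}

golden_min <- function(cc, h, gamma, r, xi, tol = 1e-13) {
  B <- (abs(cc) + gamma + xi) / max(h, 1e-12) + 1
  lo <- -B; hi <- B
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- omega_fn(x1, cc, h, gamma, r, xi)
  f2 <- omega_fn(x2, cc, h, gamma, r, xi)
  it <- 0L
  # relative interval tolerance: an absolute one is unreachable below the
  # floating-point spacing when the initial bracket is wide (tiny h)
  while (hi - lo > tol * (1 + abs(lo) + abs(hi)) && it < 500L) {
    it <- it + 1L
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo)
      f1 <- omega_fn(x1, cc, h, gamma, r, xi)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo)
      f2 <- omega_fn(x2, cc, h, gamma, r, xi)
    }
  }
  (lo + hi) / 2
}

# Small random penalized-logistic instance with grouped design.
random_instance <- function(seed, n = 50, p = 4, d = 3, M = 2,
                            signal = 1.2) {
  set.seed(seed)
  pd <- p * d
  X <- scale(matrix(rnorm(n * pd), n, pd))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  gi <- rep(seq_len(p), each = d)
  K <- M - 1L
  bt <- matrix(0, pd, K)
  bt[seq_len(d), 1] <- signal
  if (K > 1) bt[(d + 1):(2 * d), 2] <- -signal
  eta <- cbind(X %*% bt, 0)
  P <- exp(eta - apply(eta, 1, max))
  P <- P / rowSums(P)
  y <- vapply(seq_len(n), function(i) sample.int(M, 1, prob = P[i, ]),
              integer(1))
  y[seq_len(M)] <- seq_len(M)            # guarantee all classes present
  list(X = X, y = y, Y = indicator_matrix(y, M), gi = gi, M = M)
}
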