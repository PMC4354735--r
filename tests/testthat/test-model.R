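test_that("class probabilities are uniform at beta = 0 and normalized", {
  set.seed(10)
  X <- matrix(rnorm(30), 10, 3)
  P <- class_probabilities(X, matrix(0, 3, 2))
  expect_equal(P, matrix(1 / 3, 10, 3))
  Pr <- class_probabilities(X, matrix(rnorm(6), 3, 2), intercepts = c(1, -1))
  expect_equal(rowSums(Pr), rep(1, 10), tolerance = 1e-12)
})

test_that("a single log-odds coefficient gives the closed-form probability", {
  P <- class_probabilities(matrix(1), matrix(log(3)))
  expect_equal(P[1, 1], 0.75)
})

test_that("probabilities stay finite and normalized at huge coefficients", {
  X <- matrix(c(1, -1), 2, 1)
  P <- class_probabilities(X, matrix(1e3))
  expect_true(all(is.finite(P)))
  expect_equal(rowSums(P), c(1, 1))
})

test_that("log-likelihood matches closed forms and is bounded by zero", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(1:2, 10)
  Y <- indicator_matrix(y)
  expect_equal(log_likelihood(X, Y, matrix(0, 2, 1)), -20 * log(2))

  # two points x = 1 with labels 1, 2 and b = ln 3
  expect_equal(log_likelihood(matrix(c(1, 1)), indicator_matrix(c(1, 2)),
                              matrix(log(3))),
               log(0.75) + log(0.25))

  # perfect separation: likelihood rises monotonically to 0
  Xs <- matrix(c(1, -1)); Ys <- indicator_matrix(c(1, 2))
  ll <- vapply(c(1, 2, 5, 10, 20), function(b)
    log_likelihood(Xs, Ys, matrix(b)), numeric(1))
  expect_true(all(diff(ll) > 0))
  expect_true(all(ll < 0))
  expect_error(log_likelihood(X, Y * 2, matrix(0, 2, 1)), "indicator")
})

test_that("penalty endpoints are exactly the Lasso and Group Lasso", {
  set.seed(12)
  beta <- matrix(rnorm(12), 6, 2)
  gi <- rep(1:2, each = 3)
  lam <- 0.7
  expect_identical(sgl_penalty(beta, lam, 1, gi), lam * sum(abs(beta)))
  gl <- sqrt(sum(beta[1:3, ]^2)) + sqrt(sum(beta[4:6, ]^2))
  expect_equal(sgl_penalty(beta, lam, 0, gi), lam * gl)
  expect_identical(sgl_penalty(matrix(0, 6, 2), lam, 0.5, gi), 0)
  w <- c(2, 0.5)
  expect_equal(sgl_penalty(beta, lam, 0, gi, weights = w),
               lam * (2 * sqrt(sum(beta[1:3, ]^2)) +
                        0.5 * sqrt(sum(beta[4:6, ]^2))))
})

test_that("penalty is positively homogeneous", {
  set.seed(13)
  beta <- matrix(rnorm(8), 4, 2)
  gi <- rep(1:2, each = 2)
  for (t in c(0, 0.3, 2, 10))
    expect_equal(sgl_penalty(t * beta, 1, 0.4, gi),
                 t * sgl_penalty(beta, 1, 0.4, gi), tolerance = 1e-12)
})

test_that("gradient matches central finite differences", {
  set.seed(14)
  n <- 10; pd <- 6; M <- 3
  X <- matrix(rnorm(n * pd), n, pd)
  y <- c(1, 2, 3, sample(1:3, n - 3, replace = TRUE))
  Y <- indicator_matrix(y, M)
  beta <- matrix(rnorm(pd * 2, sd = 0.5), pd, 2)
  G <- sgl_gradient(X, Y, beta)
  eps <- 1e-6
  for (j in seq_len(pd))
    for (k in 1:2) {
      bp <- beta; bp[j, k] <- bp[j, k] + eps
      bm <- beta; bm[j, k] <- bm[j, k] - eps
      fd <- (-log_likelihood(X, Y, bp) + log_likelihood(X, Y, bm)) / (2 * eps)
      expect_lt(abs(G[j, k] - fd), 1e-6)
    }
})

test_that("the score vanishes when labels equal model probabilities", {
  set.seed(15)
  X <- matrix(rnorm(40), 20, 2)
  beta <- matrix(rnorm(2), 2, 1)
  P <- class_probabilities(X, beta)
  expect_equal(max(abs(sgl_gradient(X, P, beta))), 0, tolerance = 1e-12)
})

test_that("Hessian blocks are symmetric PSD and match the binary formula", {
  set.seed(16)
  n <- 15; pd <- 4
  X <- matrix(rnorm(n * pd), n, pd)
  beta <- matrix(rnorm(pd * 2, sd = 0.4), pd, 2)
  H <- hessian_blocks(X, beta)
  for (j in seq_len(pd)) {
    expect_equal(H[, , j], t(H[, , j]))
    expect_gt(min(eigen(H[, , j], symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
  }
  # binary case: scalar sum x_ij^2 p_i (1 - p_i)
  b2 <- matrix(rnorm(pd), pd, 1)
  H2 <- hessian_blocks(X, b2)
  p <- class_probabilities(X, b2)[, 1]
  for (j in seq_len(pd))
    expect_equal(H2[1, 1, j], sum(X[, j]^2 * p * (1 - p)), tolerance = 1e-12)
  # saturated probabilities make the curvature vanish
  Hs <- hessian_blocks(X, 1e4 * b2)
  expect_lt(max(abs(Hs)), 1e-8)
})

test_that("objective at beta = 0 is N log M", {
  set.seed(17)
  X <- matrix(rnorm(30), 10, 3)
  y <- c(1, 2, 3, sample(1:3, 7, replace = TRUE))
  expect_equal(sgl_objective(X, indicator_matrix(y, 3), matrix(0, 3, 2),
                             0.5, 0.5, c(1, 1, 2)),
               10 * log(3))
})
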