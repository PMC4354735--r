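tight <- solver_settings(outer_tol = 1e-14, middle_tol = 1e-12,
                         inner_tol = 1e-12, max_outer = 400L)

test_that("inner update reproduces the closed-form branches", {
  # r = 0 branch: threshold at xi + gamma
  expect_equal(inner_coordinate_update(c = 5, h = 1, gamma = 1, r = 0,
                                       xi = 1), -3)
  expect_identical(inner_coordinate_update(c = 1.5, h = 1, gamma = 1, r = 0,
                                           xi = 1), 0)
  expect_equal(inner_coordinate_update(c = -4, h = 2, gamma = 0, r = 3,
                                       xi = 1), (4 - 1) / 2)
  # |c| <= xi zero branch with active group norm
  expect_identical(inner_coordinate_update(c = 0.4, h = 1, gamma = 0.5,
                                           r = 1, xi = 0.5), 0)
  # h = 0 parks the coordinate at zero
  expect_identical(inner_coordinate_update(c = 2, h = 0, gamma = 1, r = 1,
                                           xi = 0.1), 0)
})

test_that("inner update minimizes omega as well as golden-section search", {
  b <- inner_coordinate_update(c = 2, h = 1, gamma = 0.5, r = 1, xi = 0.5,
                               tol = 1e-12)
  bg <- golden_min(2, 1, 0.5, 1, 0.5)
  expect_lt(abs(b - bg), 1e-6)
  expect_lt(omega_fn(b, 2, 1, 0.5, 1, 0.5) -
              omega_fn(bg, 2, 1, 0.5, 1, 0.5), 1e-10)

  set.seed(20)
  for (i in 1:100) {
    cc <- rnorm(1, sd = 3); h <- rexp(1); gamma <- rexp(1, 2)
    r <- rexp(1); xi <- rexp(1, 2)
    b <- inner_coordinate_update(cc, h, gamma, r, xi, tol = 1e-12)
    bg <- golden_min(cc, h, gamma, r, xi)
    expect_lt(omega_fn(b, cc, h, gamma, r, xi) -
                omega_fn(bg, cc, h, gamma, r, xi), 1e-8)
  }
})

test_that("group zero test handles its analytic special cases", {
  expect_true(group_zero_test(rep(0, 4), lambda = 1, alpha = 0.5))
  g <- c(3, -1, 0.5)
  # alpha = 0 reduces to the group-lasso norm test
  expect_identical(group_zero_test(g, lambda = 4, alpha = 0),
                   sqrt(sum(g^2)) <= 4)
  expect_identical(group_zero_test(g, lambda = 3, alpha = 0),
                   sqrt(sum(g^2)) <= 3)
  # alpha = 1: zero iff every coordinate is below the soft threshold
  expect_true(group_zero_test(g, lambda = 3.5, alpha = 1))
  expect_false(group_zero_test(g, lambda = 2.5, alpha = 1))
})

test_that("quadratic subproblem matches closed forms and a prox oracle", {
  set.seed(21)
  # single group, alpha = 0, isotropic curvature: group soft-thresholding
  d <- 4; h <- 2
  q <- matrix(rnorm(d), d, 1)
  H <- array(0, c(1, 1, d)); H[1, 1, ] <- h
  lam <- 0.8
  bt <- matrix(0, d, 1)
  sol <- solve_quadratic_subproblem(q, H, bt, lambda = lam, alpha = 0,
                                    group_index = rep(1, d),
                                    settings = tight)
  closed <- max(0, 1 - lam / sqrt(sum(q^2))) * (-q / h)
  expect_equal(sol, closed, tolerance = 1e-8)

  # q = 0 at beta_tilde = 0 keeps everything at zero
  z <- solve_quadratic_subproblem(matrix(0, d, 1), H, bt, 0.5, 0.5,
                                  rep(1, d))
  expect_identical(z, matrix(0, d, 1))

  # multi-group random instances against an independent prox-gradient oracle
  for (seed in 1:3) {
    set.seed(seed)
    pd <- 8; K <- 2; gi <- rep(1:2, each = 4)
    q <- matrix(rnorm(pd * K), pd, K)
    H <- array(0, c(K, K, pd))
    for (j in seq_len(pd)) {
      A <- matrix(rnorm(K * K), K)
      H[, , j] <- crossprod(A) + 0.5 * diag(K)
    }
    btl <- matrix(rnorm(pd * K, sd = 0.3), pd, K)
    lam <- 0.6; alpha <- 0.3
    ours <- solve_quadratic_subproblem(q, H, btl, lam, alpha, gi,
                                       settings = tight)
    orac <- prox_quad_sgl(q, H, btl, lam, alpha, gi, iters = 20000)
    v1 <- quad_penalized_value(ours, q, H, btl, lam, alpha, gi)
    v2 <- quad_penalized_value(orac, q, H, btl, lam, alpha, gi)
    expect_lt(abs(v1 - v2) / (abs(v2) + 1), 1e-7)
    # agreement of the zero pattern with the oracle's group norms
    for (g in 1:2) {
      nr_o <- sqrt(sum(orac[gi == g, ]^2))
      nr_u <- sqrt(sum(ours[gi == g, ]^2))
      if (nr_o < 1e-8) expect_identical(nr_u, 0)
    }
  }
})

test_that("the whole-path zero test agrees with the prox oracle groupwise", {
  set.seed(22)
  pd <- 8; gi <- rep(1:2, each = 4)
  for (i in 1:20) {
    q <- matrix(rnorm(pd, sd = 2), pd, 1)
    H <- array(0, c(1, 1, pd)); H[1, 1, ] <- rexp(pd) + 0.2
    lam <- rexp(1) + 0.1; alpha <- runif(1)
    bt <- matrix(0, pd, 1)
    orac <- prox_quad_sgl(q, H, bt, lam, alpha, gi, iters = 20000)
    for (g in 1:2) {
      pred_zero <- group_zero_test(q[gi == g, ], lam, alpha)
      orac_zero <- sqrt(sum(orac[gi == g, ]^2)) < 1e-8
      expect_identical(pred_zero, orac_zero)
    }
  }
})

test_that("descent direction at zero is a descent direction", {
  g <- c(2, -0.1, -3)
  expect_identical(descent_direction_at_zero(c(0.1, -0.2), 1, 0.5),
                   c(0, 0))
  expect_equal(descent_direction_at_zero(g, 1, 0), -g)
  lam <- 1; alpha <- 0.4
  d <- descent_direction_at_zero(g, lam, alpha)
  # directional derivative of Q + lambda*Phi at 0 along d, by finite step
  H <- array(0, c(1, 1, 3)); H[1, 1, ] <- 1
  val <- function(t) quad_penalized_value(matrix(t * d), matrix(g),
                                          H, matrix(0, 3, 1), lam, alpha,
                                          rep(1, 3))
  expect_lt((val(1e-6) - val(0)) / 1e-6, 0)
})

test_that("fit matches the FISTA oracle on a seeded random instance", {
  inst <- random_instance(42)
  lam <- 0.2 * kkt_lambda_max(inst$X, inst$y, 0.5, inst$gi)
  fit <- sgl_fit(inst$X, inst$y, lambda = lam, alpha = 0.5,
                 group_index = inst$gi, settings = tight)
  orac <- fista_sgl(inst$X, inst$Y, lam, 0.5, inst$gi, iters = 30000)
  expect_lt(abs(fit$value - orac$obj) / abs(orac$obj), 1e-6)
  expect_lt(fit$kkt, 1e-5)
})

test_that("penalty dominance gives the exact all-zero solution", {
  for (seed in 1:3) {
    inst <- random_instance(seed)
    lmax <- kkt_lambda_max(inst$X, inst$y, 0.5, inst$gi)
    f1 <- sgl_fit(inst$X, inst$y, lambda = lmax, alpha = 0.5,
                  group_index = inst$gi)
    expect_true(all(f1$beta == 0))
    f2 <- sgl_fit(inst$X, inst$y, lambda = 0.9 * lmax, alpha = 0.5,
                  group_index = inst$gi)
    expect_true(any(f2$beta != 0))
  }
})

test_that("the objective trace is non-increasing and refits are bitwise equal", {
  inst <- random_instance(7)
  lam <- 0.1 * kkt_lambda_max(inst$X, inst$y, 0.25, inst$gi)
  f1 <- sgl_fit(inst$X, inst$y, lambda = lam, alpha = 0.25,
                group_index = inst$gi)
  expect_true(all(diff(f1$objective) <= 1e-10))
  f2 <- sgl_fit(inst$X, inst$y, lambda = lam, alpha = 0.25,
                group_index = inst$gi)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$intercepts, f2$intercepts)
})

test_that("reported zeros are hard zeros", {
  inst <- random_instance(9)
  lam <- 0.5 * kkt_lambda_max(inst$X, inst$y, 0.5, inst$gi)
  fit <- sgl_fit(inst$X, inst$y, lambda = lam, alpha = 0.5,
                 group_index = inst$gi)
  small <- abs(fit$beta) < 1e-8
  expect_true(all(fit$beta[small] == 0))
  expect_true(any(small))                # the penalty does produce zeros here
})

test_that("KKT residual separates optima from arbitrary points", {
  inst <- random_instance(12)
  lmax <- kkt_lambda_max(inst$X, inst$y, 0.5, inst$gi, intercept = FALSE)
  expect_lt(kkt_residual(inst$X, inst$Y, matrix(0, ncol(inst$X), 1),
                         lmax, 0.5, inst$gi,
                         intercepts = NULL), 1e-10)
  set.seed(1)
  bad <- matrix(rnorm(ncol(inst$X)), ncol(inst$X), 1)
  expect_gt(kkt_residual(inst$X, inst$Y, bad, 0.1 * lmax, 0.5, inst$gi),
            0.01)
})

test_that("an unconverged fit is flagged, not silently returned", {
  inst <- random_instance(3)
  lam <- 0.05 * kkt_lambda_max(inst$X, inst$y, 0.5, inst$gi)
  fit <- sgl_fit(inst$X, inst$y, lambda = lam, alpha = 0.5,
                 group_index = inst$gi,
                 settings = solver_settings(outer_tol = 1e-15,
                                            max_outer = 2L))
  expect_false(fit$converged)
})
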