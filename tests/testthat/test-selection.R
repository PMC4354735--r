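small_design <- function(seed = 1) {
  gen_design(design_sim_spec(n = 120, p_groups = 6, d = 3,
                             active_groups = 1:2, magnitude = 2,
                             seed = seed))
}

test_that("the lambda path is geometric and starts at an all-zero fit", {
  sim <- small_design()
  Xs <- scale(sim$X)
  path <- build_lambda_path(Xs, sim$y, 0.5, sim$group_index,
                            n_lambda = 12)
  expect_length(path, 12L)
  expect_true(all(diff(path) < 0))
  ratios <- path[-1] / path[-length(path)]
  expect_lt(diff(range(ratios)), 1e-12)
  fit <- sgl_fit(Xs, sim$y, lambda = path[1], alpha = 0.5,
                 group_index = sim$group_index)
  expect_true(all(fit$beta == 0))
  expect_length(build_lambda_path(Xs, sim$y, 0.5, sim$group_index,
                                  n_lambda = 1), 1L)
})

test_that("stratified folds balance classes and catch infeasible requests", {
  y <- rep(1:2, each = 30)
  f <- sgleeg:::make_folds(y, 10, seed = 0)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10)
    expect_equal(sum(y[f == k] == 1), 3L)
  f2 <- sgleeg:::make_folds(y, 10, seed = 0)
  expect_identical(f, f2)

  # a singleton class necessarily vanishes from one training fold
  y_bad <- c(rep(1, 59), 2)
  expect_error(
    sgl_cv(matrix(rnorm(180), 60, 3), y_bad, rep(1, 3), alpha_grid = 0.5,
           n_lambda = 3, folds = 10),
    "fewer folds")
})

test_that("cross-validation selects a high-accuracy sparse model", {
  # 3 informative groups of 20, strong effect, n = 300
  sim <- gen_design(design_sim_spec(n = 300, p_groups = 20, d = 5,
                                    active_groups = 1:3, magnitude = 3,
                                    seed = 2))
  m <- sgl_cv(sim$X, sim$y, sim$group_index, alpha_grid = c(0.25, 0.75),
              n_lambda = 10, folds = 10)
  expect_equal(nrow(m$cv_table), 2L * 10L)
  expect_gte(m$cv_accuracy, 0.9)
  expect_true(m$chosen$alpha %in% c(0.25, 0.75))
  # selected sets are exactly the nonzero pattern of beta
  expect_equal(m$selection$features,
               which(rowSums(abs(m$beta)) > 0))
  expect_equal(m$selection$channels,
               sort(unique(sim$group_index[m$selection$features])))
})

test_that("re-running the CV with the same seeds reproduces the choice", {
  sim <- small_design(3)
  m1 <- sgl_cv(sim$X, sim$y, sim$group_index, alpha_grid = 0.5,
               n_lambda = 8, folds = 5)
  m2 <- sgl_cv(sim$X, sim$y, sim$group_index, alpha_grid = 0.5,
               n_lambda = 8, folds = 5)
  expect_identical(m1$chosen, m2$chosen)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$selection$channels, m2$selection$channels)
})

test_that("selection extraction reports counts and proportions", {
  beta <- matrix(0, 6, 2)
  gi <- rep(1:2, each = 3)
  s0 <- sgl_select(beta, gi)
  expect_length(s0$features, 0L)
  expect_length(s0$channels, 0L)
  expect_equal(s0$prop_features, 0)

  beta[5, 2] <- 0.3
  s1 <- sgl_select(beta, gi)
  expect_equal(s1$features, 5L)
  expect_equal(s1$channels, 2L)
  expect_equal(s1$n_features, 1L)
  expect_equal(s1$prop_features, 100 / 6)
  expect_equal(s1$prop_channels, 50)
  expect_equal(s1$per_channel$n_features, 1L)
})

test_that("evaluation returns the misclassification fraction", {
  # constant (all-zero) model predicts class 1 everywhere
  model <- structure(
    list(beta = matrix(0, 3, 1), intercepts = 0,
         center = rep(0, 3), scale = rep(1, 3),
         group_index = rep(1, 3), classes = 2L),
    class = "sgl_model")
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(1:2, each = 10)
  expect_equal(evaluate_model(model, X, y), 0.5)
  expect_equal(evaluate_model(model, X, rep(1, 20)), 0)
})

test_that("the 1se rule never selects a denser model than the raw argmax", {
  sim <- small_design(4)
  m_best <- sgl_cv(sim$X, sim$y, sim$group_index, alpha_grid = 0.5,
                   n_lambda = 10, folds = 5, selection_rule = "best")
  m_1se <- sgl_cv(sim$X, sim$y, sim$group_index, alpha_grid = 0.5,
                  n_lambda = 10, folds = 5, selection_rule = "1se")
  expect_gte(m_1se$chosen$lambda, m_best$chosen$lambda)
  expect_lte(m_1se$selection$n_features, m_best$selection$n_features)
})
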