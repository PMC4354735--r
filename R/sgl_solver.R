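#' Solver settings for the three-loop Sparse Group Lasso estimator
#'
#' @param outer_tol Relative objective-change tolerance of the outer
#'   coordinate-gradient-descent loop (default 1e-6).
#' @param middle_tol Coefficient-change tolerance of the blockwise middle loop
#'   (default 1e-8).
#' @param inner_tol Tolerance of the inner coordinate updates and root finder
#'   (default 1e-8).
#' @param max_outer,max_middle,max_inner Iteration caps (200 / 200 / 1000).
#' @param zero_threshold Group norm below which a group counts as "at zero"
#'   for the re-entry branch (default 1e-10).
#' @param ls_contraction Backtracking contraction factor (default 0.5).
#' @param ls_sufficient Armijo sufficient-decrease constant (default 1e-4).
#' @param max_backtracks Line-search cap (default 50).
#' @param group_weight_mode `"unit"` (default) or `"sqrt_size"` group weights.
#'
#' @return List of class `solver_settings`. The solver is deterministic: no
#'   setting involves randomness.
#' @export
solver_settings <- function(outer_tol = 1e-6, middle_tol = 1e-8,
                            inner_tol = 1e-8, max_outer = 200L,
                            max_middle = 200L, max_inner = 1000L,
                            zero_threshold = 1e-10, ls_contraction = 0.5,
                            ls_sufficient = 1e-4, max_backtracks = 50L,
                            group_weight_mode = c("unit", "sqrt_size")) {
  group_weight_mode <- match.arg(group_weight_mode)
  stopifnot(outer_tol > 0, middle_tol > 0, inner_tol > 0, max_outer >= 1,
            max_middle >= 1, max_inner >= 1, zero_threshold > 0,
            ls_contraction > 0, ls_contraction < 1, ls_sufficient > 0,
            ls_sufficient < 1)
  structure(list(outer_tol = outer_tol, middle_tol = middle_tol,
                 inner_tol = inner_tol, max_outer = as.integer(max_outer),
                 max_middle = as.integer(max_middle),
                 max_inner = as.integer(max_inner),
                 zero_threshold = zero_threshold,
                 ls_contraction = ls_contraction,
                 ls_sufficient = ls_sufficient,
                 max_backtracks = as.integer(max_backtracks),
                 group_weight_mode = group_weight_mode),
            class = "solver_settings")
}

#' Fit the Sparse-Group-Lasso-penalized multinomial logistic model
#'
#' Three-loop estimator: the outer loop builds a quadratic model of the
#' negative log-likelihood at the current iterate (exact gradient plus
#' per-feature block-diagonal curvature), the middle loop solves the
#' penalized quadratic subproblem by blockwise coordinate descent over
#' channel groups, and an Armijo backtracking line search on the true
#' penalized objective accepts the step. Zeros are produced exactly by the
#' group subgradient test and coordinate thresholding.
#'
#' @param X N x (p*d) design matrix (standardize beforehand, or use
#'   [sgl_cv()] which standardizes per training fold).
#' @param y Integer class labels `1..M` (alternatively pass `Y`).
#' @param lambda Nonnegative penalty weight.
#' @param alpha Mixing parameter in `[0, 1]`; 1 = Lasso, 0 = Group Lasso.
#' @param group_index Integer channel id per column of `X` (contiguous
#'   blocks).
#' @param Y Optional N x M indicator matrix instead of `y`.
#' @param weights Optional per-group penalty weights; by default determined
#'   by `settings$group_weight_mode`.
#' @param intercept Fit unpenalized per-class intercepts (default TRUE).
#' @param settings A [solver_settings()].
#' @param beta0,b0 Optional warm-start coefficients and intercepts.
#'
#' @return Object of class `sgl_fit`: `beta` ((p*d) x (M-1)), `intercepts`,
#'   `objective` (trace over outer iterations), `kkt` (KKT residual at the
#'   solution), `iterations`, `converged`, plus the penalty specification.
#' @export
sgl_fit <- function(X, y = NULL, lambda, alpha = 0.5, group_index,
                    Y = NULL, weights = NULL, intercept = TRUE,
                    settings = solver_settings(), beta0 = NULL, b0 = NULL) {
  X <- as.matrix(X)
  if (is.null(Y)) {
    if (is.null(y)) stop("provide labels 'y' or an indicator matrix 'Y'")
    Y <- indicator_matrix(y)
  }
  check_indicator(Y)
  M <- ncol(Y)
  K <- M - 1L
  pd <- ncol(X)
  check_penalty(lambda, alpha)
  gi <- check_groups(group_index, pd)
  w <- resolve_weights(weights, gi, settings$group_weight_mode, K)

  beta <- if (is.null(beta0)) matrix(0, pd, K) else as.matrix(beta0)
  if (nrow(beta) != pd || ncol(beta) != K) stop("beta0 has wrong shape")
  ints <- if (intercept) {
    if (is.null(b0)) numeric(K) else as.numeric(b0)
  } else NULL

  # hot-loop objective: validation done once above, penalty via group rowsum
  pen <- function(b)
    lambda * ((1 - alpha) *
                sum(w * sqrt(rowsum(rowSums(b * b), group_index,
                                    reorder = FALSE))) +
              alpha * sum(abs(b)))
  obj <- function(b, i0) {
    eta <- linear_predictor(X, b, i0)
    mx <- row_max(eta)
    -(sum(Y * eta) - sum(mx + log(rowSums(exp(eta - mx))))) + pen(b)
  }
  trace <- numeric(0)
  converged <- FALSE
  f_cur <- obj(beta, ints)
  if (!is.finite(f_cur)) stop("non-finite objective at the starting point")
  it <- 0L
  while (it < settings$max_outer) {
    it <- it + 1L
    if (intercept) {
      ints <- update_intercepts(X, Y, beta, ints)
      f_cur <- obj(beta, ints)
    }
    q <- sgl_gradient(X, Y, beta, ints)
    H <- hessian_blocks(X, beta, ints)
    beta_hat <- cpp_solve_subproblem(
      q, as.numeric(H), beta, beta, gi$starts - 1L, gi$lengths,
      lambda, alpha, w, settings$middle_tol, settings$inner_tol,
      settings$max_middle, settings$max_inner, settings$zero_threshold)
    delta <- beta_hat - beta
    if (max(abs(delta)) == 0) { trace <- c(trace, f_cur); converged <- TRUE; break }
    # Armijo backtracking on the true penalized objective
    pen_new <- pen(beta_hat)
    pen_old <- pen(beta)
    D <- sum(q * delta) + pen_new - pen_old
    t <- 1
    accepted <- FALSE
    for (bt in seq_len(settings$max_backtracks)) {
      cand <- beta + t * delta
      if (t == 1) cand <- beta_hat              # keep exact zeros at full step
      f_new <- obj(cand, ints)
      if (is.finite(f_new) &&
          f_new <= f_cur + settings$ls_sufficient * t * min(D, 0) &&
          f_new <= f_cur) {
        beta <- cand
        f_prev <- f_cur
        f_cur <- f_new
        accepted <- TRUE
        break
      }
      t <- t * settings$ls_contraction
    }
    trace <- c(trace, f_cur)
    if (!accepted) { converged <- TRUE; break }  # no further descent possible
    if (abs(f_prev - f_cur) <= settings$outer_tol * (abs(f_prev) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!is.finite(f_cur)) stop("solver diverged to a non-finite objective")
  # polish: one more subproblem pass so reported zeros are exact (thresholded)
  # rather than small floats left by a partial line-search step
  q <- sgl_gradient(X, Y, beta, ints)
  H <- hessian_blocks(X, beta, ints)
  beta_hat <- cpp_solve_subproblem(
    q, as.numeric(H), beta, beta, gi$starts - 1L, gi$lengths,
    lambda, alpha, w, settings$middle_tol, settings$inner_tol,
    settings$max_middle, settings$max_inner, settings$zero_threshold)
  f_hat <- obj(beta_hat, ints)
  if (is.finite(f_hat) && f_hat <= f_cur + 1e-12 * (abs(f_cur) + 1)) {
    beta <- beta_hat
    f_cur <- min(f_cur, f_hat)
  }
  kkt <- kkt_residual(X, Y, beta, lambda, alpha, group_index, w, ints)
  structure(
    list(beta = beta, intercepts = ints, lambda = lambda, alpha = alpha,
         group_index = group_index, weights = w, objective = trace,
         value = f_cur, kkt = kkt, iterations = it, converged = converged,
         classes = M),
    class = "sgl_fit"
  )
}

#' @export
print.sgl_fit <- function(x, ...) {
  nz <- sum(rowSums(abs(x$beta)) > 0)
  cat(sprintf(
    "sgl_fit: lambda=%.4g alpha=%.2f | %d/%d nonzero rows, %d/%d groups\n",
    x$lambda, x$alpha, nz, nrow(x$beta),
    length(unique(x$group_index[rowSums(abs(x$beta)) > 0])),
    length(unique(x$group_index))))
  cat(sprintf("  objective %.6g after %d outer iterations (KKT %.2e)%s\n",
              x$value, x$iterations, x$kkt,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

# Damped Newton steps on the unpenalized intercepts (coefficients fixed).
# Few steps per call suffice: the outer loop revisits the intercepts anyway.
update_intercepts <- function(X, Y, beta, ints, tol = 1e-10, max_it = 5L) {
  K <- ncol(Y) - 1L
  for (i in seq_len(max_it)) {
    P <- class_probabilities(X, beta, ints)
    g <- colSums(P[, seq_len(K), drop = FALSE] - Y[, seq_len(K), drop = FALSE])
    if (max(abs(g)) < tol) break
    Pf <- P[, seq_len(K), drop = FALSE]
    Hm <- crossprod(Pf, -Pf)
    diag(Hm) <- colSums(Pf * (1 - Pf))
    step <- tryCatch(solve(Hm + diag(1e-10, K), g),
                     error = function(e) g / max(diag(Hm), 1e-10))
    ll0 <- log_likelihood(X, Y, beta, ints)
    t <- 1
    repeat {
      cand <- ints - t * step
      if (log_likelihood(X, Y, beta, cand) >= ll0 || t < 1e-8) break
      t <- t / 2
    }
    ints <- ints - t * step
  }
  ints
}

#' Solve the penalized quadratic subproblem by blockwise coordinate descent
#'
#' Minimizes `Q(beta) + lambda * Phi(beta)` where `Q` is the quadratic model
#' `q'(beta - beta_tilde) + 0.5 (beta - beta_tilde)' H (beta - beta_tilde)`
#' with per-feature block-diagonal curvature `H`. Groups are visited in cyclic
#' order; each group is first screened by [group_zero_test()] and otherwise
#' minimized by the inner modified coordinate descent.
#'
#' @param q Gradient matrix at the expansion point ((p*d) x (M-1)).
#' @param H Curvature array from [hessian_blocks()].
#' @param beta_tilde Expansion point.
#' @param lambda,alpha,group_index,weights Penalty specification.
#' @param settings A [solver_settings()].
#' @param beta_init Starting coefficients (defaults to `beta_tilde`).
#'
#' @return Coefficient matrix minimizing the penalized quadratic model.
#' @export
solve_quadratic_subproblem <- function(q, H, beta_tilde, lambda, alpha,
                                       group_index, weights = NULL,
                                       settings = solver_settings(),
                                       beta_init = beta_tilde) {
  q <- as.matrix(q)
  gi <- check_groups(group_index, nrow(q))
  w <- resolve_weights(weights, gi, settings$group_weight_mode, ncol(q))
  check_penalty(lambda, alpha)
  cpp_solve_subproblem(q, as.numeric(H), as.matrix(beta_tilde),
                       as.matrix(beta_init), gi$starts - 1L, gi$lengths,
                       lambda, alpha, w, settings$middle_tol,
                       settings$inner_tol, settings$max_middle,
                       settings$max_inner, settings$zero_threshold)
}

#' Group zero test
#'
#' Subgradient condition for an entire group to be exactly zero:
#' `|| S(g_J, lambda * alpha) ||_2 <= lambda * (1 - alpha) * w_J`, where `S`
#' is elementwise soft-thresholding and `g_J` is the group gradient evaluated
#' with the group's coefficients at zero.
#'
#' @param g_J Numeric group gradient (vector or matrix).
#' @param lambda,alpha Penalty parameters.
#' @param weight Group weight `w_J` (default 1).
#' @return `TRUE` iff the group solves to exactly zero.
#' @export
group_zero_test <- function(g_J, lambda, alpha, weight = 1) {
  check_penalty(lambda, alpha)
  s <- soft_threshold(as.numeric(g_J), lambda * alpha)
  sqrt(sum(s^2)) <= lambda * (1 - alpha) * weight
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

#' Inner coordinate update
#'
#' Minimizes the one-dimensional function
#' `w(b) = c*b + h*b^2/2 + gamma*sqrt(b^2 + r) + xi*|b|` arising for one
#' coordinate of a group: closed-form soft-thresholding when `r = 0` or
#' `gamma = 0`, zero when `|c| <= xi`, otherwise the root of the stationarity
#' condition found by a safeguarded bracketing root finder.
#'
#' @param c Linear term (gradient plus cross-class curvature contribution).
#' @param h Curvature diagonal entry (must be >= 0; 0 returns 0).
#' @param gamma Group penalty weight `lambda * (1 - alpha) * w_J`.
#' @param r Squared L2 norm of the group's other coefficients.
#' @param xi Lasso penalty weight `lambda * alpha`.
#' @param tol Root-finder tolerance (default 1e-8).
#' @return The minimizing coordinate value (exactly 0 on the zero branches).
#' @export
inner_coordinate_update <- function(c, h, gamma, r, xi, tol = 1e-8) {
  stopifnot(h >= 0, r >= 0, gamma >= 0, xi >= 0)
  cpp_inner_update(c, h, gamma, r, xi, tol)
}

#' Descent direction for a group parked at zero
#'
#' When a group sits at zero but fails the zero test, the blockwise loop
#' re-enters it along the soft-thresholded negative gradient:
#' `Delta_i = 0` if `|g_i| <= lambda * alpha`, otherwise
#' `Delta_i = -(g_i - lambda * alpha * sign(g_i))`.
#'
#' @param g_J Numeric group gradient at zero.
#' @param lambda,alpha Penalty parameters.
#' @return Vector (same shape as `g_J`) pointing into the descent halfspace.
#' @export
descent_direction_at_zero <- function(g_J, lambda, alpha) {
  check_penalty(lambda, alpha)
  d <- -soft_threshold(g_J, lambda * alpha)
  attributes(d) <- attributes(g_J)
  d
}

#' KKT residual of the penalized problem
#'
#' Maximum violation of the sparse-group-lasso subgradient conditions at
#' `beta`: zero groups must pass the group zero test, zero coordinates inside
#' active groups must satisfy `|g_j| <= lambda * alpha`, and nonzero
#' coordinates must have a vanishing total (sub)gradient. Zero at the exact
#' optimum.
#'
#' @inheritParams sgl_fit
#' @param beta Coefficient matrix to check.
#' @param intercepts Optional intercepts (their gradient is included when
#'   given).
#' @return Nonnegative scalar.
#' @export
kkt_residual <- function(X, Y, beta, lambda, alpha, group_index,
                         weights = NULL, intercepts = NULL) {
  beta <- as.matrix(beta)
  gi <- check_groups(group_index, nrow(beta))
  w <- resolve_weights(weights, gi)
  G <- sgl_gradient(X, Y, beta, intercepts)
  xi <- lambda * alpha
  res <- 0
  for (k in seq_along(gi$ids)) {
    rows <- gi$starts[k]:(gi$starts[k] + gi$lengths[k] - 1L)
    B <- beta[rows, , drop = FALSE]
    Gg <- G[rows, , drop = FALSE]
    gn <- sqrt(sum(B^2))
    gamma <- lambda * (1 - alpha) * w[k]
    if (gn == 0) {
      s <- soft_threshold(as.numeric(Gg), xi)
      res <- max(res, sqrt(sum(s^2)) - gamma)
    } else {
      grp_term <- gamma * B / gn
      nz <- B != 0
      if (any(nz))
        res <- max(res, max(abs(Gg[nz] + grp_term[nz] +
                                  xi * sign(B[nz]))))
      if (any(!nz))
        res <- max(res, max(abs(Gg[!nz] + grp_term[!nz]) - xi))
    }
  }
  if (!is.null(intercepts)) {
    K <- ncol(Y) - 1L
    P <- class_probabilities(X, beta, intercepts)
    res <- max(res, max(abs(colSums(P[, seq_len(K), drop = FALSE] -
                                      Y[, seq_len(K), drop = FALSE]))))
  }
  max(res, 0)
}

#' Smallest penalty weight with an all-zero solution
#'
#' Computes the head of the regularization path: the smallest `lambda` for
#' which every group passes the zero test at `beta = 0` (with intercepts at
#' their null-model optimum when `intercept = TRUE`).
#'
#' @inheritParams sgl_fit
#' @return Positive scalar `lambda_max`.
#' @export
kkt_lambda_max <- function(X, y = NULL, alpha = 0.5, group_index, Y = NULL,
                           weights = NULL, intercept = TRUE,
                           group_weight_mode = c("unit", "sqrt_size")) {
  group_weight_mode <- match.arg(group_weight_mode)
  X <- as.matrix(X)
  if (is.null(Y)) Y <- indicator_matrix(y)
  check_indicator(Y)
  K <- ncol(Y) - 1L
  gi <- check_groups(group_index, ncol(X))
  w <- resolve_weights(weights, gi, group_weight_mode, K)
  beta0 <- matrix(0, ncol(X), K)
  ints <- if (intercept) {
    freq <- colMeans(Y)
    log(freq[seq_len(K)] / freq[K + 1L])
  } else NULL
  G <- sgl_gradient(X, Y, beta0, ints)
  lam <- vapply(seq_along(gi$ids), function(k) {
    rows <- gi$starts[k]:(gi$starts[k] + gi$lengths[k] - 1L)
    g <- as.numeric(G[rows, , drop = FALSE])
    gmax <- max(abs(g))
    if (gmax == 0) return(0)
    if (alpha >= 1) return(gmax)
    if (alpha == 0) return(sqrt(sum(g^2)) / max(w[k], 1e-300))
    f <- function(l) sqrt(sum(soft_threshold(g, l * alpha)^2)) -
      l * (1 - alpha) * w[k]
    stats::uniroot(f, c(1e-12, gmax / alpha), tol = 1e-12)$root
  }, numeric(1))
  # round up marginally so the returned value itself passes every zero test
  # despite the finite root-finder tolerance
  max(lam) * (1 + 1e-9)
}
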