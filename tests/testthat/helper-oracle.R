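# Independent numerical oracles used to cross-check the package's solvers.
# These deliberately share no code with the implementation: the group-lasso
# oracle is accelerated proximal gradient (FISTA with restart) on the
# explicit dense objective; the ridge oracle is generic BFGS.

# Minimize -loglik(b0, beta) + sum_j lambda_j ||beta_{G_j}||_2 over a dense
# design X (no intercept column; the intercept is the unpenalized first
# coefficient internally).  `groups`: list of column-index vectors into X;
# `lambda`: per-group penalty levels (already including gamma * w * sqrt(p)).
oracle_group_lasso <- function(X, y, groups, lambda, maxit = 200000,
                               tol = 1e-11) {
  X <- as.matrix(X)
  Xt <- cbind(1, X)
  n <- nrow(Xt)
  step <- 1 / (0.25 * svd(Xt, nu = 0, nv = 0)$d[1]^2 + 1e-12)
  idxs <- lapply(groups, function(g) g + 2L)  # 1-based, past the intercept
  smooth_grad <- function(b) {
    eta <- drop(Xt %*% b)
    -drop(crossprod(Xt, y - stats::plogis(eta)))
  }
  objective <- function(b) {
    eta <- drop(Xt %*% b)
    ll <- sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
    pen <- sum(vapply(seq_along(idxs), function(j) {
      lambda[j] * sqrt(sum(b[idxs[[j]]]^2))
    }, 0.0))
    -ll + pen
  }
  prox <- function(b) {
    for (j in seq_along(idxs)) {
      ii <- idxs[[j]]
      nrm <- sqrt(sum(b[ii]^2))
      thr <- lambda[j] * step
      b[ii] <- if (nrm <= thr) 0 else b[ii] * (1 - thr / nrm)
    }
    b
  }
  b <- numeric(ncol(Xt))
  b[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-9), 1e-9))
  v <- b
  tk <- 1
  f_prev <- objective(b)
  for (it in seq_len(maxit)) {
    b_new <- prox(v - step * smooth_grad(v))
    f_new <- objective(b_new)
    if (f_new > f_prev) {       # restart the momentum
      v <- b
      tk <- 1
      b_new <- prox(v - step * smooth_grad(v))
      f_new <- objective(b_new)
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- b_new + ((tk - 1) / t_new) * (b_new - b)
    delta <- max(abs(b_new - b))
    b <- b_new
    tk <- t_new
    f_prev <- f_new
    if (delta < tol && it > 50) break
  }
  list(intercept = b[1], beta = b[-1], objective = objective(b), iters = it)
}

# Generic smooth-optimizer oracle for the ridge-penalized logistic refit.
oracle_ridge_logistic <- function(X, y, ridge) {
  Xt <- cbind(1, as.matrix(X))
  gam <- c(0, rep(ridge, ncol(Xt) - 1L))
  negpen <- function(b) {
    eta <- drop(Xt %*% b)
    -(sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta)))) -
        sum(gam * b^2) / 2)
  }
  grad <- function(b) {
    eta <- drop(Xt %*% b)
    -(drop(crossprod(Xt, y - stats::plogis(eta))) - gam * b)
  }
  fit <- stats::optim(numeric(ncol(Xt)), negpen, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  eta <- drop(Xt %*% fit$par)
  list(coef = fit$par,
       loglik = sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta)))))
}

# Map a grouped_design to the oracle's dense inputs.
oracle_inputs <- function(design, gamma, weights) {
  X <- as.matrix(design_matrix(design, force = TRUE))
  groups <- lapply(seq_len(nrow(design$groups)), function(g) {
    seq(design$groups$col_start[g], design$groups$col_end[g]) - 1L
  })
  lambda <- gamma * weights * sqrt(design$groups$size)
  list(X = X, groups = groups, lambda = lambda)
}

# Small random case-control dataset for solver tests (no special structure).
random_dataset <- function(n = 40, L = 3, seed = 1) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * L, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2)), n, L)
  y <- sample(rep(0:1, length.out = n))
  genotype_dataset(G, y, seed = seed)
}
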