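#' Control parameters for group-lasso fitting and adaptive reweighting
#'
#' @param tol Coefficient-change convergence tolerance of the outer IRLS
#'   loop (default 1e-5).
#' @param maxit_irls Cap on IRLS outer iterations per fit (default 50).
#' @param maxit_cd Cap on coordinate-descent passes per IRLS step
#'   (default 100).
#' @param ufloor Floor on the IRLS working weights p(1-p) (default 1e-5),
#'   guarding against division blow-up at fitted probabilities near 0/1.
#' @param kkt_tol Relative slack of the KKT screening/certification bound
#'   (default 1e-4).
#' @param n_folds Cross-validation folds (default 5).
#' @param n_gamma Length of the penalty grid (default 25).
#' @param gamma_min_ratio Smallest grid value as a fraction of
#'   `gamma_max` (default 0.05).
#' @param cv_rule `"1se"` (largest gamma within one standard error of the
#'   minimum, favoring sparsity) or `"min"`.
#' @param cv_loss `"deviance"` (default) or `"class"` (misclassification).
#' @param dfmax Cap on the active-set size along a penalty path; grid
#'   points whose model grows beyond it are abandoned (they are never
#'   competitive in cross-validation).  Default 50.
#' @param weight_power Exponent a in the adaptive update
#'   `w_j = ||beta_j||^-a` (default 1).
#' @param max_reweight_iter Cap on adaptive reweighting iterations
#'   (default 10).
#' @param recv_gamma Re-select gamma by cross-validation at every
#'   reweighting iteration (default TRUE); FALSE reuses iteration 0's gamma.
#' @return A named list of class `agl_control`.
#' @export
agl_control <- function(tol = 1e-5, maxit_irls = 50, maxit_cd = 100,
                        ufloor = 1e-5, kkt_tol = 1e-4, n_folds = 5,
                        n_gamma = 25, gamma_min_ratio = 0.05,
                        cv_rule = c("1se", "min"),
                        cv_loss = c("deviance", "class"),
                        dfmax = 50, weight_power = 1,
                        max_reweight_iter = 10, recv_gamma = TRUE) {
  structure(list(tol = tol, maxit_irls = as.integer(maxit_irls),
                 maxit_cd = as.integer(maxit_cd), ufloor = ufloor,
                 kkt_tol = kkt_tol, n_folds = as.integer(n_folds),
                 n_gamma = as.integer(n_gamma),
                 gamma_min_ratio = gamma_min_ratio,
                 cv_rule = match.arg(cv_rule),
                 cv_loss = match.arg(cv_loss),
                 dfmax = as.integer(dfmax),
                 weight_power = weight_power,
                 max_reweight_iter = as.integer(max_reweight_iter),
                 recv_gamma = isTRUE(recv_gamma)),
            class = "agl_control")
}

check_weights <- function(design, weights) {
  J <- nrow(design$groups)
  if (length(weights) == 1L) weights <- rep(weights, J)
  if (length(weights) != J || any(is.na(weights)) || any(weights <= 0)) {
    stop("`weights` must be positive (or +Inf) with one entry per group",
         call. = FALSE)
  }
  weights
}

check_phenotype <- function(design, phenotype) {
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != design$n || !all(phenotype %in% c(0, 1))) {
    stop("phenotype must be binary 0/1 of length n", call. = FALSE)
  }
  phenotype
}

#' Bernoulli log-likelihood of a grouped logistic model
#'
#' `sum_i [ y_i eta_i - log(1 + exp(eta_i)) ]` with
#' `eta_i = intercept + sum_j X_ij beta_j`, numerically stabilized for
#' large `|eta|`.
#'
#' @param design A `grouped_design`.
#' @param intercept Scalar intercept.
#' @param beta Either a full concatenated coefficient vector (length
#'   `design$p`) or a named list over (a subset of) group labels.
#' @param phenotype Binary response.
#' @return Log-likelihood (scalar).
#' @export
logistic_loglik <- function(design, intercept, beta, phenotype) {
  phenotype <- check_phenotype(design, phenotype)
  eta <- linear_predictor(design, intercept, beta)
  sum(phenotype * eta - log1pexp(eta))
}

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# accepts beta as concatenated vector or named list keyed by group label
beta_as_vector <- function(design, beta) {
  if (is.list(beta)) {
    v <- numeric(design$p)
    for (nm in names(beta)) {
      g <- match(nm, design$groups$label)
      if (is.na(g)) stop("unknown group label: ", nm, call. = FALSE)
      v[design$groups$col_start[g]:design$groups$col_end[g]] <- beta[[nm]]
    }
    v
  } else {
    stopifnot(length(beta) == design$p)
    as.numeric(beta)
  }
}

linear_predictor <- function(design, intercept, beta, rows = NULL) {
  v <- beta_as_vector(design, beta)
  if (is.null(rows)) rows <- seq_len(design$n)
  .linpred_cpp(design$genotypes, design$groups$a - 1L,
               ifelse(is.na(design$groups$b), -1L, design$groups$b - 1L),
               intercept, v, rows - 1L)
}

ga0 <- function(design) design$groups$a - 1L
gb0 <- function(design) ifelse(is.na(design$groups$b), -1L,
                               design$groups$b - 1L)

#' Smallest penalty at which all groups are zero
#'
#' `gamma_max = max_j ||X_j' (y - ybar)||_2 / (w_j sqrt(p_j))`.  Fitting at
#' any `gamma >= gamma_max` yields an empty active set with intercept
#' `logit(ybar)`.
#'
#' @param design A `grouped_design`.
#' @param phenotype Binary response.
#' @param weights Group weights (scalar or per group; +Inf locks a group).
#' @return Scalar penalty value.
#' @export
gamma_max <- function(design, phenotype, weights = 1) {
  phenotype <- check_phenotype(design, phenotype)
  weights <- check_weights(design, weights)
  if (all(!is.finite(weights))) {
    stop("gamma_max undefined: all group weights are infinite", call. = FALSE)
  }
  resid <- phenotype - mean(phenotype)
  norms <- .group_grad_norms_cpp(design$genotypes, resid, ga0(design),
                                 gb0(design), seq_len(design$n) - 1L)
  max(norms / (weights * sqrt(design$groups$size)), na.rm = TRUE)
}

#' Fit a group-lasso logistic regression at a fixed penalty
#'
#' Minimizes `-l(beta) + gamma * sum_j w_j sqrt(p_j) ||beta_j||_2` (the
#' intercept is unpenalized) by IRLS quadratic approximation with block
#' coordinate descent, an active-set working strategy with full KKT
#' sweeps, and a step-halving line search that makes the penalized
#' objective non-increasing across outer iterations.
#'
#' @param design A `grouped_design`.
#' @param phenotype Binary response of length n.
#' @param gamma Penalty value (>= 0).
#' @param weights Group weights (scalar or per-group; +Inf locks a group
#'   at zero).
#' @param init Optional warm start: a previous `group_lasso_fit` or a list
#'   with `intercept` and `beta` (concatenated vector).
#' @param control An [agl_control()].
#' @return A `group_lasso_fit`: intercept, per-group coefficients of the
#'   active set (`beta`, named list), `active_set` labels, penalty,
#'   weights, final penalized objective and iteration counters.
#' @export
fit_group_lasso <- function(design, phenotype, gamma, weights = 1,
                            init = NULL, control = agl_control()) {
  stopifnot(inherits(design, "grouped_design"), gamma >= 0)
  phenotype <- check_phenotype(design, phenotype)
  weights <- check_weights(design, weights)
  init_b0 <- stats::qlogis(max(min(mean(phenotype), 1 - 1e-12), 1e-12))
  init_beta <- numeric(0)
  if (!is.null(init)) {
    if (inherits(init, "group_lasso_fit")) {
      init_b0 <- init$intercept
      init_beta <- beta_as_vector(design, init$beta)
    } else {
      init_b0 <- init$intercept
      init_beta <- as.numeric(init$beta)
    }
  }
  ctl <- unclass(control)
  ctl$dfmax <- 0L   # single fits are solved exactly, never truncated
  res <- .glfit_cpp(design$genotypes, phenotype, ga0(design), gb0(design),
                    weights, gamma, seq_len(design$n) - 1L, ctl,
                    init_b0, init_beta)
  as_fit(design, res, gamma, weights)
}

as_fit <- function(design, res, gamma, weights) {
  act <- res$active
  beta <- stats::setNames(lapply(act, function(g) {
    res$beta[design$groups$col_start[g]:design$groups$col_end[g]]
  }), design$groups$label[act])
  structure(list(intercept = res$intercept, beta = beta,
                 beta_vector = res$beta,
                 active_set = design$groups$label[act],
                 active_idx = act, gamma = gamma, weights = weights,
                 objective = res$objective,
                 n_irls_iters = max(res$n_irls, 1L),
                 n_cd_passes = max(res$n_cd, 1L),
                 converged = res$converged),
            class = "group_lasso_fit")
}

#' @export
print.group_lasso_fit <- function(x, ...) {
  cat(sprintf("group_lasso_fit: gamma = %.4g, %d active group(s), objective %.4f\n",
              x$gamma, length(x$active_set), x$objective))
  if (length(x$active_set)) cat(" ", paste(x$active_set, collapse = ", "), "\n")
  invisible(x)
}

#' KKT certification of a group-lasso fit
#'
#' Checks the subgradient conditions at the fitted point: every inactive
#' group must satisfy `||X_j'(y - p)|| <= gamma w_j sqrt(p_j) (1 + tol)`
#' and every active group the stationarity equation
#' `X_j'(y - p) = gamma w_j sqrt(p_j) beta_j / ||beta_j||`.
#'
#' @param fit A `group_lasso_fit`.
#' @param design The `grouped_design` it was fitted on.
#' @param phenotype Binary response.
#' @param tol Relative tolerance.
#' @return List with `ok` (logical), `max_inactive_excess` and
#'   `max_active_violation` (both scaled by the penalty level).
#' @export
kkt_check <- function(fit, design, phenotype, tol = 1e-3) {
  phenotype <- check_phenotype(design, phenotype)
  eta <- linear_predictor(design, fit$intercept, fit$beta)
  p <- stats::plogis(eta)
  resid <- phenotype - p
  norms <- .group_grad_norms_cpp(design$genotypes, resid, ga0(design),
                                 gb0(design), seq_len(design$n) - 1L)
  lam <- fit$gamma * fit$weights * sqrt(design$groups$size)
  scale <- max(fit$gamma, 1)
  inact <- setdiff(seq_len(nrow(design$groups)), fit$active_idx)
  inact <- inact[is.finite(lam[inact])]
  max_in <- if (length(inact)) max((norms[inact] - lam[inact]) / scale) else -Inf
  max_act <- -Inf
  for (g in fit$active_idx) {
    bj <- fit$beta[[design$groups$label[g]]]
    lev <- if (is.na(design$groups$b[g])) design$genotypes[, design$groups$a[g]]
           else 3L * design$genotypes[, design$groups$a[g]] +
                design$genotypes[, design$groups$b[g]]
    grad <- vapply(seq_along(bj) - 1L, function(k) sum(resid[lev == k]), 0.0)
    viol <- sqrt(sum((grad - lam[g] * bj / sqrt(sum(bj^2)))^2)) / scale
    max_act <- max(max_act, viol)
  }
  list(ok = (max_in <= tol) && (max_act <= tol * 10),
       max_inactive_excess = max_in, max_active_violation = max_act)
}

#' Penalty grid for a path fit
#'
#' Log-spaced descending grid from `gamma_max` down to
#' `gamma_min_ratio * gamma_max`.
#' @param design,phenotype,weights As in [fit_group_lasso()].
#' @param control An [agl_control()].
#' @return Descending numeric vector.
#' @export
gamma_grid <- function(design, phenotype, weights = 1,
                       control = agl_control()) {
  gmax <- gamma_max(design, phenotype, weights)
  if (gmax <= 0) return(0)
  exp(seq(log(gmax), log(gmax * control$gamma_min_ratio),
          length.out = control$n_gamma))
}

#' Select the penalty by stratified k-fold cross-validation
#'
#' Folds preserve the case/control proportions.  Each fold fits a
#' warm-started path over the descending grid and records the validation
#' loss; the selected gamma minimizes the mean loss, with the `"1se"` rule
#' (default) taking the largest gamma whose mean loss is within one
#' standard error of the minimum.
#'
#' @param design A `grouped_design`.
#' @param phenotype Binary response.
#' @param weights Group weights.
#' @param n_folds Number of folds (>= 2).
#' @param grid Descending penalty grid; default [gamma_grid()].
#' @param control An [agl_control()].
#' @return List with `gamma`, `grid`, `cvm`, `cvse`, `n_active` (mean
#'   active-set size per grid point) and the selection index.
#' @export
cv_select_gamma <- function(design, phenotype, weights = 1,
                            n_folds = NULL, grid = NULL,
                            control = agl_control()) {
  phenotype <- check_phenotype(design, phenotype)
  weights <- check_weights(design, weights)
  if (is.null(n_folds)) n_folds <- control$n_folds
  if (n_folds < 2) stop("need at least 2 folds", call. = FALSE)
  if (is.null(grid)) grid <- gamma_grid(design, phenotype, weights, control)
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  if (length(grid) == 1L) {
    return(list(gamma = grid, grid = grid, cvm = NA_real_, cvse = NA_real_,
                n_active = NA_real_, index = 1L))
  }
  n <- design$n
  folds <- integer(n)
  for (cls in 0:1) {
    idx <- which(phenotype == cls)
    if (length(idx) < n_folds) {
      stop("too few samples in one class to stratify folds", call. = FALSE)
    }
    folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  loss <- matrix(NA_real_, n_folds, length(grid))
  nact <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); va <- which(folds == f)
    if (length(unique(phenotype[va])) < 2L) {
      stop("a validation fold has a single class", call. = FALSE)
    }
    path <- .glpath_cpp(design$genotypes, phenotype, ga0(design), gb0(design),
                        weights, grid, tr - 1L, va - 1L, unclass(control),
                        FALSE)
    loss[f, ] <- if (control$cv_loss == "deviance") {
      path$deviance / length(va)
    } else {
      path$misclass / length(va)
    }
    nact[f, ] <- path$n_active
  }
  cvm <- colMeans(loss)          # NA where any fold abandoned the path
  cvse <- apply(loss, 2, stats::sd) / sqrt(n_folds)
  valid <- which(!is.na(cvm))
  if (!length(valid)) stop("no penalty value completed in all folds",
                           call. = FALSE)
  imin <- valid[which.min(cvm[valid])]
  index <- if (control$cv_rule == "1se") {
    min(valid[cvm[valid] <= cvm[imin] + cvse[imin]])
  } else {
    imin
  }
  list(gamma = grid[index], grid = grid, cvm = cvm, cvse = cvse,
       n_active = colMeans(nact), index = index)
}

# warm-started path fit on the full data down to `gamma`, returning the
# fit at the last grid point
path_fit_to <- function(design, phenotype, weights, grid, gamma, control) {
  grid <- grid[grid >= gamma - 1e-12]
  if (!length(grid) || abs(grid[length(grid)] - gamma) > 1e-12 * max(1, gamma)) {
    grid <- c(grid, gamma)
  }
  res <- .glpath_cpp(design$genotypes, phenotype, ga0(design), gb0(design),
                     weights, grid, seq_len(design$n) - 1L, integer(0),
                     unclass(control), TRUE)
  k <- length(grid)
  if (res$last_done < k) {
    # path abandoned by the dfmax guard before the target: fit directly
    ctl <- unclass(control)
    ctl$dfmax <- 0L
    res2 <- .glfit_cpp(design$genotypes, phenotype, ga0(design), gb0(design),
                       weights, gamma, seq_len(design$n) - 1L, ctl,
                       res$intercept, res$beta)
    return(as_fit(design, res2, gamma, weights))
  }
  as_fit(design,
         list(intercept = res$intercept, beta = res$beta,
              active = res$active[[k]],
              objective = res$objective[k],
              n_irls = res$n_irls, n_cd = res$n_cd, converged = TRUE),
         gamma, weights)
}
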