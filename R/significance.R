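# Dense dummy-column matrix for a set of groups (rows a, b with b = NA for
# main effects).  Small by construction: only selected groups are tested.
dummy_cols <- function(genotypes, groups) {
  n <- nrow(genotypes)
  blocks <- lapply(seq_len(nrow(groups)), function(g) {
    a <- groups$a[g]; b <- groups$b[g]
    if (is.na(b)) {
      lev <- genotypes[, a]
      K <- 3L
    } else {
      lev <- 3L * genotypes[, a] + genotypes[, b]
      K <- 9L
    }
    m <- matrix(0, n, K)
    m[cbind(seq_len(n), lev + 1L)] <- 1
    m
  })
  do.call(cbind, blocks)
}

#' Ridge-stabilized logistic refit
#'
#' Maximizes `l(beta) - (ridge/2) ||beta||^2` (intercept unpenalized) by
#' Newton iterations with step halving.  The ridge term makes the problem
#' strictly concave, so collinear dummy blocks (each SNP's three dummies
#' sum to one) never break the fit.
#'
#' @param X Design columns of the selected groups (no intercept column).
#' @param y Binary response.
#' @param ridge Penalty (default 1e-4).
#' @param grad_tol Gradient-norm convergence target (default 1e-8).
#' @param maxit Newton iteration cap.
#' @return List: `coef` (intercept first), `loglik` (unpenalized, at the
#'   penalized optimum), `fitted`, `converged`, `iter`.
#' @export
ridge_logistic_refit <- function(X, y, ridge = 1e-4, grad_tol = 1e-8,
                                 maxit = 200) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(ridge > 0, nrow(X) == length(y), all(y %in% c(0, 1)))
  Xt <- cbind(1, X)
  P <- ncol(Xt)
  gam <- c(0, rep(ridge, P - 1L))
  beta <- numeric(P)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-12), 1e-12))
  pen_ll <- function(b) {
    eta <- drop(Xt %*% b)
    sum(y * eta - log1pexp(eta)) - sum(gam * b^2) / 2
  }
  f <- pen_ll(beta)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    eta <- drop(Xt %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(Xt, y - p)) - gam * beta
    if (sqrt(sum(grad^2)) < grad_tol) { converged <- TRUE; break }
    u <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xt, Xt * u) + diag(gam, P)
    step <- solve(H, grad)
    s <- 1
    repeat {
      f_new <- pen_ll(beta + s * step)
      if (f_new >= f - 1e-12 * abs(f)) break
      s <- s / 2
      if (s < 1e-12) break
    }
    beta <- beta + s * step
    f <- pen_ll(beta)
  }
  eta <- drop(Xt %*% beta)
  list(coef = beta, loglik = sum(y * eta - log1pexp(eta)),
       fitted = stats::plogis(eta), converged = converged, iter = it)
}

#' Effective degrees of freedom of a ridge logistic fit
#'
#' `df = trace[ (X'UX + Gamma)^{-1} X'UX ]` where `X` includes the
#' intercept column, `U = diag(p_i (1 - p_i))` at the converged fit, and
#' `Gamma` is diagonal with 0 on the intercept and the ridge value on
#' every coefficient.  As ridge -> 0 this tends to the column rank; as
#' ridge -> Inf it tends to 1 (intercept only).
#'
#' @param X Design columns of the selected groups (no intercept column).
#' @param fitted_probs Converged fitted probabilities.
#' @param ridge Ridge penalty used in the refit.
#' @return Real-valued effective df in (0, ncol(X) + 1\].
#' @export
effective_df <- function(X, fitted_probs, ridge) {
  X <- as.matrix(X)
  Xt <- cbind(1, X)
  u <- fitted_probs * (1 - fitted_probs)
  A <- crossprod(Xt, Xt * u)
  sum(diag(solve(A + diag(c(0, rep(ridge, ncol(X))), ncol(Xt)), A)))
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s) in \[0, 1\].
#' @param correction_factor Number of hypotheses searched (>= 1).
#' @return `min(1, p_raw * correction_factor)`.
#' @export
bonferroni <- function(p_raw, correction_factor) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1), correction_factor >= 1)
  pmin(1, p_raw * correction_factor)
}

association_result <- function(group_id, snp_ids, stat, df, p_raw,
                               correction_factor, threshold) {
  p_bonf <- bonferroni(p_raw, correction_factor)
  structure(data.frame(group_id = group_id, snp_ids = snp_ids,
                       stat = stat, df = df, p_raw = p_raw, p_bonf = p_bonf,
                       significant = p_bonf <= threshold,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

lrt_pvalue <- function(stat, df) {
  stat <- max(stat, 0)   # guard tiny negative round-off of nested refits
  df <- max(df, .Machine$double.eps)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Significance tests of selected main-effect SNPs
#'
#' Leave-one-SNP-out likelihood-ratio tests: the full ridge-stabilized
#' logistic model contains the 3-dummy blocks of all selected SNPs; for
#' each SNP j the reduced model drops its block.  The statistic
#' `2 (l_full - l_\\j)` is referred to a chi-square distribution with
#' real-valued df equal to the difference of the effective degrees of
#' freedom of the two fits (about 2 per SNP).
#'
#' @param dataset A [genotype_dataset()].
#' @param active_snps Integer SNP column indices or SNP id labels.
#' @param threshold Significance threshold on the corrected p-value
#'   (default 0.3).
#' @param correction_factor Bonferroni factor; default the number of SNPs
#'   L in the dataset (the searched hypothesis space).
#' @param ridge Ridge penalty of the refits (default 1e-4).
#' @return An `association_result` data frame, one row per tested SNP;
#'   empty if `active_snps` is empty.
#' @export
test_main_effects <- function(dataset, active_snps, threshold = 0.3,
                              correction_factor = NULL, ridge = 1e-4) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.character(active_snps)) {
    active_snps <- match(active_snps, dataset$snp_ids)
  }
  if (anyNA(active_snps)) stop("unknown SNP id in active set", call. = FALSE)
  if (is.null(correction_factor)) correction_factor <- ncol(dataset$genotypes)
  if (length(active_snps) == 0L) {
    return(association_result(character(0), character(0), numeric(0),
                              numeric(0), numeric(0), correction_factor,
                              threshold))
  }
  groups <- data.frame(a = as.integer(active_snps), b = NA_integer_)
  y <- dataset$phenotype
  X_full <- dummy_cols(dataset$genotypes, groups)
  full <- ridge_logistic_refit(X_full, y, ridge)
  df_full <- effective_df(X_full, full$fitted, ridge)
  res <- lapply(seq_len(nrow(groups)), function(j) {
    red_groups <- groups[-j, , drop = FALSE]
    if (nrow(red_groups)) {
      X_red <- dummy_cols(dataset$genotypes, red_groups)
      red <- ridge_logistic_refit(X_red, y, ridge)
      df_red <- effective_df(X_red, red$fitted, ridge)
      ll_red <- red$loglik
    } else {
      p0 <- mean(y)
      ll_red <- sum(y * log(p0) + (1 - y) * log(1 - p0))
      df_red <- 1
    }
    c(stat = 2 * (full$loglik - ll_red), df = df_full - df_red)
  })
  stat <- vapply(res, `[[`, 0.0, "stat")
  df <- vapply(res, `[[`, 0.0, "df")
  labels <- dataset$snp_ids[active_snps]
  association_result(labels, labels, stat, df,
                     vapply(seq_along(stat),
                            function(i) lrt_pvalue(stat[i], df[i]), 0.0),
                     correction_factor, threshold)
}

#' Significance tests of selected epistatic interactions
#'
#' Implements the definition of interaction as departure from the
#' main-effects model: for each selected pair group, the reduced model
#' replaces its 9-dummy block with the two 3-dummy main-effect blocks of
#' its SNPs (deduplicated against blocks already present), while all other
#' selected groups stay in the model.  Because each main-effect block lies
#' in the column span of the pair block, the reduced model is nested in the
#' full one and `2 (l_full - l_\\l) >= 0` up to round-off.  The df is the
#' difference of effective degrees of freedom.
#'
#' @param dataset A [genotype_dataset()].
#' @param active_groups Data frame with columns `a`, `b` (NA for main
#'   effects), e.g. from [active_groups()]; only pair rows are tested.
#' @param threshold Corrected-significance threshold (default 0.3).
#' @param correction_factor Bonferroni factor; default
#'   `L + L (L - 1) / 2`, the candidate-group space of the interaction
#'   model.
#' @param ridge Ridge penalty of the refits (default 1e-4).
#' @return An `association_result` data frame, one row per tested pair.
#' @export
test_interactions <- function(dataset, active_groups, threshold = 0.3,
                              correction_factor = NULL, ridge = 1e-4) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  groups <- as.data.frame(active_groups)
  if (!all(c("a", "b") %in% names(groups))) {
    stop("`active_groups` needs columns `a` and `b`", call. = FALSE)
  }
  L <- ncol(dataset$genotypes)
  if (is.null(correction_factor)) correction_factor <- L + L * (L - 1) / 2
  pair_rows <- which(!is.na(groups$b))
  if (length(pair_rows) == 0L) {
    return(association_result(character(0), character(0), numeric(0),
                              numeric(0), numeric(0), correction_factor,
                              threshold))
  }
  y <- dataset$phenotype
  X_full <- dummy_cols(dataset$genotypes, groups)
  full <- ridge_logistic_refit(X_full, y, ridge)
  df_full <- effective_df(X_full, full$fitted, ridge)
  res <- lapply(pair_rows, function(l) {
    a <- groups$a[l]; b <- groups$b[l]
    red_groups <- groups[-l, , drop = FALSE]
    add <- setdiff(c(a, b), red_groups$a[is.na(red_groups$b)])
    if (length(add)) {
      red_groups <- rbind(red_groups,
                          data.frame(a = add, b = NA_integer_))
    }
    X_red <- dummy_cols(dataset$genotypes, red_groups)
    red <- ridge_logistic_refit(X_red, y, ridge)
    df_red <- effective_df(X_red, red$fitted, ridge)
    c(stat = 2 * (full$loglik - red$loglik), df = df_full - df_red)
  })
  stat <- vapply(res, `[[`, 0.0, "stat")
  df <- vapply(res, `[[`, 0.0, "df")
  ids_a <- dataset$snp_ids[groups$a[pair_rows]]
  ids_b <- dataset$snp_ids[groups$b[pair_rows]]
  association_result(paste0(ids_a, ":", ids_b),
                     paste(ids_a, ids_b, sep = ","), stat, df,
                     vapply(seq_along(stat),
                            function(i) lrt_pvalue(stat[i], df[i]), 0.0),
                     correction_factor, threshold)
}
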