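#' Adaptive weight update from a fitted model
#'
#' Active groups get `w_j = ||beta_j||_2^(-a)` (default a = 1): the smaller
#' the previous estimate, the heavier the next penalty, sharpening sparsity
#' across reweighting iterations.  Inactive groups are removed from the
#' candidate set by the caller and receive no weight.
#'
#' @param fit A `group_lasso_fit`.
#' @param power Exponent a (default 1).
#' @return Named numeric vector of weights over the active groups.
#' @export
update_weights <- function(fit, power = 1) {
  stopifnot(inherits(fit, "group_lasso_fit"))
  norms <- vapply(fit$beta, function(b) sqrt(sum(b^2)), 0.0)
  stats::setNames(norms^(-power), names(fit$beta))
}

#' Adaptive group lasso: the reweighting loop
#'
#' Iterates (cross-validated penalty selection, group-lasso fit, weight
#' update, removal of inactive groups) until the active set repeats between
#' consecutive iterations or an iteration cap is reached.  Iteration 0 uses
#' unit weights for all candidate groups; once a group leaves the active
#' set it never re-enters.  Works identically for main-effect designs and
#' interaction designs (where pair groups already carry a heavier baseline
#' penalty through the sqrt(9) group-size factor).
#'
#' @param design A `grouped_design` (main or interaction).
#' @param phenotype Binary response of length n.
#' @param control An [agl_control()].
#' @param verbose Print one line per iteration.
#' @return An `adaptive_trace`: per-iteration records (iteration, gamma,
#'   active labels, active-set size, weights), `converged`,
#'   `n_iterations`, and `final_fit`.  Reproducible from the caller's RNG
#'   state (cross-validation folds are the only source of randomness).
#' @export
adaptive_fit <- function(design, phenotype, control = agl_control(),
                         verbose = FALSE) {
  stopifnot(inherits(design, "grouped_design"))
  phenotype <- check_phenotype(design, phenotype)
  cand_idx <- seq_len(nrow(design$groups))   # indices into design$groups
  cand_design <- design
  weights <- rep(1, length(cand_idx))
  trace <- list()
  prev_active <- NULL
  converged <- FALSE
  final_fit <- NULL
  gamma0 <- NA_real_
  for (m in seq_len(control$max_reweight_iter) - 1L) {
    grid <- gamma_grid(cand_design, phenotype, weights, control)
    if (identical(grid, 0)) {
      gamma <- 0
      cv <- NULL
    } else if (m == 0L || control$recv_gamma) {
      cv <- cv_select_gamma(cand_design, phenotype, weights,
                            grid = grid, control = control)
      gamma <- cv$gamma
    } else {
      gamma <- min(gamma0, max(grid))
      cv <- NULL
    }
    if (m == 0L) gamma0 <- gamma
    fit <- path_fit_to(cand_design, phenotype, weights, grid, gamma, control)
    active_labels <- fit$active_set
    trace[[m + 1L]] <- list(iteration = m, gamma = gamma,
                            weights = stats::setNames(weights,
                                                      cand_design$groups$label),
                            active = active_labels,
                            n_active = length(active_labels))
    if (verbose) {
      message(sprintf("iter %d: gamma = %.4g, %d candidate(s), %d active",
                      m, gamma, nrow(cand_design$groups),
                      length(active_labels)))
    }
    final_fit <- fit
    if (!is.null(prev_active) && setequal(active_labels, prev_active)) {
      converged <- TRUE
      break
    }
    if (length(active_labels) == 0L) {
      converged <- TRUE        # empty model: nothing left to reweight
      break
    }
    prev_active <- active_labels
    # reweight the active groups and drop the rest for good
    w_new <- update_weights(fit, control$weight_power)
    keep <- match(active_labels, cand_design$groups$label)
    cand_idx <- cand_idx[keep]
    cand_design <- subset_groups(design, cand_idx)
    weights <- as.numeric(w_new[cand_design$groups$label])
  }
  structure(list(trace = trace, converged = converged,
                 n_iterations = length(trace), final_fit = final_fit,
                 active_set = final_fit$active_set,
                 design_groups = design$groups[cand_idx, , drop = FALSE]),
            class = "adaptive_trace")
}

#' @export
print.adaptive_trace <- function(x, ...) {
  sizes <- vapply(x$trace, function(t) t$n_active, 0L)
  cat(sprintf("adaptive_trace: %d iteration(s), %s; active-set sizes: %s\n",
              x$n_iterations,
              if (x$converged) "converged" else "iteration cap reached",
              paste(sizes, collapse = " -> ")))
  if (length(x$active_set)) {
    cat("final active set:", paste(x$active_set, collapse = ", "), "\n")
  } else {
    cat("final active set: (empty)\n")
  }
  invisible(x)
}

#' Active groups of an adaptive fit, as a group table
#'
#' @param trace An `adaptive_trace`.
#' @return Data frame with columns `label`, `a`, `b` (NA for main-effect
#'   groups), one row per finally active group.
#' @export
active_groups <- function(trace) {
  stopifnot(inherits(trace, "adaptive_trace"))
  g <- trace$design_groups
  g[g$label %in% trace$active_set, c("label", "a", "b")]
}
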