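#' Configuration for a simulation experiment
#'
#' Presets: for the null (type-I error) study, `scale = "paper"` is 100
#' datasets of 10,000 SNPs x 1,000 samples and `scale = "desk"` is 10
#' datasets of 2,000 SNPs x 500 samples.  For the power study,
#' `scale = "paper"` is 100 replicates with 200 cases, 200 controls and
#' 1,000 SNPs; `scale = "desk"` keeps the sample sizes and reduces to 20
#' replicates of 200 SNPs.
#'
#' @param kind `"type1"` or `"power"`.
#' @param model Penetrance model name (power only), passed to
#'   [table2_model()], or a `penetrance_model`.
#' @param scale `"desk"` or `"paper"`, or NULL to give all counts
#'   explicitly.
#' @param n_datasets,n_snps,n_samples,n_cases,n_controls Overrides.
#' @param maf_range MAF range of noise/null SNPs.
#' @param threshold Corrected significance threshold (default 0.3).
#' @param correction_factor Bonferroni factor; NULL (default) uses the
#'   searched hypothesis space of the run itself (L for main effects,
#'   L + L(L-1)/2 for interactions).  Reduced-scale null runs may keep the
#'   full-scale factor instead, preserving the per-hypothesis stringency
#'   of the full design.
#' @param seed Root seed; dataset d uses `seed + d`.
#' @param control An [agl_control()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("type1", "power"), model = NULL,
                              scale = c("desk", "paper"),
                              n_datasets = NULL, n_snps = NULL,
                              n_samples = NULL, n_cases = NULL,
                              n_controls = NULL, maf_range = c(0.05, 0.5),
                              threshold = 0.3, correction_factor = NULL,
                              seed = 1, control = agl_control()) {
  kind <- match.arg(kind)
  scale <- if (is.null(scale)) "custom" else match.arg(scale)
  preset <- if (kind == "type1") {
    switch(scale,
           desk  = list(n_datasets = 10, n_snps = 2000, n_samples = 500),
           paper = list(n_datasets = 100, n_snps = 10000, n_samples = 1000),
           list())
  } else {
    switch(scale,
           desk  = list(n_datasets = 20, n_snps = 200,
                        n_cases = 200, n_controls = 200),
           paper = list(n_datasets = 100, n_snps = 1000,
                        n_cases = 200, n_controls = 200),
           list())
  }
  cfg <- list(kind = kind, scale = scale,
              n_datasets = n_datasets %||% preset$n_datasets,
              n_snps = n_snps %||% preset$n_snps,
              n_samples = n_samples %||% preset$n_samples,
              n_cases = n_cases %||% preset$n_cases,
              n_controls = n_controls %||% preset$n_controls,
              maf_range = maf_range, threshold = threshold,
              correction_factor = correction_factor,
              seed = as.integer(seed), control = control)
  if (kind == "power") {
    if (is.null(model)) stop("power experiments need a `model`", call. = FALSE)
    cfg$model <- if (inherits(model, "penetrance_model")) model
                 else table2_model(model)
  }
  stopifnot(cfg$n_datasets >= 1, cfg$n_snps >= 1, threshold > 0,
            threshold <= 1)
  structure(cfg, class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nominal Bonferroni false-positive rate of the null design
#'
#' With `n_snps` SNPs per dataset, correction factor equal to the number
#' of SNPs and corrected threshold `threshold`, the expected false-positive
#' count per dataset is `threshold`, i.e. `1e6 * threshold / n_snps` per
#' million SNPs.
#'
#' @param threshold Corrected significance threshold.
#' @param n_snps SNPs per dataset (also the Bonferroni factor).
#' @return Expected false positives per one million SNPs.
#' @export
nominal_type1_rate <- function(threshold, n_snps) {
  1e6 * threshold / n_snps
}

#' Type-I error experiment on null data
#'
#' For each dataset: simulate independent null SNPs, run the main-effect
#' adaptive group lasso, test the surviving SNPs with the
#' leave-one-out likelihood-ratio procedure, and count groups whose
#' Bonferroni-corrected p-value (factor = number of SNPs) falls below each
#' threshold in `thresholds`.  Reports false positives per million SNPs
#' with exact Poisson 95% intervals.
#'
#' @param config An [experiment_config()] of kind `"type1"`.
#' @param thresholds Corrected thresholds to tabulate (default
#'   0.1 / 0.2 / 0.3).
#' @param verbose Print one line per dataset.
#' @return List of class `experiment_report`: `per_dataset` data frame,
#'   `rates` data frame (threshold, false positives, rate per million,
#'   Poisson CI), and the config.
#' @export
run_type1_experiment <- function(config, thresholds = c(0.1, 0.2, 0.3),
                                 verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"), config$kind == "type1")
  L <- config$n_snps
  factor <- config$correction_factor %||% L
  per <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    seed_d <- config$seed + d
    ds <- simulate_null(L, config$n_samples, config$maf_range, seed = seed_d)
    design <- build_main_design(ds)
    tr <- adaptive_fit(design, ds$phenotype, control = config$control)
    n_sig <- stats::setNames(numeric(length(thresholds)),
                             paste0("t", thresholds))
    if (length(tr$active_set)) {
      res <- test_main_effects(ds, tr$active_set, threshold = max(thresholds),
                               correction_factor = factor)
      for (k in seq_along(thresholds)) {
        n_sig[k] <- sum(res$p_bonf <= thresholds[k])
      }
    }
    per[[d]] <- data.frame(dataset = d, seed = seed_d,
                           n_active = length(tr$active_set),
                           n_iterations = tr$n_iterations,
                           t(n_sig))
    if (verbose) {
      message(sprintf("null dataset %d/%d: %d active, %s significant at %.1f",
                      d, config$n_datasets, length(tr$active_set),
                      n_sig[length(n_sig)], max(thresholds)))
    }
  }
  per <- do.call(rbind, per)
  snps_total <- config$n_datasets * L
  rates <- do.call(rbind, lapply(seq_along(thresholds), function(k) {
    fp <- sum(per[[paste0("t", thresholds[k])]])
    ci <- stats::poisson.test(fp)$conf.int
    data.frame(threshold = thresholds[k], false_positives = fp,
               rate_per_million = fp / snps_total * 1e6,
               ci_lo = ci[1] / snps_total * 1e6,
               ci_hi = ci[2] / snps_total * 1e6,
               nominal = nominal_type1_rate(thresholds[k], factor))
  }))
  structure(list(kind = "type1", per_dataset = per, rates = rates,
                 config = config), class = "experiment_report")
}

#' Power experiment on a two-locus penetrance model
#'
#' For each replicate: simulate a case-control dataset from the penetrance
#' model, run the interaction adaptive group lasso over all SNP pairs, test
#' the selected pair groups, and score a success when the ground-truth pair
#' is significant at the corrected threshold (Bonferroni factor
#' `L + L(L-1)/2`, the candidate-group space).  The fitting path never sees
#' the truth; it is consulted only at scoring time.  Also records the
#' active-set-size trajectory and iteration count of the reweighting loop.
#'
#' @param config An [experiment_config()] of kind `"power"`.
#' @param verbose Print one line per replicate.
#' @return List of class `experiment_report`: `per_dataset` data frame
#'   (hit flag, iterations, active-set sizes), `power` (in percent) with a
#'   binomial 95% CI, `median_iterations`, and the share of replicates in
#'   which the first reweighting shrank the active set.
#' @export
run_power_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"), config$kind == "power")
  L <- config$n_snps
  factor <- config$correction_factor %||% (L + L * (L - 1) / 2)
  per <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    seed_d <- config$seed + d
    ds <- simulate_case_control(config$model, config$n_cases,
                                config$n_controls, L - 2L,
                                config$maf_range, seed = seed_d)
    design <- build_interaction_design(ds)
    tr <- adaptive_fit(design, ds$phenotype, control = config$control)
    hit <- FALSE
    truth_label <- paste0(ds$snp_ids[ds$truth$loci[1]], ":",
                          ds$snp_ids[ds$truth$loci[2]])
    if (length(tr$active_set)) {
      res <- test_interactions(ds, active_groups(tr),
                               threshold = config$threshold,
                               correction_factor = factor)
      hit <- truth_label %in% res$group_id[res$significant]
    }
    sizes <- vapply(tr$trace, function(t) t$n_active, 0L)
    per[[d]] <- data.frame(dataset = d, seed = seed_d, hit = hit,
                           n_iterations = tr$n_iterations,
                           converged = tr$converged,
                           size_iter0 = sizes[1],
                           size_iter1 = if (length(sizes) > 1) sizes[2]
                                        else NA_integer_,
                           truth_pair = truth_label)
    if (verbose) {
      message(sprintf("replicate %d/%d: %s (%d iteration(s), sizes %s)",
                      d, config$n_datasets, if (hit) "hit" else "miss",
                      tr$n_iterations, paste(sizes, collapse = "->")))
    }
  }
  per <- do.call(rbind, per)
  bt <- stats::binom.test(sum(per$hit), nrow(per))
  drops <- per$size_iter1 < per$size_iter0
  structure(list(kind = "power", per_dataset = per,
                 power = 100 * mean(per$hit),
                 power_ci = 100 * bt$conf.int,
                 median_iterations = stats::median(per$n_iterations),
                 prop_first_reweight_shrinks = mean(drops, na.rm = TRUE),
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  if (x$kind == "type1") {
    cat(sprintf("Type-I error experiment: %d null datasets x %d SNPs x %d samples\n",
                x$config$n_datasets, x$config$n_snps, x$config$n_samples))
    print(x$rates, row.names = FALSE, digits = 4)
  } else {
    cat(sprintf("Power experiment, model %s: %d replicates, %d/%d cases/controls, %d SNPs\n",
                x$config$model$name, x$config$n_datasets, x$config$n_cases,
                x$config$n_controls, x$config$n_snps))
    cat(sprintf("power = %.1f%% (95%% CI %.1f-%.1f), median iterations = %g\n",
                x$power, x$power_ci[1], x$power_ci[2], x$median_iterations))
    cat(sprintf("first reweighting shrank the active set in %.0f%% of replicates\n",
                100 * x$prop_first_reweight_shrinks))
  }
  invisible(x)
}
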