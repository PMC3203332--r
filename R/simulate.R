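#' Construct a genotype dataset
#'
#' Container for a case-control SNP dataset: an N x L matrix of
#' minor-allele counts (0 = homozygous major, 1 = heterozygous,
#' 2 = homozygous minor), a binary phenotype (0 control / 1 case), SNP
#' identifiers, and optionally the ground-truth disease loci of a
#' simulation.
#'
#' @param genotypes Integer N x L matrix over \{0, 1, 2\}.
#' @param phenotype Length-N vector over \{0, 1\}.
#' @param snp_ids Length-L character vector (default `snp1..snpL`).
#' @param truth Optional list with elements `loci` (integer vector of
#'   disease-locus columns) and `pairs` (list of integer pairs).
#' @param seed Integer seed the dataset was generated from, or `NA`.
#' @param meta Optional named list of provenance (model name, parameters).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, phenotype, snp_ids = NULL,
                             truth = NULL, seed = NA_integer_, meta = list()) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (anyNA(genotypes) || !all(genotypes %in% 0:2)) {
    stop("genotypes must be 0, 1 or 2 (minor-allele counts)", call. = FALSE)
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes)) {
    stop("phenotype length must equal the number of samples", call. = FALSE)
  }
  if (anyNA(phenotype) || !all(phenotype %in% 0:1)) {
    stop("phenotype must be strictly binary (0 control, 1 case)", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  if (length(snp_ids) != ncol(genotypes)) {
    stop("snp_ids length must equal the number of SNPs", call. = FALSE)
  }
  colnames(genotypes) <- snp_ids
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 snp_ids = as.character(snp_ids), truth = truth,
                 seed = seed, meta = meta),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls) x %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$genotypes)))
  if (!is.null(x$truth) && length(x$truth$loci)) {
    cat("truth loci:", paste(x$truth$loci, collapse = ", "), "\n")
  }
  invisible(x)
}

# draw n genotypes (codes 0/1/2) under HWE for one MAF
draw_hwe <- function(n, maf) {
  p <- hwe_genotype_probs(maf)
  findInterval(stats::runif(n), cumsum(p)[1:2])
}

#' Simulate a case-control dataset from a two-locus penetrance model
#'
#' The two disease loci are drawn jointly under Hardy-Weinberg equilibrium
#' (independent loci, linkage equilibrium); disease status is Bernoulli
#' with probability given by the penetrance table; samples accumulate by
#' rejection until the case and control quotas are filled exactly.  Noise
#' SNPs are independent of phenotype, each with its own MAF drawn uniformly
#' from `noise_maf_range`.  The two disease loci are placed at random
#' positions, recorded in `truth`.
#'
#' @param model A [penetrance_model()].
#' @param n_cases,n_controls Exact case and control counts.
#' @param n_noise_snps Number of unassociated SNPs (total L = noise + 2).
#' @param noise_maf_range Length-2 range for noise-SNP MAFs.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param max_attempts Rejection-sampling cap before failing.
#' @return A [genotype_dataset()] with rows ordered cases first.
#' @export
simulate_case_control <- function(model, n_cases, n_controls, n_noise_snps,
                                  noise_maf_range = c(0.05, 0.5), seed,
                                  max_attempts = 1e7) {
  stopifnot(inherits(model, "penetrance_model"),
            n_cases >= 1, n_controls >= 0, n_noise_snps >= 0)
  f <- model$table
  if (all(f == 0) && n_cases > 0) {
    stop("penetrance table is identically zero: cases unfillable",
         call. = FALSE)
  }
  if (all(f == 1) && n_controls > 0) {
    stop("penetrance table is identically one: controls unfillable",
         call. = FALSE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  pa <- hwe_genotype_probs(model$maf_a)
  pb <- hwe_genotype_probs(model$maf_b)

  case_g <- matrix(integer(0), 0, 2)
  ctrl_g <- matrix(integer(0), 0, 2)
  attempts <- 0
  while (nrow(case_g) < n_cases || nrow(ctrl_g) < n_controls) {
    need <- (n_cases - nrow(case_g)) + (n_controls - nrow(ctrl_g))
    nb <- min(max(4L * need, 256L), max_attempts - attempts)
    if (nb <= 0) {
      stop(sprintf("case/control quotas unfilled after %g attempts",
                   max_attempts), call. = FALSE)
    }
    attempts <- attempts + nb
    ga <- sample.int(3L, nb, replace = TRUE, prob = pa) - 1L
    gb <- sample.int(3L, nb, replace = TRUE, prob = pb) - 1L
    d <- stats::rbinom(nb, 1L, f[cbind(ga + 1L, gb + 1L)])
    if (nrow(case_g) < n_cases) {
      idx <- which(d == 1L)
      idx <- idx[seq_len(min(length(idx), n_cases - nrow(case_g)))]
      case_g <- rbind(case_g, cbind(ga[idx], gb[idx]))
    }
    if (nrow(ctrl_g) < n_controls) {
      idx <- which(d == 0L)
      idx <- idx[seq_len(min(length(idx), n_controls - nrow(ctrl_g)))]
      ctrl_g <- rbind(ctrl_g, cbind(ga[idx], gb[idx]))
    }
  }

  n <- n_cases + n_controls
  L <- n_noise_snps + 2L
  loci <- sort(sample.int(L, 2L))
  G <- matrix(0L, n, L)
  G[, loci] <- rbind(case_g, ctrl_g)
  noise_cols <- setdiff(seq_len(L), loci)
  mafs <- stats::runif(length(noise_cols), noise_maf_range[1], noise_maf_range[2])
  for (k in seq_along(noise_cols)) {
    G[, noise_cols[k]] <- draw_hwe(n, mafs[k])
  }
  genotype_dataset(
    G, c(rep(1L, n_cases), rep(0L, n_controls)),
    truth = list(loci = loci, pairs = list(loci)),
    seed = as.integer(seed),
    meta = list(model = model$name, maf_a = model$maf_a, maf_b = model$maf_b,
                n_cases = n_cases, n_controls = n_controls,
                attempts = attempts)
  )
}

#' Simulate a null dataset (no disease association)
#'
#' All SNPs are generated independently under Hardy-Weinberg equilibrium
#' with per-SNP MAFs uniform in `maf_range`; the phenotype is a balanced
#' case/control split assigned independently of the genotypes.
#'
#' @param n_snps,n_samples Dataset dimensions.
#' @param maf_range Length-2 MAF range (default \[0.05, 0.5\]).
#' @param seed Integer seed.
#' @return A [genotype_dataset()] with empty `truth`.
#' @export
simulate_null <- function(n_snps, n_samples, maf_range = c(0.05, 0.5), seed) {
  stopifnot(n_snps >= 1, n_samples >= 1)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  G <- matrix(0L, n_samples, n_snps)
  for (k in seq_len(n_snps)) G[, k] <- draw_hwe(n_samples, mafs[k])
  phen <- sample(rep(0:1, length.out = n_samples))
  genotype_dataset(G, phen,
                   truth = list(loci = integer(0), pairs = list()),
                   seed = as.integer(seed),
                   meta = list(model = "null", maf_range = maf_range,
                               drawn_mafs = mafs))
}
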