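#' Hardy-Weinberg genotype probabilities
#'
#' Probabilities of the three genotypes of a bi-allelic marker under
#' Hardy-Weinberg equilibrium, ordered as (homozygous major, heterozygous,
#' homozygous minor), i.e. genotype codes 0, 1, 2.
#'
#' @param maf Minor-allele frequency, in (0, 0.5].
#' @return Numeric vector of length 3 summing to 1.
#' @examples
#' hwe_genotype_probs(0.4)  # 0.36 0.48 0.16
#' @export
hwe_genotype_probs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf > 0.5) {
    stop("`maf` must be a single number in (0, 0.5]", call. = FALSE)
  }
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

genotype_labels_a <- c("AA", "Aa", "aa")
genotype_labels_b <- c("BB", "Bb", "bb")

#' Construct a two-locus penetrance model
#'
#' A penetrance model is a 3 x 3 table of disease probabilities indexed by
#' the genotype of locus A (rows AA, Aa, aa) and locus B (columns BB, Bb,
#' bb), together with the minor-allele frequencies of the two loci.
#'
#' @param name Model label.
#' @param table 3 x 3 numeric matrix of penetrances in \[0, 1\];
#'   rows = locus A genotypes (AA, Aa, aa), columns = locus B genotypes.
#' @param maf_a,maf_b Minor-allele frequencies in (0, 0.5].
#' @return An object of class `penetrance_model`.
#' @export
penetrance_model <- function(name, table, maf_a, maf_b) {
  table <- as.matrix(table)
  if (!is.numeric(table) || !identical(dim(table), c(3L, 3L))) {
    stop("`table` must be a 3 x 3 numeric matrix", call. = FALSE)
  }
  if (anyNA(table) || any(table < 0) || any(table > 1)) {
    stop("penetrance entries must lie in [0, 1]", call. = FALSE)
  }
  hwe_genotype_probs(maf_a)  # domain check
  hwe_genotype_probs(maf_b)
  dimnames(table) <- list(genotype_labels_a, genotype_labels_b)
  structure(list(name = name, table = table, maf_a = maf_a, maf_b = maf_b),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("Two-locus penetrance model", x$name,
      sprintf("(MAF %.3g / %.3g)\n", x$maf_a, x$maf_b))
  print(round(x$table, 4))
  cat(sprintf("prevalence K = %.4f, heritability h2 = %.4f\n",
              prevalence(x), heritability(x)))
  invisible(x)
}

#' Multiplicative and interference penetrance models
#'
#' Builds the two parametric epistasis models used in the power studies.
#' `M1-1` is multiplicative: cell (Aa, Bb) has penetrance
#' `alpha * (1 + theta)^2`, cells (Aa, bb) and (aa, Bb) have
#' `alpha * (1 + theta)^3`, cell (aa, bb) has `alpha * (1 + theta)^4`, and
#' every cell involving AA or BB stays at the baseline `alpha`.  `M1-2`
#' exhibits interference: baseline `alpha` everywhere except cells
#' (Aa, Bb) and (aa, bb), which equal `alpha * (1 + theta)`.
#'
#' @param variant `"M1-1"` or `"M1-2"`.
#' @param alpha Baseline penetrance (documented default 0.05).
#' @param theta Effect size (>= 0); `theta = 0` gives a constant table.
#' @param maf_a,maf_b Minor-allele frequencies.
#' @return A [penetrance_model()].
#' @export
build_table1_model <- function(variant = c("M1-1", "M1-2"), alpha = 0.05,
                               theta, maf_a, maf_b) {
  variant <- match.arg(variant)
  if (alpha < 0 || theta < 0) {
    stop("`alpha` and `theta` must be non-negative", call. = FALSE)
  }
  tab <- matrix(alpha, 3, 3)
  if (variant == "M1-1") {
    tab[2, 2] <- alpha * (1 + theta)^2
    tab[2, 3] <- alpha * (1 + theta)^3
    tab[3, 2] <- alpha * (1 + theta)^3
    tab[3, 3] <- alpha * (1 + theta)^4
  } else {
    tab[2, 2] <- alpha * (1 + theta)
    tab[3, 3] <- alpha * (1 + theta)
  }
  if (any(tab > 1)) {
    stop("penetrance exceeds 1; reduce `alpha` or `theta`", call. = FALSE)
  }
  penetrance_model(variant, tab, maf_a, maf_b)
}

# Printed pure-epistasis tables; rows = locus A (AA, Aa, aa),
# columns = locus B (BB, Bb, bb); both MAFs are 0.4.
table2_tables <- list(
  "M1-3" = matrix(c(0.077, 0.689, 0.417,
                    0.763, 0.150, 0.491,
                    0.196, 0.657, 0.247), 3, 3),
  "M1-4" = matrix(c(0.086, 0.536, 0.641,
                    0.677, 0.275, 0.096,
                    0.219, 0.413, 0.712), 3, 3),
  "M1-5" = matrix(c(0.068, 0.299, 0.017,
                    0.289, 0.044, 0.285,
                    0.048, 0.262, 0.174), 3, 3),
  "M1-6" = matrix(c(0.005, 0.179, 0.251,
                    0.211, 0.100, 0.026,
                    0.156, 0.098, 0.156), 3, 3)
)

#' Pure epistasis penetrance models M1-3 .. M1-6
#'
#' Four fixed two-locus models with little or no marginal effect, with both
#' minor-allele frequencies equal to 0.4.  Their heritabilities are
#' approximately 0.3, 0.2, 0.1 and 0.05 respectively (see [heritability()]).
#'
#' @param variant One of `"M1-3"`, `"M1-4"`, `"M1-5"`, `"M1-6"`.
#' @return A [penetrance_model()].
#' @examples
#' table2_model("M1-3")$table["AA", "BB"]  # 0.077
#' @export
table2_model <- function(variant = c("M1-3", "M1-4", "M1-5", "M1-6")) {
  variant <- match.arg(variant)
  penetrance_model(variant, table2_tables[[variant]], 0.4, 0.4)
}

# 3 x 3 matrix of joint HWE genotype probabilities (independent loci)
joint_hwe_probs <- function(model) {
  outer(hwe_genotype_probs(model$maf_a), hwe_genotype_probs(model$maf_b))
}

#' Disease prevalence of a penetrance model
#'
#' `K = sum_g P(g) f(g)` where `P(g)` are joint Hardy-Weinberg genotype
#' probabilities of the two (independent) loci and `f(g)` the penetrance.
#'
#' @param model A [penetrance_model()].
#' @return Prevalence in \[0, 1\].
#' @export
prevalence <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  sum(joint_hwe_probs(model) * model$table)
}

#' Broad-sense heritability of a penetrance model
#'
#' `h2 = sum_g P(g) (f(g) - K)^2 / (K (1 - K))`, the genotype-explained
#' fraction of phenotypic variance for a binary trait with prevalence `K`.
#'
#' @param model A [penetrance_model()].
#' @return Heritability in \[0, 1\].
#' @examples
#' heritability(table2_model("M1-3"))  # ~0.30
#' @export
heritability <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  P <- joint_hwe_probs(model)
  K <- sum(P * model$table)
  if (K <= 0 || K >= 1) {
    stop("heritability undefined: prevalence is 0 or 1", call. = FALSE)
  }
  sum(P * (model$table - K)^2) / (K * (1 - K))
}
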