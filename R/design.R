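#' One-hot encode a single SNP genotype
#'
#' Genotype code 0 (AA) maps to `[1 0 0]`, 1 (Aa) to `[0 1 0]` and
#' 2 (aa) to `[0 0 1]`.  Missing or other codes are rejected: analyses
#' require complete hard-called genotypes.
#'
#' @param genotype_code Integer in \{0, 1, 2\}.
#' @return Numeric one-hot vector of length 3.
#' @export
encode_snp <- function(genotype_code) {
  if (length(genotype_code) != 1L || is.na(genotype_code) ||
      !genotype_code %in% 0:2) {
    stop("genotype code must be 0, 1 or 2 (no missing data)", call. = FALSE)
  }
  v <- numeric(3)
  v[genotype_code + 1L] <- 1
  v
}

#' One-hot encode a genotype pair as a 9-level factor
#'
#' The combination of two SNPs is treated as a 9-level factor in row-major
#' order (AA,BB), (AA,Bb), ..., (aa,bb), with the first SNP as the slow
#' index.  Equals the flattened outer product of the two 3-level encodings.
#'
#' @param code_a,code_b Genotype codes in \{0, 1, 2\}.
#' @return Numeric one-hot vector of length 9.
#' @export
encode_pair <- function(code_a, code_b) {
  ea <- encode_snp(code_a)
  eb <- encode_snp(code_b)
  as.numeric(t(outer(ea, eb)))  # row-major: a is the slow index
}

group_label <- function(snp_ids, a, b) {
  ifelse(is.na(b), snp_ids[a], paste0(snp_ids[a], ":", snp_ids[pmax(b, 1L)]))
}

new_grouped_design <- function(dataset, groups, max_dense_cols) {
  sizes <- ifelse(is.na(groups$b), 3L, 9L)
  col_end <- cumsum(sizes)
  groups$size <- sizes
  groups$col_start <- col_end - sizes + 1L
  groups$col_end <- col_end
  groups$label <- group_label(dataset$snp_ids, groups$a, groups$b)
  P <- sum(sizes)
  N <- nrow(dataset$genotypes)
  mat <- NULL
  if (P <= max_dense_cols) {
    G <- dataset$genotypes
    ii <- jj <- vector("list", nrow(groups))
    for (g in seq_len(nrow(groups))) {
      lev <- if (is.na(groups$b[g])) G[, groups$a[g]]
             else 3L * G[, groups$a[g]] + G[, groups$b[g]]
      ii[[g]] <- seq_len(N)
      jj[[g]] <- groups$col_start[g] + lev
    }
    mat <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                                dims = c(N, P))
    colnames(mat) <- unlist(lapply(seq_len(nrow(groups)), function(g) {
      paste0(groups$label[g], ".", seq_len(groups$size[g]))
    }))
  }
  structure(list(genotypes = dataset$genotypes, groups = groups,
                 snp_ids = dataset$snp_ids, n = N, p = P, matrix = mat,
                 max_dense_cols = max_dense_cols),
            class = "grouped_design")
}

#' @export
print.grouped_design <- function(x, ...) {
  n_pair <- sum(!is.na(x$groups$b))
  cat(sprintf("grouped_design: %d samples, %d groups (%d main, %d pair), %d columns%s\n",
              x$n, nrow(x$groups), nrow(x$groups) - n_pair, n_pair, x$p,
              if (is.null(x$matrix)) " [matrix not materialized]" else ""))
  invisible(x)
}

#' Main-effect grouped design
#'
#' One three-column dummy group per SNP, in SNP order; the design matrix is
#' N x 3L (the intercept is handled separately by the solver).
#'
#' @param dataset A [genotype_dataset()].
#' @param max_dense_cols Column budget above which the dummy matrix is not
#'   materialized (group blocks are then generated on the fly).
#' @return A `grouped_design`.
#' @export
build_main_design <- function(dataset, max_dense_cols = 30000) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  L <- ncol(dataset$genotypes)
  groups <- data.frame(a = seq_len(L), b = NA_integer_)
  new_grouped_design(dataset, groups, max_dense_cols)
}

#' Interaction grouped design (main effects + pairwise interactions)
#'
#' All L main-effect groups (3 columns each) followed by pair groups
#' (9 columns each) for every admitted unordered SNP pair in lexicographic
#' order.  The default admits all L(L-1)/2 pairs; `pair_filter` restricts
#' the pair set (a hook for external pre-screening).
#'
#' @param dataset A [genotype_dataset()].
#' @param pair_filter Optional predicate `function(a, b)` returning TRUE
#'   for pairs to admit (vectorized over equal-length index vectors).
#' @param max_dense_cols Column budget for materializing the dummy matrix;
#'   larger designs keep `matrix = NULL` and are handled lazily.
#' @return A `grouped_design`.
#' @export
build_interaction_design <- function(dataset, pair_filter = NULL,
                                     max_dense_cols = 30000) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  L <- ncol(dataset$genotypes)
  if (L < 2L) stop("interaction design needs at least 2 SNPs", call. = FALSE)
  a <- rep(seq_len(L - 1L), times = (L - 1L):1L)
  b <- sequence((L - 1L):1L) + a
  if (!is.null(pair_filter)) {
    keep <- pair_filter(a, b)
    a <- a[keep]; b <- b[keep]
  }
  groups <- data.frame(a = c(seq_len(L), a), b = c(rep(NA_integer_, L), b))
  new_grouped_design(dataset, groups, max_dense_cols)
}

#' Dummy design matrix of a grouped design
#'
#' Returns the sparse N x P dummy matrix, materializing it if necessary.
#' Refuses when the column count exceeds the design's budget unless
#' `force = TRUE`.
#'
#' @param design A `grouped_design`.
#' @param force Materialize even above the column budget.
#' @return A sparse `Matrix::dgCMatrix`.
#' @export
design_matrix <- function(design, force = FALSE) {
  stopifnot(inherits(design, "grouped_design"))
  if (!is.null(design$matrix)) return(design$matrix)
  if (!force) {
    stop(sprintf("design has %d columns, above the %d-column budget; use force = TRUE",
                 design$p, design$max_dense_cols), call. = FALSE)
  }
  d2 <- new_grouped_design(
    genotype_dataset(design$genotypes, rep(0L, design$n),
                     snp_ids = design$snp_ids),
    design$groups[, c("a", "b")], max_dense_cols = Inf)
  d2$matrix
}

#' Restrict a grouped design to a subset of groups
#'
#' @param design A `grouped_design`.
#' @param idx Integer row indices into `design$groups` (order preserved).
#' @return A `grouped_design` over the same samples with only those groups.
#' @export
subset_groups <- function(design, idx) {
  stopifnot(inherits(design, "grouped_design"))
  groups <- design$groups[idx, c("a", "b"), drop = FALSE]
  ds <- genotype_dataset(design$genotypes, rep(0L, design$n),
                         snp_ids = design$snp_ids)
  new_grouped_design(ds, groups, design$max_dense_cols)
}
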