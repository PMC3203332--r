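#' Write a genotype dataset to disk
#'
#' Two plain-text formats are supported.  `tsv`: a header row of SNP ids
#' plus a final `phenotype` column, then one row per sample with genotypes
#' 0/1/2 and phenotype 0/1.  `plink_raw`: the PLINK `.raw` additive-coding
#' dialect with leading columns FID IID PAT MAT SEX PHENOTYPE (phenotype
#' coded 1 = control, 2 = case) followed by one `<snp>_m` minor-allele
#' count column per SNP.  A sidecar JSON (`<path>.json`) records model
#' name, parameters, seed and truth loci when `sidecar = TRUE`.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file path.
#' @param format `"tsv"` or `"plink_raw"`.
#' @param sidecar Write the provenance JSON next to the file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, format = c("tsv", "plink_raw"),
                            sidecar = TRUE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(dataset$genotypes)
    names(df) <- dataset$snp_ids
    df$phenotype <- dataset$phenotype
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    n <- nrow(dataset$genotypes)
    df <- data.frame(FID = paste0("F", seq_len(n)),
                     IID = paste0("I", seq_len(n)),
                     PAT = 0L, MAT = 0L, SEX = 0L,
                     PHENOTYPE = dataset$phenotype + 1L)
    geno <- as.data.frame(dataset$genotypes)
    names(geno) <- paste0(dataset$snp_ids, "_m")
    utils::write.table(cbind(df, geno), path, sep = " ", quote = FALSE,
                       row.names = FALSE)
  }
  if (sidecar) {
    jsonlite::write_json(
      list(format = format, seed = dataset$seed,
           n_samples = nrow(dataset$genotypes),
           n_snps = ncol(dataset$genotypes),
           truth = dataset$truth, meta = dataset$meta),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a genotype dataset from disk
#'
#' Counterpart of [write_genotypes()].  Validates every genotype entry
#' (must be 0, 1 or 2) and the phenotype (binary; PLINK 1/2 is recoded to
#' 0/1).  Offending SNPs and rows are named in the error.  If a sidecar
#' JSON is present its seed and truth loci are restored.
#'
#' @param path Input file path.
#' @param format `"tsv"` or `"plink_raw"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "tsv") "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "tsv") {
    if (!"phenotype" %in% names(df)) {
      stop("tsv genotype file must contain a `phenotype` column",
           call. = FALSE)
    }
    phen <- df$phenotype
    geno <- df[, setdiff(names(df), "phenotype"), drop = FALSE]
    snp_ids <- names(geno)
    if (!all(phen %in% 0:1)) {
      stop("phenotype must be 0/1 in tsv format", call. = FALSE)
    }
  } else {
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% names(df))) {
      stop("plink_raw file must start with columns ",
           paste(lead, collapse = " "), call. = FALSE)
    }
    phen_raw <- df$PHENOTYPE
    if (!all(phen_raw %in% 1:2)) {
      stop("PHENOTYPE must be 1 (control) / 2 (case) in plink_raw format",
           call. = FALSE)
    }
    phen <- phen_raw - 1L
    geno <- df[, setdiff(names(df), lead), drop = FALSE]
    snp_ids <- sub("_[ACGTm]+$", "", names(geno))
  }
  bad <- vapply(geno, function(col) !all(col %in% 0:2), TRUE)
  if (any(bad)) {
    stop("non-{0,1,2} genotype in SNP(s): ",
         paste(snp_ids[bad], collapse = ", "), call. = FALSE)
  }
  G <- as.matrix(geno)
  seed <- NA_integer_
  truth <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seed <- if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_
    if (!is.null(meta$truth)) {
      pr <- meta$truth$pairs
      pairs <- if (is.null(pr)) {
        list()
      } else if (is.matrix(pr)) {
        lapply(seq_len(nrow(pr)), function(i) as.integer(pr[i, ]))
      } else {
        lapply(pr, as.integer)
      }
      truth <- list(loci = as.integer(meta$truth$loci), pairs = pairs)
    }
  }
  genotype_dataset(G, phen, snp_ids = snp_ids, truth = truth, seed = seed)
}
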