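# Access to non-exported plumbing used by a few tests.

warm_path_active_sets <- function(design, y, grid,
                                  control = agl_control()) {
  ctl <- unclass(control)
  ctl$dfmax <- 0L
  res <- aglsnp:::.glpath_cpp(
    design$genotypes, as.numeric(y),
    design$groups$a - 1L,
    ifelse(is.na(design$groups$b), -1L, design$groups$b - 1L),
    rep(1, nrow(design$groups)), grid,
    seq_len(design$n) - 1L, integer(0), ctl, FALSE)
  res$active
}

dummy_cols_for_test <- function(genotypes, groups) {
  aglsnp:::dummy_cols(genotypes, groups)
}
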