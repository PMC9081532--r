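# Shared fixtures, all built in code.

# two toy signatures with disjoint channel support
disjoint_catalog <- function() {
  s1 <- c(rep(1 / 8, 8), rep(0, 88))
  s2 <- c(rep(0, 88), rep(1 / 8, 8))
  signature_catalog(rbind(S1 = s1, S2 = s2))
}

# k sparse toy signatures on non-overlapping channel blocks
block_catalog <- function(k, block = 8) {
  stopifnot(k * block <= 96)
  mat <- matrix(0, k, 96)
  for (i in seq_len(k)) mat[i, (i - 1) * block + seq_len(block)] <- 1 / block
  rownames(mat) <- paste0("S", seq_len(k))
  signature_catalog(mat)
}

# multinomial spectra from given true exposures
draw_spectra <- function(exposures, catalog, n_mutations, seed) {
  set.seed(seed)
  exposures <- as.matrix(exposures)
  out <- t(vapply(seq_len(nrow(exposures)), function(i) {
    p <- drop(crossprod(catalog$matrix, exposures[i, ]))
    stats::rmultinom(1, n_mutations, p)[, 1]
  }, numeric(96)))
  colnames(out) <- channel_labels()
  rownames(out) <- rownames(exposures) %||%
    paste0("SAMP", seq_len(nrow(exposures)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unname_rows <- function(m) { rownames(m) <- NULL; m }

write_toy_maf <- function(path, rows) {
  header <- paste(c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                    "Reference_Allele", "Tumor_Seq_Allele2", "Hugo_Symbol",
                    "ref_context"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}
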