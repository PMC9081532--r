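# Per-sample 96-channel spectra from mutation records.

#' Annotate trinucleotide contexts from a reference genome
#'
#' Fills the `context` column of a mutation record table with the 3-mer
#' `genome[pos-1 .. pos+1]`. Records whose genome base disagrees with the
#' recorded reference allele are dropped; records on missing chromosomes or
#' at contig edges are skipped. Counts of each are attached as the
#' `"reconciliation"` attribute.
#'
#' @param records Mutation record data frame (see [read_maf()]).
#' @param genome Named character vector of chromosome sequences (names
#'   without the `"chr"` prefix), or any object coercible to one with
#'   `as.character()` that keeps its names (e.g. a `Biostrings::DNAStringSet`).
#' @return The record table with `context` set, minus dropped/skipped rows.
#' @export
annotate_context <- function(records, genome) {
  seqs <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  if (is.null(names(seqs))) stop("genome must be a named sequence set")
  names(seqs) <- sub("^chr", "", names(seqs))
  chrom_ok <- records$chrom %in% names(seqs)
  lens <- nchar(seqs)[records$chrom]
  edge_ok <- chrom_ok & records$pos > 1L & records$pos < lens
  ctx <- rep(NA_character_, nrow(records))
  if (any(edge_ok)) {
    ctx[edge_ok] <- toupper(substr(seqs[records$chrom[edge_ok]],
                                   records$pos[edge_ok] - 1L,
                                   records$pos[edge_ok] + 1L))
  }
  ref_match <- edge_ok & substr(ctx, 2L, 2L) == records$ref
  report <- c(missing_chrom = sum(!chrom_ok),
              contig_edge = sum(chrom_ok & !edge_ok),
              ref_mismatch = sum(edge_ok & !ref_match))
  if (sum(report) > 0L) {
    message("annotate_context: dropped ", sum(report), " record(s) (",
            paste(names(report), report, sep = "=", collapse = ", "), ")")
  }
  out <- records[ref_match, , drop = FALSE]
  out$context <- ctx[ref_match]
  attr(out, "reconciliation") <- report
  out
}

#' Build per-sample 96-channel spectra
#'
#' Counts the classifiable substitutions of each sample over the canonical
#' channels. Records lacking a context, or with ambiguous (non-ACGT) bases,
#' are skipped and counted in the `"skipped"` attribute.
#'
#' @param records Mutation record data frame with `context` set (from
#'   [read_maf()] with a `ref_context` column, or [annotate_context()]).
#' @return Integer matrix, samples x 96, rownames = sample ids, colnames =
#'   [channel_labels()]. Attribute `"skipped"` holds the skip count.
#' @export
build_spectra <- function(records) {
  idx <- classify_channel(records$ref, records$alt, records$context,
                          on_error = "na")
  ok <- !is.na(idx)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message("build_spectra: skipped ", n_skipped,
            " record(s) without a classifiable context")
  }
  samples <- unique(records$sample_id)
  spectra <- matrix(0L, nrow = length(samples), ncol = 96L,
                    dimnames = list(samples, CHANNELS96))
  if (any(ok)) {
    tab <- table(factor(records$sample_id[ok], levels = samples),
                 factor(idx[ok], levels = 1:96))
    spectra[] <- as.integer(tab)
  }
  attr(spectra, "skipped") <- n_skipped
  spectra
}
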