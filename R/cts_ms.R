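# Cancer-type-specific signature patterns and tumor-specific mutation
# markers from a labeled cohort.

.check_cohort <- function(exposures, types) {
  exposures <- as.matrix(exposures)
  types <- as.character(types)
  stopifnot(nrow(exposures) == length(types))
  list(exposures = exposures, types = types)
}

#' Per-type signature prevalence
#'
#' For each (type, signature) pair, the fraction of that type's samples in
#' which the signature contributes strictly more than `presence_cutoff`.
#'
#' @param exposures Samples x signatures matrix of contributions in `[0, 1]`.
#' @param types Cancer-type label per sample.
#' @param presence_cutoff Contribution above which a signature counts as
#'   observed in a sample (strict inequality; default 0.06).
#' @return Types x signatures matrix of fractions.
#' @export
signature_prevalence <- function(exposures, types, presence_cutoff = 0.06) {
  ck <- .check_cohort(exposures, types)
  lv <- unique(ck$types)
  present <- ck$exposures > presence_cutoff
  res <- vapply(lv, function(t) colMeans(present[ck$types == t, , drop = FALSE]),
                numeric(ncol(ck$exposures)))
  if (is.null(dim(res))) res <- matrix(res, nrow = 1L)  # single-signature case
  out <- t(res)
  dimnames(out) <- list(lv, colnames(ck$exposures))
  out
}

#' Select cancer-type-specific signatures (CTS-MS)
#'
#' A signature is specific to `type_name` when it is observed (contribution
#' strictly above `presence_cutoff`) in at least `min_fraction` of the
#' type's samples, its mean contribution shows a fold change strictly above
#' `min_fc` versus all other samples pooled, and the absolute difference of
#' means strictly exceeds `min_diff`. The fold change uses a symmetric
#' pseudo-count: `(m_type + epsilon) / (m_rest + epsilon)`.
#'
#' @inheritParams signature_prevalence
#' @param type_name The cancer type to characterize.
#' @param min_fraction Minimum within-type prevalence (default 0.20).
#' @param min_fc Minimum fold change, strict (default 1.5).
#' @param min_diff Minimum absolute difference of means, strict (default 0.1).
#' @param epsilon Pseudo-count protecting the fold change from zero means.
#' @param center `"mean"` (default) or `"median"` location for the
#'   within/rest comparison.
#' @return Data frame sorted by `abs_diff` descending, with columns
#'   `signature`, `fraction_in_type`, `mean_in_type`, `mean_in_rest`,
#'   `fold_change`, `abs_diff` — only the signatures passing all three
#'   filters.
#' @export
select_cts_ms <- function(exposures, types, type_name, min_fraction = 0.20,
                          min_fc = 1.5, min_diff = 0.1, epsilon = 1e-3,
                          presence_cutoff = 0.06,
                          center = c("mean", "median")) {
  center <- match.arg(center)
  ck <- .check_cohort(exposures, types)
  if (!type_name %in% ck$types) stop("unknown type: ", type_name)
  if (length(unique(ck$types)) < 2L) {
    stop("CTS-MS selection needs at least two cancer types")
  }
  in_type <- ck$types == type_name
  loc <- if (center == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)
  m_t <- loc(ck$exposures[in_type, , drop = FALSE])
  m_r <- loc(ck$exposures[!in_type, , drop = FALSE])
  frac <- colMeans(ck$exposures[in_type, , drop = FALSE] > presence_cutoff)
  fc <- (m_t + epsilon) / (m_r + epsilon)
  ad <- abs(m_t - m_r)
  keep <- frac >= min_fraction & fc > min_fc & ad > min_diff
  out <- data.frame(signature = colnames(ck$exposures),
                    fraction_in_type = frac, mean_in_type = m_t,
                    mean_in_rest = m_r, fold_change = fc, abs_diff = ad,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$abs_diff), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "type_name") <- type_name
  out
}

#' Select tumor-specific mutation markers
#'
#' Candidate genes are those mutated in strictly more than `min_freq` of the
#' type's samples; a candidate is retained when its mutation frequency
#' differs from the pooled rest by strictly more than `min_diff`.
#'
#' @param gene_matrix Samples x genes binary mutation indicator matrix.
#' @param types Cancer-type label per sample.
#' @param type_name The cancer type to characterize.
#' @param min_freq Candidate threshold on within-type frequency (strict;
#'   default 0.05).
#' @param min_diff Required absolute frequency difference (strict; default 0.1).
#' @return Data frame sorted by `abs_diff` descending with columns `gene`,
#'   `freq_in_type`, `freq_in_rest`, `abs_diff`.
#' @export
select_specific_mutations <- function(gene_matrix, types, type_name,
                                      min_freq = 0.05, min_diff = 0.1) {
  ck <- .check_cohort(gene_matrix, types)
  if (!type_name %in% ck$types) stop("unknown type: ", type_name)
  if (length(unique(ck$types)) < 2L) {
    stop("marker selection needs at least two cancer types")
  }
  in_type <- ck$types == type_name
  f_t <- colMeans(ck$exposures[in_type, , drop = FALSE] > 0)
  f_r <- colMeans(ck$exposures[!in_type, , drop = FALSE] > 0)
  ad <- abs(f_t - f_r)
  keep <- f_t > min_freq & ad > min_diff
  out <- data.frame(gene = colnames(ck$exposures), freq_in_type = f_t,
                    freq_in_rest = f_r, abs_diff = ad,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$abs_diff), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "type_name") <- type_name
  out
}
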