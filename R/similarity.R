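# Sample-pair cosine similarity, cohort-level aggregation, the rank
# normalization sequence, and primary-metastasis concordance.

#' Pairwise cosine similarity between two exposure matrices
#'
#' @param exposures_m,exposures_n Numeric matrices (m x k and n x k) with no
#'   all-zero rows.
#' @return m x n matrix with entry (i, j) the cosine similarity of row i of
#'   `exposures_m` and row j of `exposures_n`.
#' @export
pairwise_rho <- function(exposures_m, exposures_n) {
  A <- as.matrix(exposures_m)
  B <- as.matrix(exposures_n)
  stopifnot(ncol(A) == ncol(B))
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  if (any(na == 0)) {
    stop("all-zero exposure row for sample: ",
         paste(utils::head(rownames(A)[na == 0], 3), collapse = ", "))
  }
  if (any(nb == 0)) {
    stop("all-zero exposure row for sample: ",
         paste(utils::head(rownames(B)[nb == 0], 3), collapse = ", "))
  }
  tcrossprod(A, B) / outer(na, nb)
}

#' Aggregate a similarity matrix into a scalar cohort similarity
#'
#' Summarizes an m x n pairwise-similarity matrix as either the mean of its
#' entries (default) or the mean of their squares.
#'
#' @param rho Numeric m x n matrix of pairwise similarities.
#' @param variant `"mean"` for `sum(rho) / (m n)`, `"mean_square"` for
#'   `sum(rho^2) / (m n)`.
#' @return Scalar aggregate similarity.
#' @export
aggregate_similarity <- function(rho, variant = c("mean", "mean_square")) {
  variant <- match.arg(variant)
  rho <- as.matrix(rho)
  if (length(rho) == 0L) stop("empty similarity matrix")
  if (variant == "mean") sum(rho) / length(rho) else sum(rho^2) / length(rho)
}

#' Row/column normalization of a similarity matrix
#'
#' Applies, strictly in order: (1) subtract row means; (2) subtract column
#' means; (3) replace each row by its average ranks divided by the number of
#' columns; (4) replace each column by its average ranks divided by the
#' number of rows. Ties receive average ranks.
#'
#' @param mat Numeric matrix with at least 2 rows and 2 columns.
#' @return The normalized matrix (entries in (0, 1]).
#' @export
normalize_similarity <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("normalization needs at least 2 rows and 2 columns")
  }
  m <- mat - rowMeans(mat)
  m <- sweep(m, 2L, colMeans(m))
  m <- t(apply(m, 1L, rank, ties.method = "average")) / ncol(m)
  m <- apply(m, 2L, rank, ties.method = "average") / nrow(m)
  dimnames(m) <- dimnames(mat)
  m
}

#' Primary-metastasis exposure concordance
#'
#' Compares the cosine similarity of matched primary/metastasis exposure
#' pairs (within) against the similarity of each primary to background
#' samples of other tumor types (between), with a two-sided rank-sum test.
#'
#' @param primary,metastasis Aligned numeric matrices (pairs x signatures):
#'   row i of `metastasis` is the lesion paired with row i of `primary`.
#' @param background Numeric matrix of comparison samples (rows) with the
#'   same signature columns.
#' @param background_types Type label per background row.
#' @param primary_types Type label per pair.
#' @return List with `within` (per-pair similarities), `between` (pooled
#'   cross-type similarities), and `p_value`.
#' @export
primary_met_concordance <- function(primary, metastasis, background,
                                    background_types, primary_types) {
  primary <- as.matrix(primary)
  metastasis <- as.matrix(metastasis)
  stopifnot(nrow(primary) == nrow(metastasis),
            length(primary_types) == nrow(primary),
            length(background_types) == nrow(background))
  if (nrow(background) == 0L) stop("empty background pool")
  within <- vapply(seq_len(nrow(primary)),
                   function(i) cosine_sim(primary[i, ], metastasis[i, ]),
                   numeric(1))
  between <- unlist(lapply(seq_len(nrow(primary)), function(i) {
    other <- background_types != primary_types[i]
    if (!any(other)) return(numeric(0))
    drop(pairwise_rho(primary[i, , drop = FALSE],
                      background[other, , drop = FALSE]))
  }))
  if (length(between) == 0L) {
    stop("background pool contains no samples of a different type")
  }
  p <- stats::wilcox.test(within, between, exact = FALSE)$p.value
  list(within = within, between = between, p_value = p)
}
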