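# Mutation connection score: the fraction of a sample's mutated genes with
# at least one protein-protein interaction among the mutated set.

#' Mutation connection score of a mutated gene set
#'
#' Induces the subgraph of the interaction network on the sample's mutated
#' genes and reports the fraction of mutated genes with degree >= 1 in that
#' induced subgraph. Genes absent from the network count as unconnected.
#' Gene symbols are matched case-insensitively after trimming.
#'
#' @param mutated_genes Non-empty character vector of mutated gene symbols
#'   (duplicates collapsed).
#' @param network A [ppi_network()].
#' @param mode `"induced"` (default) counts interactions among the mutated
#'   genes themselves; `"full"` counts any interaction of a mutated gene in
#'   the whole network, making the score a pure coverage measure.
#' @return List with `n_mutated`, `n_connected`, and `score`
#'   (`n_connected / n_mutated`).
#' @export
connection_score <- function(mutated_genes, network,
                             mode = c("induced", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "ppi_network"))
  genes <- unique(toupper(trimws(as.character(mutated_genes))))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("empty mutated gene set")
  e <- network$edges
  if (mode == "induced") {
    keep <- e$from %in% genes & e$to %in% genes
    connected <- unique(c(e$from[keep], e$to[keep]))
  } else {
    connected <- intersect(genes, unique(c(e$from, e$to)))
  }
  n_c <- length(intersect(genes, connected))
  list(n_mutated = length(genes), n_connected = n_c,
       score = n_c / length(genes))
}

#' Compare connection scores (or any scores) between groups
#'
#' Pairwise two-sided rank-sum comparison of score distributions. When the
#' total sample size is small enough for full enumeration, an exact
#' permutation distribution of the rank-sum statistic is used (correct in
#' the presence of ties); otherwise the tie-corrected normal approximation
#' of `stats::wilcox.test()`.
#'
#' @param scores_by_group Named list of numeric vectors, each of length >= 2.
#' @param max_enumeration Largest number of group assignments enumerated
#'   exactly.
#' @return Data frame with one row per group pair: `group_a`, `group_b`,
#'   `statistic` (rank sum of group a), `p_value`, `method`.
#' @export
compare_score_groups <- function(scores_by_group, max_enumeration = 20000) {
  stopifnot(is.list(scores_by_group), length(scores_by_group) >= 2L)
  if (is.null(names(scores_by_group))) {
    names(scores_by_group) <- paste0("group", seq_along(scores_by_group))
  }
  sizes <- lengths(scores_by_group)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 observations; offending group(s): ",
         paste(names(scores_by_group)[sizes < 2L], collapse = ", "))
  }
  pairs <- utils::combn(names(scores_by_group), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- scores_by_group[[pairs[1L, i]]]
    b <- scores_by_group[[pairs[2L, i]]]
    m <- length(a); n <- length(b)
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_len(m)])
    n_comb <- choose(m + n, m)
    if (n_comb <= max_enumeration) {
      combos <- utils::combn(m + n, m)
      w_all <- colSums(matrix(r[combos], nrow = m))
      p <- min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                          mean(w_all >= w_obs - 1e-9)))
      method <- "exact"
    } else {
      p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
      method <- "normal"
    }
    data.frame(group_a = pairs[1L, i], group_b = pairs[2L, i],
               statistic = w_obs, p_value = p, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
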