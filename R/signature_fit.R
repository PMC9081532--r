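# Exposure refitting against a reference catalog, exhaustive-subset oracle,
# de novo extraction by NMF, and catalog mapping by cosine similarity.

#' Cosine similarity of two non-negative vectors
#'
#' @param u,v Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return `u . v / (|u| |v|)`, in `[0, 1]` for non-negative inputs.
#' @export
cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# Non-negative least squares on the Gram form: minimize |p - S'w|^2 given
# G = S S' and b = S p, by the Lawson-Hanson active-set method. Small dense
# problems only (catalog-sized); cross-checked against pracma::lsqnonneg in
# the test suite.
nnls_gram <- function(G, b) {
  n <- length(b)
  eps <- 1e-12 * max(c(diag(G), 1))
  P <- logical(n)
  w <- numeric(n)
  solve_P <- function(idx) {
    tryCatch(drop(solve(G[idx, idx, drop = FALSE], b[idx])),
             error = function(e) drop(qr.solve(G[idx, idx, drop = FALSE], b[idx])))
  }
  for (outer in seq_len(3L * n + 10L)) {
    grad <- b - drop(G %*% w)
    cand <- which(!P & grad > eps)
    if (length(cand) == 0L) break
    P[cand[which.max(grad[cand])]] <- TRUE
    z <- solve_P(which(P))
    while (any(z <= eps)) {
      idx <- which(P)
      wz <- w[idx]
      neg <- which(z <= eps)
      alpha <- suppressWarnings(min(wz[neg] / (wz[neg] - z[neg])))
      if (!is.finite(alpha) || alpha < 0) alpha <- 0
      w[idx] <- wz + alpha * (z - wz)
      drop_i <- idx[w[idx] <= eps | seq_along(idx) %in% neg & alpha == 0]
      P[drop_i] <- FALSE
      w[drop_i] <- 0
      if (!any(P)) break
      z <- solve_P(which(P))
    }
    w[] <- 0
    if (any(P)) w[which(P)] <- z
  }
  w
}

.refit_prepare <- function(counts, catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  counts <- as.numeric(counts)
  if (length(counts) != 96L) stop("expected a 96-channel spectrum")
  if (nrow(catalog$matrix) == 0L) stop("empty signature catalog")
  total <- sum(counts)
  if (total <= 0) stop("degenerate input: spectrum contains no mutations")
  list(p = counts / total, S = catalog$matrix, total = total)
}

# solve NNLS on an active set and rescale so the weights sum to at most 1
.solve_rescaled <- function(G, b, idx) {
  w <- nnls_gram(G[idx, idx, drop = FALSE], b[idx])
  s <- sum(w)
  if (s > 1) w <- w / s
  w
}

# iterate the contribution cutoff: zero weights under `cutoff`, re-solve on
# the survivors, repeat until every surviving weight clears the cutoff
.apply_cutoff <- function(G, b, idx, w, cutoff) {
  k <- length(b)
  w_full <- numeric(k)
  w_full[idx] <- w
  repeat {
    keep <- which(w_full >= cutoff)
    w_full <- numeric(k)
    if (length(keep) == 0L) break
    w_new <- .solve_rescaled(G, b, keep)
    w_full[keep] <- w_new
    if (all(w_new >= cutoff)) break
  }
  w_full
}

.sse_quad <- function(pp, G, b, w_full) {
  nz <- which(w_full > 0)
  if (length(nz) == 0L) return(pp)
  w <- w_full[nz]
  pp - 2 * sum(b[nz] * w) +
    drop(t(w) %*% G[nz, nz, drop = FALSE] %*% w)
}

#' Refit signature exposures by forward selection
#'
#' Estimates the non-negative linear combination of catalog signatures that
#' best reconstructs a sample's normalized spectrum. Signatures are added
#' greedily: at each step the candidate whose inclusion most reduces the
#' residual sum of squares is added, with the active-set weights re-solved
#' jointly by non-negative least squares and rescaled so they sum to at most
#' 1. Selection stops when the relative SSE improvement falls below `tol`.
#' Finally, contributions below `cutoff` are zeroed and the surviving set is
#' re-solved, so every reported weight is either 0 or at least `cutoff`.
#'
#' @param counts Integer/numeric vector of 96 channel counts (total >= 1).
#' @param catalog A [signature_catalog()].
#' @param cutoff Minimum reportable contribution (default 0.06).
#' @param tol Relative SSE improvement below which selection stops.
#' @param sample_id Optional sample label carried into the result.
#' @return An `exposure_profile`: list with `sample_id`, `weights` (named
#'   over all catalog signatures, zeros included), `residual_error` (final
#'   SSE on the normalized spectrum) and `total` (input mutation count).
#' @export
refit_exposures <- function(counts, catalog, cutoff = 0.06, tol = 1e-3,
                            sample_id = NULL) {
  prep <- .refit_prepare(counts, catalog)
  S <- prep$S; p <- prep$p
  k <- nrow(S)
  G <- S %*% t(S)
  b <- drop(S %*% p)
  pp <- sum(p * p)

  active <- integer(0)
  sse_cur <- pp
  remaining <- seq_len(k)
  w_cur <- numeric(0)
  while (length(remaining) > 0L) {
    best_sse <- Inf
    best_j <- NA_integer_
    best_w <- NULL
    for (j in remaining) {  # ascending order: lowest index wins exact ties
      idx <- c(active, j)
      w <- .solve_rescaled(G, b, idx)
      sse <- pp - 2 * sum(b[idx] * w) +
        drop(t(w) %*% G[idx, idx, drop = FALSE] %*% w)
      if (sse < best_sse) {
        best_sse <- sse; best_j <- j; best_w <- w
      }
    }
    improve <- (sse_cur - best_sse) / max(sse_cur, .Machine$double.xmin)
    if (length(active) > 0L && improve < tol) break
    if (length(active) == 0L && best_sse > sse_cur) break
    active <- c(active, best_j)
    remaining <- setdiff(remaining, best_j)
    w_cur <- best_w
    sse_cur <- best_sse
  }

  w_full <- .apply_cutoff(G, b, active, w_cur, cutoff)
  weights <- stats::setNames(w_full, catalog$names)
  structure(list(sample_id = sample_id, weights = weights,
                 residual_error = .sse_quad(pp, G, b, w_full),
                 total = prep$total),
            class = "exposure_profile")
}

#' Refit every sample of a spectra matrix
#'
#' @param spectra Samples x 96 count matrix (see [build_spectra()]).
#' @inheritParams refit_exposures
#' @return List with `exposures` (samples x signatures matrix) and
#'   `residuals` (named numeric vector of reconstruction SSEs).
#' @export
refit_cohort <- function(spectra, catalog, cutoff = 0.06, tol = 1e-3) {
  n <- nrow(spectra)
  exposures <- matrix(0, n, length(catalog$names),
                      dimnames = list(rownames(spectra), catalog$names))
  residuals <- stats::setNames(numeric(n), rownames(spectra))
  for (i in seq_len(n)) {
    fit <- refit_exposures(spectra[i, ], catalog, cutoff = cutoff, tol = tol,
                           sample_id = rownames(spectra)[i])
    exposures[i, ] <- fit$weights
    residuals[i] <- fit$residual_error
  }
  list(exposures = exposures, residuals = residuals)
}

#' Exhaustive-subset refitting oracle
#'
#' Brute-force reference for [refit_exposures()]: enumerates every signature
#' subset up to `max_subset`, solves non-negative least squares on each
#' (rescaled so weights sum to at most 1), keeps the global SSE minimizer,
#' then applies the same contribution cutoff rule. Only feasible for small
#' catalogs; refuses more than 12 signatures.
#'
#' @inheritParams refit_exposures
#' @param max_subset Largest subset size to enumerate.
#' @return An `exposure_profile` (see [refit_exposures()]).
#' @export
nnls_subset_oracle <- function(counts, catalog, max_subset = nrow(catalog$matrix),
                               cutoff = 0.06, sample_id = NULL) {
  if (nrow(catalog$matrix) > 12L) {
    stop("catalog too large for exhaustive enumeration; use refit_exposures()")
  }
  prep <- .refit_prepare(counts, catalog)
  S <- prep$S; p <- prep$p
  k <- nrow(S)
  pp <- sum(p * p)
  best_sse <- pp
  best_idx <- integer(0)
  best_w <- numeric(0)
  for (size in seq_len(min(max_subset, k))) {
    combos <- utils::combn(k, size)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      A <- t(S[idx, , drop = FALSE])
      w <- pracma::lsqnonneg(A, p)$x
      s <- sum(w)
      if (s > 1) w <- w / s
      resid <- p - A %*% w
      sse <- sum(resid^2)
      if (sse < best_sse - 1e-15) {
        best_sse <- sse; best_idx <- idx; best_w <- w
      }
    }
  }
  G <- S %*% t(S)
  b <- drop(S %*% p)
  w_full <- .apply_cutoff(G, b, best_idx, best_w, cutoff)
  weights <- stats::setNames(w_full, catalog$names)
  structure(list(sample_id = sample_id, weights = weights,
                 residual_error = .sse_quad(pp, G, b, w_full),
                 total = prep$total),
            class = "exposure_profile")
}

#' De novo signature extraction by NMF
#'
#' Factorizes the row-normalized samples x 96 spectrum matrix into
#' non-negative loadings and signatures by multiplicative updates
#' minimizing Frobenius error, keeping the best of `n_restarts` seeded
#' restarts. Signature rows are renormalized to sum to 1, with loadings
#' rescaled compensatorily.
#'
#' @param spectra Samples x 96 count (or proportion) matrix.
#' @param k Number of signatures to extract (1 <= k <= number of samples).
#' @param n_restarts Number of random restarts (best kept).
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param max_iter Iteration cap per restart.
#' @param tol Relative Frobenius-error change declaring convergence.
#' @return A `denovo_result`: list with `signatures` (k x 96, rows sum to
#'   1), `loadings` (samples x k), `k`, `frobenius_error`, and `mapping`
#'   (`NULL` until [map_to_catalog()] is applied).
#' @export
extract_denovo <- function(spectra, k, n_restarts = 10, seed = 1,
                           max_iter = 2000, tol = 1e-6) {
  V <- as.matrix(spectra)
  rs <- rowSums(V)
  if (any(rs <= 0)) stop("spectra contain an empty sample")
  V <- V / rs
  n <- nrow(V)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k exceeds the number of samples (", n, ")")
  best_err <- Inf
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    H <- matrix(stats::runif(k * 96L, 0.1, 1), k, 96L)
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + 1e-12)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + 1e-12)
      if (it %% 10L == 0L) {
        err <- sum((V - W %*% H)^2)
        if (is.finite(err_prev) &&
            (err_prev - err) / max(err_prev, .Machine$double.xmin) < tol) break
        err_prev <- err
      }
    }
    err <- sum((V - W %*% H)^2)
    if (err < best_err) {
      best_err <- err
      best <- list(W = W, H = H)
    }
  }
  hs <- rowSums(best$H)
  H <- best$H / hs
  W <- sweep(best$W, 2L, hs, "*")
  rownames(H) <- paste0("DN", seq_len(k))
  colnames(H) <- CHANNELS96
  dimnames(W) <- list(rownames(spectra), rownames(H))
  structure(list(signatures = H, loadings = W, k = k,
                 frobenius_error = best_err, mapping = NULL),
            class = "denovo_result")
}

#' Map de novo signatures onto a reference catalog
#'
#' Each extracted signature is assigned to the catalog signature of maximal
#' cosine similarity when that maximum exceeds `threshold` (strictly),
#' otherwise it is left unmapped. Many-to-one mappings are permitted.
#'
#' @param denovo A `denovo_result` from [extract_denovo()].
#' @param catalog A [signature_catalog()].
#' @param threshold Similarity above which a match is accepted (default 0.75).
#' @return The `denovo_result` with `mapping` set: a data frame with columns
#'   `denovo`, `catalog` (`NA` when unmapped) and `similarity` (the best
#'   cosine similarity found).
#' @export
map_to_catalog <- function(denovo, catalog, threshold = 0.75) {
  stopifnot(inherits(denovo, "denovo_result"),
            inherits(catalog, "signature_catalog"))
  sims <- pairwise_rho(denovo$signatures, catalog$matrix)
  best <- apply(sims, 1L, which.max)
  best_sim <- sims[cbind(seq_len(nrow(sims)), best)]
  mapped <- best_sim > threshold
  denovo$mapping <- data.frame(
    denovo = rownames(denovo$signatures),
    catalog = ifelse(mapped, catalog$names[best], NA_character_),
    similarity = best_sim,
    stringsAsFactors = FALSE
  )
  denovo
}
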