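test_that("cosine similarity matches hand arithmetic", {
  v <- runif(96)
  expect_equal(cosine_sim(v, v), 1)
  expect_equal(cosine_sim(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_sim(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_error(cosine_sim(c(0, 0), c(1, 0)), "zero vector")
})

test_that("refit recovers an exact single-signature spectrum", {
  cat5 <- synthetic_catalog(5, seed = 3)
  counts <- round(cat5$matrix[3, ] * 1e6)
  fit <- refit_exposures(counts, cat5)
  expect_equal(unname(fit$weights["S3"]), 1, tolerance = 1e-6)
  expect_equal(sum(fit$weights > 0), 1L)
  expect_lt(fit$residual_error, 1e-10)
})

test_that("refit recovers a two-signature mix within tolerance", {
  cat2 <- disjoint_catalog()
  truth <- matrix(c(0.7, 0.3), 1, dimnames = list("x", c("S1", "S2")))
  sp <- draw_spectra(truth, cat2, 10000, seed = 11)
  fit <- refit_exposures(sp[1, ], cat2)
  expect_equal(unname(fit$weights["S1"]), 0.7, tolerance = 0.02)
  expect_equal(unname(fit$weights["S2"]), 0.3, tolerance = 0.02)
  # cross-check against the exhaustive oracle on the same spectrum
  oracle <- nnls_subset_oracle(sp[1, ], cat2)
  expect_equal(fit$weights, oracle$weights, tolerance = 1e-8)
})

test_that("contributions below the cutoff are zeroed exactly", {
  cat3 <- block_catalog(3)
  truth <- matrix(c(0.6, 0.36, 0.04), 1,
                  dimnames = list("x", c("S1", "S2", "S3")))
  # exact expected spectrum (no sampling noise): the 0.04 component must be
  # cut at the 0.06 threshold
  counts <- drop(crossprod(cat3$matrix, truth[1, ])) * 1e5
  fit <- refit_exposures(counts, cat3)
  expect_identical(unname(fit$weights["S3"]), 0)
  expect_true(all(fit$weights == 0 | fit$weights >= 0.06))
})

test_that("refit weights are invariant to count scaling", {
  cat4 <- synthetic_catalog(4, seed = 8)
  sp <- draw_spectra(matrix(c(0.5, 0.3, 0.2, 0), 1,
                            dimnames = list("x", cat4$names)),
                     cat4, 2000, seed = 2)
  f1 <- refit_exposures(sp[1, ], cat4)
  f2 <- refit_exposures(sp[1, ] * 7L, cat4)
  expect_equal(f1$weights, f2$weights)
  expect_equal(f1$residual_error, f2$residual_error)
})

test_that("degenerate refit inputs raise the documented errors", {
  cat2 <- disjoint_catalog()
  expect_error(refit_exposures(rep(0, 96), cat2), "degenerate")
  big <- synthetic_catalog(13, seed = 1)
  expect_error(nnls_subset_oracle(rep(1, 96), big), "refit_exposures")
})

test_that("oracle edge cases: single signature and empty subset", {
  cat1 <- signature_catalog(matrix(rep(1 / 96, 96), 1,
                                   dimnames = list("S1", NULL)))
  counts <- rep(10, 96)
  fit <- nnls_subset_oracle(counts, cat1)
  expect_equal(unname(fit$weights["S1"]), 1, tolerance = 1e-9)

  fit0 <- nnls_subset_oracle(counts, cat1, max_subset = 0)
  p <- counts / sum(counts)
  expect_identical(unname(fit0$weights["S1"]), 0)
  expect_equal(fit0$residual_error, sum(p^2))
})

test_that("forward-selection residual is non-increasing along its path", {
  cat8 <- synthetic_catalog(8, seed = 5)
  set.seed(31)
  for (r in 1:5) {
    expo <- sigtrace:::.rdirichlet1(rep(2, 8))
    names(expo) <- cat8$names
    sp <- draw_spectra(matrix(expo, 1, dimnames = list("x", cat8$names)),
                       cat8, 1000, seed = 100 + r)
    p <- sp[1, ] / sum(sp[1, ])
    # residual with the selected set can never exceed the best single fit
    fit <- refit_exposures(sp[1, ], cat8)
    best_single <- min(vapply(1:8, function(j) {
      w <- max(0, min(1, sum(cat8$matrix[j, ] * p) / sum(cat8$matrix[j, ]^2)))
      sum((p - w * cat8$matrix[j, ])^2)
    }, numeric(1)))
    expect_lte(fit$residual_error, best_single + 1e-12)
  }
})

test_that("NMF recovers a rank-1 cohort and is deterministic", {
  cat2 <- disjoint_catalog()
  profile <- cat2$matrix[1, ]
  sp <- t(vapply(1:6, function(i) round(profile * 1000 * i), numeric(96)))
  rownames(sp) <- paste0("s", 1:6)
  dn <- extract_denovo(sp, k = 1, n_restarts = 3, seed = 7)
  expect_gte(cosine_sim(dn$signatures[1, ], profile), 0.999)
  expect_equal(rowSums(dn$signatures), c(DN1 = 1), tolerance = 1e-6)
  dn2 <- extract_denovo(sp, k = 1, n_restarts = 3, seed = 7)
  expect_identical(dn, dn2)
  expect_error(extract_denovo(sp, k = 7), "exceeds")
})

test_that("catalog mapping uses strict similarity at the threshold", {
  cat5 <- block_catalog(5)
  dn <- structure(list(
    signatures = rbind(DN1 = cat5$matrix[2, ],
                       DN2 = rep(1 / 96, 96)),
    loadings = matrix(1, 1, 2), k = 2, frobenius_error = 0,
    mapping = NULL), class = "denovo_result")
  mapped <- map_to_catalog(dn, cat5, threshold = 0.75)
  expect_identical(mapped$mapping$catalog[1], "S2")
  expect_equal(mapped$mapping$similarity[1], 1)
  # uniform row: best cosine against an 8-channel block signature is
  # 8/ (sqrt(96) * sqrt(8)) = sqrt(8/96) ~= 0.2887 -> unmapped
  expect_true(is.na(mapped$mapping$catalog[2]))
  expect_equal(mapped$mapping$similarity[2], sqrt(8 / 96), tolerance = 1e-9)
  # exactly at the threshold stays unmapped (strict inequality)
  u <- cat5$matrix[3, ] / sqrt(sum(cat5$matrix[3, ]^2))
  v <- cat5$matrix[4, ] / sqrt(sum(cat5$matrix[4, ]^2))
  dn$signatures[2, ] <- 0.75 * u + sqrt(1 - 0.75^2) * v
  mapped2 <- map_to_catalog(dn, cat5, threshold = 0.75)
  expect_true(is.na(mapped2$mapping$catalog[2]))
  expect_equal(mapped2$mapping$similarity[2], 0.75, tolerance = 1e-9)
})
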