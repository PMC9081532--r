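make_cohort_exposures <- function() {
  # 10 samples of type A, 10 of type B over 3 signatures
  set.seed(1)
  expo <- rbind(
    cbind(S1 = rep(0.4, 10), S2 = rep(0.3, 10), S3 = rep(0.3, 10)),
    cbind(S1 = rep(0.05, 10), S2 = rep(0.45, 10), S3 = rep(0.5, 10))
  )
  list(expo = expo, types = rep(c("A", "B"), each = 10))
}

test_that("prevalence uses a strict presence cutoff", {
  expo <- matrix(c(rep(0.1, 3), rep(0, 7)), ncol = 1,
                 dimnames = list(NULL, "S1"))
  types <- rep("A", 10)
  expect_equal(unname(signature_prevalence(expo, types)[, "S1"]), 0.3)

  boundary <- matrix(rep(0.06, 10), ncol = 1, dimnames = list(NULL, "S1"))
  expect_equal(unname(signature_prevalence(boundary, types)[, "S1"]), 0)

  ones <- matrix(rep(1, 10), ncol = 1, dimnames = list(NULL, "S1"))
  expect_equal(unname(signature_prevalence(ones, types)[, "S1"]), 1)
})

test_that("CTS-MS selection applies the three filters with correct strictness", {
  ck <- make_cohort_exposures()
  sel <- select_cts_ms(ck$expo, ck$types, "A")
  expect_identical(sel$signature, "S1")   # diff 0.35, FC ~7.9, fraction 1
  expect_equal(sel$abs_diff, 0.35)
  expect_equal(sel$fold_change, (0.4 + 1e-3) / (0.05 + 1e-3), tolerance = 1e-9)

  # high fold change but insufficient prevalence is rejected
  expo <- cbind(S1 = c(rep(0.9, 1), rep(0, 9), rep(0, 10)),
                S2 = c(rep(0.1, 1), rep(1, 9), rep(1, 10)))
  types <- rep(c("A", "B"), each = 10)
  sel2 <- select_cts_ms(expo, types, "A", min_fraction = 0.2)
  expect_false("S1" %in% sel2$signature)

  expect_error(select_cts_ms(ck$expo, rep("A", 20), "A"), "two cancer types")
  expect_error(select_cts_ms(ck$expo, ck$types, "Z"), "unknown type")
})

test_that("selection is monotone in its thresholds and order-invariant", {
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 4)
  co <- simulate_cohort(profs, 30, cat12, seed = 3)
  sel_loose <- select_cts_ms(co$exposures, co$truth$type, "TYPE01",
                             min_fraction = 0.1, min_fc = 1.2, min_diff = 0.05)
  sel_tight <- select_cts_ms(co$exposures, co$truth$type, "TYPE01")
  expect_true(all(sel_tight$signature %in% sel_loose$signature))

  perm <- sample(nrow(co$exposures))
  sel_perm <- select_cts_ms(co$exposures[perm, ], co$truth$type[perm],
                            "TYPE01")
  expect_identical(sel_perm, sel_tight)

  dup <- select_cts_ms(rbind(co$exposures, co$exposures),
                       c(co$truth$type, co$truth$type), "TYPE01")
  expect_identical(dup, sel_tight)
})

test_that("planted type-specific signatures are recovered from true exposures", {
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 6)
  for (seed in 1:3) {
    co <- simulate_cohort(profs, 50, cat12, seed = seed)
    for (t in names(profs)) {
      sel <- select_cts_ms(co$exposures, co$truth$type, t)
      expect_true(profs[[t]]$specific_signatures %in% sel$signature)
      # shared background signatures (true diff 0) never selected
      shared <- cat12$names[11:12]
      expect_false(any(shared %in% sel$signature))
    }
  }
})

test_that("mutation-marker selection applies strict frequency rules", {
  gm <- cbind(
    HOT = c(rep(1, 6), rep(0, 14)),    # 60% in A, 0% in B
    HOT_B = c(rep(0, 10), rep(1, 4), rep(0, 6)),
    RARE = c(1, rep(0, 19))            # exactly 10% in A
  )
  types <- rep(c("A", "B"), each = 10)
  sel <- select_specific_mutations(gm, types, "A", min_freq = 0.1,
                                   min_diff = 0.1)
  expect_true("HOT" %in% sel$gene)
  expect_false("RARE" %in% sel$gene)   # candidacy is strict: 0.1 is not > 0.1
  expect_equal(sel$abs_diff[sel$gene == "HOT"], 0.6)

  # planted 0.4-vs-0.02 driver recovered across seeds
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 4)
  for (seed in 4:6) {
    co <- simulate_cohort(profs, 50, cat12, background_rate = 0.02,
                          seed = seed)
    sel <- select_specific_mutations(co$gene_matrix, co$truth$type, "TYPE02")
    expect_true(all(names(profs$TYPE02$driver_gene_freqs) %in% sel$gene))
  }
})
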