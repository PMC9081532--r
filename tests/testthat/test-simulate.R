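test_that("cohorts are reproducible and respect the degenerate concentration", {
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 3)
  co1 <- simulate_cohort(profs, 5, cat12, seed = 9)
  co2 <- simulate_cohort(profs, 5, cat12, seed = 9)
  expect_identical(co1, co2)

  co_inf <- simulate_cohort(profs, 4, cat12, concentration = Inf, seed = 9)
  for (t in names(profs)) {
    rows <- co_inf$truth$type == t
    em <- numeric(12); names(em) <- cat12$names
    em[names(profs[[t]]$exposure_mean)] <- profs[[t]]$exposure_mean
    expect_true(all(apply(co_inf$exposures[rows, , drop = FALSE], 1,
                          function(r) all(abs(r - em) < 1e-12))))
  }
})

test_that("spectra sum to the recorded burden and exposures to one", {
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 4)
  co <- simulate_cohort(profs, 10, cat12, seed = 21)
  expect_identical(unname(rowSums(co$spectra)), as.numeric(co$truth$mutation_count))
  expect_true(all(abs(rowSums(co$exposures) - 1) < 1e-9))
  expect_true(all(co$truth$mutation_count >= 10))
})

test_that("empirical exposure mean matches the Dirichlet moment", {
  # mean 0.5 on the planted signature; concentration c gives
  # var = m (1 - m) / (c + 1); the empirical mean of 1000 draws must sit
  # within 3 standard errors of 0.5
  cat3 <- block_catalog(3)
  prof <- cancer_type_profile(
    "T1", c(S1 = 0.5, S2 = 0.3, S3 = 0.2), "S1")
  conc <- 50
  co <- simulate_cohort(list(T1 = prof), 1000, cat3, concentration = conc,
                        burden_meanlog = log(50), seed = 33)
  v <- 0.5 * 0.5 / (conc + 1)
  se <- sqrt(v / 1000)
  expect_lt(abs(mean(co$exposures[, "S1"]) - 0.5), 3 * se)
})

test_that("profiles referencing unknown signatures are rejected", {
  cat3 <- block_catalog(3)
  prof <- cancer_type_profile("T1", c(S1 = 0.5, S9 = 0.5), character(0))
  expect_error(simulate_cohort(list(prof), 2, cat3, seed = 1), "absent")
  expect_error(cancer_type_profile("T1", c(S1 = 0.5, S2 = 0.4)), "sum to 1")
  expect_error(cancer_type_profile("T1", c(S1 = 0.9, S2 = 0.1), "S2"),
               "0.15")
})

test_that("metastases copy primaries up to drift and record their pairing", {
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 3)
  co <- simulate_cohort(profs, 10, cat12, seed = 4)

  # vanishing drift: exposures copied exactly
  co0 <- simulate_metastases(co, 5, drift = 1e-12, seed = 6)
  met <- co0$truth$compartment == "metastasis"
  prim <- match(co0$truth$paired_primary[met], co0$truth$sample_id)
  expect_identical(unname_rows(co0$exposures[met, , drop = FALSE]),
                   unname_rows(co0$exposures[prim, , drop = FALSE]))

  expect_error(simulate_metastases(co, 5, drift = 0), "positive")
  expect_identical(simulate_metastases(co, 0, drift = 0.05), co)

  # matched pairs stay closer than random cross-type samples
  co2 <- simulate_metastases(co, 20, drift = 0.05, seed = 8)
  met2 <- which(co2$truth$compartment == "metastasis")
  prim2 <- match(co2$truth$paired_primary[met2], co2$truth$sample_id)
  set.seed(12)
  wins <- vapply(seq_along(met2), function(i) {
    other <- which(co2$truth$compartment == "tissue" &
                     co2$truth$type != co2$truth$type[met2[i]])
    j <- sample(other, 1)
    cosine_sim(co2$exposures[met2[i], ], co2$exposures[prim2[i], ]) >=
      cosine_sim(co2$exposures[met2[i], ], co2$exposures[j, ])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("cfDNA thinning follows binomial moments", {
  cat3 <- block_catalog(3)
  prof <- cancer_type_profile("T1", c(S1 = 0.5, S2 = 0.3, S3 = 0.2), "S1",
                              driver_gene_freqs = setNames(rep(1, 100),
                                                           sprintf("DRV%03d", 1:100)))
  co <- simulate_cohort(list(T1 = prof), 1, cat3,
                        burden_meanlog = log(1000), burden_sdlog = 0,
                        background_rate = 0, seed = 2)

  # dilution 1, dropout 0: identical copy
  cf1 <- simulate_cfdna(co, dilution = 1, dropout = 0, seed = 3)
  expect_identical(unname(cf1$spectra[2, ]), unname(cf1$spectra[1, ]))
  expect_identical(unname(cf1$gene_matrix[2, ]), unname(cf1$gene_matrix[1, ]))

  # dilution 0.2 on ~1000 mutations: total within 3 sd of n p
  n <- co$truth$mutation_count[1]
  cf2 <- simulate_cfdna(co, dilution = 0.2, seed = 5)
  expect_lt(abs(sum(cf2$spectra[2, ]) - 0.2 * n),
            3 * sqrt(n * 0.2 * 0.8))

  # dropout 0.5 over 100 planted drivers: retained count within 3 sd of 50
  cf3 <- simulate_cfdna(co, dilution = 1, dropout = 0.5, seed = 7)
  drivers <- grep("^DRV", colnames(co$gene_matrix))
  expect_lt(abs(sum(cf3$gene_matrix[2, drivers]) - 50), 3 * sqrt(25))

  expect_error(simulate_cfdna(co, dilution = 0), "dilution")
  expect_error(simulate_cfdna(co, dilution = 1.5), "dilution")
})

test_that("planted PPI modules behave as configured", {
  net <- simulate_ppi(c("A", "B", "C"), background_genes = 5,
                      p_in = 1, p_out = 0, seed = 1)
  expect_identical(nrow(net$edges), 3L)
  expect_true(all(net$edges$from %in% c("A", "B", "C")))
  expect_error(simulate_ppi(c("A", "B"), 5, p_in = 0.2, p_out = 0.2),
               "exceed")
  net2 <- simulate_ppi(c("A", "B", "C"), 5, p_in = 0.5, p_out = 0.1, seed = 2)
  expect_identical(net2, simulate_ppi(c("A", "B", "C"), 5, p_in = 0.5,
                                      p_out = 0.1, seed = 2))
})
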