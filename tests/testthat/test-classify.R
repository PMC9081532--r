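test_that("a perfectly separating feature is selected and scored near 1", {
  set.seed(1)
  X <- cbind(sep = c(rep(0, 50), rep(1, 50)),
             noise = runif(100))
  y <- c(rep(0, 50), rep(1, 50))
  m <- fit_one_vs_rest(X, y, type_name = "T")
  expect_true("sep" %in% m$feature_names)
  expect_true(m$ridge)
  expect_true(all(predict(m, X)[y == 1] >= 0.99))
  expect_true(all(predict(m, X)[y == 0] <= 0.01))
})

test_that("under the null, stepwise AIC keeps the intercept-only model at the chi-square rate", {
  # with one candidate noise feature, a spurious selection needs the
  # likelihood-ratio chi-square(1) to exceed 2 (the AIC penalty), which
  # happens with probability P(chi2_1 > 2) ~= 0.157; the empirical
  # empty-model rate over R replicates must sit within 3 binomial SEs of
  # 1 - 0.157 and above the 0.8 working requirement
  R <- 200
  p_empty <- stats::pchisq(2, df = 1)
  set.seed(7)
  empty <- vapply(seq_len(R), function(r) {
    X <- cbind(noise = rnorm(200))
    y <- rbinom(200, 1, 0.5)
    length(fit_one_vs_rest(X, y)$feature_names) == 0L
  }, logical(1))
  se <- sqrt(p_empty * (1 - p_empty) / R)
  expect_lt(abs(mean(empty) - p_empty), 3 * se)
  expect_gte(mean(empty), 0.8)
})

test_that("planted signatures reappear in the selected set across seeds", {
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 4)
  for (seed in 1:3) {
    co <- simulate_cohort(profs, 40, cat12, seed = seed)
    m <- fit_one_vs_rest(co$exposures, co$truth$type == "TYPE03",
                         type_name = "TYPE03")
    expect_true("S3" %in% m$feature_names)
  }
})

test_that("model scores follow the logistic form", {
  m <- structure(list(type_name = "T", feature_names = "f",
                      coefficients = 2, intercept = -1, ridge = FALSE,
                      training_meta = list()), class = "cancer_model")
  expect_equal(predict(m, c(f = 0.5)), 0.5)         # logistic(0)
  expect_equal(predict(m, c(f = 0)), plogis(-1))
  # strictly increasing in a positive-coefficient feature
  vals <- predict(m, matrix(seq(0, 1, 0.1), ncol = 1,
                            dimnames = list(NULL, "f")))
  expect_true(all(diff(vals) > 0))
  # missing feature treated as zero, with a warning
  expect_warning(s <- predict(m, matrix(1, 1, 1,
                                        dimnames = list(NULL, "other"))),
                 "missing feature")
  expect_equal(s, plogis(-1))
})

test_that("AUC is the Mann-Whitney probability with half-weight ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # {0.9, 0.4} positives vs {0.8, 0.1} negatives: 3 wins of 4 pairs
  expect_equal(auc(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "one class")
  # invariance under strictly monotone transforms
  set.seed(3)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(auc(qlogis(s), y), auc(s, y))
  expect_equal(auc(s^3, y), auc(s, y))
})

test_that("confusion statistics match the 2x2 definitions", {
  expect_equal(confusion_stats(c(1, 0), c(1, 0), positive_class = 1),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  pred <- c(rep("P", 3), rep("N", 7))
  truth <- c("P", "P", "N", "P", rep("N", 6))
  cs <- confusion_stats(pred, truth, positive_class = "P")
  expect_equal(cs$accuracy, 0.8)
  expect_equal(cs$sensitivity, 2 / 3)
  expect_equal(cs$specificity, 6 / 7)
  # all-negative predictions: sensitivity 0
  expect_equal(confusion_stats(rep("N", 4), c("P", "P", "N", "N"),
                               positive_class = "P")$sensitivity, 0)
  expect_error(confusion_stats(1:3, 1:4), "length")
})

test_that("the origin network nails separable classes and is seed-deterministic", {
  X <- diag(3)[rep(1:3, each = 20), ]
  colnames(X) <- c("f1", "f2", "f3")
  y <- rep(c("a", "b", "c"), each = 20)
  m <- fit_origin_model(X, y, seed = 5)
  expect_identical(predict(m, X, type = "class"), y)
  pr <- predict(m, X, type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  m2 <- fit_origin_model(X, y, seed = 5)
  expect_identical(m$net$wts, m2$net$wts)
  expect_error(fit_origin_model(X, rep("a", 60)), "2 classes")
})

test_that("origin model generalizes on planted-signature types", {
  cat12 <- synthetic_catalog(12, seed = 1)
  profs <- default_type_profiles(cat12, 4)
  tr <- simulate_cohort(profs, 100, cat12, seed = 11)
  te <- simulate_cohort(profs, 30, cat12, seed = 12)
  keep <- c("TYPE01", "TYPE02", "TYPE03")
  models <- lapply(keep, function(t)
    fit_one_vs_rest(tr$exposures, tr$truth$type == t, type_name = t))
  names(models) <- keep
  tr_idx <- tr$truth$type %in% keep
  om <- fit_origin_model(build_origin_features(tr$exposures[tr_idx, ],
                                               models),
                         tr$truth$type[tr_idx], seed = 2)
  te_idx <- te$truth$type %in% keep
  pred <- predict(om, build_origin_features(te$exposures[te_idx, ], models),
                  type = "class")
  expect_gte(mean(pred == te$truth$type[te_idx]), 0.9)
})

test_that("the cascade routes by the liver-score threshold", {
  liver <- structure(list(type_name = "L", feature_names = "S1",
                          coefficients = 10, intercept = -5, ridge = FALSE,
                          training_meta = list()), class = "cancer_model")
  other <- structure(list(type_name = "O", feature_names = "S2",
                          coefficients = 10, intercept = -5, ridge = FALSE,
                          training_meta = list()), class = "cancer_model")
  expo <- rbind(liverish = c(S1 = 0.9, S2 = 0.1),
                otherish = c(S1 = 0.1, S2 = 0.9))
  om <- fit_origin_model(
    build_origin_features(rbind(expo, expo) + 0, list(O = other)),
    rep(c("x", "y"), 2), seed = 1)
  tr <- trace_metastasis(expo, liver, list(O = other), om, threshold = 0.5)
  expect_identical(tr$stage1_call, c("liver-primary", "non-liver-origin"))
  expect_true(is.na(tr$origin[1]) && !is.na(tr$origin[2]))
  # boundary thresholds: 0 calls everything liver-primary (scores are
  # always positive), 1 routes everything to stage 2
  tr0 <- trace_metastasis(expo, liver, list(O = other), om, threshold = 0)
  expect_true(all(tr0$stage1_call == "liver-primary"))
  tr1 <- trace_metastasis(expo, liver, list(O = other), om, threshold = 1)
  expect_true(all(tr1$stage1_call == "non-liver-origin"))
  expect_false(anyNA(tr1$origin))
})

test_that("cfDNA pairwise call picks the higher score and flags ties", {
  ma <- structure(list(type_name = "A", feature_names = "f",
                       coefficients = 4, intercept = -2, ridge = FALSE,
                       training_meta = list()), class = "cancer_model")
  mb <- structure(list(type_name = "B", feature_names = "g",
                       coefficients = 4, intercept = -2, ridge = FALSE,
                       training_meta = list()), class = "cancer_model")
  X <- rbind(a_like = c(f = 1, g = 0), tie = c(f = 0.5, g = 0.5))
  res <- suppressMessages(classify_cfdna(X, ma, mb))
  expect_identical(res$call, c("A", "A"))
  expect_identical(res$tie, c(FALSE, TRUE))
})
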