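# Per-type one-vs-rest stepwise logistic models, evaluation metrics, the
# metastatic tissue-of-origin cascade, and the cfDNA pairwise call.

.backtick <- function(x) sprintf("`%s`", x)

# Ridge-penalized logistic regression by iteratively reweighted least
# squares (penalty excluded from the intercept). Used as a deterministic
# fallback when the maximum-likelihood fit separates.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 200, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  p <- ncol(X1)
  pen <- diag(lambda, p)
  pen[1L, 1L] <- 0
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wts
    A <- crossprod(X1 * wts, X1) + pen
    beta_new <- drop(solve(A, crossprod(X1 * wts, z)))
    if (sum((beta_new - beta)^2) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  stats::setNames(beta, colnames(X1))
}

#' Fit a one-vs-rest cancer-type classifier
#'
#' Bidirectional stepwise logistic regression by AIC, starting from the
#' intercept-only model, over the supplied candidate features (normally the
#' type's cancer-type-specific signatures). When the maximum-likelihood fit
#' separates (fitted probabilities numerically 0/1 or non-convergence), the
#' selected feature set is refit with a small L2 ridge penalty and the model
#' is flagged.
#'
#' @param features Samples x features numeric matrix or data frame.
#' @param labels Binary vector (1/TRUE = the target type).
#' @param candidate_features Feature names the selection may use (default:
#'   all columns).
#' @param type_name Label stored in the model.
#' @param seed Integer recorded in the training metadata (the fit itself is
#'   deterministic).
#' @param ridge_lambda Penalty strength of the separation fallback.
#' @return A `cancer_model`: list with `type_name`, `feature_names`
#'   (selected), `coefficients`, `intercept`, `ridge` flag, and
#'   `training_meta` (`n_pos`, `n_neg`, `seed`, `selection_path`).
#' @export
fit_one_vs_rest <- function(features, labels, candidate_features = NULL,
                            type_name = "positive", seed = 1,
                            ridge_lambda = 1e-4) {
  X <- as.data.frame(as.matrix(features), check.names = FALSE)
  y <- as.integer(as.logical(labels))
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (is.null(candidate_features)) candidate_features <- colnames(X)
  candidate_features <- intersect(candidate_features, colnames(X))
  if (length(candidate_features) == 0L) stop("no candidate features available")

  d <- cbind(.y = y, X[candidate_features])
  separated <- FALSE
  handler <- function(w) {
    if (grepl("numerically 0 or 1|did not converge", conditionMessage(w))) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  }
  sel <- withCallingHandlers({
    null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = d)
    upper <- stats::reformulate(.backtick(candidate_features))
    stats::step(null_fit, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0)
  }, warning = handler)
  selected <- attr(stats::terms(sel), "term.labels")
  selected <- gsub("`", "", selected, fixed = TRUE)
  path <- sel$anova$Step
  path <- if (is.null(path)) character(0) else as.character(path)

  # step() can swallow glm.fit's separation warning; detect it from the
  # fitted probabilities as well
  mu <- stats::fitted(sel)
  if (any(mu < 1e-10 | mu > 1 - 1e-10)) separated <- TRUE

  if (separated && length(selected) > 0L) {
    beta <- ridge_logistic(as.matrix(X[selected]), y, lambda = ridge_lambda)
    intercept <- beta[1L]
    coefs <- beta[-1L]
  } else {
    cf <- stats::coef(sel)
    intercept <- cf[["(Intercept)"]]
    coefs <- cf[setdiff(names(cf), "(Intercept)")]
    names(coefs) <- gsub("`", "", names(coefs), fixed = TRUE)
    coefs <- coefs[selected]
  }
  structure(list(
    type_name = type_name,
    feature_names = selected,
    coefficients = unname(coefs),
    intercept = unname(intercept),
    ridge = separated,
    training_meta = list(n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                         seed = seed, selection_path = path)
  ), class = "cancer_model")
}

#' @export
print.cancer_model <- function(x, ...) {
  cat("cancer_model <", x$type_name, ">: ",
      length(x$feature_names), " feature(s)",
      if (x$ridge) " [ridge fallback]", "\n", sep = "")
  invisible(x)
}

.align_features <- function(newdata, feature_names) {
  X <- as.matrix(as.data.frame(newdata, check.names = FALSE))
  missing_f <- setdiff(feature_names, colnames(X))
  if (length(missing_f)) {
    warning("missing feature(s) treated as 0: ",
            paste(missing_f, collapse = ", "))
    X <- cbind(X, matrix(0, nrow(X), length(missing_f),
                         dimnames = list(NULL, missing_f)))
  }
  X[, feature_names, drop = FALSE]
}

#' Score samples under a one-vs-rest model
#'
#' @param object A `cancer_model`.
#' @param newdata Feature matrix/data frame (missing model features are
#'   treated as 0 with a warning) or a single named feature vector.
#' @param ... Unused.
#' @return Numeric vector of membership scores in (0, 1):
#'   `plogis(intercept + coefficients . features)`.
#' @export
predict.cancer_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata)) && !is.data.frame(newdata)) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  if (length(object$feature_names) == 0L) {
    return(rep(stats::plogis(object$intercept), nrow(as.matrix(newdata))))
  }
  X <- .align_features(newdata, object$feature_names)
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) stop("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix summary statistics
#'
#' @param predictions,truth Label vectors of equal length.
#' @param positive_class Optional label treated as positive; when given,
#'   sensitivity and specificity of the implied 2x2 table are reported.
#' @return List with `accuracy` (fraction of exact matches) and, when
#'   `positive_class` is given, `sensitivity` and `specificity`.
#' @export
confusion_stats <- function(predictions, truth, positive_class = NULL) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth differ in length")
  }
  out <- list(accuracy = mean(predictions == truth))
  if (!is.null(positive_class)) {
    pp <- predictions == positive_class
    tp_ <- truth == positive_class
    tp <- sum(pp & tp_); fn <- sum(!pp & tp_)
    fp <- sum(pp & !tp_); tn <- sum(!pp & !tp_)
    out$sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out$specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  out
}

#' Fit the multi-class tissue-of-origin model
#'
#' Single-hidden-layer neural network (logistic hidden units, softmax
#' output, cross-entropy loss) over the stage-2 feature vector — normally
#' the cancer-type-specific exposures concatenated with the per-type model
#' scores (see [build_origin_features()]). Training is seeded and therefore
#' reproducible.
#'
#' @param features Samples x features numeric matrix.
#' @param labels Multi-class label per sample (at least 2 classes).
#' @param hidden_units Hidden-layer width (default 8).
#' @param seed Integer seed for the weight initialization.
#' @param max_iter Optimizer iteration cap.
#' @param decay L2 weight decay (stabilizes separable training sets).
#' @return An `origin_model` wrapping the fitted network, its feature names
#'   and class levels.
#' @export
fit_origin_model <- function(features, labels, hidden_units = 8, seed = 1,
                             max_iter = 5000, decay = 1e-3) {
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("origin model needs at least 2 classes")
  set.seed(seed)
  net <- nnet::nnet(x = X, y = nnet::class.ind(y), size = hidden_units,
                    softmax = TRUE, maxit = max_iter, decay = decay,
                    trace = FALSE)
  structure(list(net = net, feature_names = colnames(X), levels = levels(y),
                 hidden_units = hidden_units, seed = seed),
            class = "origin_model")
}

#' Predict tissue of origin
#'
#' @param object An `origin_model`.
#' @param newdata Feature matrix (missing columns treated as 0 with a
#'   warning).
#' @param type `"prob"` for class probabilities (rows sum to 1), `"class"`
#'   for the argmax label.
#' @param ... Unused.
#' @export
predict.origin_model <- function(object, newdata, type = c("prob", "class"),
                                 ...) {
  type <- match.arg(type)
  X <- .align_features(newdata, object$feature_names)
  pr <- stats::predict(object$net, X)
  colnames(pr) <- object$levels
  if (type == "prob") pr else object$levels[max.col(pr, ties.method = "first")]
}

#' Assemble stage-2 origin features
#'
#' Concatenates the exposures of every signature any of the per-type models
#' uses with the scores of those models (one `score_<type>` column each).
#'
#' @param exposures Samples x signatures exposure matrix.
#' @param type_models Named list of `cancer_model`s for the candidate
#'   origin types.
#' @return Numeric feature matrix for [fit_origin_model()] /
#'   [trace_metastasis()].
#' @export
build_origin_features <- function(exposures, type_models) {
  stopifnot(length(type_models) >= 1L, !is.null(names(type_models)))
  exposures <- as.matrix(exposures)
  feats <- unique(unlist(lapply(type_models, `[[`, "feature_names")))
  scores <- vapply(type_models, function(m) predict(m, exposures),
                   numeric(nrow(exposures)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- paste0("score_", names(type_models))
  cbind(exposures[, feats, drop = FALSE], scores)
}

#' Two-stage metastatic tissue-of-origin cascade
#'
#' Stage 1 calls each liver lesion primary-liver when the liver model score
#' reaches `threshold`, otherwise non-liver-origin. Stage 2 predicts the
#' origin of the non-liver-origin lesions from the concatenation of
#' cancer-type-specific exposures and per-type model scores.
#'
#' @param exposures Samples x signatures exposure matrix of liver lesions.
#' @param liver_model `cancer_model` for the liver type.
#' @param type_models Named list of `cancer_model`s for the candidate
#'   origin types (same models the origin model was trained with).
#' @param origin_model An `origin_model` from [fit_origin_model()].
#' @param threshold Stage-1 decision threshold on the liver score.
#' @return Data frame with `sample_id`, `stage1_call` (`"liver-primary"` or
#'   `"non-liver-origin"`), `stage1_score`, and `origin` (`NA` for
#'   liver-primary calls). Stage-2 class probabilities are attached as the
#'   `"stage2_prob"` attribute.
#' @export
trace_metastasis <- function(exposures, liver_model, type_models,
                             origin_model, threshold = 0.5) {
  exposures <- as.matrix(exposures)
  s1 <- predict(liver_model, exposures)
  call1 <- ifelse(s1 >= threshold, "liver-primary", "non-liver-origin")
  origin <- rep(NA_character_, nrow(exposures))
  probs <- NULL
  idx <- which(call1 == "non-liver-origin")
  if (length(idx)) {
    of <- build_origin_features(exposures[idx, , drop = FALSE], type_models)
    missing_f <- setdiff(origin_model$feature_names, colnames(of))
    if (length(missing_f)) stop("origin model feature mismatch: ",
                                paste(missing_f, collapse = ", "))
    probs <- predict(origin_model, of, type = "prob")
    origin[idx] <- origin_model$levels[max.col(probs, ties.method = "first")]
    rownames(probs) <- rownames(exposures)[idx]
  }
  out <- data.frame(sample_id = rownames(exposures) %||% seq_len(nrow(exposures)),
                    stage1_call = call1, stage1_score = s1, origin = origin,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "stage2_prob") <- probs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise cfDNA type call
#'
#' Scores each sample under two one-vs-rest models and calls the type whose
#' model scores higher; exact ties are broken toward `model_a` and flagged.
#'
#' @param features Samples x features matrix (exposures, optionally with
#'   mutation-marker indicator columns).
#' @param model_a,model_b `cancer_model`s of the two candidate types.
#' @return Data frame with `sample_id`, `score_a`, `score_b`, `call`, `tie`.
#' @export
classify_cfdna <- function(features, model_a, model_b) {
  features <- as.matrix(features)
  sa <- predict(model_a, features)
  sb <- predict(model_b, features)
  tie <- sa == sb
  if (any(tie)) message("classify_cfdna: ", sum(tie),
                        " exact tie(s) broken toward ", model_a$type_name)
  data.frame(
    sample_id = rownames(features) %||% seq_len(nrow(features)),
    score_a = sa, score_b = sb,
    call = ifelse(sa >= sb, model_a$type_name, model_b$type_name),
    tie = tie, stringsAsFactors = FALSE, row.names = NULL
  )
}
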