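# Episignature SVM training, Platt-calibrated MVP scoring and clinical
# calls at the 0.25 / 0.5 cutoffs.

#' Stratified train/test split
#'
#' Splits a sample sheet into training and test sets, stratified by group
#' label: each group contributes `floor(fraction * n)` samples (at least 1
#' when the group has >= 2 members) to training; the remainder is the test
#' set. Deterministic under the seed.
#'
#' @param sample_sheet Sample sheet data.frame.
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
split_train_test <- function(sample_sheet, fraction = 0.75, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop_episign("argument_error", "fraction must lie in (0, 1)")
  groups <- split(sample_sheet$sample_id, sample_sheet$group)
  train <- character(0); test <- character(0)
  withr::with_seed(as.integer(seed), {
    for (g in names(groups)) {
      ids <- sort(groups[[g]])
      n <- length(ids)
      if (n < 2L)
        stop_episign("split_error",
                     "group '%s' has %d sample(s); cannot populate both splits", g, n)
      n_train <- max(1L, floor(fraction * n))
      if (n_train >= n) n_train <- n - 1L
      picked <- sample(ids, n_train)
      train <- c(train, picked)
      test <- c(test, setdiff(ids, picked))
    }
  })
  list(train = train, test = test)
}

# Fit the Platt sigmoid p = 1 / (1 + exp(A*d + B)) mapping decision values
# to calibrated probabilities, by Newton iteration on the regularized
# maximum-likelihood problem (prior-corrected targets keep A finite even
# for separable decision values).
platt_fit <- function(d, y) {
  stopifnot(length(d) == length(y))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y == 1, hi, lo)
  A <- 0; B <- log((n_neg + 1) / (n_pos + 1))
  sigma <- 1e-12
  fApB <- A * d + B
  obj <- function(fApB) {
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- obj(fApB)
  for (it in 1:100) {
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    w <- p * q
    h11 <- sum(d * d * w) + sigma
    h22 <- sum(w) + sigma
    h21 <- sum(d * w)
    g1 <- sum(d * (t - p))
    g2 <- sum(t - p)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newf <- obj(newA * d + newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf; fApB <- A * d + B
        break
      }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

# Deterministic stratified fold assignment for internal calibration.
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Fit a linear SVM and return the primal weight vector and intercept,
# oriented so that cases score positive decision values.
fit_linear_svm <- function(x, y01, C, class_weights) {
  yf <- factor(ifelse(y01 == 1, "case", "negative"),
               levels = c("case", "negative"))
  model <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE,
                      class.weights = class_weights, fitted = FALSE)
  w <- drop(crossprod(model$coefs, model$SV))
  b <- -model$rho
  d <- drop(x %*% w) + b
  if (mean(d[y01 == 1]) < mean(d[y01 == 0])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

#' Train the episignature SVM classifier
#'
#' Fits a linear-kernel maximum-margin classifier on the beta values of
#' the signature probes (features in the probe set's stored order), with
#' balanced class weighting. Cases form the positive class; the negative
#' class is controls together with any other-disorder samples present.
#' The MVP sigmoid calibration `(A, B)` is fitted by Platt scaling on
#' decision values from an internal 3-fold cross-validation, so calibrated
#' scores are not inflated by the training fit.
#'
#' @param beta Probes x samples beta matrix containing all probes of
#'   `probe_set` and all training samples.
#' @param probe_set A [select_probes()] result (or any object with ordered
#'   `probe_ids`).
#' @param sample_sheet Sample sheet for the training samples; group
#'   `case` is the positive class.
#' @param C Soft-margin cost (default 1).
#' @param seed Integer seed for the calibration folds.
#' @param feature_space `"beta"` (default) or `"m"`.
#' @return An object of class `episign_classifier`: probe ids, weights,
#'   intercept, calibration `(A, B)`, training manifest and parameters.
#' @export
train_svm <- function(beta, probe_set, sample_sheet, C = 1, seed = 1L,
                      feature_space = c("beta", "m")) {
  feature_space <- match.arg(feature_space)
  probe_ids <- probe_set$probe_ids
  missing <- setdiff(probe_ids, rownames(beta))
  if (length(missing))
    stop_episign("scoring_error", "probes missing from beta matrix: %s",
                 paste(utils::head(missing, 5L), collapse = ", "))
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  y01 <- as.numeric(sheet$group == "case")
  if (length(unique(y01)) < 2L)
    stop_episign("training_error", "training labels contain a single class")
  if (sum(y01 == 1) < 2L || sum(y01 == 0) < 2L)
    stop_episign("training_error", "need >= 2 samples per class")

  feats <- beta[probe_ids, , drop = FALSE]
  if (feature_space == "m") feats <- beta_to_m(feats)
  x <- t(feats)

  n <- length(y01)
  class_weights <- c(case = n / (2 * sum(y01 == 1)),
                     negative = n / (2 * sum(y01 == 0)))
  svm_fit <- fit_linear_svm(x, y01, C, class_weights)

  # cross-validated decision values for calibration
  fold <- make_folds(y01, 3L, seed)
  d_cv <- numeric(n)
  for (k in 1:3) {
    tr <- fold != k
    f <- fit_linear_svm(x[tr, , drop = FALSE], y01[tr], C, class_weights)
    d_cv[!tr] <- drop(x[!tr, , drop = FALSE] %*% f$w) + f$b
  }
  cal <- platt_fit(d_cv, y01)

  structure(list(probe_ids = probe_ids,
                 weights = stats::setNames(svm_fit$w, probe_ids),
                 intercept = svm_fit$b,
                 A = cal$A, B = cal$B,
                 params = list(C = C, seed = as.integer(seed),
                               feature_space = feature_space,
                               class_weights = class_weights),
                 manifest = list(train_ids = colnames(beta),
                                 case_ids = colnames(beta)[y01 == 1],
                                 negative_ids = colnames(beta)[y01 == 0])),
            class = "episign_classifier")
}

#' @export
print.episign_classifier <- function(x, ...) {
  cat(sprintf("episign_classifier: %d probes, %d training samples (A=%.3f, B=%.3f)\n",
              length(x$probe_ids), length(x$manifest$train_ids), x$A, x$B))
  invisible(x)
}

#' Score samples with a trained classifier (MVP score)
#'
#' The methylation variant pathogenicity (MVP) score is the calibrated
#' probability `1 / (1 + exp(A*d + B))` where `d` is the signed decision
#' value of the linear SVM; it lies in (0, 1) and increases with evidence
#' for the episignature.
#'
#' @param classifier An `episign_classifier`.
#' @param x A probes x samples beta matrix (or named numeric vector for a
#'   single sample) containing every signature probe.
#' @return Named numeric vector of MVP scores.
#' @export
mvp_score <- function(classifier, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                   dimnames = list(names(x), "sample"))
  missing <- setdiff(classifier$probe_ids, rownames(x))
  if (length(missing))
    stop_episign("scoring_error", "missing probe value(s): %s",
                 paste(utils::head(missing, 10L), collapse = ", "))
  feats <- x[classifier$probe_ids, , drop = FALSE]
  if (classifier$params$feature_space == "m") feats <- beta_to_m(feats)
  d <- drop(crossprod(feats, classifier$weights)) + classifier$intercept
  mvp <- 1 / (1 + exp(classifier$A * d + classifier$B))
  stats::setNames(as.numeric(mvp), colnames(x))
}

#' Categorical call from an MVP score
#'
#' Positive above 0.5, negative below 0.25, inconclusive in between
#' (strict inequalities: the boundary values are inconclusive).
#'
#' @param mvp Numeric vector of MVP scores in `[0, 1]`.
#' @return Character vector of calls.
#' @export
classify_call <- function(mvp) {
  if (any(mvp < 0 | mvp > 1, na.rm = TRUE))
    stop_episign("argument_error", "MVP scores must lie in [0, 1]")
  ifelse(mvp > 0.5, "positive", ifelse(mvp < 0.25, "negative", "inconclusive"))
}

#' Per-sample MVP report
#'
#' @param classifier An `episign_classifier`.
#' @param beta Probes x samples beta matrix.
#' @return Data.frame with `sample_id`, `mvp`, `call`.
#' @export
mvp_report <- function(classifier, beta) {
  mvp <- mvp_score(classifier, beta)
  data.frame(sample_id = names(mvp), mvp = unname(mvp),
             call = classify_call(unname(mvp)), stringsAsFactors = FALSE)
}

#' Specificity on held-out negative samples
#'
#' Percentage of true-negative samples scoring below the clinical negative
#' cutoff of 0.25.
#'
#' @param classifier An `episign_classifier`.
#' @param beta_negatives Probes x samples matrix of held-out negatives.
#' @param cutoff MVP cutoff (default 0.25).
#' @return Specificity in percent.
#' @export
assess_specificity <- function(classifier, beta_negatives, cutoff = 0.25) {
  if (is.null(beta_negatives) ||
      (is.matrix(beta_negatives) && ncol(beta_negatives) == 0L) ||
      length(beta_negatives) == 0L)
    stop_episign("argument_error", "held-out negative set is empty")
  mvp <- mvp_score(classifier, beta_negatives)
  100 * sum(mvp < cutoff) / length(mvp)
}

#' Serialize / restore a trained classifier (JSON)
#' @param classifier An `episign_classifier`.
#' @param path Output path.
#' @export
write_classifier <- function(classifier, path) {
  jsonlite::write_json(unclass(classifier), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- stats::setNames(as.numeric(obj$weights), obj$probe_ids)
  structure(obj, class = "episign_classifier")
}
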