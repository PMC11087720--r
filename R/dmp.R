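# Differential methylation statistics: per-probe linear models on
# M-values, empirical-Bayes variance moderation, BH FDR, effect sizes on
# the beta scale, episignature probe selection and iterative removal of
# episignature-negative discovery cases.

# Build the model matrix: intercept + case indicator + optional covariates
# (numeric columns used as-is, character/factor columns dummy-coded).
build_design <- function(sample_sheet, covariates = NULL) {
  group <- as.numeric(sample_sheet$group == "case")
  X <- cbind(`(Intercept)` = 1, group = group)
  if (!is.null(covariates)) {
    for (cv in covariates) {
      v <- sample_sheet[[cv]]
      if (is.null(v))
        stop_episign("argument_error", "covariate '%s' not in sample sheet", cv)
      if (is.numeric(v)) {
        X <- cbind(X, v)
        colnames(X)[ncol(X)] <- cv
      } else {
        f <- factor(v)
        mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1L])
        X <- cbind(X, mm)
      }
    }
  }
  X
}

#' Fit per-probe linear models on M-values
#'
#' Ordinary least squares of each probe's M-values on
#' `[intercept, case indicator, covariates]`. All probes share one design,
#' so a single QR decomposition is reused across the matrix.
#'
#' @param M Probes x samples matrix of M-values.
#' @param sample_sheet Sample sheet aligned with `colnames(M)`; rows with
#'   group `case` form the case class, everything else the reference.
#' @param covariates Character vector of sample-sheet column names to
#'   adjust for (e.g. `c("age", "sex")`).
#' @return A list with per-probe `coef` (case effect on the M scale),
#'   `s2` (residual mean square), scalar `df` (residual degrees of
#'   freedom), `se_unit` (unscaled standard error of the case
#'   coefficient) and the `design` matrix.
#' @export
fit_probe_models <- function(M, sample_sheet, covariates = NULL) {
  sheet <- sample_sheet[match(colnames(M), sample_sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop_episign("argument_error", "samples in M missing from the sample sheet")
  n_case <- sum(sheet$group == "case")
  n_ref <- sum(sheet$group != "case")
  if (n_case < 2L || n_ref < 2L)
    stop_episign("argument_error", "need at least 2 samples per group (%d cases, %d reference)",
                 n_case, n_ref)
  X <- build_design(sheet, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_episign("model_error", "design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(X, t(M))
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1L,
                                           dimnames = list(names(coefs), NULL))
  df <- nrow(X) - qx$rank
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se_unit <- sqrt(xtx_inv[2L, 2L])
  list(coef = stats::setNames(coefs["group", ], rownames(M)),
       s2 = stats::setNames(s2, rownames(M)),
       df = df, se_unit = se_unit, design = X)
}

# Invert the trigamma function by Newton iteration on a convex transform
# (monotone decreasing; standard approach for fitting the scaled-F prior).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks each probe's residual variance towards a pooled prior and forms
#' moderated t-statistics. The prior is a scaled inverse-chi-square with
#' `d0` degrees of freedom and scale `s0^2`, fitted by the method of
#' moments on `log(s2)`: writing
#' `e = log(s2) - digamma(df/2) + log(df/2)`, the excess variance of `e`
#' over `trigamma(df/2)` identifies `d0` through the trigamma function and
#' its mean identifies `s0^2`. The posterior variance is
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)` and
#' `t_mod = coef / (sqrt(s2_post) * se_unit)` is referred to a
#' t-distribution with `d0 + df` degrees of freedom. If the observed
#' variances are under-dispersed relative to chi-square sampling noise,
#' `d0` is infinite and every probe is tested at the common prior
#' variance.
#'
#' @param coef Per-probe case coefficients (M scale).
#' @param s2 Per-probe residual variances (all >= 0).
#' @param df Residual degrees of freedom (scalar, >= 1).
#' @param se_unit Unscaled standard error of the case coefficient.
#' @param d0 Optional forced prior degrees of freedom (`0` recovers the
#'   ordinary t-statistic, `Inf` fully pools the variance); `NULL` (the
#'   default) estimates `d0` from the data.
#' @return A list with `prior` (list `d0`, `s0_sq`), `t_mod`, `p`
#'   (two-sided) and `s2_post`.
#' @export
ebayes_moderate <- function(coef, s2, df, se_unit, d0 = NULL) {
  if (df < 1L) stop_episign("argument_error", "df must be >= 1")
  if (any(s2 < 0)) stop_episign("argument_error", "variances must be non-negative")
  if (all(s2 == 0))
    stop_episign("degenerate_variance_error",
                 "all residual variances are zero; cannot moderate")
  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.null(d0)) {
    if (d0 == 0) {
      prior <- list(d0 = 0, s0_sq = exp(ebar))
    } else if (is.infinite(d0)) {
      prior <- list(d0 = Inf, s0_sq = exp(ebar))
    } else {
      prior <- list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
    }
  } else if (is.na(evar) || evar <= 0) {
    prior <- list(d0 = Inf, s0_sq = exp(ebar))
  } else {
    d0_hat <- 2 * trigamma_inverse(evar)
    prior <- list(d0 = d0_hat,
                  s0_sq = exp(ebar + digamma(d0_hat / 2) - log(d0_hat / 2)))
  }
  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
    names(s2_post) <- names(s2)
    df_total <- Inf
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
    df_total <- prior$d0 + df
  }
  t_mod <- coef / (sqrt(s2_post) * se_unit)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p <- pmax(p, .Machine$double.xmin)  # keep p strictly in (0, 1]
  list(prior = prior, t_mod = t_mod, p = p, s2_post = s2_post)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment: after sorting ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, mapped back to input order.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) stop_episign("argument_error", "empty p-value vector")
  if (any(p <= 0 | p > 1 | is.na(p)))
    stop_episign("argument_error", "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe beta-scale effect size
#'
#' Case mean beta minus control-group mean beta for each probe.
#'
#' @param beta Probes x samples matrix.
#' @param groups Character vector aligned with columns; `"case"` marks the
#'   case group, everything else the reference group.
#' @return Named per-probe delta-beta vector.
#' @export
compute_delta_beta <- function(beta, groups) {
  is_case <- groups == "case"
  if (!any(is_case) || all(is_case))
    stop_episign("argument_error", "both case and reference groups must be present")
  rowMeans(beta[, is_case, drop = FALSE]) -
    rowMeans(beta[, !is_case, drop = FALSE])
}

#' Differential methylation table
#'
#' Runs the full per-probe discovery statistics: M-value transform, OLS
#' fits, empirical-Bayes moderation, BH FDR and beta-scale effect sizes.
#' The ranking score combines effect and evidence as
#' `|delta_beta| * (-log10 p)`.
#'
#' @inheritParams fit_probe_models
#' @param beta Probes x samples beta matrix.
#' @param epsilon Clipping constant for the M transform.
#' @param d0 Optional forced prior degrees of freedom (see
#'   [ebayes_moderate()]).
#' @return A data.frame (one row per probe, in input order) with columns
#'   `probe_id`, `delta_beta`, `coef`, `s2`, `df`, `t_mod`, `p`, `q`,
#'   `rank_score`, plus the fitted prior as attribute `"prior"`.
#' @export
dmp_table <- function(beta, sample_sheet, covariates = NULL, epsilon = 0.01,
                      d0 = NULL) {
  check_beta_matrix(beta)
  M <- beta_to_m(beta, epsilon = epsilon)
  fit <- fit_probe_models(M, sample_sheet, covariates)
  mod <- ebayes_moderate(fit$coef, fit$s2, fit$df, fit$se_unit, d0 = d0)
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  db <- compute_delta_beta(beta, sheet$group)
  out <- data.frame(probe_id = rownames(beta),
                    delta_beta = unname(db),
                    coef = unname(fit$coef),
                    s2 = unname(fit$s2),
                    df = fit$df,
                    t_mod = unname(mod$t_mod),
                    p = unname(mod$p),
                    q = unname(bh_fdr(mod$p)),
                    stringsAsFactors = FALSE)
  out$rank_score <- abs(out$delta_beta) * (-log10(out$p))
  attr(out, "prior") <- mod$prior
  out
}

#' Select episignature probes
#'
#' Filters the DMP table to probes with `q <= q_max` and
#' `|delta_beta| >= min_abs_delta`, orders by the ranking score
#' (descending, ties by probe id), truncates to `top_n`, then greedily
#' drops any probe whose Pearson correlation (beta scale, across the
#' training samples) with an already-kept probe exceeds `corr_max`.
#'
#' @param dmp A [dmp_table()] data.frame.
#' @param beta Training beta matrix (used for the correlation pruning and
#'   the stored per-group training statistics).
#' @param groups Character group labels aligned with `colnames(beta)`.
#' @param q_max,min_abs_delta,top_n,corr_max Selection parameters. The
#'   default effect-size floor of 0.05 is the conventional minimum
#'   methylation difference for blood episignatures.
#' @return An object of class `probe_set`: list with `probe_ids` (ordered
#'   by ranking score), `stats` (per-probe case/control training means and
#'   SDs on the beta scale), and `params`.
#' @export
select_probes <- function(dmp, beta, groups, q_max = 0.01,
                          min_abs_delta = 0.05, top_n = 500L,
                          corr_max = 0.85) {
  pass <- dmp$q <= q_max & abs(dmp$delta_beta) >= min_abs_delta
  if (!any(pass)) {
    stop_episign("selection_error",
                 "no probes pass the filters (strictest attained: q = %.3g, |delta_beta| = %.3g)",
                 min(dmp$q), max(abs(dmp$delta_beta)))
  }
  cand <- dmp[pass, , drop = FALSE]
  ord <- order(-cand$rank_score, cand$probe_id)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[seq_len(min(top_n, nrow(cand))), , drop = FALSE]

  # greedy redundancy pruning in rank order
  mat <- beta[cand$probe_id, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept) == 0L) { kept <- i; next }
    r <- suppressWarnings(stats::cor(mat[i, ], t(mat[kept, , drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r <= corr_max)) kept <- c(kept, i)
  }
  cand <- cand[kept, , drop = FALSE]

  is_case <- groups == "case"
  sub <- beta[cand$probe_id, , drop = FALSE]
  stats_df <- data.frame(
    probe_id = cand$probe_id,
    case_mean = rowMeans(sub[, is_case, drop = FALSE]),
    case_sd = apply(sub[, is_case, drop = FALSE], 1L, stats::sd),
    control_mean = rowMeans(sub[, !is_case, drop = FALSE]),
    control_sd = apply(sub[, !is_case, drop = FALSE], 1L, stats::sd),
    delta_beta = cand$delta_beta,
    rank_score = cand$rank_score,
    stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  structure(list(probe_ids = cand$probe_id, stats = stats_df,
                 params = list(q_max = q_max, min_abs_delta = min_abs_delta,
                               top_n = top_n, corr_max = corr_max)),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: %d probes (q <= %g, |delta_beta| >= %g, top %d, corr <= %g)\n",
              length(x$probe_ids), x$params$q_max, x$params$min_abs_delta,
              x$params$top_n, x$params$corr_max))
  invisible(x)
}

# Derive a probe set and classifier on one cohort; internal one-shot used
# by the pruning loop and cross-validation.
derive_and_train <- function(beta, sample_sheet, covariates = NULL,
                             select_params = list(), svm_params = list(),
                             seed = 1L) {
  tab <- dmp_table(beta, sample_sheet, covariates = covariates)
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  ps <- do.call(select_probes,
                c(list(dmp = tab, beta = beta, groups = sheet$group),
                  select_params))
  clf <- do.call(train_svm,
                 c(list(beta = beta, probe_set = ps, sample_sheet = sheet,
                        seed = seed), svm_params))
  list(dmp = tab, probe_set = ps, classifier = clf)
}

#' Iteratively remove episignature-negative discovery cases
#'
#' Some discovery cases carry no episignature (mosaicism, hypomorphic or
#' benign variants) and dilute probe selection. Each round derives the
#' episignature on the current cohort and scores every current case with a
#' classifier trained with that case held out; cases whose held-out MVP
#' falls below `mvp_cutoff` are removed, and the loop repeats until no
#' case is flagged (or `max_rounds` is reached). The final probe set is
#' derived on the retained cohort.
#'
#' @param beta Probes x samples beta matrix (cases and controls).
#' @param sample_sheet Matching sample sheet.
#' @param covariates Covariate columns for the per-probe models.
#' @param select_params,svm_params Parameter lists forwarded to
#'   [select_probes()] and [train_svm()].
#' @param mvp_cutoff Held-out MVP below which a case is flagged (default
#'   0.25, the clinical negative cutoff).
#' @param max_rounds Maximum pruning rounds (default 3).
#' @param seed Integer seed for classifier training.
#' @return A list with `probe_set` (final, on the retained cohort),
#'   `classifier` (trained on the retained cohort), `removed_case_ids`,
#'   `rounds` (per-round held-out MVP table) and `retained_sheet`.
#' @export
iterative_case_pruning <- function(beta, sample_sheet, covariates = NULL,
                                   select_params = list(),
                                   svm_params = list(),
                                   mvp_cutoff = 0.25, max_rounds = 3L,
                                   seed = 1L) {
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  case_ids <- sheet$sample_id[sheet$group == "case"]
  ref_ids <- sheet$sample_id[sheet$group != "case"]
  if (length(case_ids) < 10L || length(ref_ids) < 10L)
    stop_episign("argument_error", "need >= 10 cases and >= 10 controls for pruning")

  removed <- character(0)
  rounds <- list()
  current <- case_ids
  for (round in seq_len(max_rounds)) {
    mvps <- stats::setNames(numeric(length(current)), current)
    for (cid in current) {
      keep <- c(setdiff(current, cid), ref_ids)
      fit <- tryCatch(
        derive_and_train(beta[, keep, drop = FALSE],
                         sheet[sheet$sample_id %in% keep, , drop = FALSE],
                         covariates = covariates,
                         select_params = select_params,
                         svm_params = svm_params,
                         seed = derive_seed(seed, round)),
        selection_error = function(e)
          stop_episign("instability_error",
                       "no selectable signature on the current cohort; signature untrustworthy (%s)",
                       conditionMessage(e)))
      mvps[cid] <- mvp_score(fit$classifier,
                             beta[fit$probe_set$probe_ids, cid, drop = FALSE])
    }
    flagged <- names(mvps)[mvps < mvp_cutoff]
    rounds[[round]] <- data.frame(round = round, case_id = names(mvps),
                                  mvp = unname(mvps),
                                  flagged = names(mvps) %in% flagged,
                                  stringsAsFactors = FALSE)
    if (length(flagged) > 0.5 * length(current))
      stop_episign("instability_error",
                   "%d of %d cases flagged in round %d; signature untrustworthy",
                   length(flagged), length(current), round)
    if (length(flagged) == 0L) break
    removed <- c(removed, flagged)
    current <- setdiff(current, flagged)
  }

  keep <- c(current, ref_ids)
  retained_sheet <- sheet[sheet$sample_id %in% keep, , drop = FALSE]
  final <- derive_and_train(beta[, keep, drop = FALSE], retained_sheet,
                            covariates = covariates,
                            select_params = select_params,
                            svm_params = svm_params, seed = seed)
  list(probe_set = final$probe_set, classifier = final$classifier,
       dmp = final$dmp,
       removed_case_ids = removed,
       rounds = do.call(rbind, rounds),
       retained_sheet = retained_sheet)
}

#' Write a DMP table to TSV
#' @param dmp A [dmp_table()] data.frame.
#' @param path Output path.
#' @export
write_dmp_table <- function(dmp, path) {
  data.table::fwrite(dmp[, c("probe_id", "delta_beta", "t_mod", "p", "q",
                             "rank_score")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Serialize a probe set to JSON
#' @param probe_set A `probe_set` object.
#' @param path Output path.
#' @export
write_probe_set <- function(probe_set, path) {
  jsonlite::write_json(list(probe_ids = probe_set$probe_ids,
                            stats = probe_set$stats,
                            params = probe_set$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_probe_set
#' @export
read_probe_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(probe_ids = obj$probe_ids,
                 stats = as.data.frame(obj$stats),
                 params = as.list(obj$params)),
            class = "probe_set")
}
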