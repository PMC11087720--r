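# Robustness views: leave-25%-out cross-validation with full
# re-derivation, Euclidean/Ward hierarchical clustering and classical
# multidimensional scaling.

#' Leave-25%-out cross-validation of the episignature classifier
#'
#' Each round holds out a stratified 25% of cases and of controls, then
#' re-derives the probe set *and* the classifier on the remainder — probe
#' selection is part of the classifier, so it must sit inside the loop for
#' the validation to be honest — and scores the held-out samples. A master
#' seed spawns per-round seeds by fixed arithmetic, so rounds are
#' independent yet reproducible.
#'
#' @param beta Probes x samples beta matrix.
#' @param sample_sheet Matching sample sheet (groups `case` and
#'   `control`).
#' @param n_rounds Number of rounds (default 20).
#' @param holdout_fraction Held-out fraction per group (default 0.25).
#' @param seed Master seed.
#' @param covariates,select_params,svm_params Forwarded to the
#'   re-derivation.
#' @return A data.frame of class `cv_report` with columns `round`,
#'   `sample_id`, `group`, `mvp`, `call`, and attribute
#'   `"probe_set_sizes"` (per-round signature size).
#' @export
cross_validate <- function(beta, sample_sheet, n_rounds = 20L,
                           holdout_fraction = 0.25, seed = 1L,
                           covariates = NULL, select_params = list(),
                           svm_params = list()) {
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  case_ids <- sort(sheet$sample_id[sheet$group == "case"])
  ctrl_ids <- sort(sheet$sample_id[sheet$group == "control"])
  n_hold_case <- round(holdout_fraction * length(case_ids))
  n_hold_ctrl <- round(holdout_fraction * length(ctrl_ids))
  if (n_hold_case < 1L || n_hold_ctrl < 1L)
    stop_episign("argument_error",
                 "cohort too small to hold out >= 1 sample per group at fraction %.2f",
                 holdout_fraction)
  out <- vector("list", n_rounds)
  sizes <- integer(n_rounds)
  for (r in seq_len(n_rounds)) {
    rs <- derive_seed(seed, r)
    withr::with_seed(rs, {
      hold <- c(sample(case_ids, n_hold_case), sample(ctrl_ids, n_hold_ctrl))
    })
    keep <- setdiff(c(case_ids, ctrl_ids), hold)
    fit <- derive_and_train(beta[, keep, drop = FALSE],
                            sheet[sheet$sample_id %in% keep, , drop = FALSE],
                            covariates = covariates,
                            select_params = select_params,
                            svm_params = svm_params,
                            seed = rs)
    rep_r <- mvp_report(fit$classifier, beta[, hold, drop = FALSE])
    rep_r$round <- r
    rep_r$group <- sheet$group[match(rep_r$sample_id, sheet$sample_id)]
    out[[r]] <- rep_r[, c("round", "sample_id", "group", "mvp", "call")]
    sizes[r] <- length(fit$probe_set$probe_ids)
  }
  res <- do.call(rbind, out)
  attr(res, "probe_set_sizes") <- sizes
  class(res) <- c("cv_report", class(res))
  res
}

#' Hierarchical clustering of samples on signature probes
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage over
#' sample columns. Columns are sorted by sample id before the distance
#' computation, which fixes the leaf order (the documented tie-break) and
#' makes the tree invariant to input column order.
#'
#' @param beta_subset Signature-probes x samples beta matrix (>= 2
#'   samples).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(beta_subset) {
  if (ncol(beta_subset) < 2L)
    stop_episign("argument_error", "need at least 2 samples to cluster")
  ord <- order(colnames(beta_subset))
  d <- stats::dist(t(beta_subset[, ord, drop = FALSE]), method = "euclidean")
  stats::hclust(d, method = "ward.D2")
}

#' Serialize an `hclust` tree as Newick
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Metric MDS on Euclidean distances: double-centered Gram matrix, top
#' eigenpairs, coordinates scaled by the square root of the eigenvalues.
#' Coordinates are centered, and the sign of each dimension is fixed so
#' that its first nonzero loading is positive.
#'
#' @param beta_subset Signature-probes x samples matrix (>= 3 samples).
#' @param n_dims Embedding dimension (default 2).
#' @return Samples x `n_dims` coordinate matrix.
#' @export
mds_embed <- function(beta_subset, n_dims = 2L) {
  if (ncol(beta_subset) < 3L)
    stop_episign("argument_error", "need at least 3 samples for MDS")
  d <- stats::dist(t(beta_subset), method = "euclidean")
  if (all(d == 0))
    stop_episign("degenerate_error", "all pairwise distances are zero")
  fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < n_dims)
    pts <- cbind(pts, matrix(0, nrow(pts), n_dims - ncol(pts)))
  pts <- sweep(pts, 2L, colMeans(pts))
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("dim", seq_len(n_dims))
  rownames(pts) <- colnames(beta_subset)
  pts
}
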