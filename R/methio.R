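# Tabular IO for the pipeline formats, the beta/M transforms, and
# age/sex-matched control selection.

#' Read a beta-value matrix from TSV
#'
#' The expected layout is the one written by [write_beta_matrix()]: a header
#' row of sample ids, a first column named `probe_id`, and one row of
#' methylation fractions per probe. All values must lie in `[0, 1]`.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (probes x samples) with probe rownames and
#'   sample colnames.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path))
    stop_episign("format_error", "beta matrix file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L)
    stop_episign("format_error", "beta matrix must have a probe_id column and at least one sample")
  probe_ids <- as.character(dt[[1L]])
  if (anyDuplicated(probe_ids))
    stop_episign("format_error", "duplicate probe ids: %s",
                 paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  sample_ids <- colnames(dt)[-1L]
  if (anyDuplicated(sample_ids))
    stop_episign("format_error", "duplicate sample ids: %s",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad_col <- which(!vapply(dt[-1L], is.numeric, logical(1L)))[1L]
    bad_row <- which(is.na(suppressWarnings(as.numeric(dt[[bad_col + 1L]]))))[1L]
    stop_episign("format_error", "non-numeric cell at probe %s, sample %s",
                 probe_ids[bad_row], sample_ids[bad_col])
  }
  rownames(vals) <- probe_ids
  out_of_range <- which(vals < 0 | vals > 1 | is.na(vals), arr.ind = TRUE)
  if (nrow(out_of_range)) {
    stop_episign("format_error",
                 "beta value out of [0,1] at probe %s, sample %s (value %s)",
                 probe_ids[out_of_range[1L, 1L]],
                 sample_ids[out_of_range[1L, 2L]],
                 format(vals[out_of_range[1L, , drop = FALSE]]))
  }
  check_beta_matrix(vals)
}

#' Write a beta-value matrix to TSV
#'
#' Values are written with six decimal places; [read_beta_matrix()] restores
#' the matrix to within 1e-6.
#'
#' @param beta Numeric probes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  check_beta_matrix(beta)
  dt <- data.table::data.table(probe_id = rownames(beta))
  for (j in seq_len(ncol(beta)))
    data.table::set(dt, j = colnames(beta)[j], value = sprintf("%.6f", beta[, j]))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read and write sample sheets
#'
#' A sample sheet is a CSV with columns `sample_id`, `group`, `age`, `sex`
#' and `cohort`. `group` is restricted to the closed vocabulary
#' `case`, `control`, `other_disorder`, `validation`, `query`; `age`
#' (years) and `sex` (`"F"`/`"M"`) may be missing.
#'
#' @param path CSV path.
#' @return `read_sample_sheet()` returns a data.frame;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path))
    stop_episign("format_error", "sample sheet not found: %s", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("age", "sex", "cohort"))
    if (!col %in% names(sheet)) sheet[[col]] <- NA
  check_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  check_sample_sheet(sheet)
  utils::write.csv(sheet[, intersect(c("sample_id", "group", "age", "sex", "cohort"),
                                     names(sheet)), drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between beta values and M-values
#'
#' The M-value is the logit-2 methylation intensity,
#' `M = log2(b / (1 - b))`, computed after clipping beta to
#' `[epsilon, 1 - epsilon]` so the transform is total and the resulting
#' values are finite. `m_to_beta()` is the exact inverse of the unclipped
#' transform, `beta = 2^M / (1 + 2^M)`.
#'
#' @param beta Numeric vector/matrix of fractions in `[0, 1]`.
#' @param epsilon Clipping constant in `(0, 0.5)`; default 0.01.
#' @return Numeric object of the same shape.
#' @export
beta_to_m <- function(beta, epsilon = 0.01) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 0.5)
    stop_episign("argument_error", "epsilon must be a single value in (0, 0.5)")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_episign("argument_error", "beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m Numeric vector/matrix of finite M-values.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m)))
    stop_episign("argument_error", "M-values must be finite")
  e <- 2^m
  e / (1 + e)
}

#' Drop probes with missing values
#'
#' The classifier needs complete probe vectors, so probes with any missing
#' sample value are removed before analysis; the number dropped is reported
#' via a message.
#'
#' @param beta Probes x samples matrix, possibly containing `NA`.
#' @return The complete-probe submatrix.
#' @export
drop_incomplete_probes <- function(beta) {
  keep <- !apply(is.na(beta), 1L, any)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(sprintf("dropping %d probe(s) with missing values", n_drop))
  beta[keep, , drop = FALSE]
}

#' Select age- and sex-matched controls for a case series
#'
#' Greedy nearest-age matching within sex strata, without replacement:
#' cases are processed in input order and each receives up to `ratio`
#' controls of the same sex with the smallest absolute age gap (ties broken
#' by control id, lexicographically). The procedure is deterministic.
#'
#' @param cases Data.frame with `sample_id`, `age`, `sex` (no missing values).
#' @param control_pool Data.frame with the same columns.
#' @param ratio Maximum controls per case (default 1).
#' @return A list with `selected` (character vector of control ids, union
#'   over cases) and `age_gap` (named per-case mean absolute age gap in
#'   years).
#' @export
match_controls <- function(cases, control_pool, ratio = 1L) {
  for (d in list(cases, control_pool))
    if (!all(c("sample_id", "age", "sex") %in% names(d)))
      stop_episign("argument_error", "cases and control_pool need sample_id, age, sex columns")
  if (anyNA(cases$age) || anyNA(cases$sex))
    stop_episign("argument_error", "every case must have age and sex")
  if (nrow(control_pool) == 0L)
    stop_episign("matching_error", "control pool is empty")
  ratio <- as.integer(ratio)
  if (ratio < 1L) stop_episign("argument_error", "ratio must be >= 1")

  pool <- control_pool[order(control_pool$sample_id), , drop = FALSE]
  available <- rep(TRUE, nrow(pool))
  selected <- character(0)
  gaps <- stats::setNames(rep(NA_real_, nrow(cases)), cases$sample_id)
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    in_stratum <- available & pool$sex == cases$sex[i] & !is.na(pool$age)
    if (!any(in_stratum)) {
      unmatched <- c(unmatched, cases$sample_id[i])
      next
    }
    idx <- which(in_stratum)
    # order by |age gap| then control id; pool rows already id-sorted so
    # order() on the gap alone preserves the lexicographic tie-break
    gap <- abs(pool$age[idx] - cases$age[i])
    take <- idx[order(gap)][seq_len(min(ratio, length(idx)))]
    available[take] <- FALSE
    selected <- c(selected, pool$sample_id[take])
    gaps[i] <- mean(abs(pool$age[take] - cases$age[i]))
  }
  if (length(unmatched))
    stop_episign("matching_error",
                 "no remaining same-sex controls for case(s): %s",
                 paste(unmatched, collapse = ", "))
  list(selected = selected, age_gap = gaps)
}
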