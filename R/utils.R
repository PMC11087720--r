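# Internal helpers shared across modules.

# Derive a child seed from a master seed by fixed arithmetic, kept inside
# the 32-bit integer range so set.seed() always accepts it.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647L)
}

# Classed error constructors so callers can distinguish user/format errors
# from runtime failures.
stop_episign <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "episignr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Validate a beta matrix: numeric matrix, dimnames present and unique,
# all values in [0,1], no NAs.
check_beta_matrix <- function(beta, what = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop_episign("format_error", "%s must be a numeric matrix", what)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop_episign("format_error", "%s must have probe rownames and sample colnames", what)
  if (anyDuplicated(rownames(beta)))
    stop_episign("format_error", "duplicate probe ids in %s", what)
  if (anyDuplicated(colnames(beta)))
    stop_episign("format_error", "duplicate sample ids in %s", what)
  if (anyNA(beta))
    stop_episign("format_error", "%s contains missing values", what)
  if (any(beta < 0 | beta > 1))
    stop_episign("format_error", "%s contains values outside [0,1]", what)
  invisible(beta)
}

check_sample_sheet <- function(sheet) {
  required <- c("sample_id", "group")
  if (!is.data.frame(sheet) || !all(required %in% names(sheet)))
    stop_episign("format_error",
                 "sample sheet must be a data.frame with columns %s",
                 paste(required, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop_episign("format_error", "duplicate sample ids in sample sheet")
  vocab <- c("case", "control", "other_disorder", "validation", "query")
  bad <- setdiff(unique(sheet$group), vocab)
  if (length(bad))
    stop_episign("format_error", "unknown group label(s): %s",
                 paste(bad, collapse = ", "))
  invisible(sheet)
}
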