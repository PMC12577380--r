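# Internal helpers: typed errors, seed stream-splitting, shared validation.

stop_format <- function(msg, ...) {
  abort(msg, class = "cprenrich_format_error", ...)
}

stop_vocab <- function(msg, ...) {
  abort(msg, class = "cprenrich_vocabulary_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "cprenrich_config_error", ...)
}

stop_input <- function(msg, ...) {
  abort(msg, class = "cprenrich_input_error", ...)
}

#' Derive a stage-specific random seed from a master seed
#'
#' Deterministically splits one master seed into independent sub-seeds, one
#' per named stage, so adding a simulation stage never perturbs the random
#' stream of another. The derivation hashes the label characters into a
#' 31-bit integer; it is stable across platforms and R sessions.
#'
#' @param seed Master integer seed.
#' @param label Character label of the consuming stage.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "counts")
#' derive_seed(42, "qpcr")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647
  h <- (seed %% m)
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Checks a wide abundance table: first column sample_id, remaining columns
# one per ASV. Returns the ASV column names invisibly.
check_wide_table <- function(tbl, what = "table", integer_counts = FALSE) {
  if (!is.data.frame(tbl) || ncol(tbl) < 1) {
    stop_format(paste0(what, " must be a data frame with a sample_id column"))
  }
  if (names(tbl)[1] != "sample_id") {
    stop_format(paste0(what, ": first column must be 'sample_id'"))
  }
  ids <- tbl$sample_id
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_format(paste0(what, ": duplicate sample id(s): ",
                       paste(dup, collapse = ", ")))
  }
  asvs <- names(tbl)[-1]
  if (anyDuplicated(asvs)) {
    dup <- unique(asvs[duplicated(asvs)])
    stop_format(paste0(what, ": duplicate ASV id(s): ",
                       paste(dup, collapse = ", ")))
  }
  if (length(asvs) && nrow(tbl) > 0) {
    m <- as.matrix(tbl[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      stop_format(paste0(what, ": all abundance cells must be numeric"))
    }
    if (anyNA(m)) stop_format(paste0(what, ": missing values not allowed"))
    if (any(m < 0)) {
      idx <- which(m < 0, arr.ind = TRUE)[1, ]
      stop_format(sprintf("%s: negative value at sample '%s', ASV '%s'",
                          what, ids[idx[1]], asvs[idx[2]]))
    }
    if (integer_counts && any(m != floor(m))) {
      idx <- which(m != floor(m), arr.ind = TRUE)[1, ]
      stop_format(sprintf("%s: non-integer count at sample '%s', ASV '%s'",
                          what, ids[idx[1]], asvs[idx[2]]))
    }
  }
  invisible(asvs)
}

# wide tibble -> numeric matrix (samples x ASVs) with dimnames
wide_to_matrix <- function(tbl) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$sample_id
  m
}

matrix_to_wide <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

canonical_pair <- function(a, b) {
  swap <- a > b
  tibble(asv_a = ifelse(swap, b, a), asv_b = ifelse(swap, a, b))
}
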