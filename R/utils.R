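# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's RNG stream is restored afterwards, so seeded functions
# do not perturb the surrounding session. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Validate an OTU-by-sample count matrix: named, unique ids, integral, >= 0.
validate_count_table <- function(t, integer = TRUE, what = "count table") {
  if (!is.matrix(t)) {
    stop(what, " must be a matrix (OTUs as rows, samples as columns)", call. = FALSE)
  }
  if (is.null(rownames(t)) || is.null(colnames(t))) {
    stop(what, " must carry OTU row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(t))) {
    stop("duplicated OTU ids: ",
         paste(unique(rownames(t)[duplicated(rownames(t))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(t))) {
    stop("duplicated sample ids: ",
         paste(unique(colnames(t)[duplicated(colnames(t))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(t)) stop(what, " contains missing values", call. = FALSE)
  if (any(t < 0)) stop(what, " contains negative values", call. = FALSE)
  if (integer && any(t != round(t))) {
    stop(what, " contains non-integer counts", call. = FALSE)
  }
  invisible(t)
}

# Align a metadata data frame to the columns of a count table.
# Returns the metadata reordered to match sample ids; errors on gaps.
align_metadata <- function(t, meta) {
  if (!is.data.frame(meta) || is.null(meta$sample_id)) {
    stop("metadata must be a data frame with a 'sample_id' column", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("metadata has duplicated sample ids", call. = FALSE)
  }
  idx <- match(colnames(t), meta$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from metadata: ",
         paste(colnames(t)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  meta[idx, , drop = FALSE]
}

is_count_integerish <- function(t) all(t == round(t))
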