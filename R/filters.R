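#' Remove low-depth samples
#'
#' Drops samples whose total read count falls below a floor (default 2000
#' reads). OTU rows are preserved, possibly becoming all-zero.
#'
#' @param t Count matrix (OTUs x samples).
#' @param floor Minimum library size retained.
#' @param strict If `FALSE` (default) samples with exactly `floor` reads are
#'   kept (column sum >= floor); `TRUE` requires column sum > floor. The
#'   boundary at exactly the floor is ambiguous in common usage, hence the
#'   switch; the default keeps it.
#' @return The filtered count matrix.
#' @export
filter_samples_min_reads <- function(t, floor = 2000, strict = FALSE) {
  validate_count_table(t)
  stopifnot(floor >= 0)
  totals <- colSums(t)
  keep <- if (strict) totals > floor else totals >= floor
  if (!any(keep)) warning("all samples fall below the read floor; empty table returned")
  t[, keep, drop = FALSE]
}

#' Remove rare features
#'
#' Retains OTUs with total count >= `min_total` across samples AND detection
#' (count > 0) in >= `min_samples` samples. The defaults drop features with a
#' frequency of ten or less, or seen in a single sample only.
#'
#' @param t Count matrix.
#' @param min_total Minimum total count (default 11, i.e. frequency > 10).
#' @param min_samples Minimum number of samples with detection (default 2).
#' @return The filtered count matrix.
#' @export
filter_features <- function(t, min_total = 11, min_samples = 2) {
  validate_count_table(t)
  stopifnot(min_total >= 0, min_samples >= 0)
  keep <- rowSums(t) >= min_total & rowSums(t > 0) >= min_samples
  t[keep, , drop = FALSE]
}

#' Collapse a count table to a higher taxonomic rank
#'
#' Rows are summed within identical rank labels; OTUs unassigned at the rank
#' are pooled under the sentinel label `"unclassified"`. Per-sample totals are
#' conserved exactly.
#'
#' @param t Count matrix.
#' @param tax Taxonomy data frame (`otu_id` plus rank columns).
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return Count matrix with rank labels as row names.
#' @export
collapse_taxonomy <- function(t, tax,
                              rank = c("phylum", "class", "order", "family",
                                       "genus", "species")) {
  rank <- match.arg(rank)
  validate_count_table(t, integer = FALSE)
  idx <- match(rownames(t), tax$otu_id)
  if (anyNA(idx)) {
    stop("taxonomy missing OTUs: ",
         paste(rownames(t)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  labels <- tax[[rank]][idx]
  labels[is.na(labels) | labels == ""] <- "unclassified"
  rowsum(t, group = labels, reorder = TRUE)
}
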