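#' Read an OTU-by-sample count table
#'
#' Reads a feature count table in either of the two supported dialects:
#' tab-separated text (OTUs as rows, samples as columns, first column
#' `otu_id`, header row of sample ids) or BIOM-JSON v1.0. The orientation of
#' the TSV dialect is fixed; no transposition heuristics are applied, so a
#' transposed table fails validation loudly rather than silently.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom_json"`.
#' @return An integer matrix with OTU row names and sample column names.
#' @export
read_count_table <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L) {
      stop("malformed TSV count table (line 1): expected tab-separated ",
           "header with an 'otu_id' column followed by sample ids", call. = FALSE)
    }
    samples <- header[-1]
    if (anyDuplicated(samples)) {
      stop("malformed TSV count table (line 1): duplicated sample ids: ",
           paste(unique(samples[duplicated(samples)]), collapse = ", "),
           call. = FALSE)
    }
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = c("character", rep("numeric", length(samples))),
                             stringsAsFactors = FALSE)
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- raw[[1]]
    colnames(m) <- samples
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("malformed TSV count table: non-numeric count at row '%s', sample '%s'",
                   rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
    }
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  }
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU-by-sample count table
#'
#' @param t Validated count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(t, path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  validate_count_table(t)
  if (format == "tsv") {
    df <- data.frame(otu_id = rownames(t), t, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    biomformat::write_biom(biomformat::make_biom(t), path)
  }
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Plain TSV keyed by `sample_id`. Values are read as character; apply
#' [harmonise_metadata()] to map raw fields onto the harmonised categories.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", stringsAsFactors = FALSE)
  if (is.null(meta$sample_id)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  meta
}

#' @rdname read_metadata
#' @param meta Metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with an `otu_id` column and any of the columns
#' `phylum`, `class`, `order`, `family`, `genus`, `species`.
#' Empty strings are treated as unassigned ranks.
#'
#' @param path Path to the file.
#' @return A data frame with `otu_id` plus rank columns; `NA` = unassigned.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (is.null(tax$otu_id)) stop("taxonomy must contain an 'otu_id' column", call. = FALSE)
  for (r in setdiff(names(tax), "otu_id")) tax[[r]][tax[[r]] == ""] <- NA_character_
  tax
}

#' Read a rooted phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] with validation of the invariants the
#' UniFrac machinery relies on: single root, unique leaf labels, non-negative
#' branch lengths.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path, call. = FALSE)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("tree has duplicated leaf labels", call. = FALSE)
  # a single root node (possibly multifurcating) must anchor the edge matrix
  if (length(setdiff(tree$edge[, 1L], tree$edge[, 2L])) != 1L) {
    stop("tree is not rooted", call. = FALSE)
  }
  invisible(tree)
}

#' Prune a tree to a set of leaves
#'
#' Retains exactly `keep_ids`, collapsing unary internal nodes by summing
#' branch lengths, so root-to-leaf path lengths of the kept leaves are
#' unchanged and UniFrac is invariant to pruning of absent taxa.
#'
#' @param tree A rooted `phylo` tree.
#' @param keep_ids Leaf labels to retain (must all be present).
#' @return The pruned `phylo` tree.
#' @export
prune_tree <- function(tree, keep_ids) {
  validate_tree(tree)
  missing <- setdiff(keep_ids, tree$tip.label)
  if (length(missing)) {
    stop("leaves absent from tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (setequal(keep_ids, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep_ids)
}

#' Read representative sequences
#'
#' @param path FASTA file of OTU/ZOTU representative sequences.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_rep_seqs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(seqs))) stop("duplicated sequence ids", call. = FALSE)
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequences present", call. = FALSE)
  seqs
}

#' Serialise a distance matrix as square TSV
#'
#' @param d A `dist` object or symmetric matrix with sample-id labels.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  stats::as.dist(m)
}
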