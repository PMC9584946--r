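# Independent-cohort validation: sequence-identity affiliation of denoised
# variants (ZOTUs) to core OTUs, core prevalence, and cross-cohort prediction.

#' Affiliate ZOTUs to core OTU references by alignment identity
#'
#' Each ZOTU is globally aligned (Needleman-Wunsch; match +1, mismatch -1,
#' gap open 2, gap extend 1) against every core reference sequence. Identity
#' is the number of matching columns divided by the total alignment columns,
#' gap columns included. A ZOTU is assigned to the best-identity reference
#' when that identity reaches `identity_min`; exact ties go to the
#' lexicographically smallest reference id, so the mapping is deterministic.
#'
#' @param zotus Named [Biostrings::DNAStringSet] (or named character vector)
#'   of denoised variant sequences.
#' @param core_refs Named DNAStringSet of core OTU representative sequences.
#' @param identity_min Assignment threshold (default 0.97).
#' @return Data frame with one row per ZOTU: `zotu_id`, `otu_id` (`NA` when
#'   unassigned), `identity` (best identity observed), `alignment_length`.
#' @export
affiliate_zotus <- function(zotus, core_refs, identity_min = 0.97) {
  as_dss <- function(x) {
    if (inherits(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
  }
  zotus <- as_dss(zotus)
  core_refs <- as_dss(core_refs)
  if (length(core_refs) == 0L) stop("empty reference set", call. = FALSE)
  if (is.null(names(zotus)) || is.null(names(core_refs))) {
    stop("sequences must be named", call. = FALSE)
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  ref_order <- order(names(core_refs))
  core_refs <- core_refs[ref_order]
  rows <- lapply(seq_along(zotus), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = core_refs, subject = zotus[[i]], type = "global",
      substitutionMatrix = submat, gapOpening = 2, gapExtension = 1)
    width <- Biostrings::width(Biostrings::alignedPattern(aln))
    ident <- Biostrings::nmatch(aln) / width
    best <- which.max(ident)  # ties: first = lexicographically smallest id
    data.frame(zotu_id = names(zotus)[i],
               otu_id = if (ident[best] >= identity_min - 1e-12)
                 names(core_refs)[best] else NA_character_,
               identity = ident[best],
               alignment_length = width[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative relative abundance of the core in a cohort
#'
#' Per sample, the sum of total-sum-scaled abundances over the core rows
#' (core OTU ids directly, or the ZOTUs affiliated to core OTUs), with the
#' mean and standard deviation across samples. Input counts are normalised
#' internally, so raw and pre-scaled tables give identical results.
#'
#' @param t Count (or relative-abundance) matrix of the cohort.
#' @param core A `core_set`, a character vector of row ids, or an affiliation
#'   data frame from [affiliate_zotus()] (assigned ZOTUs are used).
#' @return Object of class `core_prevalence`: list with `per_sample`
#'   (named vector), `mean`, `sd`.
#' @export
core_prevalence <- function(t, core) {
  ids <- if (inherits(core, "core_set")) {
    core$members
  } else if (is.data.frame(core)) {
    core$zotu_id[!is.na(core$otu_id)]
  } else {
    as.character(core)
  }
  ids <- intersect(ids, rownames(t))
  if (length(ids) == 0L) stop("no core taxa present in the table", call. = FALSE)
  rel <- tss(t)
  per_sample <- colSums(rel[ids, , drop = FALSE])
  structure(list(per_sample = per_sample,
                 mean = mean(per_sample),
                 sd = stats::sd(per_sample),
                 n_core_rows = length(ids)),
            class = "core_prevalence")
}

#' @export
print.core_prevalence <- function(x, ...) {
  cat(sprintf("Core prevalence: %.1f%% +/- %.1f%% of reads (%d samples, %d core rows)\n",
              100 * x$mean, 100 * (x$sd %||% 0), length(x$per_sample), x$n_core_rows))
  invisible(x)
}

#' Apply a trained classifier to an independent cohort
#'
#' Reconciles the cohort's feature space with the training space: features
#' unseen in training are dropped, training features missing from the cohort
#' are zero-filled (both choices are reported). Per-sample class votes give
#' the majority label; when true labels are supplied, overall accuracy and —
#' for binary categories with both labels present — the ROC AUC computed from
#' vote fractions are returned.
#'
#' @param model An [rf_train()] model.
#' @param test Feature matrix of the independent cohort (same taxonomic
#'   level as the training table).
#' @param labels Optional true labels, in `colnames(test)` order.
#' @return Object of class `transfer_prediction`: list with `predicted`,
#'   `votes`, `accuracy` (`NA` without labels), `auc` (`NA` when undefined),
#'   `n_features_used`, `n_features_zero_filled`.
#' @export
transfer_predict <- function(model, test, labels = NULL) {
  stopifnot(inherits(model, "rf_model"))
  validate_count_table(test, integer = FALSE)
  shared <- intersect(model$feature_ids, rownames(test))
  if (length(shared) == 0L) stop("no feature overlap with the training space",
                                 call. = FALSE)
  x <- matrix(0, ncol(test), length(model$feature_ids),
              dimnames = list(colnames(test), model$feature_names))
  x[, match(shared, model$feature_ids)] <- t(test[shared, , drop = FALSE])
  votes <- stats::predict(model$forest, x, type = "vote", norm.votes = TRUE)
  predicted <- colnames(votes)[max.col(votes, ties.method = "first")]
  names(predicted) <- rownames(x)
  accuracy <- NA_real_
  auc <- NA_real_
  if (!is.null(labels)) {
    labels <- as.character(labels)
    accuracy <- mean(predicted == labels)
    if (length(model$levels) == 2L && length(unique(labels)) == 2L &&
        length(labels) >= 2L) {
      roc <- pROC::roc(response = factor(labels, levels = model$levels),
                       predictor = votes[, model$levels[2L]],
                       levels = model$levels, direction = "<", quiet = TRUE)
      auc <- as.numeric(pROC::auc(roc))
    }
  }
  structure(list(predicted = predicted, votes = votes,
                 accuracy = accuracy, auc = auc,
                 n_features_used = length(shared),
                 n_features_zero_filled = length(model$feature_ids) - length(shared)),
            class = "transfer_prediction")
}

#' @export
print.transfer_prediction <- function(x, ...) {
  cat("Transfer prediction:", length(x$predicted), "samples;",
      x$n_features_used, "shared features,",
      x$n_features_zero_filled, "zero-filled\n")
  if (!is.na(x$accuracy)) cat(sprintf("Accuracy: %.1f%%", 100 * x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC: %.1f%%", 100 * x$auc))
  if (!is.na(x$accuracy) || !is.na(x$auc)) cat("\n")
  invisible(x)
}
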