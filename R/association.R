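# Random-forest host-factor association and rank-sum differential abundance.

prepare_rf_data <- function(t, meta, category) {
  meta <- align_metadata(t, meta)
  keep <- !(meta[[category]] %in% "unknown") & !is.na(meta[[category]])
  y <- factor(meta[[category]][keep])
  y <- droplevels(y)
  if (nlevels(y) < 2L) {
    stop("category '", category, "' has fewer than two informative levels",
         call. = FALSE)
  }
  if (any(table(y) < 2L)) {
    stop("category '", category, "' has level(s) with fewer than two samples",
         call. = FALSE)
  }
  x <- t(t[, keep, drop = FALSE])
  colnames(x) <- make.names(colnames(x))  # randomForest needs syntactic names
  list(x = x, y = y, feature_ids = rownames(t))
}

#' Train a random-forest classifier for one category
#'
#' Bagged ensemble of 500 classification trees with sqrt(p) candidate
#' features per split (the standard defaults); out-of-bag error is recorded.
#' Samples with an `unknown` level are excluded.
#'
#' @param t Feature matrix (taxa x samples), any normalisation.
#' @param meta Harmonised metadata.
#' @param category Metadata column to classify.
#' @param ntree Number of trees (default 500).
#' @param seed Seed for the ensemble.
#' @return Object of class `rf_model`: list with `forest`, `category`,
#'   `feature_ids`, `oob_error`, `n_samples`.
#' @export
rf_train <- function(t, meta, category, ntree = 500, seed = NULL) {
  dat <- prepare_rf_data(t, meta, category)
  forest <- with_seed(seed, {
    randomForest::randomForest(dat$x, dat$y, ntree = ntree,
                               importance = TRUE, proximity = FALSE)
  })
  structure(list(forest = forest, category = category,
                 feature_ids = dat$feature_ids,
                 feature_names = colnames(dat$x),
                 oob_error = unname(forest$err.rate[ntree, "OOB"]),
                 n_samples = nrow(dat$x), levels = levels(dat$y)),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat("Random forest:", x$category, "(", length(x$levels), "classes,",
      x$n_samples, "samples,", length(x$feature_ids), "features )\n")
  cat("OOB error:", sprintf("%.1f%%", 100 * x$oob_error), "\n")
  invisible(x)
}

#' Random-forest grid over categories, taxonomic levels and normalisations
#'
#' Fits one classifier per crossing of the requested categories, taxonomic
#' levels and normalisation methods, recording the out-of-bag error of each.
#' The grid is the machinery behind comparisons of which host factor is most
#' predictable from the community profile and how normalisation affects it.
#'
#' @param t OTU count matrix.
#' @param meta Harmonised metadata.
#' @param categories Metadata columns to classify.
#' @param tax Taxonomy table; required when `levels` includes a rank other
#'   than `"otu"`.
#' @param levels Taxonomic levels (`"otu"` plus any of the six ranks).
#' @param normalisations Subset of `c("tss", "rar", "rra", "clr")`.
#' @param depth Rarefaction depth for `"rar"`/`"rra"`.
#' @param ntree Trees per forest.
#' @param seed Base seed; each crossing uses a distinct derived seed.
#' @param keep_models Attach the fitted `rf_model` objects as an attribute.
#' @return Data frame of class `rf_grid`: one row per crossing with
#'   `category`, `level`, `normalisation`, `oob_error`, `n_samples`,
#'   `n_features`, `seed`.
#' @export
rf_grid <- function(t, meta, categories, tax = NULL, levels = "otu",
                    normalisations = "tss", depth = 5000, ntree = 500,
                    seed = NULL, keep_models = FALSE) {
  crossings <- expand.grid(category = categories, level = levels,
                           normalisation = normalisations,
                           stringsAsFactors = FALSE)
  rows <- vector("list", nrow(crossings))
  models <- if (keep_models) vector("list", nrow(crossings)) else NULL
  for (i in seq_len(nrow(crossings))) {
    cr <- crossings[i, ]
    ti <- if (cr$level == "otu") t else {
      if (is.null(tax)) stop("taxonomy required for level ", cr$level, call. = FALSE)
      collapse_taxonomy(t, tax, cr$level)
    }
    seed_i <- if (is.null(seed)) NULL else seed + i
    ni <- normalise(ti, cr$normalisation, depth = depth, seed = seed_i)
    fit <- rf_train(ni, meta, cr$category, ntree = ntree, seed = seed_i)
    rows[[i]] <- data.frame(category = cr$category, level = cr$level,
                            normalisation = cr$normalisation,
                            oob_error = fit$oob_error,
                            n_samples = fit$n_samples,
                            n_features = nrow(ni),
                            seed = seed_i %||% NA_integer_,
                            stringsAsFactors = FALSE)
    if (keep_models) models[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rf_grid", "data.frame")
  if (keep_models) attr(out, "models") <- models
  out
}

#' Cross-validated selection of important features
#'
#' Features are ranked by mean decrease in accuracy from a full-data forest;
#' the cross-validation error is evaluated over geometrically reduced feature
#' counts (ten-fold, repeated), and the selected set is the top-ranked prefix
#' at the smallest feature count whose mean CV error is within one pooled
#' standard deviation of the minimum — the point where the error curve starts
#' to stabilise. The one-standard-deviation reading of "stabilise" is a
#' formalisation choice; the threshold is configurable via `sd_factor`.
#'
#' @param t Feature matrix (taxa x samples).
#' @param meta Harmonised metadata.
#' @param category Metadata column.
#' @param cv_folds Folds (default 10).
#' @param repeats Repetitions of the CV (default 5).
#' @param step Geometric reduction factor for the feature counts (default 0.5).
#' @param sd_factor Multiplier on the pooled SD in the stabilisation rule.
#' @param ntree Trees per forest.
#' @param seed Seed.
#' @return Object of class `important_features`: list with `category`,
#'   `ranking` (all features, most important first), `selected`,
#'   `cv_curve` (data frame `n_features`, `mean_error`, `sd_error`).
#' @export
important_features <- function(t, meta, category, cv_folds = 10, repeats = 5,
                               step = 0.5, sd_factor = 1, ntree = 500,
                               seed = NULL) {
  dat <- prepare_rf_data(t, meta, category)
  if (nrow(dat$x) < cv_folds) {
    stop("fewer samples than cross-validation folds", call. = FALSE)
  }
  res <- with_seed(seed, {
    fit <- randomForest::randomForest(dat$x, dat$y, ntree = ntree,
                                      importance = TRUE)
    imp <- randomForest::importance(fit, type = 1)[, 1L]
    errs <- NULL
    for (r in seq_len(repeats)) {
      cv <- randomForest::rfcv(dat$x, dat$y, cv.fold = cv_folds, step = step,
                               ntree = ntree)
      errs <- rbind(errs, cv$error.cv)
    }
    list(imp = imp, counts = as.integer(colnames(errs)), errs = errs)
  })
  mean_err <- colMeans(res$errs)
  sd_err <- apply(res$errs, 2L, stats::sd)
  sd_err[is.na(sd_err)] <- 0  # single repeat: no dispersion estimate
  counts <- res$counts
  i_min <- which.min(mean_err)
  cutoff <- mean_err[i_min] + sd_factor * sd_err[i_min]
  n_sel <- min(counts[mean_err <= cutoff + 1e-12])
  ranking <- dat$feature_ids[order(res$imp, decreasing = TRUE)]
  structure(list(category = category, ranking = ranking,
                 selected = ranking[seq_len(min(n_sel, length(ranking)))],
                 cv_curve = data.frame(n_features = counts,
                                       mean_error = mean_err,
                                       sd_error = sd_err, row.names = NULL)),
            class = "important_features")
}

#' @export
print.important_features <- function(x, ...) {
  cat("Important features for", x$category, ":", length(x$selected),
      "of", length(x$ranking), "selected\n")
  invisible(x)
}

#' Wilcoxon rank-sum differential abundance
#'
#' Two-sided Wilcoxon rank-sum test (midranks; R's standard exact /
#' normal-approximation switch) per taxon between two levels of a category,
#' Benjamini-Hochberg adjustment across taxa, and a log2 fold change of group
#' medians with a pseudo-abundance equal to the smallest non-zero relative
#' abundance in the table. Taxa that are all-zero in both groups are excluded.
#'
#' @param t Count or relative-abundance matrix (taxa x samples).
#' @param meta Harmonised metadata.
#' @param category Metadata column.
#' @param pair Length-2 character vector of levels; the fold change is
#'   log2(median(pair1) / median(pair2)).
#' @param normalise Convert `t` to relative abundance first (default `TRUE`).
#' @return Data frame with `taxon`, `log2_fold`, `statistic`, `p_value`, `q_value`.
#' @export
differential_rank_sum <- function(t, meta, category, pair, normalise = TRUE) {
  stopifnot(length(pair) == 2L)
  meta <- align_metadata(t, meta)
  rel <- if (normalise) tss(t) else t
  ia <- which(meta[[category]] == pair[1L])
  ib <- which(meta[[category]] == pair[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both levels need at least two samples", call. = FALSE)
  }
  eps <- min(rel[rel > 0])
  rows <- lapply(rownames(rel), function(tx) {
    a <- rel[tx, ia]; b <- rel[tx, ib]
    if (all(a == 0) && all(b == 0)) return(NULL)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    data.frame(taxon = tx,
               log2_fold = log2((stats::median(a) + eps) / (stats::median(b) + eps)),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable taxa", call. = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
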