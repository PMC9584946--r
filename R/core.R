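# Core-microbiome definition: abundance-occupancy statistics, the threshold
# rule, ranked occupancy-contribution prioritisation under Bray-Curtis and
# weighted UniFrac, and the consensus of the three.

#' Abundance-occupancy statistics per OTU
#'
#' Samples are rarefied to `rarefy_depth` reads (detection = rarefied count
#' > 0), mean relative abundance is computed on the total-sum-scaled rarefied
#' table, and occupancy is tallied overall and within each study.
#'
#' @param t Count matrix (OTUs x samples).
#' @param meta Harmonised metadata covering every sample (column `study`).
#' @param rarefy_depth Rarefaction depth (default 5000); samples below it are
#'   dropped. Use `NULL` to skip rarefaction (e.g. when `t` is already
#'   rarefied).
#' @param seed Seed for the rarefaction draw.
#' @return Object of class `abundance_occupancy`: data frame with `otu_id`,
#'   `mra` (mean relative abundance), `occ_samples` (fraction of samples with
#'   detection), `mean_study_occ` (mean of per-study occupancies),
#'   `n_studies_full` (studies with occupancy 1). Attributes: `occ_by_study`
#'   (OTU x study matrix), `rarefied` (the rarefied table), `n_studies`.
#' @export
abundance_occupancy <- function(t, meta, rarefy_depth = 5000, seed = NULL) {
  meta <- align_metadata(t, meta)
  all_studies <- unique(meta$study)
  r <- if (is.null(rarefy_depth)) t else rarefy(t, depth = rarefy_depth, seed = seed)
  meta <- meta[match(colnames(r), meta$sample_id), , drop = FALSE]
  studies <- unique(meta$study)
  dropped <- setdiff(all_studies, studies)
  if (length(dropped)) warning("studies with no retained samples dropped: ",
                               paste(dropped, collapse = ", "))
  rel <- tss(r)
  det <- r > 0
  occ_by_study <- vapply(studies, function(s) {
    rowMeans(det[, meta$study == s, drop = FALSE])
  }, numeric(nrow(r)))
  out <- data.frame(
    otu_id = rownames(r),
    mra = rowMeans(rel),
    occ_samples = rowMeans(det),
    mean_study_occ = rowMeans(occ_by_study),
    n_studies_full = rowSums(occ_by_study == 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("abundance_occupancy", "data.frame"),
            occ_by_study = occ_by_study, rarefied = r, n_studies = length(studies))
}

new_core_set <- function(method, members, stats, params) {
  structure(list(method = method, members = members,
                 stats = stats[match(members, stats$otu_id), , drop = FALSE],
                 params = params),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("Core set (", x$method, "): ", length(x$members), " OTUs\n", sep = "")
  if (length(x$members)) {
    cat("Top members:", paste(utils::head(x$members, 8), collapse = ", "),
        if (length(x$members) > 8) "...\n" else "\n")
  }
  invisible(x)
}

#' Threshold definition of the core
#'
#' An OTU is a core member iff its mean relative abundance exceeds `mra_min`
#' AND it is either present in more than `occ_min` of all samples or shows
#' 100% occupancy in more than `full_study_min` studies. Both comparisons are
#' strict, following the usual phrasing of these criteria. Members are ordered
#' by descending mean relative abundance.
#'
#' @param ao An [abundance_occupancy()] table.
#' @param mra_min Mean-relative-abundance threshold (default 0.001, i.e. 0.1%).
#' @param occ_min Overall occupancy threshold (default 0.75).
#' @param full_study_min Number of fully occupied studies that rescues an OTU
#'   failing the overall occupancy clause (default 10).
#' @return A `core_set` with method `"MRA_OCC"`.
#' @export
core_by_threshold <- function(ao, mra_min = 0.001, occ_min = 0.75,
                              full_study_min = 10) {
  stopifnot(mra_min >= 0, occ_min >= 0, occ_min <= 1, full_study_min >= 0)
  keep <- ao$mra > mra_min &
    (ao$occ_samples > occ_min | ao$n_studies_full > full_study_min)
  members <- ao$otu_id[keep][order(-ao$mra[keep], ao$otu_id[keep])]
  new_core_set("MRA_OCC", members, ao,
               list(mra_min = mra_min, occ_min = occ_min,
                    full_study_min = full_study_min))
}

#' Rank OTUs by occupancy across studies
#'
#' Primary key: mean of the per-study occupancies, descending. Ties are broken
#' by descending mean relative abundance, then lexicographic OTU id, so the
#' ordering is deterministic. An alternative key sums the within-study
#' occupancy ranks of each OTU (the ranked-occupancy convention of the
#' prioritisation literature).
#'
#' @param ao An [abundance_occupancy()] table.
#' @param key `"mean_study_occupancy"` (default) or `"rank_sum"`.
#' @return Character vector of OTU ids, highest occupancy first.
#' @export
rank_by_occupancy <- function(ao, key = c("mean_study_occupancy", "rank_sum")) {
  key <- match.arg(key)
  if (nrow(ao) == 0L) stop("empty abundance-occupancy table", call. = FALSE)
  score <- if (key == "mean_study_occupancy") {
    ao$mean_study_occ
  } else {
    occ <- attr(ao, "occ_by_study")
    rowSums(apply(occ, 2L, rank))
  }
  ao$otu_id[order(-score, -ao$mra, ao$otu_id)]
}

# Pairwise Manhattan distances of the columns of m, as the lower-triangle
# vector of dist(); m may be a plain vector (one row).
pair_l1 <- function(m) {
  as.vector(stats::dist(if (is.matrix(m)) t(m) else m, method = "manhattan"))
}

#' Cumulative contribution of ranked OTUs to beta diversity
#'
#' For each prefix of the ranked OTU list the table is restricted to those
#' OTUs (all other taxa contribute zero mass, while per-sample totals stay at
#' the full-sample depth) and the chosen dissimilarity is recomputed; the
#' explained fraction at rank r is the mean over sample pairs of
#' d(prefix) / d(full table). Sample pairs with zero full dissimilarity are
#' excluded. Keeping the full-sample denominators makes the Bray-Curtis curve
#' non-decreasing and guarantees it ends at exactly 1; the weighted UniFrac
#' curve also ends at 1 but can dip locally where subtree differences cancel.
#'
#' @param t Count matrix, typically the rarefied table from
#'   [abundance_occupancy()].
#' @param ranked Ordered OTU ids from [rank_by_occupancy()].
#' @param metric `"bray_curtis"` or `"weighted_unifrac"`.
#' @param tree Required for weighted UniFrac.
#' @param max_rank Evaluate the curve up to this rank only (default: all).
#' @return Object of class `contribution_curve`: data frame with `rank`,
#'   `otu_id`, `explained`; attribute `metric`.
#' @export
contribution_curve <- function(t, ranked,
                               metric = c("bray_curtis", "weighted_unifrac"),
                               tree = NULL, max_rank = length(ranked)) {
  metric <- match.arg(metric)
  validate_count_table(t, integer = FALSE)
  if (!all(ranked %in% rownames(t))) {
    stop("ranked OTUs absent from table: ",
         paste(setdiff(ranked, rownames(t)), collapse = ", "), call. = FALSE)
  }
  if (length(ranked) == 0L) stop("empty ranking", call. = FALSE)
  n <- ncol(t)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  max_rank <- min(max_rank, length(ranked))
  totals <- colSums(t)

  if (metric == "bray_curtis") {
    full_num <- pair_l1(t)           # sum over all OTUs of |x - y| per pair
    ok <- full_num > 0
    num <- numeric(length(full_num))
    explained <- numeric(max_rank)
    for (r in seq_len(max_rank)) {
      num <- num + pair_l1(t[ranked[r], ])
      explained[r] <- mean(num[ok] / full_num[ok])
    }
  } else {
    if (is.null(tree)) stop("weighted UniFrac requires a tree", call. = FALSE)
    validate_tree(tree)
    bm_full <- unifrac_branch_mass(t, tree, totals = totals)
    full_num <- pair_l1(bm_full$u)
    ok <- full_num > 0
    # incremental update: adding one OTU only changes branches on its
    # root path, so per pair we swap those branches' |difference| terms
    tre <- prune_tree(tree, intersect(tree$tip.label, rownames(t)))
    n_tip <- length(tre$tip.label)
    edge_of_child <- integer(n_tip + tre$Nnode)
    edge_of_child[tre$edge[, 2L]] <- seq_len(nrow(tre$edge))
    parent_of <- integer(n_tip + tre$Nnode)
    parent_of[tre$edge[, 2L]] <- tre$edge[, 1L]
    root <- n_tip + 1L
    u <- matrix(0, nrow(tre$edge), n)   # current branch-mass matrix
    num <- numeric(length(full_num))
    explained <- numeric(max_rank)
    for (r in seq_len(max_rank)) {
      tip <- match(ranked[r], tre$tip.label)
      p_leaf <- t[ranked[r], ] / pmax(totals, 1)
      node <- tip
      while (node != root) {
        e <- edge_of_child[node]
        old <- pair_l1(u[e, ])
        u[e, ] <- u[e, ] + tre$edge.length[e] * p_leaf
        num <- num + pair_l1(u[e, ]) - old
        node <- parent_of[node]
      }
      explained[r] <- mean(num[ok] / full_num[ok])
    }
  }
  structure(data.frame(rank = seq_len(max_rank),
                       otu_id = ranked[seq_len(max_rank)],
                       explained = explained,
                       stringsAsFactors = FALSE),
            class = c("contribution_curve", "data.frame"), metric = metric)
}

#' Mantel-style alternative contribution curve
#'
#' Correlation between the prefix-restricted and full distance matrices at
#' each evaluated rank; offered as a clearly labelled alternative reading of
#' "contribution to overall beta diversity", not the default.
#'
#' @inheritParams contribution_curve
#' @param ranks Ranks at which to evaluate (default: every rank).
#' @return A `contribution_curve` object with attribute `metric` suffixed
#'   `"_mantel"`.
#' @export
contribution_curve_mantel <- function(t, ranked,
                                      metric = c("bray_curtis", "weighted_unifrac"),
                                      tree = NULL,
                                      ranks = seq_along(ranked)) {
  metric <- match.arg(metric)
  full <- as.vector(beta_diversity(t, metric, tree = tree))
  zero_pad <- function(r) {
    sub <- t
    sub[setdiff(rownames(t), ranked[seq_len(r)]), ] <- 0
    sub
  }
  explained <- vapply(ranks, function(r) {
    dsub <- as.vector(suppressWarnings(beta_diversity(zero_pad(r), metric, tree = tree)))
    if (stats::sd(dsub) == 0) 0 else stats::cor(dsub, full)
  }, numeric(1))
  structure(data.frame(rank = ranks, otu_id = ranked[ranks],
                       explained = explained, stringsAsFactors = FALSE),
            class = c("contribution_curve", "data.frame"),
            metric = paste0(metric, "_mantel"))
}

#' Ranked-contribution definition of the core
#'
#' Scans the contribution curve for the last rank whose step still adds
#' materially to the explained beta diversity and keeps the ranked prefix up
#' to it. Two formalisations of the "final 2% increase" criterion are
#' offered:
#'
#' * `rule = "relative"` (default): the last rank r with
#'   explained(r) / explained(r-1) >= 1 + gain_threshold — the last step that
#'   raises the explained fraction by at least 2% of its running value, as in
#'   the ranked abundance-occupancy prioritisation procedure this follows.
#' * `rule = "absolute"`: the last rank r with
#'   explained(r) - explained(r-1) >= gain_threshold * final explained value.
#'   Note that no more than 1/gain_threshold ranks can ever satisfy this when
#'   gains shrink with rank, which caps the core size at 50 for the default
#'   threshold; it is kept for comparison.
#'
#' @param curve A [contribution_curve()].
#' @param gain_threshold Gain threshold (default 0.02).
#' @param rule `"relative"` or `"absolute"`.
#' @return A `core_set` with method `"RANKED_BC"` or `"RANKED_WUF"`, carrying
#'   the stopping parameters and the curve.
#' @export
core_by_ranked_contribution <- function(curve, gain_threshold = 0.02,
                                        rule = c("relative", "absolute")) {
  rule <- match.arg(rule)
  stopifnot(gain_threshold > 0)
  expl <- curve$explained
  nr <- length(expl)
  gains <- diff(c(0, expl))
  hits <- if (rule == "relative") {
    prev <- c(NA, expl[-nr])
    which(!is.na(prev) & (prev <= 0 | (expl / prev - 1) >= gain_threshold - 1e-12))
  } else {
    which(gains >= gain_threshold * expl[nr] - 1e-12)
  }
  if (length(hits) == 0L) {
    warning("flat contribution curve; core reduced to the top-ranked OTU")
    last <- 1L
  } else {
    last <- max(hits)
  }
  metric <- attr(curve, "metric")
  method <- if (grepl("unifrac", metric)) "RANKED_WUF" else "RANKED_BC"
  members <- curve$otu_id[seq_len(last)]
  stats <- data.frame(otu_id = members, stringsAsFactors = FALSE)
  structure(list(method = method, members = members, stats = stats,
                 params = list(gain_threshold = gain_threshold, rule = rule,
                               metric = metric, last_rank = last),
                 curve = curve),
            class = "core_set")
}

#' Consensus of several core definitions
#'
#' Exact set intersection of the member lists; order-independent and
#' idempotent. Member statistics are merged from the first input that carries
#' them, and members are ordered by descending mean relative abundance where
#' available.
#'
#' @param cores List of `core_set` objects (at least two).
#' @return A `core_set` with method `"CONSENSUS"`.
#' @export
consensus_core <- function(cores) {
  stopifnot(is.list(cores), length(cores) >= 2L)
  members <- Reduce(intersect, lapply(cores, function(cs) cs$members))
  if (length(members) == 0L) warning("consensus core is empty")
  stats <- NULL
  for (cs in cores) {
    if (!is.null(cs$stats$mra)) { stats <- cs$stats; break }
  }
  if (!is.null(stats)) {
    stats <- stats[match(members, stats$otu_id), , drop = FALSE]
    members <- members[order(-stats$mra, members)]
    stats <- stats[match(members, stats$otu_id), , drop = FALSE]
  } else {
    stats <- data.frame(otu_id = members, stringsAsFactors = FALSE)
  }
  structure(list(method = "CONSENSUS", members = members, stats = stats,
                 params = list(inputs = vapply(cores, `[[`, "", "method"))),
            class = "core_set")
}

#' One-call core detection
#'
#' Runs the full core-detection workflow: abundance-occupancy statistics on
#' the rarefied table, the threshold core, occupancy ranking, contribution
#' curves under Bray-Curtis and weighted UniFrac, the two ranked cores, and
#' their consensus.
#'
#' @inheritParams abundance_occupancy
#' @param tree Rooted tree over the OTU ids (for weighted UniFrac).
#' @param gain_threshold Stopping threshold for the ranked cores.
#' @param rule Stopping rule, see [core_by_ranked_contribution()].
#' @param max_rank Truncate contribution curves at this rank (default: all
#'   OTUs); ranks beyond it can never enter a ranked core.
#' @return List with elements `ao`, `threshold`, `ranked`, `curve_bc`,
#'   `curve_wuf`, `core_bc`, `core_wuf`, `consensus`.
#' @export
define_core <- function(t, meta, tree, rarefy_depth = 5000, seed = NULL,
                        gain_threshold = 0.02, rule = "relative",
                        max_rank = nrow(t)) {
  ao <- abundance_occupancy(t, meta, rarefy_depth = rarefy_depth, seed = seed)
  r <- attr(ao, "rarefied")
  thr <- core_by_threshold(ao)
  ranked <- rank_by_occupancy(ao)
  curve_bc <- contribution_curve(r, ranked, "bray_curtis", max_rank = max_rank)
  curve_wuf <- contribution_curve(r, ranked, "weighted_unifrac", tree = tree,
                                  max_rank = max_rank)
  core_bc <- core_by_ranked_contribution(curve_bc, gain_threshold, rule)
  core_wuf <- core_by_ranked_contribution(curve_wuf, gain_threshold, rule)
  cons <- consensus_core(list(thr, core_bc, core_wuf))
  list(ao = ao, threshold = thr, ranked = ranked,
       curve_bc = curve_bc, curve_wuf = curve_wuf,
       core_bc = core_bc, core_wuf = core_wuf, consensus = cons)
}

#' Mean relative abundance of core OTUs across sub-groups
#'
#' For each level of each requested category, the mean relative abundance of
#' every core OTU over the samples at that level (samples with `unknown`
#' values are excluded from that category only; empty levels are dropped).
#' The attribute `cumulative` carries the per-level cumulative relative
#' abundance of the whole core.
#'
#' @param t Count matrix.
#' @param meta Harmonised metadata.
#' @param core A `core_set` (or character vector of OTU ids).
#' @param categories Metadata columns to profile.
#' @return Matrix core OTU x "category:level" of mean relative abundances.
#' @export
subgroup_profiles <- function(t, meta, core,
                              categories = c("location", "region", "sample_type",
                                             "gender", "age_group", "smoking",
                                             "drinking")) {
  meta <- align_metadata(t, meta)
  members <- if (inherits(core, "core_set")) core$members else core
  members <- intersect(members, rownames(t))
  if (!length(members)) stop("no core OTUs present in table", call. = FALSE)
  rel <- tss(t)
  cols <- list(); cum <- numeric(0)
  for (cat in categories) {
    if (is.null(meta[[cat]])) stop("no such category: ", cat, call. = FALSE)
    keep <- !(meta[[cat]] %in% "unknown")
    for (lv in unique(meta[[cat]][keep])) {
      idx <- which(meta[[cat]] == lv)
      if (!length(idx)) next
      m <- rowMeans(rel[members, idx, drop = FALSE])
      cols[[paste(cat, lv, sep = ":")]] <- m
      cum[paste(cat, lv, sep = ":")] <- sum(m)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- members
  attr(out, "cumulative") <- cum
  out
}

#' Cluster core OTUs by their sub-group distribution pattern
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' log10-transformed sub-group profiles, cut at `k` groups.
#'
#' @param profiles Matrix from [subgroup_profiles()].
#' @param k Number of clusters (default 4).
#' @param eps Pseudo-abundance added before the log (default 1e-6).
#' @return Named integer vector of cluster labels.
#' @export
cluster_profiles <- function(profiles, k = 4, eps = 1e-6) {
  if (k > nrow(profiles) - 1L) stop("k must be at most n - 1", call. = FALSE)
  hc <- stats::hclust(stats::dist(log10(profiles + eps)), method = "ward.D2")
  stats::cutree(hc, k = k)
}
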