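# Beta diversity distance matrices.

dist_attrs <- function(d, metric) {
  attr(d, "metric") <- metric
  d
}

check_beta_input <- function(t) {
  validate_count_table(t, integer = FALSE)
  if (ncol(t) < 2L) stop("need at least two samples", call. = FALSE)
  empty <- colSums(t) == 0
  if (sum(empty) >= 2L) {
    stop("dissimilarity undefined for pairs of all-zero samples: ",
         paste(colnames(t)[empty], collapse = ", "), call. = FALSE)
  }
  invisible(t)
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over features.
#'
#' @param t Abundance matrix (OTUs x samples), counts or relative abundances.
#' @return A `dist` object labelled with sample ids, attribute
#'   `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(t) {
  check_beta_input(t)
  dist_attrs(vegan::vegdist(t(t), method = "bray"), "bray_curtis")
}

#' Euclidean distance between samples
#'
#' @inheritParams bray_curtis
#' @return A `dist` object, attribute `metric = "euclidean"`.
#' @export
euclidean_dist <- function(t) {
  validate_count_table(t, integer = FALSE)
  if (ncol(t) < 2L) stop("need at least two samples", call. = FALSE)
  dist_attrs(stats::dist(t(t), method = "euclidean"), "euclidean")
}

# Per-branch descendant-proportion matrix for a set of samples.
# Returns list(u = branch-length-weighted proportions (edges x samples),
#              s = per-sample total branch mass sum(b * P)).
unifrac_branch_mass <- function(t, tree, totals = colSums(t)) {
  present <- rownames(t)[rowSums(t) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    stop("OTUs absent from tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tree <- prune_tree(tree, intersect(tree$tip.label, rownames(t)))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # proportions of each sample's reads at each tip (full-sample totals)
  p_tip <- t[tree$tip.label, , drop = FALSE]
  p_tip <- sweep(p_tip, 2L, pmax(totals, 1), "/")
  node_p <- matrix(0, n_node, ncol(t))
  node_p[seq_len(n_tip), ] <- p_tip
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (k in seq_len(nrow(edge))) {
    node_p[edge[k, 1L], ] <- node_p[edge[k, 1L], ] + node_p[edge[k, 2L], ]
  }
  child <- tree$edge[, 2L]
  u <- node_p[child, , drop = FALSE] * tree$edge.length
  colnames(u) <- colnames(t)
  list(u = u, s = colSums(u))
}

#' Weighted UniFrac distance between samples
#'
#' Raw form: sum over branches of b_j |P_j(A) - P_j(B)|, where P_j is the
#' proportion of a sample's reads descending from branch j (samples are
#' converted to proportions internally). The normalised form divides by
#' sum_j b_j (P_j(A) + P_j(B)) and is bounded by 1; it is the default, for
#' use alongside Bray-Curtis. Implemented with a single post-order traversal
#' computing subtree proportions once per sample.
#'
#' @param t Count matrix; every OTU with non-zero counts must be a tree leaf.
#' @param tree Rooted `phylo` tree with branch lengths over the OTU ids.
#' @param normalised Divide by the total abundance-weighted branch mass of
#'   each pair (default `TRUE`).
#' @return A `dist` object, attribute `metric = "weighted_unifrac"`.
#' @export
weighted_unifrac <- function(t, tree, normalised = TRUE) {
  check_beta_input(t)
  validate_tree(tree)
  bm <- unifrac_branch_mass(t, tree)
  raw <- stats::dist(t(bm$u), method = "manhattan")
  if (normalised) {
    n <- ncol(t)
    ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
    denom <- bm$s[ij[, 2L]] + bm$s[ij[, 1L]]
    if (any(denom == 0)) {
      stop("weighted UniFrac undefined for pairs of all-zero samples", call. = FALSE)
    }
    raw[] <- as.vector(raw) / denom
  }
  dist_attrs(raw, "weighted_unifrac")
}

#' Compute a distance matrix by metric name
#'
#' @param t Abundance matrix.
#' @param metric `"bray_curtis"`, `"euclidean"` or `"weighted_unifrac"`.
#' @param tree Required for weighted UniFrac.
#' @param ... Passed to the metric function.
#' @return A `dist` object.
#' @export
beta_diversity <- function(t, metric = c("bray_curtis", "euclidean",
                                         "weighted_unifrac"),
                           tree = NULL, ...) {
  metric <- match.arg(metric)
  switch(metric,
         bray_curtis = bray_curtis(t),
         euclidean = euclidean_dist(t),
         weighted_unifrac = {
           if (is.null(tree)) stop("weighted UniFrac requires a tree", call. = FALSE)
           weighted_unifrac(t, tree, ...)
         })
}
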