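# Spearman co-occurrence network and hub-taxon identification.

#' Build a Spearman co-occurrence network
#'
#' Pairwise Spearman correlations (midranks for ties) between OTU relative
#' abundance profiles; p-values from the t-distribution approximation on
#' n - 2 degrees of freedom. An edge is kept when |rho| exceeds `rho_min`
#' AND p falls below `p_max` (the conventional robustness criterion; raw
#' p-values by default, Benjamini-Hochberg adjustment optionally). Isolated
#' OTUs keep a row in the node table but carry no edges. OTUs with constant
#' abundance have undefined rank correlation and are excluded with a warning.
#'
#' @param relab Relative-abundance matrix (OTUs x samples), >= 5 samples.
#' @param rho_min Absolute correlation threshold (default 0.5, strict).
#' @param p_max P-value threshold (default 0.01, strict).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param core Optional character vector of core OTU ids, recorded as a node
#'   attribute.
#' @return Object of class `cooccurrence_network`: list with `graph` (igraph,
#'   undirected, no self-loops), `edges` (data frame `source`, `target`,
#'   `rho`, `p_value`, `sign`), `nodes` (data frame `otu_id`, `mra`,
#'   `is_core`, `degree`).
#' @export
build_network <- function(relab, rho_min = 0.5, p_max = 0.01,
                          p_adjust = c("none", "BH"), core = NULL) {
  p_adjust <- match.arg(p_adjust)
  validate_count_table(relab, integer = FALSE)
  n <- ncol(relab)
  if (n < 5L) stop("need at least 5 samples for the p-value approximation",
                   call. = FALSE)
  constant <- apply(relab, 1L, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warning(sum(constant), " constant-abundance OTU(s) excluded: rho undefined")
    relab <- relab[!constant, , drop = FALSE]
  }
  rho <- stats::cor(t(relab), method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  ut <- upper.tri(rho)
  if (p_adjust == "BH") p[ut] <- stats::p.adjust(p[ut], method = "BH")
  sel <- ut & abs(rho) > rho_min & p < p_max
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(
    source = rownames(relab)[idx[, 1L]],
    target = rownames(relab)[idx[, 2L]],
    rho = rho[sel], p_value = p[sel],
    sign = ifelse(rho[sel] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = rownames(relab), stringsAsFactors = FALSE))
  igraph::E(g)$rho <- edges$rho
  igraph::E(g)$p_value <- edges$p_value
  nodes <- data.frame(
    otu_id = rownames(relab),
    mra = rowMeans(relab),
    is_core = rownames(relab) %in% (core %||% character(0)),
    degree = as.integer(igraph::degree(g)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(graph = g, edges = edges, nodes = nodes,
                 params = list(rho_min = rho_min, p_max = p_max,
                               p_adjust = p_adjust, n_samples = n)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$degree > 0), "connected ),", nrow(x$edges), "edges\n")
  cat("Thresholds: |rho| >", x$params$rho_min, ", p <", x$params$p_max, "\n")
  invisible(x)
}

#' Node centralities
#'
#' Degree and exact shortest-path betweenness on the unweighted graph.
#'
#' @param net A `cooccurrence_network`.
#' @return Data frame `otu_id`, `degree`, `betweenness`.
#' @export
centralities <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  data.frame(
    otu_id = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    betweenness = igraph::betweenness(g, directed = FALSE, weights = NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Detect hub taxa
#'
#' Hubs are nodes lying jointly in the upper tail of both degree and
#' betweenness: degree and betweenness at or above their `quantile` across
#' connected nodes, with strictly positive betweenness (a hub must broker at
#' least one shortest path, so fully cliqued graphs yield none).
#'
#' @param net A `cooccurrence_network`.
#' @param quantile Upper-tail quantile (default 0.95).
#' @return Character vector of hub OTU ids.
#' @export
detect_hubs <- function(net, quantile = 0.95) {
  cen <- centralities(net)
  cen <- cen[cen$degree > 0, , drop = FALSE]
  if (nrow(cen) == 0L) return(character(0))
  qd <- stats::quantile(cen$degree, quantile, names = FALSE)
  qb <- stats::quantile(cen$betweenness, quantile, names = FALSE)
  cen$otu_id[cen$degree >= qd & cen$betweenness >= qb & cen$betweenness > 0]
}

#' Write network tables
#'
#' Edge list and node attribute TSVs importable by standard graph tools.
#'
#' @param net A `cooccurrence_network`.
#' @param edge_path,node_path Output paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}
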