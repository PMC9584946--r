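# Spearman co-occurrence network and hubs.

test_that("perfectly monotone profiles give unit-magnitude edges", {
  set.seed(1)
  base <- matrix(runif(4 * 12), 4, 12,
                 dimnames = list(paste0("o", 1:4), paste0("s", 1:12)))
  base[2, ] <- base[1, ]^2          # monotone increasing transform
  base[3, ] <- 1 - base[1, ] / 2    # monotone decreasing
  net <- build_network(base, rho_min = 0.5, p_max = 0.01)
  e12 <- net$edges[net$edges$source == "o1" & net$edges$target == "o2", ]
  e13 <- net$edges[net$edges$source == "o1" & net$edges$target == "o3", ]
  expect_equal(e12$rho, 1)
  expect_equal(e12$sign, "positive")
  expect_equal(e13$rho, -1)
  expect_equal(e13$sign, "negative")
})

test_that("rho matches the rank-then-Pearson oracle including ties", {
  set.seed(2)
  m <- matrix(sample(0:5, 6 * 10, TRUE), 6, 10,
              dimnames = list(paste0("o", 1:6), paste0("s", 1:10)))
  m <- m[apply(m, 1, function(x) length(unique(x)) > 1), ]
  net <- build_network(m, rho_min = -1e-9, p_max = 1.1)  # keep all edges
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    expect_equal(e$rho, spearman_oracle(m[e$source, ], m[e$target, ]),
                 tolerance = 1e-12)
  }
})

test_that("input validation catches small n and constant OTUs", {
  m <- make_counts(4, 4, seed = 3)
  expect_error(build_network(tss(m)), "at least 5")
  m2 <- make_counts(4, 8, seed = 4)
  m2[1, ] <- 5L
  expect_warning(net <- build_network(m2, rho_min = 0.2, p_max = 0.5),
                 "constant")
  expect_false("o01" %in% net$nodes$otu_id)
})

test_that("edge set is invariant to sample and OTU order", {
  m <- make_counts(8, 10, seed = 5)
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$source, e$target), pmax(e$source, e$target),
               round(e$rho, 10)))
  }
  n1 <- build_network(m, rho_min = 0.3, p_max = 0.2)
  n2 <- build_network(m[sample(nrow(m)), sample(ncol(m))],
                      rho_min = 0.3, p_max = 0.2)
  expect_equal(key(n1), key(n2))
})

test_that("centralities and hub detection follow graph structure", {
  mk_net <- function(edges, nodes) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    structure(list(graph = g, edges = edges,
                   nodes = data.frame(otu_id = nodes,
                                      degree = as.integer(igraph::degree(g)))),
              class = "cooccurrence_network")
  }
  # path of 5: middle node brokers 4 pairs
  path <- mk_net(data.frame(source = c("A", "B", "C", "D"),
                            target = c("B", "C", "D", "E")), LETTERS[1:5])
  cen <- centralities(path)
  expect_equal(cen$betweenness[cen$otu_id == "C"], 4)
  expect_equal(cen$betweenness[cen$otu_id %in% c("A", "E")], c(0, 0))

  # star: centre is the sole hub
  star <- mk_net(data.frame(source = "hub", target = paste0("leaf", 1:6)),
                 c("hub", paste0("leaf", 1:6)))
  expect_equal(detect_hubs(star, quantile = 0.9), "hub")

  # complete graph: all betweenness zero, joint criterion yields no hub
  cmb <- t(combn(LETTERS[1:5], 2))
  complete <- mk_net(data.frame(source = cmb[, 1], target = cmb[, 2]),
                     LETTERS[1:5])
  expect_true(all(centralities(complete)$betweenness == 0))
  expect_length(detect_hubs(complete, quantile = 0.5), 0)
})

test_that("betweenness agrees with exhaustive path counting", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 7
    adj <- matrix(0, n, n)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- sample(nrow(pairs), 9)
    for (k in on) adj[pairs[k, 1], pairs[k, 2]] <- adj[pairs[k, 2], pairs[k, 1]] <- 1
    nodes <- paste0("n", 1:n)
    edges <- data.frame(source = nodes[pairs[on, 1]], target = nodes[pairs[on, 2]])
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    net <- structure(list(graph = g), class = "cooccurrence_network")
    expect_equal(centralities(net)$betweenness, betweenness_oracle(adj),
                 tolerance = 1e-12)
  }
})

test_that("independent profiles produce essentially no spurious edges", {
  set.seed(7)
  n_edges <- 0; n_pairs <- 0
  for (rep in 1:40) {
    m <- matrix(rlnorm(30 * 60), 30, 60,
                dimnames = list(paste0("o", 1:30), paste0("s", 1:60)))
    net <- build_network(tss(m), rho_min = 0.5, p_max = 0.01)
    n_edges <- n_edges + nrow(net$edges)
    n_pairs <- n_pairs + choose(30, 2)
  }
  expect_lt(n_edges / n_pairs, 0.005)
})

test_that("network tables serialise to importable TSVs", {
  m <- make_counts(8, 10, seed = 9)
  net <- build_network(m, rho_min = 0.3, p_max = 0.3)
  ef <- tempfile(); nf <- tempfile()
  write_network(net, ef, nf)
  edges <- utils::read.delim(ef)
  nodes <- utils::read.delim(nf)
  expect_equal(nrow(edges), nrow(net$edges))
  expect_setequal(nodes$otu_id, net$nodes$otu_id)
})

test_that("hubs always lie among connected nodes", {
  m <- make_counts(12, 15, seed = 8)
  net <- build_network(m, rho_min = 0.3, p_max = 0.3)
  hubs <- detect_hubs(net, quantile = 0.8)
  connected <- net$nodes$otu_id[net$nodes$degree > 0]
  expect_true(all(hubs %in% connected))
})
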