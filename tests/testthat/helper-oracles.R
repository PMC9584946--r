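# Shared fixtures and independent brute-force oracles used across tests.

# random Poisson count matrix with dimnames
make_counts <- function(n_otu, n_samp, seed = 1, lambda = 20) {
  set.seed(seed)
  matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp,
         dimnames = list(sprintf("o%02d", seq_len(n_otu)),
                         sprintf("s%02d", seq_len(n_samp))))
}

# -- naive double-loop distance oracles ---------------------------------------

bc_oracle <- function(t) {
  n <- ncol(t)
  d <- matrix(0, n, n, dimnames = list(colnames(t), colnames(t)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(t[, i] - t[, j])) / sum(t[, i] + t[, j])
  }
  d
}

euc_oracle <- function(t) {
  n <- ncol(t)
  d <- matrix(0, n, n, dimnames = list(colnames(t), colnames(t)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((t[, i] - t[, j])^2))
  }
  d
}

# Spearman rho via explicit midranks + Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Wilcoxon rank-sum W (midranks), as sum of group-A ranks minus nA(nA+1)/2
wilcox_oracle <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact betweenness by enumerating all shortest paths (small graphs only)
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(i, j) {
    # BFS shortest-path counting through each vertex
    dist <- rep(Inf, n); dist[i] <- 0
    nsp <- rep(0, n); nsp[i] <- 1
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) nsp[w] <- nsp[w] + nsp[v]
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, nsp = nsp)
  }
  btw <- rep(0, n)
  for (i in seq_len(n - 1)) {
    fwd <- paths_between(i, 0)
    for (j in seq((i + 1), n)) {
      if (is.infinite(fwd$dist[j]) || fwd$nsp[j] == 0) next
      bwd <- paths_between(j, 0)
      for (v in seq_len(n)) {
        if (v == i || v == j) next
        if (fwd$dist[v] + bwd$dist[v] == fwd$dist[j]) {
          btw[v] <- btw[v] + fwd$nsp[v] * bwd$nsp[v] / fwd$nsp[j]
        }
      }
    }
  }
  btw
}

# small synthetic world reused by several module tests
small_world <- function(seed = 3) {
  sp <- synthetic_spec(n_studies = 6, samples_per_study = c(20, 20),
                       n_otus = 120, n_core = 15, core_floor_share = 0.006)
  generate_dataset(sp, seed = seed)
}
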