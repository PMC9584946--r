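# Random-forest association and rank-sum differential abundance.

test_that("rf_grid covers the requested crossings and flags bad categories", {
  d <- small_world(seed = 3)
  rel <- tss(d$counts)
  g <- rf_grid(rel, d$metadata, categories = c("location", "gender"),
               normalisations = c("tss"), ntree = 100, seed = 5)
  expect_s3_class(g, "rf_grid")
  expect_equal(nrow(g), 2L)
  expect_true(all(g$oob_error >= 0 & g$oob_error <= 1))

  md <- d$metadata; md$mono <- "one"
  expect_error(rf_train(rel, md, "mono", ntree = 50), "two informative levels")
})

test_that("perfectly separable groups give near-zero OOB error", {
  set.seed(4)
  a <- matrix(rpois(20 * 15, c(rep(40, 10), rep(0, 10))), 20, 15)
  b <- matrix(rpois(20 * 15, c(rep(0, 10), rep(40, 10))), 20, 15)
  m <- cbind(a, b)
  dimnames(m) <- list(paste0("o", 1:20), paste0("s", 1:30))
  md <- data.frame(sample_id = colnames(m), study = "S",
                   grp = rep(c("left", "right"), each = 15))
  fit <- rf_train(tss(m), md, "grp", ntree = 300, seed = 6)
  expect_lt(fit$oob_error, 0.05)
})

test_that("permuted labels drive OOB error to the majority-class rate", {
  d <- small_world(seed = 5)
  rel <- tss(d$counts)
  md <- d$metadata
  set.seed(10)
  md$shuffled <- sample(md$location)
  fit <- rf_train(rel, md, "shuffled", ntree = 300, seed = 11)
  base_rate <- 1 - max(table(md$shuffled) / nrow(md))
  se <- sqrt(base_rate * (1 - base_rate) / fit$n_samples)
  expect_lt(abs(fit$oob_error - base_rate), 4 * se)
})

test_that("planted informative features are recovered by the CV selection", {
  set.seed(12)
  n_samp <- 60
  noise <- matrix(rnorm(100 * n_samp), 100, n_samp)
  grp <- rep(c("a", "b"), each = n_samp / 2)
  informative <- matrix(rnorm(5 * n_samp, mean = ifelse(grp == "a", 0, 2)),
                        5, n_samp, byrow = FALSE)
  for (i in 1:5) informative[i, ] <- rnorm(n_samp, ifelse(grp == "a", 0, 2))
  m <- rbind(informative, noise)
  m <- m - min(m)  # keep the table non-negative
  dimnames(m) <- list(c(paste0("inf", 1:5), paste0("noise", 1:100)),
                      paste0("s", 1:n_samp))
  md <- data.frame(sample_id = colnames(m), study = "S", grp = grp)
  hits <- 0
  for (seed in 1:3) {
    sel <- important_features(m, md, "grp", repeats = 2, ntree = 200,
                              seed = seed)$selected
    hits <- hits + sum(paste0("inf", 1:5) %in% sel)
  }
  expect_gte(hits / 3, 4)  # >= 4 of 5 informative features on average
})

test_that("pure-noise features never justify the full feature set", {
  set.seed(13)
  m <- matrix(abs(rnorm(40 * 40)), 40, 40,
              dimnames = list(paste0("o", 1:40), paste0("s", 1:40)))
  md <- data.frame(sample_id = colnames(m), study = "S",
                   grp = rep(c("a", "b"), 20))
  sel <- important_features(m, md, "grp", repeats = 2, ntree = 150, seed = 14)
  # no informative features: the curve hovers at chance and the rule stops
  # well short of the full set
  expect_lt(length(sel$selected), nrow(m))
  at_sel <- sel$cv_curve$mean_error[sel$cv_curve$n_features ==
                                      length(sel$selected)]
  expect_lt(abs(at_sel - 0.5), 0.2)
})

test_that("cross-validated selection is reproducible under a fixed seed", {
  d <- small_world(seed = 3)
  rel <- tss(d$counts)
  s1 <- important_features(rel, d$metadata, "location", repeats = 1,
                           ntree = 100, seed = 21)
  s2 <- important_features(rel, d$metadata, "location", repeats = 1,
                           ntree = 100, seed = 21)
  expect_identical(s1$cv_curve, s2$cv_curve)
  expect_identical(s1$selected, s2$selected)
})

test_that("rank-sum differential abundance recovers a planted 4x shift", {
  set.seed(15)
  n <- 10
  base <- matrix(rpois(6 * 2 * n, 50) + 1L, 6, 2 * n,
                 dimnames = list(paste0("o", 1:6), paste0("s", 1:(2 * n))))
  grp <- rep(c("hi", "lo"), each = n)
  # quadruple one taxon in group hi without altering the others' totals
  base["o1", grp == "hi"] <- base["o1", grp == "hi"] * 40L
  md <- data.frame(sample_id = colnames(base), study = "S", grp = grp)
  res <- differential_rank_sum(base, md, "grp", c("hi", "lo"))
  r1 <- res[res$taxon == "o1", ]
  expect_lt(r1$q_value, 0.05)
  expect_gt(r1$log2_fold, 2)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # identical groups: no discoveries
  same <- base[, c(which(grp == "hi"), which(grp == "hi"))]
  colnames(same) <- paste0("s", seq_len(ncol(same)))
  md2 <- data.frame(sample_id = colnames(same), study = "S",
                    grp = rep(c("x", "y"), each = n))
  res2 <- differential_rank_sum(same, md2, "grp", c("x", "y"))
  expect_true(all(res2$q_value > 0.9))
})

test_that("reported statistics match the midrank oracle and hand-stepped BH", {
  set.seed(16)
  m <- matrix(rpois(8 * 14, 15), 8, 14,
              dimnames = list(paste0("o", 1:8), paste0("s", 1:14)))
  md <- data.frame(sample_id = colnames(m), study = "S",
                   grp = rep(c("a", "b"), each = 7))
  res <- differential_rank_sum(m, md, "grp", c("a", "b"))
  rel <- tss(m)
  for (k in seq_len(nrow(res))) {
    tx <- res$taxon[k]
    expect_equal(res$statistic[k],
                 wilcox_oracle(rel[tx, 1:7], rel[tx, 8:14]), tolerance = 1e-12)
  }
  # hand BH step-up on the reported p-values reproduces the q-values
  p <- res$p_value; n <- length(p)
  o <- order(p)
  q_hand <- numeric(n)
  q_hand[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(res$q_value, pmin(q_hand, 1), tolerance = 1e-12)
  # q respects the p ordering
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
})
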