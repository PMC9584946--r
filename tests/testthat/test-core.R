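# Core-microbiome detection machinery.

# hand-built abundance-occupancy table for threshold tests
make_ao <- function(n, seed) {
  set.seed(seed)
  structure(data.frame(
    otu_id = sprintf("o%03d", seq_len(n)),
    mra = runif(n, 0, 0.01),
    occ_samples = runif(n),
    mean_study_occ = runif(n),
    n_studies_full = sample(0:15, n, TRUE),
    stringsAsFactors = FALSE
  ), class = c("abundance_occupancy", "data.frame"))
}

test_that("abundance-occupancy statistics count detection per study", {
  m <- rbind(everywhere = c(5L, 5L, 5L, 5L),
             a_only = c(3L, 2L, 1L, 0L),
             nowhere = c(0L, 0L, 0L, 0L))
  colnames(m) <- paste0("s", 1:4)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     study = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  ao <- abundance_occupancy(m, meta, rarefy_depth = NULL)
  expect_equal(ao$occ_samples[ao$otu_id == "everywhere"], 1)
  expect_equal(ao$n_studies_full[ao$otu_id == "everywhere"], 2)
  expect_equal(ao$mra[ao$otu_id == "nowhere"], 0)
  expect_equal(ao$occ_samples[ao$otu_id == "nowhere"], 0)
  occ <- attr(ao, "occ_by_study")
  expect_equal(unname(occ["a_only", ]), c(1, 0.5))
  expect_equal(ao$n_studies_full[ao$otu_id == "a_only"], 1)
})

test_that("threshold core applies the strict joint rule", {
  ao <- make_ao(3, seed = 1)
  ao$mra <- c(0.002, 0.002, 0.0005)
  ao$occ_samples <- c(0.80, 0.50, 0.99)
  ao$n_studies_full <- c(0, 11, 15)
  cs <- core_by_threshold(ao)
  expect_setequal(cs$members, c("o001", "o002"))  # o003 fails the MRA clause
})

test_that("threshold core equals brute-force filtering on random tables", {
  for (seed in 1:25) {
    ao <- make_ao(40, seed = seed)
    cs <- core_by_threshold(ao)
    brute <- ao$otu_id[vapply(seq_len(nrow(ao)), function(i) {
      ao$mra[i] > 0.001 &&
        (ao$occ_samples[i] > 0.75 || ao$n_studies_full[i] > 10)
    }, logical(1))]
    expect_setequal(cs$members, brute)
    expect_false(is.unsorted(rev(cs$stats$mra)))  # descending MRA order
  }
})

test_that("occupancy ranking uses mean study occupancy with MRA tie-break", {
  ao <- make_ao(3, seed = 2)
  ao$mean_study_occ <- c(1.0, 0.7, 0.7)
  ao$mra <- c(0.005, 0.01, 0.02)
  expect_equal(rank_by_occupancy(ao), c("o001", "o003", "o002"))

  tie <- make_ao(3, seed = 3)
  tie$mean_study_occ <- 0.5; tie$mra <- 0.001
  expect_equal(rank_by_occupancy(tie), sort(tie$otu_id))
  expect_equal(rank_by_occupancy(tie[1, , drop = FALSE]), "o001")
})

test_that("contribution curve reaches 1 and is monotone for Bray-Curtis", {
  # one OTU carries all between-sample differences
  m <- rbind(driver = c(0L, 100L, 50L), flat = c(50L, 50L, 50L))
  colnames(m) <- paste0("s", 1:3)
  cc <- contribution_curve(m, c("driver", "flat"), "bray_curtis")
  expect_equal(cc$explained[1], 1)
  expect_equal(cc$explained[2], 1)

  for (seed in 1:4) {
    r <- make_counts(12, 6, seed = seed)
    ranked <- sample(rownames(r))
    cc <- contribution_curve(r, ranked, "bray_curtis")
    expect_true(all(diff(cc$explained) >= -1e-12))
    expect_equal(cc$explained[12], 1, tolerance = 1e-12)
  }
})

test_that("weighted UniFrac contribution curve ends at 1", {
  r <- make_counts(8, 5, seed = 6)
  tree <- generate_tree(8, seed = 7, labels = rownames(r))
  cc <- contribution_curve(r, rownames(r), "weighted_unifrac", tree = tree)
  expect_equal(cc$explained[8], 1, tolerance = 1e-9)
  # prefix values agree with a from-scratch evaluation at each rank
  for (k in c(2, 5)) {
    sub <- r; sub[rownames(r)[-seq_len(k)], ] <- 0L
    bm_sub <- coremicro:::unifrac_branch_mass(sub, tree, totals = colSums(r))
    bm_full <- coremicro:::unifrac_branch_mass(r, tree, totals = colSums(r))
    direct <- mean(coremicro:::pair_l1(bm_sub$u) / coremicro:::pair_l1(bm_full$u))
    expect_equal(cc$explained[k], direct, tolerance = 1e-9)
  }
})

test_that("the Mantel-style alternative curve also saturates at 1", {
  m <- make_counts(8, 6, seed = 9) + 1L
  cm <- contribution_curve_mantel(m, rownames(m), "bray_curtis",
                                  ranks = c(2, 4, 8))
  expect_equal(cm$explained[3], 1, tolerance = 1e-9)
  expect_true(all(cm$explained >= -1 & cm$explained <= 1 + 1e-12))
  expect_equal(attr(cm, "metric"), "bray_curtis_mantel")
})

test_that("stopping rule finds the last informative rank", {
  mk_curve <- function(v) structure(
    data.frame(rank = seq_along(v), otu_id = paste0("o", seq_along(v)),
               explained = v),
    class = c("contribution_curve", "data.frame"), metric = "bray_curtis")

  v <- c(0.5, 0.9, 0.905, 0.906, 0.907, 0.91, 0.95, 1.0)
  v[7:8] <- c(0.912, 0.913)  # keep the tail below a 2% step
  expect_equal(core_by_ranked_contribution(mk_curve(v))$params$last_rank, 2)
  expect_equal(core_by_ranked_contribution(mk_curve(v), rule = "absolute")$params$last_rank, 2)

  lin <- mk_curve(seq(0.1, 1, by = 0.1))       # strictly linear: all kept
  expect_equal(core_by_ranked_contribution(lin)$params$last_rank, 10)
  expect_equal(core_by_ranked_contribution(lin, rule = "absolute")$params$last_rank, 10)

  flat <- mk_curve(rep(1, 5))
  expect_warning(cs <- core_by_ranked_contribution(flat), "flat")
  expect_equal(cs$members, "o1")
})

test_that("consensus is the exact intersection, order-independent", {
  mk <- function(members, method = "MRA_OCC") {
    structure(list(method = method, members = members,
                   stats = data.frame(otu_id = members), params = list()),
              class = "core_set")
  }
  a <- mk(c("A", "B", "C")); b <- mk(c("B", "C", "D")); c3 <- mk(c("B", "C"))
  expect_setequal(consensus_core(list(a, b, c3))$members, c("B", "C"))
  expect_setequal(consensus_core(list(c3, b, a))$members, c("B", "C"))
  expect_warning(out <- consensus_core(list(mk("A"), mk("Z"))), "empty")
  expect_length(out$members, 0)
  expect_setequal(consensus_core(list(a, a))$members, a$members)
})

test_that("sub-group profiles average within levels and cluster consistently", {
  d <- small_world(seed = 5)
  keep <- filter_samples_min_reads(d$counts, 2000)
  core <- d$truth$core
  prof <- subgroup_profiles(keep, d$metadata, core,
                            categories = c("location", "gender"))
  expect_equal(nrow(prof), length(intersect(core, rownames(keep))))
  expect_true(all(prof >= 0 & prof <= 1))
  cum <- attr(prof, "cumulative")
  expect_equal(unname(cum), unname(colSums(prof)), tolerance = 1e-12)

  # an OTU with equal abundance everywhere has a flat profile
  flat <- rbind(even = rep(100L, 8), rest = rep(300L, 8))
  colnames(flat) <- paste0("s", 1:8)
  md <- data.frame(sample_id = colnames(flat), study = "A",
                   location = rep(c("China", "Europe"), 4))
  pf <- subgroup_profiles(flat, md, c("even", "rest"), categories = "location")
  expect_equal(pf["even", 1], pf["even", 2])

  # identical profiles always co-cluster
  prof2 <- rbind(prof, twin = prof[1, ])
  for (k in 2:4) {
    cl <- cluster_profiles(prof2, k = k)
    expect_equal(unname(cl["twin"]), unname(cl[1]))
  }
})

test_that("planted core structure is recovered on a small world", {
  d <- small_world(seed = 3)
  ft <- filter_features(filter_samples_min_reads(d$counts), 11, 2)
  res <- define_core(ft, d$metadata, d$tree, rarefy_depth = 2000, seed = 2)
  # thresholds alone recover the planted core exactly here
  expect_setequal(res$threshold$members, d$truth$core)
  # consensus never admits a non-core taxon past the threshold filter
  expect_true(all(res$consensus$members %in% d$truth$core))
  expect_gte(length(res$consensus$members), 0.8 * length(d$truth$core))
})
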