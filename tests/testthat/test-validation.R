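# ZOTU affiliation, core prevalence and cross-cohort prediction.

test_that("affiliation identity is exact for self and counts substitutions", {
  refs <- random_sequences(paste0("core", 1:4), length = 100, seed = 1)
  self <- affiliate_zotus(refs, refs)
  expect_true(all(self$identity == 1))
  expect_equal(self$otu_id, names(refs))

  # 5 substitutions in 100 nt: identity 0.95, below the 0.97 threshold
  mut <- mutate_sequences(refs[1], divergence = 0.05, seed = 2)
  names(mut) <- "z1"
  a <- affiliate_zotus(mut, refs)
  expect_equal(a$identity, 0.95)
  expect_true(is.na(a$otu_id))

  expect_error(affiliate_zotus(refs, refs[0]), "empty reference")
})

test_that("ties are broken toward the lexicographically smallest reference", {
  base <- random_sequences("x", length = 100, seed = 3)[[1]]
  refs <- Biostrings::DNAStringSet(c(refB = as.character(base),
                                     refA = as.character(base)))
  z <- Biostrings::DNAStringSet(c(z1 = as.character(
    mutate_sequences(Biostrings::DNAStringSet(c(q = as.character(base))),
                     0.02, seed = 4)[[1]])))
  a <- affiliate_zotus(z, refs)
  expect_equal(a$otu_id, "refA")   # equidistant: smaller id wins
  expect_equal(a$identity, 0.98)
})

test_that("affiliation identity is symmetric", {
  s1 <- random_sequences("a", length = 120, seed = 5)
  s2 <- mutate_sequences(s1, 0.04, seed = 6); names(s2) <- "b"
  ab <- affiliate_zotus(s1, s2, identity_min = 0)
  ba <- affiliate_zotus(s2, s1, identity_min = 0)
  expect_equal(ab$identity, ba$identity, tolerance = 1e-12)
})

test_that("divergence thresholds behave as planted", {
  refs <- random_sequences(sprintf("core%02d", 1:20), length = 250, seed = 7)
  close <- mutate_sequences(refs, 0.01, seed = 8)
  names(close) <- sprintf("z%02d", 1:20)
  a1 <- affiliate_zotus(close, refs)
  expect_gte(mean(a1$otu_id == names(refs), na.rm = FALSE), 0.99)

  far <- mutate_sequences(refs, 0.06, seed = 9)
  names(far) <- sprintf("w%02d", 1:20)
  a6 <- affiliate_zotus(far, refs)
  expect_lte(mean(!is.na(a6$otu_id)), 0.05)
})

test_that("mutate_sequences applies the exact substitution count", {
  refs <- random_sequences("r", length = 250, seed = 10)
  expect_identical(as.character(mutate_sequences(refs, 0, seed = 1)),
                   as.character(refs))
  m <- mutate_sequences(refs, 0.03, seed = 11)
  diffs <- sum(strsplit(as.character(refs[[1]]), "")[[1]] !=
                 strsplit(as.character(m[[1]]), "")[[1]])
  expect_equal(diffs, round(0.03 * 250))  # exactly 8 substitutions
  expect_equal(1 - diffs / 250, 0.968)
})

test_that("core prevalence sums TSS mass over core rows", {
  m <- rbind(core1 = c(30L, 60L), core2 = c(45L, 15L), other = c(25L, 25L))
  colnames(m) <- c("s1", "s2")
  cp <- core_prevalence(m, c("core1", "core2"))
  expect_equal(unname(cp$per_sample), c(0.75, 0.75))
  expect_equal(cp$mean, 0.75)
  expect_equal(cp$sd, 0)

  expect_equal(core_prevalence(m, rownames(m))$per_sample,
               c(s1 = 1, s2 = 1))
  expect_error(core_prevalence(m, "absent"), "no core taxa")

  # invariant to pre-scaling of the input
  cp2 <- core_prevalence(tss(m), c("core1", "core2"))
  expect_equal(cp2$per_sample, cp$per_sample, tolerance = 1e-12)

  # an affiliation table routes through its assigned ZOTUs
  aff <- data.frame(zotu_id = c("core1", "core2", "other"),
                    otu_id = c("refA", "refB", NA), identity = c(1, 1, 0.5))
  expect_equal(core_prevalence(m, aff)$mean, 0.75)
})

test_that("transfer prediction reconciles feature spaces and degenerates sanely", {
  d <- small_world(seed = 3)
  fit <- rf_train(tss(d$counts), d$metadata, "smoking", ntree = 200, seed = 1)
  co <- generate_cohort(d, n_studies = 2, samples_per_study = c(12, 12), seed = 2)
  test_rel <- tss(co$counts)

  # missing features zero-filled, unseen features dropped
  test_sub <- test_rel[-(1:10), , drop = FALSE]
  extra <- rbind(test_sub, novel = rep(0.01, ncol(test_sub)))
  tp <- transfer_predict(fit, extra, labels = co$metadata$smoking)
  expect_equal(tp$n_features_zero_filled, 10)
  expect_true(all(tp$predicted %in% fit$levels))
  expect_false(is.na(tp$auc))

  one <- transfer_predict(fit, test_rel[, 1, drop = FALSE],
                          labels = co$metadata$smoking[1])
  expect_length(one$predicted, 1)
  expect_true(is.na(one$auc))   # AUC undefined for a single sample

  rownames(test_rel) <- paste0("alien", seq_len(nrow(test_rel)))
  expect_error(transfer_predict(fit, test_rel), "no feature overlap")
})

test_that("a same-world cohort is predictable, a permuted one is not", {
  d <- small_world(seed = 3)
  fit <- rf_train(tss(d$counts), d$metadata, "smoking", ntree = 300, seed = 4)
  co <- generate_cohort(d, n_studies = 3, samples_per_study = c(15, 15), seed = 5)
  tp <- transfer_predict(fit, tss(co$counts), labels = co$metadata$smoking)
  expect_gt(tp$accuracy, 0.8)
  expect_gt(tp$auc, 0.8)

  set.seed(6)
  null_auc <- replicate(5, {
    transfer_predict(fit, tss(co$counts),
                     labels = sample(co$metadata$smoking))$auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 3 * stats::sd(null_auc) / sqrt(5) + 0.1)
})
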