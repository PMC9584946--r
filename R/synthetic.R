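# Synthetic multi-study 16S count data with planted ground truth.
#
# The generator emulates the statistical structure a multi-study saliva
# meta-analysis has to cope with: a high-occupancy core carrying most reads,
# a dominant per-study composition bias, weaker host-factor effects on taxon
# subsets, a hypervariable-region detection artefact for non-core taxa,
# lognormal library sizes, and Dirichlet-multinomial overdispersion.
# Per-taxon host "carriage" probabilities (core near 1, non-core low) are
# what give occupancy its realistic sample-to-sample noise independent of
# abundance.

#' Specification of a synthetic multi-study dataset
#'
#' Defaults describe the reference condition used throughout the test suite:
#' 20 studies of 40 samples, 900 OTUs with a 68-member planted core at 72%
#' expected cumulative relative abundance, a dominant study effect and weaker
#' host-factor effects.
#'
#' @param n_studies Number of studies.
#' @param samples_per_study Range (min, max) of samples drawn per study.
#' @param n_otus,n_core Total and core taxon counts.
#' @param core_mra_target Expected cumulative relative abundance of the core.
#' @param core_abund_sd,noncore_abund_sd Lognormal sd of base shares.
#' @param core_floor_share Minimum base share of any core taxon (keeps every
#'   core member comfortably detectable and above the 0.1% abundance
#'   threshold).
#' @param study_effect_sd Lognormal sd of the per-study, per-taxon
#'   composition bias.
#' @param core_bias_trunc Cap (in sd units) on the study bias of core taxa,
#'   protecting their detectability in every study.
#' @param region_dropout Probability that a non-core taxon is undetectable
#'   under one hypervariable-region label.
#' @param core_carriage,noncore_carriage Ranges of the per-taxon host
#'   carriage probability.
#' @param category_effects List of planted host-factor effects; each element
#'   is `list(category=, level=, n_core=, n_noncore=, log2fc=)`, applied
#'   multiplicatively to the affected taxa in samples at that level.
#' @param dm_concentration Dirichlet-multinomial concentration (larger =
#'   closer to multinomial).
#' @param depth_lognormal `c(meanlog, sdlog)` of library sizes.
#' @param seed Default seed for [generate_dataset()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_studies = 20,
                           samples_per_study = c(40, 40),
                           n_otus = 900, n_core = 68,
                           core_mra_target = 0.72,
                           core_abund_sd = 0.6,
                           noncore_abund_sd = 1.1,
                           core_floor_share = 0.002,
                           study_effect_sd = 1.0,
                           core_bias_trunc = 1.0,
                           region_dropout = 0.3,
                           core_carriage = c(0.93, 0.999),
                           noncore_carriage = c(0.15, 0.65),
                           category_effects = list(
                             location = list(category = "location", level = "China",
                                             n_core = 28, n_noncore = 10, log2fc = 2),
                             smoking = list(category = "smoking", level = "smoker",
                                            n_core = 8, n_noncore = 7, log2fc = 1.5),
                             gender = list(category = "gender", level = "female",
                                           n_core = 2, n_noncore = 2, log2fc = 0.5)
                           ),
                           dm_concentration = 3000,
                           depth_lognormal = c(log(12000), 0.4),
                           seed = NULL) {
  spec <- list(n_studies = n_studies, samples_per_study = samples_per_study,
               n_otus = n_otus, n_core = n_core,
               core_mra_target = core_mra_target,
               core_abund_sd = core_abund_sd, noncore_abund_sd = noncore_abund_sd,
               core_floor_share = core_floor_share,
               study_effect_sd = study_effect_sd,
               core_bias_trunc = core_bias_trunc,
               region_dropout = region_dropout,
               core_carriage = core_carriage, noncore_carriage = noncore_carriage,
               category_effects = category_effects,
               dm_concentration = dm_concentration,
               depth_lognormal = depth_lognormal, seed = seed)
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    stopifnot(n_studies >= 1, n_otus >= 2, n_core >= 0, n_core <= n_otus,
              samples_per_study[1] >= 1,
              samples_per_study[2] >= samples_per_study[1],
              region_dropout >= 0, region_dropout <= 1,
              all(core_carriage >= 0), all(core_carriage <= 1),
              all(noncore_carriage >= 0), all(noncore_carriage <= 1),
              dm_concentration > 0, study_effect_sd >= 0)
    if (core_mra_target >= 1 && n_core < n_otus) {
      stop("infeasible spec: core_mra_target = 1 leaves no mass for the ",
           n_otus - n_core, " non-core taxa", call. = FALSE)
    }
    if (core_mra_target < 0 || core_mra_target > 1) {
      stop("core_mra_target must lie in [0, 1]", call. = FALSE)
    }
    if (n_core > 0 && core_floor_share * n_core > core_mra_target) {
      stop("infeasible spec: core floor exceeds the cumulative target", call. = FALSE)
    }
  })
  invisible(spec)
}

#' Random rooted bifurcating tree
#'
#' Random topology (sequential random attachment) with branch lengths drawn
#' from Exponential(rate 10); leaf ids are taken from `labels`.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Seed.
#' @param labels Leaf labels (default `t1..tn`).
#' @return A rooted `phylo` tree.
#' @export
generate_tree <- function(n_leaves, seed = NULL, labels = NULL) {
  stopifnot(n_leaves >= 2)
  with_seed(seed, {
    tree <- ape::rtree(n_leaves, rooted = TRUE)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 10)
    if (!is.null(labels)) {
      stopifnot(length(labels) == n_leaves)
      tree$tip.label <- labels[order(match(tree$tip.label,
                                           paste0("t", seq_len(n_leaves))))]
    }
    tree
  })
}

# enforce a floor on the core shares while keeping their sum at `target`
floor_shares <- function(shares, floor, target) {
  for (i in 1:20) {
    low <- shares < floor
    if (!any(low)) break
    shares[low] <- floor
    excess <- target - sum(shares[low])
    shares[!low] <- shares[!low] * excess / sum(shares[!low])
  }
  shares
}

#' Generate a synthetic multi-study dataset
#'
#' Draws a complete dataset under a [synthetic_spec()]: count table, study
#' metadata, taxonomy, phylogeny and the planted ground truth. Base lognormal
#' abundances (core taxa from the upper tail, scaled so the expected
#' cumulative core relative abundance equals the target) are combined
#' per-sample with the study bias, the host-factor multipliers, the
#' region-dropout mask and the carriage draws, then counts are sampled
#' Dirichlet-multinomially at a lognormal depth. Base shares are
#' pre-divided by each taxon's expected multiplier (carriage probability,
#' effect and dropout expectations) so the realised composition matches the
#' planted one.
#'
#' @param spec A `synthetic_spec`.
#' @param seed Seed (defaults to `spec$seed`).
#' @return List with `counts`, `metadata`, `taxonomy`, `tree`, `truth`,
#'   `spec`. `truth` records the core ids, per-category affected taxa and
#'   directions, per-study bias matrix, carriage probabilities and base
#'   shares.
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = spec$seed) {
  validate_synthetic_spec(spec)
  with_seed(seed, {
    k <- spec$n_core
    n <- spec$n_otus
    otu_ids <- sprintf("OTU%04d", seq_len(n))
    core_ids <- sort(sample(otu_ids, k))
    is_core <- otu_ids %in% core_ids

    # base composition: core from the upper tail, scaled to the target
    shares <- numeric(n)
    if (k > 0) {
      w <- exp(stats::rnorm(k, 0, spec$core_abund_sd))
      cs <- spec$core_mra_target * w / sum(w)
      shares[is_core] <- floor_shares(cs, spec$core_floor_share,
                                      spec$core_mra_target)
    }
    v <- exp(stats::rnorm(n - k, 0, spec$noncore_abund_sd))
    shares[!is_core] <- (1 - spec$core_mra_target) * v / sum(v)

    # host carriage probability, independent of abundance
    carriage <- numeric(n)
    carriage[is_core] <- stats::runif(k, spec$core_carriage[1], spec$core_carriage[2])
    carriage[!is_core] <- stats::runif(n - k, spec$noncore_carriage[1],
                                       spec$noncore_carriage[2])

    # study design
    s_ids <- sprintf("S%02d", seq_len(spec$n_studies))
    loc <- c("NorthAmerica", "Europe", "China")[(seq_len(spec$n_studies) - 1L) %% 3L + 1L]
    if (spec$n_studies >= 10) loc[spec$n_studies] <- "others"
    reg <- c("V3V4", "V4")[(seq_len(spec$n_studies) - 1L) %% 2L + 1L]
    if (spec$n_studies >= 10) reg[spec$n_studies - 1L] <- "others"
    stype <- c("spit", "spit", "mouthwash", "oral_rinse")[(seq_len(spec$n_studies) - 1L) %% 4L + 1L]
    n_per <- spec$samples_per_study[1] +
      sample.int(spec$samples_per_study[2] - spec$samples_per_study[1] + 1L,
                 spec$n_studies, replace = TRUE) - 1L

    # per-study, per-taxon multiplicative bias; rows standardised to mean 1
    z <- matrix(stats::rnorm(n * spec$n_studies, 0, spec$study_effect_sd),
                n, spec$n_studies, dimnames = list(otu_ids, s_ids))
    tr <- spec$core_bias_trunc * spec$study_effect_sd
    z[is_core, ] <- pmin(pmax(z[is_core, ], -tr), tr)
    bias <- exp(z)
    if (spec$study_effect_sd > 0) bias <- bias / rowMeans(bias)

    # hypervariable-region dropout for non-core taxa
    dropped_region <- rep(NA_character_, n)
    hit <- !is_core & stats::runif(n) < spec$region_dropout
    dropped_region[hit] <- sample(c("V3V4", "V4"), sum(hit), replace = TRUE)

    # planted host-factor effects
    effects <- lapply(spec$category_effects, function(ef) {
      taxa <- c(sample(core_ids, min(ef$n_core, k)),
                sample(otu_ids[!is_core], min(ef$n_noncore, n - k)))
      ef$taxa <- taxa
      ef
    })

    # per-sample metadata
    study <- rep(s_ids, n_per)
    n_samp <- length(study)
    sample_id <- paste0(study, "_", unlist(lapply(n_per, function(m) sprintf("%03d", seq_len(m)))))
    meta <- data.frame(
      sample_id = sample_id, study = study,
      location = loc[match(study, s_ids)],
      region = reg[match(study, s_ids)],
      sample_type = stype[match(study, s_ids)],
      gender = sample(c("male", "female", "unknown"), n_samp, TRUE,
                      prob = c(0.48, 0.48, 0.04)),
      age_group = sample(c("18-30", "31-55", "56+", "unknown"), n_samp, TRUE,
                         prob = c(0.30, 0.40, 0.25, 0.05)),
      smoking = sample(c("smoker", "non_smoker", "unknown"), n_samp, TRUE,
                       prob = c(0.25, 0.65, 0.10)),
      drinking = sample(c("drinker", "non_drinker", "unknown"), n_samp, TRUE,
                        prob = c(0.45, 0.45, 0.10)),
      stringsAsFactors = FALSE
    )

    # expected multiplier per taxon, used to centre the realised composition
    # on the planted shares
    level_frac <- function(category, level) mean(meta[[category]] == level)
    e_mult <- carriage
    for (ef in effects) {
      f <- level_frac(ef$category, ef$level)
      idx <- otu_ids %in% ef$taxa
      e_mult[idx] <- e_mult[idx] * ((1 - f) + f * 2^ef$log2fc)
    }
    reg_frac <- vapply(c("V3V4", "V4"), function(r) mean(meta$region == r), 0)
    has_drop <- !is.na(dropped_region)
    e_mult[has_drop] <- e_mult[has_drop] * (1 - reg_frac[dropped_region[has_drop]])
    base <- shares / pmax(e_mult, 1e-9)

    depth <- pmax(round(stats::rlnorm(n_samp, spec$depth_lognormal[1],
                                      spec$depth_lognormal[2])), 100)
    counts <- matrix(0L, n, n_samp, dimnames = list(otu_ids, sample_id))
    for (j in seq_len(n_samp)) {
      wj <- base * bias[, meta$study[j]]
      if (any(has_drop)) {
        off <- has_drop & dropped_region == meta$region[j]
        wj[off] <- 0
      }
      for (ef in effects) {
        if (meta[[ef$category]][j] == ef$level) {
          idx <- otu_ids %in% ef$taxa
          wj[idx] <- wj[idx] * 2^ef$log2fc
        }
      }
      wj <- wj * (stats::runif(n) < carriage)
      if (all(wj == 0)) wj[sample.int(n, 1L)] <- 1
      alpha <- spec$dm_concentration * wj / sum(wj)
      p <- stats::rgamma(n, shape = alpha)
      live <- p > 0
      counts[live, j] <- stats::rmultinom(1L, depth[j], p[live])[, 1L]
    }

    taxonomy <- synth_taxonomy(otu_ids)
    tree <- generate_tree(n, labels = otu_ids)

    truth <- list(core = core_ids,
                  effects = effects,
                  study_bias = bias,
                  carriage = stats::setNames(carriage, otu_ids),
                  base_shares = stats::setNames(shares, otu_ids),
                  dropped_region = stats::setNames(dropped_region, otu_ids),
                  depth = stats::setNames(depth, sample_id))
    list(counts = counts, metadata = meta, taxonomy = taxonomy,
         tree = tree, truth = truth, spec = spec)
  })
}

#' Generate an independent cohort from an existing synthetic world
#'
#' Draws new studies and samples under the SAME planted biology as a dataset
#' from [generate_dataset()] — identical taxa, base shares, carriage
#' probabilities, host-factor effect taxa and region-dropout mask — but fresh
#' study identities, study biases, metadata and count draws. This is the
#' synthetic analogue of recruiting an independent validation cohort from the
#' same population.
#'
#' @param dataset A [generate_dataset()] result (its `truth` and `spec` are
#'   reused).
#' @param n_studies,samples_per_study Cohort design (defaults: 2 studies of
#'   13 samples each).
#' @param seed Seed.
#' @return A list shaped like [generate_dataset()] output (without a new
#'   tree/taxonomy: the originals apply).
#' @export
generate_cohort <- function(dataset, n_studies = 2, samples_per_study = c(13, 13),
                            seed = NULL) {
  spec <- dataset$spec
  truth <- dataset$truth
  otu_ids <- names(truth$base_shares)
  n <- length(otu_ids)
  is_core <- otu_ids %in% truth$core
  with_seed(seed, {
    s_ids <- sprintf("V%02d", seq_len(n_studies))
    loc <- c("China", "NorthAmerica", "Europe")[(seq_len(n_studies) - 1L) %% 3L + 1L]
    reg <- rep("V4", n_studies)
    stype <- rep("spit", n_studies)
    n_per <- samples_per_study[1] +
      sample.int(samples_per_study[2] - samples_per_study[1] + 1L,
                 n_studies, replace = TRUE) - 1L
    z <- matrix(stats::rnorm(n * n_studies, 0, spec$study_effect_sd),
                n, n_studies, dimnames = list(otu_ids, s_ids))
    tr <- spec$core_bias_trunc * spec$study_effect_sd
    z[is_core, ] <- pmin(pmax(z[is_core, ], -tr), tr)
    bias <- exp(z)
    if (spec$study_effect_sd > 0) bias <- bias / rowMeans(bias)

    study <- rep(s_ids, n_per)
    n_samp <- length(study)
    sample_id <- paste0(study, "_", unlist(lapply(n_per, function(m) sprintf("%03d", seq_len(m)))))
    meta <- data.frame(
      sample_id = sample_id, study = study,
      location = loc[match(study, s_ids)],
      region = reg[match(study, s_ids)],
      sample_type = stype[match(study, s_ids)],
      gender = sample(c("male", "female"), n_samp, TRUE),
      age_group = sample(c("18-30", "31-55", "56+"), n_samp, TRUE,
                         prob = c(0.35, 0.4, 0.25)),
      smoking = sample(c("smoker", "non_smoker"), n_samp, TRUE, prob = c(0.25, 0.75)),
      drinking = sample(c("drinker", "non_drinker"), n_samp, TRUE),
      stringsAsFactors = FALSE
    )
    carriage <- truth$carriage
    base <- truth$base_shares / pmax(carriage, 1e-9)
    has_drop <- !is.na(truth$dropped_region)
    depth <- pmax(round(stats::rlnorm(n_samp, spec$depth_lognormal[1],
                                      spec$depth_lognormal[2])), 100)
    counts <- matrix(0L, n, n_samp, dimnames = list(otu_ids, sample_id))
    for (j in seq_len(n_samp)) {
      wj <- base * bias[, meta$study[j]]
      off <- has_drop & truth$dropped_region == meta$region[j]
      wj[off] <- 0
      for (ef in truth$effects) {
        if (meta[[ef$category]][j] == ef$level) {
          idx <- otu_ids %in% ef$taxa
          wj[idx] <- wj[idx] * 2^ef$log2fc
        }
      }
      wj <- wj * (stats::runif(n) < carriage)
      if (all(wj == 0)) wj[sample.int(n, 1L)] <- 1
      alpha <- spec$dm_concentration * wj / sum(wj)
      p <- stats::rgamma(n, shape = alpha)
      live <- p > 0
      counts[live, j] <- stats::rmultinom(1L, depth[j], p[live])[, 1L]
    }
    list(counts = counts, metadata = meta, truth = truth, spec = spec)
  })
}

# simple nested random taxonomy over the synthetic OTUs
synth_taxonomy <- function(otu_ids) {
  n <- length(otu_ids)
  phyla <- paste0("Phylum", 1:6)
  ph <- sample(phyla, n, TRUE, prob = c(0.3, 0.25, 0.2, 0.12, 0.08, 0.05))
  cl <- paste0(ph, "_c", sample(1:2, n, TRUE))
  or <- paste0(cl, "_o", sample(1:2, n, TRUE))
  fa <- paste0(or, "_f", sample(1:3, n, TRUE))
  ge <- paste0(fa, "_g", sample(1:3, n, TRUE))
  sp <- paste0(ge, "_s", seq_len(n))
  ge[stats::runif(n) < 0.05] <- NA
  sp[stats::runif(n) < 0.10] <- NA
  data.frame(otu_id = otu_ids, phylum = ph, class = cl, order = or,
             family = fa, genus = ge, species = sp, stringsAsFactors = FALSE)
}

#' Random nucleotide sequences
#'
#' @param ids Names for the sequences.
#' @param length Sequence length (default 250 nt).
#' @param seed Seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
random_sequences <- function(ids, length = 250, seed = NULL) {
  with_seed(seed, {
    seqs <- vapply(ids, function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Mutate sequences to a fixed divergence
#'
#' Substitutes `round(divergence * length)` positions of each sequence,
#' chosen uniformly without replacement, to a different base.
#'
#' @param refs Named DNAStringSet (or character vector).
#' @param divergence Fraction of positions substituted, in [0, 0.5].
#' @param seed Seed.
#' @return A DNAStringSet of mutated sequences with the same names.
#' @export
mutate_sequences <- function(refs, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  chr <- if (inherits(refs, "DNAStringSet")) as.character(refs) else as.character(refs)
  with_seed(seed, {
    out <- vapply(chr, function(s) {
      b <- strsplit(s, "", fixed = TRUE)[[1]]
      m <- round(divergence * length(b))
      if (m > 0) {
        pos <- sample(length(b), m)
        b[pos] <- vapply(b[pos], function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1L)
        }, character(1))
      }
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    stats::setNames(Biostrings::DNAStringSet(out), names(chr))
  })
}
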