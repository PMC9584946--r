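# The four normalisation strategies compared throughout the analysis.

norm_attrs <- function(x, method, depth = NULL, seed = NULL) {
  attr(x, "method") <- method
  attr(x, "depth") <- depth
  attr(x, "seed") <- seed
  x
}

#' Rarefy samples to a fixed depth
#'
#' Subsamples each sample's reads uniformly without replacement (multivariate
#' hypergeometric, the vegan/QIIME2 convention) to `depth` reads. Samples with
#' fewer total reads than `depth` are dropped with a warning rather than
#' padded. Reproducible given `seed`; the caller's RNG stream is untouched.
#'
#' @param t Count matrix (OTUs x samples), integer.
#' @param depth Target library size (default 5000).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Integer matrix whose columns each sum to `depth`, with attributes
#'   `method = "RAR"`, `depth` and `seed`.
#' @export
rarefy <- function(t, depth = 5000, seed = NULL) {
  validate_count_table(t)
  if (depth <= 0) stop("depth must be a positive integer", call. = FALSE)
  totals <- colSums(t)
  drop <- totals < depth
  if (any(drop)) {
    warning(sum(drop), " sample(s) below rarefaction depth ", depth, " dropped")
    t <- t[, !drop, drop = FALSE]
  }
  out <- with_seed(seed, {
    # vegan warns when it suspects pre-normalised input; irrelevant here.
    withCallingHandlers(
      t(vegan::rrarefy(t(t), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
      }
    )
  })
  storage.mode(out) <- "integer"
  norm_attrs(out, "RAR", depth = depth, seed = seed)
}

#' Total-sum scaling
#'
#' Converts counts to within-sample relative abundances.
#'
#' @param t Count (or non-negative) matrix.
#' @return Real matrix with unit column sums, attribute `method = "TSS"`.
#' @export
tss <- function(t) {
  validate_count_table(t, integer = FALSE)
  totals <- colSums(t)
  if (any(totals == 0)) {
    stop("zero-sum sample(s): ", paste(colnames(t)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  norm_attrs(sweep(t, 2L, totals, "/"), "TSS")
}

#' Rarefied relative abundance
#'
#' Composition of [rarefy()] then [tss()]: samples are rarefied to `depth`
#' and converted to relative abundance, so values lie on the grid k/depth.
#'
#' @inheritParams rarefy
#' @return Real matrix with unit column sums, attribute `method = "RRA"`.
#' @export
rra <- function(t, depth = 5000, seed = NULL) {
  r <- rarefy(t, depth = depth, seed = seed)
  norm_attrs(tss(r), "RRA", depth = depth, seed = seed)
}

#' Centred log-ratio transform with multiplicative zero replacement
#'
#' Zeros are imputed by the count-zero-multiplicative rule: in each sample the
#' detection limit of a proportion is 1/total, each zero is replaced by
#' `delta` times that limit, and the non-zero proportions are shrunk by the
#' factor (1 - sum of replacements) so the composition stays closed. The
#' centred log-ratio ln(x_i / g(x)) is then taken per sample; columns sum to
#' zero by construction.
#'
#' @param t Count matrix.
#' @param delta Fraction of the detection limit used for imputation
#'   (default 0.65).
#' @return Real matrix with zero column sums, attribute `method = "CLR"`.
#' @export
clr_czm <- function(t, delta = 0.65) {
  validate_count_table(t)
  totals <- colSums(t)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ", paste(colnames(t)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  out <- t * 0
  for (j in seq_len(ncol(t))) {
    p <- t[, j] / totals[j]
    z <- p == 0
    if (any(z)) {
      repl <- delta / totals[j]
      shrink <- 1 - sum(z) * repl
      if (shrink <= 0) {
        stop("zero replacement exceeds unit mass in sample ", colnames(t)[j],
             call. = FALSE)
      }
      p[z] <- repl
      p[!z] <- p[!z] * shrink
    }
    lp <- log(p)
    out[, j] <- lp - mean(lp)
  }
  norm_attrs(out, "CLR")
}

#' Apply a normalisation by name
#'
#' @param t Count matrix.
#' @param method `"rar"`, `"tss"`, `"rra"` or `"clr"`.
#' @param depth Rarefaction depth for `"rar"`/`"rra"`.
#' @param seed Seed for the rarefaction draw.
#' @return The normalised matrix.
#' @export
normalise <- function(t, method = c("tss", "rar", "rra", "clr"),
                      depth = 5000, seed = NULL) {
  method <- match.arg(method)
  switch(method,
         rar = rarefy(t, depth, seed),
         tss = tss(t),
         rra = rra(t, depth, seed),
         clr = clr_czm(t))
}
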