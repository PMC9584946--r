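#' Per-sample alpha diversity
#'
#' Computes observed richness, the Chao1 richness estimate, Shannon entropy
#' (natural log) and Simpson's index for every sample.
#'
#' Chao1 uses the bias-corrected form S_obs + F1(F1 - 1) / (2 (F2 + 1)),
#' which stays defined when no doubletons are observed; the classic form
#' S_obs + F1^2 / (2 F2) is available via `chao1`. Simpson is reported as the
#' Gini-Simpson probability 1 - sum(p_i^2) by default, with the inverse form
#' 1 / sum(p_i^2) behind `simpson`.
#'
#' @param t Count matrix (OTUs x samples). Chao1 requires integer counts;
#'   Shannon and Simpson accept any non-negative table.
#' @param indices Subset of `c("chao1", "shannon", "simpson")`.
#' @param chao1 `"bias_corrected"` (default) or `"classic"`.
#' @param simpson `"gini_simpson"` (default) or `"inverse"`.
#' @return Data frame with one row per sample: `sample_id`, `observed`, and
#'   the requested indices.
#' @export
alpha_diversity <- function(t, indices = c("chao1", "shannon", "simpson"),
                            chao1 = c("bias_corrected", "classic"),
                            simpson = c("gini_simpson", "inverse")) {
  indices <- match.arg(indices, several.ok = TRUE)
  chao1 <- match.arg(chao1)
  simpson <- match.arg(simpson)
  validate_count_table(t, integer = FALSE)
  if ("chao1" %in% indices && !is_count_integerish(t)) {
    stop("Chao1 requires integer counts", call. = FALSE)
  }
  out <- data.frame(sample_id = colnames(t),
                    observed = colSums(t > 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  if ("chao1" %in% indices) {
    out$chao1 <- apply(t, 2L, function(x) {
      s <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      if (chao1 == "bias_corrected") {
        s + f1 * (f1 - 1) / (2 * (f2 + 1))
      } else {
        if (f2 == 0) s else s + f1^2 / (2 * f2)
      }
    })
  }
  if ("shannon" %in% indices) {
    out$shannon <- unname(vegan::diversity(t(t), index = "shannon"))
  }
  if ("simpson" %in% indices) {
    out$simpson <- unname(vegan::diversity(
      t(t), index = if (simpson == "inverse") "invsimpson" else "simpson"))
  }
  out
}
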