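#' Principal coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower double-centred
#' matrix -1/2 J D^2 J. Axes are ordered by eigenvalue; negative eigenvalues
#' are reported and, by default, excluded from the denominator of the
#' proportion of variance explained. No Cailliez correction is applied.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of axes to return (at most n - 1).
#' @param negative How negative eigenvalues enter the proportion denominator:
#'   `"exclude"` (default, positive eigenvalues only) or `"absolute"`.
#' @return An object of class `pcoa_result`: list with `points` (samples x k),
#'   `eigenvalues` (descending), `proportion_explained` (per returned axis).
#' @export
pcoa <- function(d, k = 2, negative = c("exclude", "absolute")) {
  negative <- match.arg(negative)
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      stop("distance matrix is not symmetric", call. = FALSE)
    }
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  if (k > n - 1L) stop("k must be at most n - 1", call. = FALSE)
  # degenerate inputs yield fewer positive axes than requested; the shortfall
  # is padded with zero coordinates below, so cmdscale's note is redundant
  fit <- withCallingHandlers(
    stats::cmdscale(d, k = k, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate input: pad axes with zero coordinates
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  rownames(pts) <- labels(d)
  colnames(pts) <- paste0("PCo", seq_len(k))
  eig <- fit$eig
  denom <- if (negative == "exclude") sum(eig[eig > 0]) else sum(abs(eig))
  prop <- if (denom > 0) pmax(eig[seq_len(k)], 0) / denom else rep(0, k)
  structure(list(points = pts, eigenvalues = eig,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$points)
  cat("Principal coordinate analysis:", nrow(x$points), "samples,", k, "axes\n")
  cat("Proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", "), "\n")
  invisible(x)
}
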