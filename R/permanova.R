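# Permutational multivariate analysis of variance on a distance matrix
# (McArdle & Anderson partitioning of the Gower-centred inner-product matrix).

gower_center <- function(D2) {
  n <- nrow(D2)
  rm <- rowMeans(D2)
  gm <- mean(D2)
  -0.5 * (D2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm)
}

# Projection matrix onto the column space of X.
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' PERMANOVA with sequential term partitioning
#'
#' Partitions the total sum of squared distances among an ordered list of
#' metadata terms (Type I, so terms entered earlier absorb shared variance
#' first; "adjusting for the study" means listing `study` as the first term).
#' The pseudo-F of each term is recomputed under random relabelling of the
#' samples, freely or within `strata` blocks, and
#' p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm).
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param data Data frame of sample covariates, either with row names or a
#'   `sample_id` column matching the labels of `d`.
#' @param terms Character vector of column names, in entry order.
#' @param n_perm Number of permutations (default 999); ignored when
#'   `exact = TRUE`.
#' @param seed Seed for the permutation draws.
#' @param strata Optional column name; permutations are then restricted to
#'   shuffling samples within levels of that column.
#' @param exact Enumerate all n! relabellings instead of sampling (only
#'   sensible for n <= 8); the p-value is then the exact permutation
#'   probability mean(F_perm >= F_obs) including the identity.
#' @return Object of class `permanova`: data frame of terms with `df`,
#'   `sum_of_squares`, `R2`, `pseudo_F`, `p_value`, plus residual and total
#'   rows; attribute `n_permutations`.
#' @export
permanova <- function(d, data, terms, n_perm = 999, seed = NULL,
                      strata = NULL, exact = FALSE) {
  D <- as.matrix(d)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  if (!is.null(data$sample_id)) {
    rownames(data) <- data$sample_id
  }
  if (!all(ids %in% rownames(data))) {
    stop("samples absent from covariate data: ",
         paste(setdiff(ids, rownames(data)), collapse = ", "), call. = FALSE)
  }
  data <- data[ids, , drop = FALSE]
  for (tm in terms) {
    v <- data[[tm]]
    if (is.null(v)) stop("no such term: ", tm, call. = FALSE)
    if (anyNA(v)) stop("term '", tm, "' has missing values; drop those samples first",
                       call. = FALSE)
    if (length(unique(v)) < 2L) stop("term '", tm, "' has a single level", call. = FALSE)
    data[[tm]] <- factor(v)
  }

  G <- gower_center(D^2)
  ss_total <- sum(diag(G))

  # cumulative hat matrices for the sequential partition
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  rank_prev <- 1L  # intercept
  for (j in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(j)]), data = data)
    hats[[j]] <- hat_matrix(X)
    rank_j <- qr(X)$rank
    dfs[j] <- rank_j - rank_prev
    if (dfs[j] == 0L) {
      stop("term '", terms[j], "' is aliased with earlier terms ",
           "(adds no degrees of freedom); reorder or drop it", call. = FALSE)
    }
    rank_prev <- rank_j
  }
  df_res <- n - rank_prev
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)

  ss_from_perm <- function(perm) {
    Gp <- G[perm, perm]
    fit_prev <- 0
    ss <- numeric(length(terms))
    for (j in seq_along(terms)) {
      fit_j <- sum(hats[[j]] * Gp)
      ss[j] <- fit_j - fit_prev
      fit_prev <- fit_j
    }
    list(ss = ss, ss_res = sum(diag(Gp)) - fit_prev)
  }

  # pseudo-F, robust to a vanishing residual (perfectly separable designs):
  # a term with positive SS against a ~zero residual scores +Inf
  tol_f <- 1e-10 * max(ss_total, 1)
  pseudo_f <- function(ss, ss_res) {
    denom <- max(ss_res, 0) / df_res
    if (denom < tol_f) {
      ifelse(ss / dfs > tol_f, Inf, 0)
    } else {
      (ss / dfs) / denom
    }
  }

  obs <- ss_from_perm(seq_len(n))
  f_obs <- pseudo_f(obs$ss, obs$ss_res)

  if (exact) {
    perms <- all_permutations(n)
    f_all <- matrix(0, nrow(perms), length(terms))
    for (i in seq_len(nrow(perms))) {
      pp <- ss_from_perm(perms[i, ])
      f_all[i, ] <- pseudo_f(pp$ss, pp$ss_res)
    }
    p <- colMeans(sweep(f_all, 2L, f_obs - 1e-12, ">="))
    n_used <- nrow(perms)
  } else {
    if (!is.null(strata)) {
      blocks <- factor(data[[strata]])
      if (any(table(blocks) == 1L)) warning("strata block(s) of size 1")
      draw <- function() {
        perm <- seq_len(n)
        for (b in levels(blocks)) {
          idx <- which(blocks == b)
          if (length(idx) > 1L) perm[idx] <- sample(idx)
        }
        perm
      }
    } else {
      draw <- function() sample.int(n)
    }
    exceed <- numeric(length(terms))
    with_seed(seed, {
      for (i in seq_len(n_perm)) {
        pp <- ss_from_perm(draw())
        fp <- pseudo_f(pp$ss, pp$ss_res)
        exceed <- exceed + (fp >= f_obs - 1e-12)
      }
    })
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    sum_of_squares = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_F = c(f_obs, NA, NA),
    p_value = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("permanova", "data.frame"),
            n_permutations = n_used, strata = strata)
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential sums of squares,",
      attr(x, "n_permutations"), "permutations)\n")
  if (!is.null(attr(x, "strata"))) {
    cat("Permutations restricted within:", attr(x, "strata"), "\n")
  }
  df <- as.data.frame(x)
  df$sum_of_squares <- signif(df$sum_of_squares, 5)
  df$R2 <- round(df$R2, 4)
  df$pseudo_F <- round(df$pseudo_F, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
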