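#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` with `p_i = n_i / N`; equals the number of taxa for a
#' perfectly even community and 1 for a single-taxon community.
#'
#' @param counts non-negative count vector for one sample, or a matrix
#'   (samples x taxa) for per-sample values.
#' @return numeric value(s) >= 1.
#' @export
inverse_simpson <- function(counts) {
  if (is.matrix(counts)) return(apply(unclass(counts), 1L, inverse_simpson))
  total <- sum(counts)
  if (total <= 0) stopf("inverse Simpson undefined for an empty sample")
  p <- counts / total
  1 / sum(p^2)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Mid-ranks for ties. For `min(n) <= 8` (and at most `1e5` distinct
#' assignments, so very unbalanced comparisons stay tractable) the
#' two-sided p-value is exact, by enumeration of all assignments of the
#' pooled observations to the two groups (conditional on the observed
#' ties); otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative refers to `x` shifted relative to `y`).
#' @return list with `U` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # exact enumeration for small groups, provided the arrangement count is
  # tractable (a 5-vs-80 comparison has ~25M arrangements and falls back)
  if (min(n1, n2) <= 8L && choose(n1 + n2, min(n1, n2)) <= 1e5) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - 1e-9),
      greater = mean(Us >= U - 1e-9),
      less = mean(Us <= U + 1e-9))
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                   less = -0.5)
      z <- (z - cc) / sqrt(sigma2)
      p <- switch(alternative,
        two.sided = 2 * stats::pnorm(-abs(z)),
        greater = stats::pnorm(z, lower.tail = FALSE),
        less = stats::pnorm(z))
      p <- min(1, p)
    }
    method <- "normal_approximation"
  }
  list(U = U, p_value = p, method = method, n = c(n1, n2))
}

#' Analysis of similarities (ANOSIM)
#'
#' All pairwise dissimilarities are ranked (mid-ranks for ties) and
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2`. Significance by permuting group labels:
#' `p = (#{permuted R >= observed} + 1) / (n_perm + 1)`.
#'
#' @param d a [as_dissim()] matrix.
#' @param groups group label per sample (in `d`'s row order).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `anosim_result`: `R`, `p_value`, `n_perm`,
#'   `group_sizes`, `R_perm` (permutation distribution).
#' @export
anosim <- function(d, groups, n_perm = 1000L, seed = NULL) {
  d <- as_dissim(unclass(d))
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stopf("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("ANOSIM needs at least 2 groups")
  if (any(sizes < 2L)) stopf("group(s) of size 1: %s",
                             paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  pr <- pair_indices(n)
  rk <- rank(dissim_vec(d))
  M <- n * (n - 1) / 2
  r_stat <- function(g) {
    within <- g[pr$i] == g[pr$j]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  R <- r_stat(groups)
  R_perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) r_stat(groups[sample.int(n)]),
           numeric(1))
  })
  p <- (sum(R_perm >= R - 1e-12) + 1) / (n_perm + 1)
  structure(list(R = R, p_value = p, n_perm = n_perm,
                 group_sizes = sizes, R_perm = R_perm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("anosim_result: R = %.3f, p = %.4g (%d permutations; groups: %s)\n",
              x$R, x$p_value, x$n_perm,
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Pairwise ANOSIM with Bonferroni correction
#'
#' Each pair of groups is tested on its submatrix; p-values are multiplied
#' by the number of pairs and capped at 1.
#'
#' @inheritParams anosim
#' @return data.frame with columns `group_a`, `group_b`, `R`, `p_value`,
#'   `p_bonferroni`.
#' @export
pairwise_anosim <- function(d, groups, n_perm = 1000L, seed = NULL) {
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) < 2L) stopf("need at least 2 groups")
  pairs <- utils::combn(levs, 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(p) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    idx <- which(groups %in% c(a, b))
    sub <- as_dissim(unclass(d)[idx, idx, drop = FALSE])
    res <- anosim(sub, groups[idx], n_perm = n_perm,
                  seed = derive_seed(seed %||% 0L, p))
    data.frame(group_a = a, group_b = b, R = res$R, p_value = res$p_value,
               p_bonferroni = min(1, res$p_value * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multivariate dispersion: distance to group centroid
#'
#' The dissimilarity matrix is embedded by PCoA keeping positive- and
#' negative-eigenvalue axes separately; the distance of a sample to its
#' group centroid is `sqrt(max(0, d_pos^2 - d_neg^2))` (Anderson's
#' construction, as in PERMDISP). Group mean distances are compared
#' pairwise with [mann_whitney()] and Bonferroni correction.
#'
#' @inheritParams anosim
#' @return object of class `dispersion_result`: `distances` (per sample),
#'   `group_means`, `comparisons` (data.frame `group_a`, `group_b`, `U`,
#'   `p_value`, `p_bonferroni`).
#' @export
beta_dispersion <- function(d, groups) {
  d <- as_dissim(unclass(d))
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stopf("one group label per sample required")
  sizes <- table(groups)
  if (any(sizes < 2L)) stopf("group(s) of size 1: %s",
                             paste(names(sizes)[sizes < 2L], collapse = ", "))
  emb <- pcoa_signed(d)
  dist2 <- numeric(nrow(d))
  for (g in names(sizes)) {
    idx <- which(groups == g)
    cp <- colMeans(emb$pos[idx, , drop = FALSE])
    d2p <- rowSums(sweep(emb$pos[idx, , drop = FALSE], 2L, cp)^2)
    d2n <- 0
    if (ncol(emb$neg)) {
      cn <- colMeans(emb$neg[idx, , drop = FALSE])
      d2n <- rowSums(sweep(emb$neg[idx, , drop = FALSE], 2L, cn)^2)
    }
    dist2[idx] <- d2p - d2n
  }
  distances <- sqrt(pmax(0, dist2))
  names(distances) <- rownames(d)
  group_means <- tapply(distances, groups, mean)
  pairs <- utils::combn(names(sizes), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(p) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    mw <- mann_whitney(distances[groups == a], distances[groups == b])
    data.frame(group_a = a, group_b = b, U = mw$U, p_value = mw$p_value,
               p_bonferroni = min(1, mw$p_value * n_pairs),
               stringsAsFactors = FALSE)
  })
  structure(list(distances = distances, group_means = group_means,
                 comparisons = do.call(rbind, rows)),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("dispersion_result: mean distance to centroid per group\n")
  print(round(x$group_means, 4))
  invisible(x)
}
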