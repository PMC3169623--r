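#' Shared-OTU estimation by resampling
#'
#' For every pair of groups, repeatedly equalizes the sampling effort and
#' counts the OTUs observed in both groups. With `design = "equal_samples"`
#' each group is subsampled (without replacement) to the smallest group's
#' sample count; `"equal_sequences"` additionally rarefies each drawn group
#' to the smallest drawn group's sequence total. The shared percentage uses
#' the pair's union of observed OTUs as denominator (per-group denominators
#' are available via `denominator`).
#'
#' @param t an [otu_table()].
#' @param groups group label per sample.
#' @param n_iter resampling iterations (default 100).
#' @param design `"equal_samples"` or `"equal_sequences"`.
#' @param denominator `"union"`, `"min_group"` or `"mean_group"`.
#' @param seed integer seed.
#' @return object of class `shared_otu_result`: data.frame `pairs` with
#'   mean/sd of shared counts and percentages, plus the design metadata.
#' @export
shared_otus <- function(t, groups, n_iter = 100L,
                        design = c("equal_samples", "equal_sequences"),
                        denominator = c("union", "min_group", "mean_group"),
                        seed = NULL) {
  design <- match.arg(design)
  denominator <- match.arg(denominator)
  groups <- as.character(groups)
  if (length(groups) != nrow(t)) stopf("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("need at least 2 groups")
  if (min(sizes) < 2L) stopf("smallest group has fewer than 2 samples")
  m <- unclass(t)
  pairs <- utils::combn(names(sizes), 2L)
  rows <- local_seed(seed, {
    lapply(seq_len(ncol(pairs)), function(p) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      ia <- which(groups == a); ib <- which(groups == b)
      n_sub <- min(length(ia), length(ib))
      shared_n <- shared_pct <- numeric(n_iter)
      for (it in seq_len(n_iter)) {
        sa <- m[sample(ia, n_sub), , drop = FALSE]
        sb <- m[sample(ib, n_sub), , drop = FALSE]
        ta <- colSums(sa); tb <- colSums(sb)
        if (design == "equal_sequences") {
          depth <- min(sum(ta), sum(tb))
          ta <- rarefy_counts(ta, depth)
          tb <- rarefy_counts(tb, depth)
        }
        pa <- ta > 0; pb <- tb > 0
        sh <- sum(pa & pb)
        den <- switch(denominator,
          union = sum(pa | pb),
          min_group = min(sum(pa), sum(pb)),
          mean_group = mean(c(sum(pa), sum(pb))))
        shared_n[it] <- sh
        shared_pct[it] <- 100 * sh / den
      }
      data.frame(group_a = a, group_b = b, n_subsampled = n_sub,
                 shared_mean = mean(shared_n), shared_sd = stats::sd(shared_n),
                 pct_mean = mean(shared_pct), pct_sd = stats::sd(shared_pct),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out$shared_sd[is.na(out$shared_sd)] <- 0
  out$pct_sd[is.na(out$pct_sd)] <- 0
  structure(list(pairs = out, n_iterations = n_iter, design = design,
                 denominator = denominator),
            class = "shared_otu_result")
}

#' @export
print.shared_otu_result <- function(x, ...) {
  cat(sprintf("shared_otu_result (%s, %d iterations):\n", x$design,
              x$n_iterations))
  print(transform(x$pairs, pct_mean = round(pct_mean, 2),
                  pct_sd = round(pct_sd, 3)))
  invisible(x)
}

# rarefy a pooled count vector to a fixed depth without replacement
rarefy_counts <- function(counts, depth) {
  total <- sum(counts)
  if (depth >= total) return(counts)
  picked <- sample.int(total, depth)
  breaks <- c(0, cumsum(counts))
  tabulate(findInterval(picked, breaks, left.open = TRUE),
           nbins = length(counts))
}

#' Balanced-group ANOSIM simulation
#'
#' Repeatedly subsamples an equal number of samples per realm (without
#' replacement), rebuilds the Hellinger + Bray-Curtis dissimilarities on the
#' subset and reruns ANOSIM, to check that group-size imbalance does not
#' drive the realm separation.
#'
#' @param t an [otu_table()] (typically aggregated at the class level).
#' @param groups realm label per sample (two levels).
#' @param n_per_group samples drawn per realm each iteration (default 140).
#' @param n_iter iterations (default 1000).
#' @param n_perm ANOSIM permutations per iteration (default 100).
#' @param alpha significance level for the "fraction significant" summary.
#' @param seed integer seed.
#' @return list with `R` (per-iteration statistics), `summary` (min, mean,
#'   max), `fraction_significant`, and the design parameters.
#' @export
balanced_anosim <- function(t, groups, n_per_group = 140L, n_iter = 1000L,
                            n_perm = 100L, alpha = 0.05, seed = NULL) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) != 2L) stopf("balanced ANOSIM expects exactly 2 groups")
  small <- names(sizes)[sizes < n_per_group]
  if (length(small)) stopf("group(s) smaller than n_per_group = %d: %s",
                           n_per_group, paste(small, collapse = ", "))
  m <- unclass(t)
  res <- local_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      idx <- unlist(lapply(names(sizes), function(g) {
        sample(which(groups == g), n_per_group)
      }), use.names = FALSE)
      sub <- m[idx, , drop = FALSE]
      keep <- colSums(sub) > 0
      d <- bray_curtis(hellinger(sub[, keep, drop = FALSE]))
      a <- anosim(d, groups[idx], n_perm = n_perm, seed = NULL)
      c(R = a$R, p = a$p_value)
    }, numeric(2))
  })
  R <- res["R", ]; p <- res["p", ]
  list(R = R, p = p,
       summary = c(min = min(R), mean = mean(R), max = max(R)),
       fraction_significant = mean(p <= alpha),
       n_per_group = n_per_group, n_iter = n_iter, n_perm = n_perm)
}

#' Sensitivity of realm separation to abundance weighting
#'
#' Multiplies one realm's raw counts by each weight (mimicking differences
#' in cell density / template amount between water and sediment samples),
#' rebuilds the dissimilarities and reruns ANOSIM. Because the default
#' composition pipeline (Hellinger + Bray-Curtis) is invariant to
#' per-sample scaling, weights act on raw counts and an additional
#' `mode = "raw"` skips the Hellinger standardization so the weighting can
#' bite; `mode = "hellinger"` documents the invariance.
#'
#' @param t an [otu_table()].
#' @param groups realm label per sample (two levels).
#' @param weights positive weights applied to the *first* realm level's
#'   counts; default spans three orders of magnitude.
#' @param mode `"raw"` (Bray-Curtis on weighted raw counts) or
#'   `"hellinger"` (full composition pipeline).
#' @param n_perm,seed passed to [anosim()].
#' @return data.frame with columns `weight`, `R`, `p_value`.
#' @export
weight_sensitivity <- function(t, groups,
                               weights = c(0.1, 0.316, 1, 3.16, 10),
                               mode = c("raw", "hellinger"),
                               n_perm = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  if (any(weights <= 0)) stopf("weights must be positive")
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) != 2L) stopf("weight sensitivity expects exactly 2 groups")
  m <- unclass(t)
  target <- groups == levs[1L]
  rows <- lapply(seq_along(weights), function(i) {
    w <- weights[i]
    mw <- m
    mw[target, ] <- mw[target, , drop = FALSE] * w
    d <- if (mode == "hellinger") bray_curtis(hellinger(mw)) else bray_curtis(mw)
    a <- anosim(d, groups, n_perm = n_perm, seed = seed)
    data.frame(weight = w, R = a$R, p_value = a$p_value)
  })
  out <- do.call(rbind, rows)
  attr(out, "weighted_group") <- levs[1L]
  attr(out, "mode") <- mode
  out
}

#' Robustness of the ordination to singletons and to presence/absence
#'
#' Builds NMDS ordinations from the Hellinger + Bray-Curtis pipeline for
#' (i) the full table, (ii) the table without dataset-wide singletons and
#' (iii) presence/absence data (same pipeline applied to the binarized
#' table), then compares (i) against (ii) and (iii) by [protest()]. All
#' variants use the same NMDS random starts (common random numbers), so an
#' unchanged input reproduces the identical ordination.
#'
#' @param t an [otu_table()] with at least 4 samples.
#' @param k,n_starts,n_perm NMDS / PROTEST controls.
#' @param seed integer seed.
#' @return data.frame with columns `comparison`, `correlation`, `m2`,
#'   `p_value`.
#' @export
robustness_procrustes <- function(t, k = 2L, n_starts = 20L, n_perm = 1000L,
                                  seed = NULL) {
  if (nrow(t) < 4L) stopf("need at least 4 samples")
  variants <- list(
    full = bray_curtis(hellinger(t)),
    no_singletons = bray_curtis(hellinger(remove_singletons(t))),
    presence_absence = bray_curtis(hellinger(presence_absence(t))))
  ords <- lapply(variants, function(d) {
    nmds(d, k = k, n_starts = n_starts, seed = derive_seed(seed %||% 0L, 1L))
  })
  names(ords) <- names(variants)
  cmp <- function(a, b, tag, i) {
    pr <- protest(ords[[a]]$coordinates, ords[[b]]$coordinates,
                  n_perm = n_perm, seed = derive_seed(seed %||% 0L, 100L + i))
    data.frame(comparison = tag, correlation = pr$correlation, m2 = pr$m2,
               p_value = pr$p_value, stringsAsFactors = FALSE)
  }
  rbind(cmp("full", "no_singletons", "with_vs_without_singletons", 1L),
        cmp("full", "presence_absence", "abundance_vs_presence_absence", 2L))
}
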