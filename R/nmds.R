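#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS minimizing stress-1
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `d` are configuration
#' distances and `dhat` is the monotone (pool-adjacent-violators) regression
#' of `d` on the observed dissimilarities. Ties in the dissimilarities are
#' treated weakly (primary approach): tied dissimilarities may receive
#' unequal fitted values. Each start alternates the monotone fit with a
#' Guttman-transform configuration update plus a backtracking line search,
#' so the recorded stress sequence is non-increasing within a start.
#' `n_starts` random starts are run plus one PCoA-seeded start; the
#' lowest-stress solution is returned, centred and rotated to its principal
#' axes (signs fixed for reproducibility).
#'
#' @param d a [as_dissim()] matrix.
#' @param k target dimensionality (default 2).
#' @param n_starts number of random starts (a PCoA-seeded start is added).
#' @param seed integer seed controlling all random starts.
#' @param max_iter,tol stopping rule: at most `max_iter` iterations or
#'   relative stress change below `tol`.
#' @return object of class `nmds_result`: `coordinates`, `stress`,
#'   `n_starts`, `converged`, `best_start`, `best_start_seed`,
#'   `stress_by_start`, `stress_trace` (per-iteration stress of the best
#'   start).
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, seed = NULL,
                 max_iter = 500L, tol = 1e-7) {
  d <- as_dissim(unclass(d))
  n <- nrow(d)
  if (k >= n - 1L) stopf("k = %d requires more than %d samples", k, k + 1L)
  dv <- dissim_vec(d)
  degenerate <- max(dv) - min(dv) < 1e-12
  if (degenerate) warnf("all dissimilarities equal; NMDS solution is degenerate")

  lower <- lower.tri(matrix(0, n, n))
  stress_of <- function(cdv, dhat) {
    denom <- sum(cdv^2)
    if (denom == 0) return(0)   # collapsed configuration of a zero matrix
    sqrt(sum((cdv - dhat)^2) / denom)
  }
  fit_dhat <- function(cdv) {
    o <- order(dv, cdv)         # weak ties: break by current distances
    out <- numeric(length(cdv))
    out[o] <- stats::isoreg(cdv[o])$yf
    out
  }
  one_start <- function(x0) {
    x <- x0
    cdv <- dissim_vec(as.matrix(stats::dist(x)))
    dhat <- fit_dhat(cdv)
    s <- stress_of(cdv, dhat)
    trace <- s
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      if (s <= 1e-12) { converged <- TRUE; break }
      # Guttman transform towards current disparities
      dh <- cd <- matrix(0, n, n)
      dh[lower] <- dhat; cd[lower] <- cdv
      dh <- dh + t(dh); cd <- cd + t(cd)
      ratio <- ifelse(cd > 0, dh / cd, 0)
      b <- -ratio
      diag(b) <- rowSums(ratio)
      xg <- b %*% x / n
      # backtracking line search on stress-1 (guarantees descent)
      alpha <- 1
      s_new <- Inf
      for (h in 1:12) {
        xt <- x + alpha * (xg - x)
        cdv_t <- dissim_vec(as.matrix(stats::dist(xt)))
        dhat_t <- fit_dhat(cdv_t)
        s_t <- stress_of(cdv_t, dhat_t)
        if (s_t <= s) { s_new <- s_t; x <- xt; cdv <- cdv_t; dhat <- dhat_t; break }
        alpha <- alpha / 2
      }
      if (!is.finite(s_new)) { converged <- TRUE; break }   # no descent direction
      trace <- c(trace, s_new)
      if ((s - s_new) < tol * max(s, 1e-12)) { s <- s_new; converged <- TRUE; break }
      s <- s_new
    }
    list(x = x, stress = s, converged = converged, trace = trace)
  }

  starts <- vector("list", n_starts + 1L)
  start_seeds <- integer(n_starts + 1L)
  # PCoA-seeded start (deterministic)
  pc <- pcoa(d)
  x0 <- pc$coordinates
  if (ncol(x0) < k) {
    x0 <- cbind(x0, matrix(0, n, k - ncol(x0)))
  }
  starts[[1L]] <- one_start(x0[, seq_len(k), drop = FALSE])
  start_seeds[1L] <- NA_integer_
  for (s in seq_len(n_starts)) {
    ss <- derive_seed(seed %||% 0L, s)
    start_seeds[s + 1L] <- ss
    x0 <- local_seed(ss, matrix(stats::runif(n * k, -0.5, 0.5), n, k))
    starts[[s + 1L]] <- one_start(x0)
  }
  stresses <- vapply(starts, `[[`, numeric(1), "stress")
  best <- which.min(stresses)
  x <- starts[[best]]$x
  # centre and rotate to principal axes, fix axis signs
  x <- sweep(x, 2L, colMeans(x))
  x <- x %*% svd(x, nu = 0)$v
  for (j in seq_len(ncol(x))) {
    if (x[which.max(abs(x[, j])), j] < 0) x[, j] <- -x[, j]
  }
  dimnames(x) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(coordinates = x, stress = stresses[best],
                 n_starts = n_starts, converged = starts[[best]]$converged,
                 best_start = best, best_start_seed = start_seeds[best],
                 stress_by_start = stresses,
                 stress_trace = starts[[best]]$trace),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("nmds_result: %d samples, k = %d, stress = %.4f (%d starts)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              x$n_starts + 1L))
  invisible(x)
}

#' Procrustes superimposition of two configurations
#'
#' Both configurations are centred and, in symmetric mode, scaled to unit
#' sum of squares; the optimal rotation comes from the SVD of the
#' cross-product. The symmetric statistic is `m2 = 1 - (sum of singular
#' values)^2` and the Procrustes correlation is `sqrt(1 - m2)`.
#'
#' @param x,y numeric coordinate matrices with identical row labels (same
#'   samples, same order) and the same number of columns.
#' @param symmetric scale both configurations (default); if `FALSE`, `y` is
#'   rotated/scaled onto `x` and `m2` is the normalized residual sum of
#'   squares.
#' @return object of class `procrustes_result` with `m2`, `correlation`,
#'   `rotation` (orthogonal matrix applied to `y`), `p_value` (`NA` unless
#'   computed by [protest()]).
#' @export
procrustes <- function(x, y, symmetric = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stopf("configurations differ in shape")
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y))) {
    stopf("mismatched sample labels between configurations")
  }
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  ssx <- sum(xc^2); ssy <- sum(yc^2)
  if (ssx == 0 || ssy == 0) stopf("degenerate (constant) configuration")
  if (symmetric) {
    xc <- xc / sqrt(ssx)
    yc <- yc / sqrt(ssy)
    ssx <- ssy <- 1
  }
  sv <- svd(crossprod(xc, yc))
  trace_w <- sum(sv$d)
  m2 <- 1 - trace_w^2 / (ssx * ssy)
  m2 <- min(max(m2, 0), 1)
  structure(list(m2 = m2, correlation = sqrt(1 - m2),
                 rotation = sv$v %*% t(sv$u),
                 symmetric = symmetric, p_value = NA_real_),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("procrustes_result: m2 = %.4g, correlation = %.4f%s\n",
              x$m2, x$correlation,
              if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value)))
  invisible(x)
}

#' PROTEST: permutation test of Procrustes concordance
#'
#' The rows of `y` are permuted `n_perm` times; the p-value is
#' `(number of permuted correlations >= observed + 1) / (n_perm + 1)`.
#'
#' @inheritParams procrustes
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return a `procrustes_result` with `p_value` and `n_perm` filled in.
#' @export
protest <- function(x, y, n_perm = 1000L, seed = NULL, symmetric = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 4L) stopf("PROTEST requires at least 4 samples")
  obs <- procrustes(x, y, symmetric = symmetric)
  yr <- rownames(y)
  corr_perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- y[sample.int(n), , drop = FALSE]
      rownames(yp) <- yr
      procrustes(x, yp, symmetric = symmetric)$correlation
    }, numeric(1))
  })
  obs$p_value <- (sum(corr_perm >= obs$correlation - 1e-12) + 1) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}

#' Cross-rank consistency of ordination patterns
#'
#' Runs NMDS on each supplied table (e.g. the OTU table plus aggregations
#' at several taxonomic ranks, restricted to common samples), then compares
#' every pair of ordinations by [protest()] with Bonferroni correction over
#' the number of pairs.
#'
#' @param tables named list of [otu_table()]s sharing the same samples.
#' @param d_builder function turning a table into a [as_dissim()] matrix;
#'   default Hellinger + Bray-Curtis.
#' @param k,n_starts,n_perm,seed passed to [nmds()] / [protest()].
#' @return list with `ordinations`, and `comparisons`: data.frame of
#'   `level_a`, `level_b`, `correlation`, `p_value`, `p_bonferroni`.
#' @export
rank_consistency <- function(tables, d_builder = function(t) bray_curtis(hellinger(t)),
                             k = 2L, n_starts = 20L, n_perm = 1000L,
                             seed = NULL) {
  if (length(tables) < 2L) stopf("need at least 2 levels to compare")
  if (is.null(names(tables))) names(tables) <- paste0("level", seq_along(tables))
  common <- Reduce(intersect, lapply(tables, rownames))
  if (length(common) < 4L) stopf("fewer than 4 samples shared across levels")
  # common random numbers across levels: identical tables give identical
  # ordinations
  ords <- lapply(tables, function(t) {
    nmds(d_builder(t[common, , drop = FALSE]), k = k, n_starts = n_starts,
         seed = derive_seed(seed %||% 0L, 1L))
  })
  names(ords) <- names(tables)
  pairs <- utils::combn(length(tables), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(p) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    pr <- protest(ords[[a]]$coordinates, ords[[b]]$coordinates,
                  n_perm = n_perm, seed = derive_seed(seed %||% 0L, 1000L + p))
    data.frame(level_a = names(tables)[a], level_b = names(tables)[b],
               correlation = pr$correlation, m2 = pr$m2, p_value = pr$p_value,
               p_bonferroni = min(1, pr$p_value * n_pairs),
               stringsAsFactors = FALSE)
  })
  list(ordinations = ords, comparisons = do.call(rbind, rows))
}
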