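#' Redundancy analysis R-squared
#'
#' Multivariate least squares of the (column-centred) response on the
#' design matrix. `R2 = SS(fitted) / SS(total)`,
#' `adjR2 = 1 - (1 - R2) (n - 1) / (n - m - 1)` with `m = rank(x)`,
#' `pseudo-F = (SS_fit / m) / (SS_res / (n - m - 1))`.
#'
#' @param y numeric response matrix (samples x variables); centred
#'   internally.
#' @param x design matrix (samples x predictors) or `NULL`/zero-column for
#'   the empty design. Centred internally; collinear columns are handled by
#'   using the rank in the degrees of freedom.
#' @return list with `r2`, `adj_r2`, `pseudo_f`, `rank`, `df_residual`.
#' @export
rda_r2 <- function(y, x) {
  y <- as.matrix(y)
  n <- nrow(y)
  yc <- sweep(y, 2L, colMeans(y))
  ss_tot <- sum(yc^2)
  if (ss_tot == 0) stopf("response has no variance")
  if (is.null(x) || NCOL(x) == 0L) {
    return(list(r2 = 0, adj_r2 = 0, pseudo_f = NA_real_, rank = 0L,
                df_residual = n - 1L))
  }
  x <- as.matrix(x)
  if (nrow(x) != n) stopf("response and design have different sample counts")
  xc <- sweep(x, 2L, colMeans(x))
  qx <- qr(xc)
  m <- qx$rank
  if (m == 0L) {
    return(list(r2 = 0, adj_r2 = 0, pseudo_f = NA_real_, rank = 0L,
                df_residual = n - 1L))
  }
  if (n <= m + 1L) stopf("design too large: n = %d, rank = %d", n, m)
  fitted <- qr.fitted(qx, yc)
  ss_fit <- sum(fitted^2)
  r2 <- ss_fit / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  f <- (ss_fit / m) / ((ss_tot - ss_fit) / (n - m - 1))
  list(r2 = r2, adj_r2 = adj, pseudo_f = f, rank = m,
       df_residual = n - m - 1L)
}

#' Distance-based redundancy analysis R-squared
#'
#' PCoA of the dissimilarity matrix (positive eigenvalues kept), then
#' [rda_r2()] on the principal coordinates. For a Euclidean dissimilarity
#' computed from a response matrix this equals RDA on that matrix.
#'
#' @param d a [as_dissim()] matrix.
#' @param x design matrix (see [rda_r2()]).
#' @return as [rda_r2()].
#' @export
db_rda_r2 <- function(d, x) {
  rda_r2(pcoa(d, "keep_positive")$coordinates, x)
}

# response coordinates from either a matrix or a dissimilarity
response_coords <- function(y_or_d) {
  if (inherits(y_or_d, "dissim")) pcoa(y_or_d, "keep_positive")$coordinates
  else as.matrix(y_or_d)
}

#' Permutation test of a pure (partial) effect
#'
#' Residualizes both the response and the focal set `x` on the conditioning
#' sets `z`, then tests the partial pseudo-F by permutation. The default
#' scheme is Freedman-Lane: residuals of the reduced model (response ~ z)
#' are permuted and added back to the reduced-model fit; `"raw"` permutes
#' response rows directly. With an empty `z` this reduces to the
#' unconditioned [rda_r2()] test.
#'
#' @param y_or_d response matrix or a [as_dissim()] matrix (embedded by
#'   PCoA first, as in db-RDA).
#' @param x focal design matrix.
#' @param z conditioning design matrix (or `NULL`).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param scheme `"freedman_lane"` or `"raw"`.
#' @return list with `pure_adj_r2`, `pseudo_f`, `p_value`, `rank_x`,
#'   `rank_z`.
#' @export
partial_test <- function(y_or_d, x, z = NULL, n_perm = 1000L, seed = NULL,
                         scheme = c("freedman_lane", "raw")) {
  scheme <- match.arg(scheme)
  y <- response_coords(y_or_d)
  n <- nrow(y)
  yc <- sweep(y, 2L, colMeans(y))
  x <- as.matrix(x)
  have_z <- !is.null(z) && NCOL(z) > 0L
  if (have_z) {
    zc <- sweep(as.matrix(z), 2L, colMeans(as.matrix(z)))
    qz <- qr(zc)
    mz <- qz$rank
    fit_z <- qr.fitted(qz, yc)
    res_z <- yc - fit_z
    xc <- sweep(x, 2L, colMeans(x))
    xres <- xc - qr.fitted(qz, xc)
  } else {
    mz <- 0L
    fit_z <- matrix(0, n, ncol(yc))
    res_z <- yc
    xres <- sweep(x, 2L, colMeans(x))
  }
  qx <- qr(xres)
  mx <- qx$rank
  # a focal set numerically absorbed by the conditioning set leaves only
  # round-off in the residualized design; treat it as rank zero
  xc_ss <- sum(sweep(x, 2L, colMeans(x))^2)
  if (sum(xres^2) < 1e-10 * max(xc_ss, 1e-300)) mx <- 0L
  if (mx == 0L) {
    warnf("focal set is collinear with the conditioning set; pure effect empty")
    return(list(pure_adj_r2 = 0, pseudo_f = NA_real_, p_value = 1,
                rank_x = 0L, rank_z = mz))
  }
  df_res <- n - mz - mx - 1L
  if (df_res < 1L) stopf("no residual degrees of freedom")
  pf_of <- function(res) {
    # res: response residualized on z; partial F of x given z
    fit_x <- qr.fitted(qx, res)
    ss_fit <- sum(fit_x^2)
    ss_res <- sum(res^2) - ss_fit
    (ss_fit / mx) / (ss_res / df_res)
  }
  f_obs <- pf_of(res_z)
  f_perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      if (scheme == "freedman_lane") {
        ystar <- fit_z + res_z[p, , drop = FALSE]
      } else {
        ystar <- yc[p, , drop = FALSE]
      }
      if (have_z) {
        rs <- ystar - qr.fitted(qz, sweep(ystar, 2L, colMeans(ystar)))
      } else {
        rs <- sweep(ystar, 2L, colMeans(ystar))
      }
      pf_of(rs)
    }, numeric(1))
  })
  p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  # pure adjusted R2: adjR2(z + x) - adjR2(z)
  full <- rda_r2(yc, if (have_z) cbind(zc, x) else x)
  base <- if (have_z) rda_r2(yc, zc)$adj_r2 else 0
  list(pure_adj_r2 = full$adj_r2 - base, pseudo_f = f_obs, p_value = p,
       rank_x = mx, rank_z = mz)
}

#' Variation partitioning over 2-4 explanatory sets
#'
#' Fits the adjusted R-squared of every union of sets, recovers all Venn
#' fractions (pure and shared) by solving the inclusion-exclusion system
#' exactly, and tests each pure fraction with [partial_test()]. Shared
#' fractions are reported untested: they are deduced numerically, not
#' fitted, and may be negative (an adjusted R-squared artefact, reported
#' as-is).
#'
#' @param y_or_d response matrix or [as_dissim()] matrix.
#' @param sets named list of 2-4 design matrices, rows aligned to samples.
#' @param n_perm permutations for the pure-effect tests.
#' @param seed integer seed.
#' @return object of class `varpart_result`: `fractions` (data.frame with
#'   `fraction` label, `sets`, `adj_r2`, `pseudo_f`, `p_value`; pure
#'   fractions first, then shared, then `unexplained`), `full_adj_r2`,
#'   `union_adj_r2` (per-union fits).
#' @export
variation_partition <- function(y_or_d, sets, n_perm = 1000L, seed = NULL) {
  k <- length(sets)
  if (k < 1L || k > 4L) stopf("1-4 explanatory sets supported (got %d)", k)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_len(k))
  }
  y <- response_coords(y_or_d)
  sets <- lapply(sets, as.matrix)
  ns <- vapply(sets, nrow, integer(1))
  if (any(ns != nrow(y))) stopf("sets not aligned to samples")

  subsets <- lapply(seq_len(2^k - 1L), function(code) {
    which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
  })
  a_union <- vapply(subsets, function(s) {
    rda_r2(y, do.call(cbind, sets[s]))$adj_r2
  }, numeric(1))
  full <- a_union[[length(a_union)]]

  # regions r_T (T = nonempty subset of sets); A(U) = sum over T with
  # T intersecting U of r_T. Solve the linear system exactly.
  m <- length(subsets)
  mat <- matrix(0, m, m)
  for (u in seq_len(m)) {
    for (t in seq_len(m)) {
      if (length(intersect(subsets[[u]], subsets[[t]]))) mat[u, t] <- 1
    }
  }
  regions <- solve(mat, a_union)

  region_label <- function(s) paste(names(sets)[s], collapse = "+")
  labels <- vapply(subsets, region_label, character(1))
  sizes <- lengths(subsets)
  df <- data.frame(fraction = ifelse(sizes == 1L, "pure", "shared"),
                   sets = labels, adj_r2 = regions,
                   pseudo_f = NA_real_, p_value = NA_real_,
                   stringsAsFactors = FALSE)
  # test pure fractions: each set conditioned on the union of the others
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    z <- if (length(others)) do.call(cbind, sets[others]) else NULL
    pt <- partial_test(y, sets[[i]], z, n_perm = n_perm,
                       seed = derive_seed(seed %||% 0L, i))
    row <- which(sizes == 1L & labels == names(sets)[i])
    df$pseudo_f[row] <- pt$pseudo_f
    df$p_value[row] <- pt$p_value
  }
  df <- df[order(sizes, df$sets), ]
  df <- rbind(df, data.frame(fraction = "unexplained", sets = "",
                             adj_r2 = 1 - full, pseudo_f = NA_real_,
                             p_value = NA_real_, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(list(fractions = df, full_adj_r2 = full,
                 union_adj_r2 = setNames(a_union, labels)),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("varpart_result: full-model adjusted R2 = %.4f\n", x$full_adj_r2))
  print(transform(x$fractions, adj_r2 = round(adj_r2, 4)))
  invisible(x)
}

#' Build explanatory sets from sample metadata
#'
#' Constructs the four classic explanatory sets: `ecosystem` (dummy-coded
#' ecosystem type, reference level dropped), `space` (principal coordinates
#' of the great-circle distance matrix plus water depth), `time` (days
#' since the earliest sampling) and `productivity` (Longhurst productivity
#' index and/or capture-fisheries yield class, integer-coded). Constant
#' columns are dropped with a warning; each set is pruned to full column
#' rank.
#'
#' @param meta classified metadata (see [classify_ecosystem()]) in the
#'   sample order of the response.
#' @param spatial_axes `"all_positive"` (all positive-eigenvalue PCoA axes
#'   of the geodesic matrix) or `"first_k"`.
#' @param k_spatial number of axes when `spatial_axes = "first_k"`.
#' @param productivity which productivity proxies enter the set.
#' @param include_depth include water depth in the space set.
#' @return named list of design matrices (class `explanatory_sets`).
#' @export
build_design <- function(meta, spatial_axes = c("all_positive", "first_k"),
                         k_spatial = 2L,
                         productivity = c("both", "longhurst", "fisheries"),
                         include_depth = TRUE) {
  spatial_axes <- match.arg(spatial_axes)
  productivity <- match.arg(productivity)
  if (is.null(meta$ecosystem)) meta <- classify_ecosystem(meta)
  n <- nrow(meta)

  eco <- droplevels(meta$ecosystem)
  if (nlevels(eco) < 2L) {
    warnf("single ecosystem level; ecosystem set is empty")
    eco_m <- matrix(numeric(0), n, 0L)
  } else {
    eco_m <- stats::model.matrix(~eco)[, -1L, drop = FALSE]
    colnames(eco_m) <- sub("^eco", "ecosystem_", colnames(eco_m))
  }

  gc <- great_circle(meta)
  pc <- pcoa(gc, "keep_positive")
  sp <- pc$coordinates
  if (spatial_axes == "first_k") {
    sp <- sp[, seq_len(min(k_spatial, ncol(sp))), drop = FALSE]
  }
  colnames(sp) <- paste0("space_", seq_len(ncol(sp)))
  if (include_depth) sp <- cbind(sp, water_depth = meta$water_depth)

  tm <- matrix(days_since_first(meta), ncol = 1L,
               dimnames = list(NULL, "days_since_first"))

  pr <- switch(productivity,
    both = cbind(longhurst = as.numeric(meta$longhurst_productivity),
                 fisheries = as.numeric(meta$fisheries_class)),
    longhurst = cbind(longhurst = as.numeric(meta$longhurst_productivity)),
    fisheries = cbind(fisheries = as.numeric(meta$fisheries_class)))

  prune <- function(m, what) {
    if (!ncol(m)) return(m)
    keep <- apply(m, 2L, function(col) stats::sd(col) > 0)
    if (!all(keep)) {
      warnf("dropping constant column(s) from %s set: %s", what,
            paste(colnames(m)[!keep], collapse = ", "))
      m <- m[, keep, drop = FALSE]
    }
    if (ncol(m) > 1L) {
      q <- qr(sweep(m, 2L, colMeans(m)))
      if (q$rank < ncol(m)) {
        drop <- q$pivot[(q$rank + 1L):ncol(m)]
        warnf("dropping collinear column(s) from %s set: %s", what,
              paste(colnames(m)[drop], collapse = ", "))
        m <- m[, -drop, drop = FALSE]
      }
    }
    m
  }
  sets <- list(ecosystem = prune(eco_m, "ecosystem"),
               space = prune(sp, "space"),
               time = prune(tm, "time"),
               productivity = prune(pr, "productivity"))
  structure(sets, class = c("explanatory_sets", "list"))
}
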