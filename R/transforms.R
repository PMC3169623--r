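#' Labelled dissimilarity matrices
#'
#' A `dissim` is a symmetric numeric matrix with zero diagonal,
#' non-negative entries and sample ids as dimnames.
#'
#' @param m square numeric matrix with matching dimnames.
#' @return object of class `dissim`.
#' @export
as_dissim <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("not a square matrix")
  if (is.null(rownames(m))) stopf("dissimilarity matrix must carry labels")
  if (!identical(rownames(m), colnames(m))) stopf("row/column labels differ")
  if (max(abs(m - t(m))) > 1e-12) stopf("matrix is not symmetric")
  if (any(m < 0)) stopf("negative dissimilarities")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, class = c("dissim", "matrix", "array"))
}

#' @export
print.dissim <- function(x, ...) {
  cat(sprintf("dissim: %d samples, range [%.4g, %.4g]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

# lower-triangle vector in dist() order
dissim_vec <- function(d) d[lower.tri(d)]

#' Write / read a dissimilarity matrix as labelled square TSV
#' @param d a `dissim`.
#' @param path file path.
#' @export
write_dissim <- function(d, path) {
  df <- data.frame(sample_id = rownames(d),
                   as.data.frame(unclass(d), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissim
#' @export
read_dissim <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  as_dissim(m)
}

#' Hellinger transformation
#'
#' Square root of relative abundance per sample: entry
#' `sqrt(count / row total)`, so each row has unit sum of squares. This
#' makes Bray-Curtis (and Euclidean) geometry insensitive to sequencing
#' depth.
#'
#' @param t an [otu_table()] or non-negative matrix with positive row sums.
#' @return numeric matrix of the same shape.
#' @export
hellinger <- function(t) {
  m <- unclass(t)
  rs <- rowSums(m)
  if (any(rs <= 0)) stopf("zero-total sample(s): %s",
                          paste(rownames(m)[rs <= 0], collapse = ", "))
  out <- sqrt(m / rs)
  dimnames(out) <- dimnames(m)
  out
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = sum |x_k - y_k| / sum (x_k + y_k)`, bounded in [0, 1] for
#' non-negative data. On presence/absence data this equals one minus the
#' Sorensen similarity.
#'
#' @param m non-negative abundance matrix (samples x taxa), e.g. the output
#'   of [hellinger()].
#' @return a [as_dissim()] matrix.
#' @export
bray_curtis <- function(m) {
  m <- unclass(m)
  if (any(m < 0)) stopf("Bray-Curtis requires non-negative data")
  rs <- rowSums(m)
  if (sum(rs == 0) >= 2L) stopf("Bray-Curtis undefined between all-zero samples")
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  den <- outer(rs, rs, "+")
  d <- num / den
  d[den == 0] <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  as_dissim(d)
}

#' Great-circle distances between samples
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0 km.
#'
#' @param meta metadata with `sample_id`, `latitude`, `longitude`.
#' @return a [as_dissim()] matrix in kilometres.
#' @export
great_circle <- function(meta) {
  lat <- meta$latitude * pi / 180
  lon <- meta$longitude * pi / 180
  n <- length(lat)
  R <- 6371.0
  dlat <- outer(lat, lat, "-") / 2
  dlon <- outer(lon, lon, "-") / 2
  a <- sin(dlat)^2 + outer(cos(lat), cos(lat)) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  d <- 2 * R * asin(sqrt(a))
  ids <- as.character(meta$sample_id)
  dimnames(d) <- list(ids, ids)
  as_dissim(d)
}

#' Principal coordinates analysis
#'
#' Gower double-centring of `-d^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are reported.
#' `keep_positive` (default) retains axes with eigenvalues above
#' `1e-8 * lambda_1`; `"lingoes"` adds the Lingoes constant to squared
#' off-diagonal dissimilarities first, making all eigenvalues non-negative.
#'
#' @param d a [as_dissim()] matrix.
#' @param negative_eig `"keep_positive"` or `"lingoes"`.
#' @return list of class `pcoa_result`: `coordinates` (samples x axes,
#'   centred, ordered by decreasing eigenvalue), `eigenvalues` (all, may
#'   include negatives), `prop_explained` (per retained axis, relative to
#'   the positive eigenvalue sum), `correction`.
#' @export
pcoa <- function(d, negative_eig = c("keep_positive", "lingoes")) {
  negative_eig <- match.arg(negative_eig)
  d <- as_dissim(unclass(d))
  n <- nrow(d)
  gower <- function(d2) {
    a <- -d2 / 2
    rm <- rowMeans(a)
    a - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(a)
  }
  g <- gower(unclass(d)^2)
  e <- eigen(g, symmetric = TRUE)
  if (negative_eig == "lingoes" && min(e$values) < -1e-8 * max(e$values, 1e-300)) {
    cc <- -min(e$values)
    d2 <- unclass(d)^2 + 2 * cc
    diag(d2) <- 0
    g <- gower(d2)
    e <- eigen(g, symmetric = TRUE)
  }
  ev <- e$values
  if (max(ev) <= 0) {  # all-zero (or degenerate) dissimilarity matrix
    coords <- matrix(0, n, 1L, dimnames = list(rownames(d), "PCo1"))
    return(structure(list(coordinates = coords, eigenvalues = ev,
                          prop_explained = 1, correction = negative_eig),
                     class = "pcoa_result"))
  }
  keep <- which(ev > 1e-8 * ev[1L])
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), length(keep))
  coords <- sweep(coords, 2L, colMeans(coords))  # numerically re-centre
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_along(keep)))
  pos_sum <- sum(ev[ev > 0])
  structure(list(coordinates = coords, eigenvalues = ev,
                 prop_explained = ev[keep] / pos_sum,
                 correction = negative_eig),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes (%d negative eigenvalues)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              sum(x$eigenvalues < -1e-12 * max(abs(x$eigenvalues)))))
  invisible(x)
}

# PCoA embedding that keeps positive- and negative-eigenvalue axes apart;
# used by beta_dispersion (Anderson's construction).
pcoa_signed <- function(d) {
  d <- as_dissim(unclass(d))
  n <- nrow(d)
  a <- -unclass(d)^2 / 2
  rm <- rowMeans(a)
  g <- a - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1e-300)
  pos <- e$values > tol
  neg <- e$values < -tol
  list(
    pos = e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos)),
    neg = e$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-e$values[neg]), sum(neg)))
}
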