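test_that("rda_r2 hits closed forms and the hat-matrix oracle", {
  x <- withr::with_seed(1, matrix(rnorm(60), 30, 2))
  b <- matrix(c(1, -2, 0.5, 3), 2, 2)
  y <- x %*% b
  expect_equal(rda_r2(y, x)$r2, 1, tolerance = 1e-12)
  # empty design
  e <- rda_r2(y, NULL)
  expect_equal(e$r2, 0)
  expect_equal(e$adj_r2, 0)
  # orthogonal design explains nothing, adjusted R2 may dip below 0
  y2 <- withr::with_seed(2, matrix(rnorm(60), 30, 2))
  xo <- withr::with_seed(3, {
    z <- matrix(rnorm(60), 30, 2)
    yc <- sweep(y2, 2, colMeans(y2))
    zc <- sweep(z, 2, colMeans(z))
    zc - yc %*% solve(crossprod(yc)) %*% crossprod(yc, zc)
  })
  ro <- rda_r2(y2, xo)
  expect_lt(ro$r2, 1e-12)
  expect_lt(ro$adj_r2, 0)
  # random instances match the brute-force projection oracle
  for (s in 1:10) {
    ys <- withr::with_seed(s, matrix(rnorm(25 * 4), 25, 4))
    xs <- withr::with_seed(s + 30, matrix(rnorm(25 * 3), 25, 3))
    expect_equal(rda_r2(ys, xs)$r2, rda_oracle_r2(ys, xs), tolerance = 1e-10)
  }
})

test_that("db-RDA equals RDA for Euclidean dissimilarities", {
  for (s in 1:5) {
    y <- withr::with_seed(s, matrix(rnorm(20 * 6), 20, 6))
    rownames(y) <- paste0("s", 1:20)
    x <- withr::with_seed(s + 60, matrix(rnorm(20 * 2), 20, 2))
    d <- as_dissim(as.matrix(dist(y)))
    expect_equal(db_rda_r2(d, x)$r2, rda_r2(y, x)$r2, tolerance = 1e-8)
    expect_equal(db_rda_r2(d, x)$adj_r2, rda_r2(y, x)$adj_r2,
                 tolerance = 1e-8)
  }
})

test_that("db-RDA on pure-noise designs centres on zero adjusted R2", {
  vals <- vapply(1:40, function(s) {
    y <- withr::with_seed(s, matrix(rnorm(30 * 5), 30, 5))
    rownames(y) <- paste0("s", 1:30)
    x <- withr::with_seed(s + 500, matrix(rnorm(30 * 2), 30, 2))
    db_rda_r2(as_dissim(as.matrix(dist(y))), x)$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("partial_test reduces, confounds and permutes correctly", {
  y <- withr::with_seed(4, matrix(rnorm(30 * 3), 30, 3))
  x <- withr::with_seed(5, matrix(rnorm(30 * 2), 30, 2))
  # empty conditioning set reduces to the unconditioned test
  pt <- partial_test(y, x, NULL, n_perm = 99, seed = 1)
  expect_equal(pt$pure_adj_r2, rda_r2(y, x)$adj_r2, tolerance = 1e-12)
  expect_equal(pt$pseudo_f, rda_r2(y, x)$pseudo_f, tolerance = 1e-12)
  # focal set duplicated inside the conditioning set: nothing left
  expect_warning(pc <- partial_test(y, x, cbind(x, rnorm(30)), n_perm = 49,
                                    seed = 2), "collinear")
  expect_equal(pc$pure_adj_r2, 0, tolerance = 1e-10)
  expect_equal(pc$p_value, 1)
  # p-values on the permutation grid
  z <- withr::with_seed(6, matrix(rnorm(30), 30, 1))
  pz <- partial_test(y, x, z, n_perm = 99, seed = 3)
  expect_true(pz$p_value %in% (1:100 / 100))
})

test_that("variation partitioning closes exactly and handles edge cases", {
  y <- withr::with_seed(7, matrix(rnorm(40 * 4), 40, 4))
  sets <- list(a = withr::with_seed(8, matrix(rnorm(80), 40, 2)),
               b = withr::with_seed(9, matrix(rnorm(40), 40, 1)),
               c = withr::with_seed(10, matrix(rnorm(80), 40, 2)))
  vp <- variation_partition(y, sets, n_perm = 49, seed = 1)
  fr <- vp$fractions
  explained <- fr$adj_r2[fr$fraction != "unexplained"]
  expect_equal(sum(explained), vp$full_adj_r2, tolerance = 1e-10)
  expect_equal(fr$adj_r2[fr$fraction == "unexplained"], 1 - vp$full_adj_r2,
               tolerance = 1e-12)
  expect_equal(nrow(fr), 2^3 - 1 + 1)
  # single set: pure fraction equals its adjusted R2
  vp1 <- variation_partition(y, sets["a"], n_perm = 49, seed = 2)
  expect_equal(vp1$fractions$adj_r2[1], rda_r2(y, sets$a)$adj_r2,
               tolerance = 1e-12)
  # more than four sets unsupported
  five <- c(sets, list(d = sets$b, e = sets$b))
  expect_error(variation_partition(y, five), "1-4")
  # works on dissimilarity input too, with the same closure
  rownames(y) <- paste0("s", 1:40)
  vpd <- variation_partition(as_dissim(as.matrix(dist(y))), sets,
                             n_perm = 49, seed = 3)
  frd <- vpd$fractions
  expect_equal(sum(frd$adj_r2[frd$fraction != "unexplained"]),
               vpd$full_adj_r2, tolerance = 1e-10)
})

test_that("orthogonal explanatory sets have near-zero shared fraction", {
  n <- 60
  xa <- withr::with_seed(11, qr.Q(qr(matrix(rnorm(n * 4), n, 4))))
  a <- xa[, 1:2]; b <- xa[, 3:4]   # exactly orthogonal sets
  y <- a %*% matrix(c(2, 0, 0, 1), 2) + b %*% matrix(c(0, 1.5, 1, 0), 2) +
    withr::with_seed(12, matrix(rnorm(n * 2, 0, 0.3), n, 2))
  vp <- variation_partition(y, list(a = a, b = b), n_perm = 49, seed = 4)
  fr <- vp$fractions
  shared <- fr$adj_r2[fr$fraction == "shared"]
  expect_lt(abs(shared), 0.02)
  pure_a <- fr$adj_r2[fr$fraction == "pure" & fr$sets == "a"]
  expect_lt(abs(pure_a - rda_r2(y, a)$adj_r2), 0.02)
})

test_that("build_design constructs the four sets from metadata", {
  sim <- small_world(seed = 19)
  sets <- build_design(sim$metadata)
  # 4 ecosystems in the small world: 3 dummies after dropping the reference
  expect_equal(ncol(sets$ecosystem),
               nlevels(droplevels(sim$metadata$ecosystem)) - 1L)
  expect_true("water_depth" %in% colnames(sets$space))
  expect_equal(colnames(sets$time), "days_since_first")
  expect_equal(ncol(sets$productivity), 2L)
  expect_equal(ncol(build_design(sim$metadata,
                                 productivity = "longhurst")$productivity), 1L)
  # meridian transect: the leading spatial axis is latitude
  meta <- tiny_meta()[rep(1, 20), ]
  meta$sample_id <- sprintf("m%02d", 1:20)
  meta$latitude <- seq(-60, 60, length.out = 20)
  meta$longitude <- 0
  meta$date <- "2003-06-14"
  meta <- classify_ecosystem(validate_metadata(meta))
  w <- capture_warnings(sets_m <- build_design(meta, spatial_axes = "first_k",
                                               k_spatial = 2))
  expect_true(any(grepl("constant|single", w)))
  expect_gt(abs(cor(sets_m$space[, 1], meta$latitude)), 0.99)
  # constant date: time set emptied with a warning
  expect_equal(ncol(sets_m$time), 0L)
})
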