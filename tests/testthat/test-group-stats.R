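test_that("inverse Simpson hits its closed forms", {
  expect_equal(inverse_simpson(rep(5, 7)), 7)
  expect_equal(inverse_simpson(c(9, 0, 0)), 1)
  expect_equal(inverse_simpson(c(3, 1)), 1.6)   # 1 / (0.5625 + 0.0625)
  expect_error(inverse_simpson(c(0, 0)), "empty")
  m <- rbind(a = c(1, 1), b = c(4, 0))
  expect_equal(unname(inverse_simpson(m)), c(2, 1))
})

test_that("Mann-Whitney exact p matches enumeration and wilcox.test", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "exact")
  # identical samples: p = 1
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  # symmetry under argument swap
  x <- c(1.2, 5.3, 2.2, 8); y <- c(0.5, 3.3, 9.1, 4.4, 6)
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value)
  # against R's exact wilcoxon on tie-free data
  for (s in 1:5) {
    xs <- withr::with_seed(s, rnorm(6))
    ys <- withr::with_seed(s + 50, rnorm(8, 0.5))
    expect_equal(mann_whitney(xs, ys)$p_value,
                 wilcox.test(xs, ys, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation matches wilcox.test with ties", {
  for (s in 1:5) {
    xs <- withr::with_seed(s, round(rnorm(12), 1))
    ys <- withr::with_seed(s + 80, round(rnorm(15, 0.3), 1))
    mine <- mann_whitney(xs, ys)
    expect_equal(mine$method, "normal_approximation")
    ref <- suppressWarnings(wilcox.test(xs, ys, exact = FALSE,
                                        correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("ANOSIM R equals 1 for complete separation and matches oracles", {
  # two groups with all between-dissimilarities above all within
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1; d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(as_dissim(d), g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  # rank-formula result equals brute-force oracle on random instances
  for (s in 1:8) {
    m <- withr::with_seed(s, matrix(rexp(8 * 5), 8, 5))
    rownames(m) <- paste0("x", 1:8)
    dr <- bray_curtis(m)
    gr <- rep(c("a", "b"), each = 4)
    expect_equal(anosim(dr, gr, n_perm = 9, seed = 1)$R,
                 anosim_oracle_R(unclass(dr), gr), tolerance = 1e-12)
  }
  # cross-check against vegan's implementation
  m <- withr::with_seed(99, matrix(rexp(60), 10, 6,
                                   dimnames = list(paste0("v", 1:10), NULL)))
  dv <- bray_curtis(m)
  gv <- rep(c("a", "b"), each = 5)
  ref <- vegan::anosim(as.dist(unclass(dv)), gv, permutations = 9)
  expect_equal(anosim(dv, gv, n_perm = 9, seed = 1)$R,
               unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM p-values live on the permutation grid and R is label-stable", {
  m <- withr::with_seed(21, matrix(rexp(10 * 6), 10, 6))
  rownames(m) <- paste0("s", 1:10)
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 5)
  r1 <- anosim(d, g, n_perm = 99, seed = 5)
  r2 <- anosim(d, g, n_perm = 99, seed = 1234)
  expect_true(r1$p_value %in% (1:100 / 100))
  expect_identical(r1$R, r2$R)
  expect_error(anosim(d, c("a", rep("b", 9)), n_perm = 9), "size 1")
  expect_error(anosim(d, g, n_perm = 0), "n_perm")
})

test_that("pairwise ANOSIM applies Bonferroni over pairs", {
  sim <- small_world(seed = 21)
  d <- bray_curtis(hellinger(sim$table))
  g <- realm_ecosystem(sim$metadata)
  pw <- pairwise_anosim(d, g, n_perm = 49, seed = 2)
  k <- choose(length(unique(g)), 2)
  expect_equal(nrow(pw), k)
  expect_equal(pw$p_bonferroni, pmin(1, pw$p_value * k))
  # duplicated identical groups have R near 0
  dd <- unclass(d)[1:12, 1:12]
  gdup <- rep(c("g1", "g2"), 6)
  r <- anosim(as_dissim(dd), gdup, n_perm = 99, seed = 3)
  expect_lt(abs(r$R), 0.35)
})

test_that("beta dispersion reduces to Euclidean distances on planar data", {
  pts <- withr::with_seed(31, matrix(rnorm(40), 20, 2))
  rownames(pts) <- paste0("p", 1:20)
  d <- as_dissim(as.matrix(dist(pts)))
  g <- rep(c("a", "b"), each = 10)
  disp <- beta_dispersion(d, g)
  for (lev in c("a", "b")) {
    idx <- which(g == lev)
    centroid <- colMeans(pts[idx, ])
    ref <- sqrt(rowSums(sweep(pts[idx, ], 2, centroid)^2))
    expect_equal(unname(disp$distances[idx]), unname(ref), tolerance = 1e-8)
  }
  # identical samples collapse to zero dispersion
  m <- rbind(s1 = c(3, 1), s2 = c(3, 1), s3 = c(3, 1), s4 = c(1, 5),
             s5 = c(2, 5), s6 = c(1, 6))
  dz <- bray_curtis(m)
  dd <- beta_dispersion(dz, rep(c("same", "diff"), each = 3))
  expect_equal(unname(dd$distances[1:3]), rep(0, 3), tolerance = 1e-12)
  # ordering of samples does not change distances
  perm <- withr::with_seed(8, sample(20))
  disp_p <- beta_dispersion(as_dissim(unclass(d)[perm, perm]), g[perm])
  expect_equal(disp_p$distances[rownames(d)], disp$distances,
               tolerance = 1e-10)
})

test_that("noisier groups show larger dispersion", {
  hits <- 0L
  for (s in 1:10) {
    base <- withr::with_seed(s, matrix(rexp(15 * 30, 1), 15, 30))
    noisy <- withr::with_seed(s + 200, {
      b <- matrix(rexp(15 * 30, 1), 15, 30)
      b * matrix(exp(rnorm(15 * 30, 0, 1.5)), 15, 30)
    })
    m <- rbind(base, noisy)
    rownames(m) <- paste0("s", 1:30)
    d <- bray_curtis(hellinger(m))
    g <- rep(c("tight", "noisy"), each = 15)
    disp <- beta_dispersion(d, g)
    mw <- mann_whitney(disp$distances[g == "noisy"],
                       disp$distances[g == "tight"],
                       alternative = "greater")
    if (mw$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
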