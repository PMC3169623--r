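test_that("shared-OTU extremes: identical groups 100%, disjoint pools 0%", {
  m <- withr::with_seed(1, matrix(rpois(6 * 20, 4), 6, 20))
  dimnames(m) <- list(paste0("s", 1:6), paste0("o", 1:20))
  m[m == 0] <- 1L   # every OTU present everywhere
  t <- otu_table(m)
  res <- shared_otus(t, rep(c("a", "b"), each = 3), n_iter = 5, seed = 1)
  expect_equal(res$pairs$pct_mean, 100)
  expect_equal(res$pairs$pct_sd, 0)

  sim0 <- small_world(seed = 4, realm_overlap = 0)
  r0 <- shared_otus(sim0$table, sim0$truth$realm, n_iter = 5, seed = 2)
  expect_equal(r0$pairs$shared_mean, 0)
  expect_equal(r0$pairs$pct_mean, 0)
})

test_that("shared-OTU resampling is seed-reproducible with zero sd at full draw", {
  sim <- small_world(seed = 6)
  g <- sim$truth$realm
  r1 <- shared_otus(sim$table, g, n_iter = 3, seed = 9)
  r2 <- shared_otus(sim$table, g, n_iter = 3, seed = 9)
  expect_identical(r1$pairs, r2$pairs)
  # equal group sizes: the subsample is the full group, sd must be 0
  idx <- c(which(g == "pelagic")[1:10], which(g == "benthic")[1:10])
  t_eq <- sim$table[idx, ]
  t_eq <- otu_table(unclass(t_eq)[, colSums(t_eq) > 0, drop = FALSE])
  r_eq <- shared_otus(t_eq, g[idx], n_iter = 4, seed = 1)
  expect_equal(r_eq$pairs$shared_sd, 0)
  expect_equal(r_eq$pairs$pct_sd, 0)
})

test_that("equal_sequences design rarefies to the smaller group total", {
  sim <- small_world(seed = 7)
  g <- sim$truth$realm
  r <- shared_otus(sim$table, g, n_iter = 3, design = "equal_sequences",
                   seed = 5)
  expect_true(all(r$pairs$pct_mean >= 0 & r$pairs$pct_mean <= 100))
  expect_identical(r$design, "equal_sequences")
})

test_that("balanced ANOSIM degenerates to the plain result at full group size", {
  sim <- small_world(seed = 10)
  g <- sim$truth$realm
  n_min <- min(table(g))
  idx <- c(which(g == "pelagic")[seq_len(n_min)],
           which(g == "benthic")[seq_len(n_min)])
  t_bal <- otu_table(unclass(sim$table)[idx, colSums(sim$table[idx, ]) > 0,
                                        drop = FALSE])
  gb <- g[idx]
  res <- balanced_anosim(t_bal, gb, n_per_group = n_min, n_iter = 3,
                         n_perm = 49, seed = 2)
  expect_equal(length(unique(round(res$R, 12))), 1L)
  plain <- anosim(bray_curtis(hellinger(t_bal)), gb, n_perm = 49, seed = 2)
  expect_equal(unique(res$R), plain$R, tolerance = 1e-12)
  expect_error(balanced_anosim(t_bal, gb, n_per_group = n_min + 1,
                               n_iter = 2, n_perm = 9),
               "smaller than n_per_group")
})

test_that("balanced ANOSIM is calibrated on structureless data and powered on real signal", {
  # null: one pool, no effects, labels are arbitrary halves
  null <- generate_community(sim_params(
    n_otus_pool = 600L, realm_overlap = 1,
    n_samples = c("pelagic:coastal" = 16L, "benthic:coastal" = 16L),
    ecosystem_effect_size = 0, spatial_effect_size = 0,
    productivity_effect_size = 0, time_effect_size = 0,
    sample_noise_sd = 0, evenness_contrast = 1,
    sequencing_depth_mean = 2000, seed = 31))
  rn <- balanced_anosim(null$table, null$truth$realm, n_per_group = 12,
                        n_iter = 30, n_perm = 49, seed = 3)
  expect_lt(abs(mean(rn$R)), 0.06)
  # strong realm structure: all iterations significant, tight R range
  sim <- small_world(seed = 13)
  rs <- balanced_anosim(sim$table, sim$truth$realm, n_per_group = 15,
                        n_iter = 10, n_perm = 99, seed = 4)
  expect_equal(rs$fraction_significant, 1)
  expect_gt(min(rs$R), 0.5)
})

test_that("weight sensitivity: identity at w = 1 and Hellinger invariance", {
  sim <- small_world(seed = 14)
  g <- sim$truth$realm
  t <- sim$table
  ws <- weight_sensitivity(t, g, weights = c(0.1, 1, 10), mode = "hellinger",
                           n_perm = 99, seed = 7)
  base <- anosim(bray_curtis(hellinger(t)), g, n_perm = 99, seed = 7)
  # w = 1 reproduces the unweighted analysis bit for bit
  expect_identical(ws$R[ws$weight == 1], base$R)
  expect_identical(ws$p_value[ws$weight == 1], base$p_value)
  # composition pipeline is scale-invariant: R constant in w
  expect_equal(diff(range(ws$R)), 0, tolerance = 1e-12)
  # raw mode lets the weights bite but keeps strong separation
  wr <- weight_sensitivity(t, g, weights = c(0.1, 1, 10), mode = "raw",
                           n_perm = 99, seed = 7)
  expect_gt(length(unique(round(wr$R, 10))), 1L)
  expect_true(all(wr$R > 0.5))
  expect_error(weight_sensitivity(t, g, weights = c(0, 1)), "positive")
})

test_that("robustness comparisons hit their trivial fixed points", {
  # no singletons (every count is 0 or >= 2): with/without variant is the
  # same input; zeros keep the presence/absence variant informative
  m <- withr::with_seed(2, matrix(rpois(8 * 30, 2), 8, 30))
  m[m == 1L] <- 2L
  m <- m[, colSums(m) > 0]
  dimnames(m) <- list(paste0("s", 1:8), paste0("o", seq_len(ncol(m))))
  t <- otu_table(m)
  expect_length(singleton_ids(t), 0L)
  res <- robustness_procrustes(t, n_starts = 4, n_perm = 49, seed = 1)
  row <- res[res$comparison == "with_vs_without_singletons", ]
  expect_equal(row$correlation, 1, tolerance = 1e-8)
  # all-binary table: abundance and presence/absence variants coincide
  b <- withr::with_seed(3, matrix(rbinom(8 * 40, 1, 0.4), 8, 40))
  dimnames(b) <- list(paste0("s", 1:8), paste0("o", 1:40))
  b[rowSums(b) == 0, 1] <- 1L
  b <- b[, colSums(b) > 0]
  tb <- otu_table(b)
  res_b <- robustness_procrustes(tb, n_starts = 4, n_perm = 49, seed = 2)
  row_b <- res_b[res_b$comparison == "abundance_vs_presence_absence", ]
  expect_equal(row_b$correlation, 1, tolerance = 1e-6)
})
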