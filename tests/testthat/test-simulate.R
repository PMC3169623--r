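test_that("generation is strictly reproducible for a fixed seed", {
  s1 <- small_world(seed = 42)
  s2 <- small_world(seed = 42)
  expect_identical(unclass(s1$table), unclass(s2$table))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$taxonomy, s2$taxonomy)
  # byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_community(s1, d1); write_community(s2, d2)
  for (f in c("otu_table.tsv", "metadata.tsv", "taxonomy.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- small_world(seed = 43)
  expect_false(identical(unclass(s1$table), unclass(s3$table)))
})

test_that("realm pools respect the overlap construction", {
  sim0 <- small_world(seed = 3, realm_overlap = 0)
  expect_length(intersect(sim0$truth$pools$pelagic, sim0$truth$pools$benthic),
                0L)
  # no OTU observed in both realms
  realm <- sim0$truth$realm
  pel <- colSums(unclass(sim0$table)[realm == "pelagic", , drop = FALSE]) > 0
  ben <- colSums(unclass(sim0$table)[realm == "benthic", , drop = FALSE]) > 0
  expect_equal(sum(pel & ben), 0L)

  sim7 <- small_world(seed = 3, realm_overlap = 0.1)
  np <- sim7$truth$params$n_otus_pool
  expect_length(sim7$truth$pools$shared, round(0.1 * np))
  expect_length(union(sim7$truth$pools$pelagic, sim7$truth$pools$benthic), np)
})

test_that("expected relative abundances sum to one before sampling", {
  sim <- small_world(seed = 5)
  expect_equal(unname(rowSums(sim$truth$expected_prop)),
               rep(1, nrow(sim$truth$expected_prop)), tolerance = 1e-9)
  # and are supported exactly on the realm pool
  realm <- sim$truth$realm
  for (r in c("pelagic", "benthic")) {
    off_pool <- setdiff(colnames(sim$truth$expected_prop),
                        sim$truth$pools[[r]])
    block <- sim$truth$expected_prop[realm == r, off_pool, drop = FALSE]
    expect_equal(max(block), 0)
  }
})

test_that("metadata classification matches the generator's intent", {
  sim <- small_world(seed = 11)
  expect_identical(as.character(sim$metadata$realm),
                   unname(sim$truth$realm))
  expect_identical(as.character(sim$metadata$ecosystem),
                   unname(sim$truth$ecosystem))
  # generated taxonomy satisfies the prefix-annotation invariant
  expect_silent(validate_taxonomy(sim$taxonomy))
})

test_that("evenness contrast moves inverse Simpson monotonically", {
  mean_is <- function(contrast) {
    sim <- small_world(seed = 17, evenness_contrast = contrast,
                       sequencing_depth_mean = 1500)
    iv <- inverse_simpson(unclass(sim$table))
    realm <- sim$truth$realm
    c(ben = mean(iv[realm == "benthic"]), pel = mean(iv[realm == "pelagic"]))
  }
  grid <- vapply(c(1, 1.8, 3), mean_is, numeric(2))
  expect_true(all(diff(grid["ben", ]) > 0))   # favoured realm gets more even
  expect_true(all(diff(grid["pel", ]) < 0))
})

test_that("a null world produces near-zero ecosystem ANOSIM within a realm", {
  for (s in 1:3) {
    sim <- generate_community(sim_params(
      n_otus_pool = 800L,
      n_samples = c("pelagic:coastal" = 20L,
                    "pelagic:surface_open_ocean" = 20L),
      ecosystem_effect_size = 0, spatial_effect_size = 0,
      productivity_effect_size = 0, time_effect_size = 0,
      sample_noise_sd = 0, evenness_contrast = 1,
      sequencing_depth_mean = 2000, seed = s))
    d <- bray_curtis(hellinger(sim$table))
    r <- anosim(d, sim$truth$ecosystem, n_perm = 99, seed = s)
    expect_lt(abs(r$R), 0.1)
  }
})

test_that("singleton calibration converges or reports honestly", {
  base <- sim_params(
    n_otus_pool = 4000L,
    n_samples = c("pelagic:coastal" = 10L, "benthic:coastal" = 10L),
    sequencing_depth_mean = 400, seed = 2)
  cal <- calibrate_singletons(base, target = 0.4)
  expect_true(cal$realized >= 0 && cal$realized <= 1)
  expect_lte(cal$iterations, 20L)
  if (cal$converged) expect_lte(abs(cal$realized - 0.4), 0.05)
  # degenerate: absurdly low target at tiny depth warns and reports best
  tiny <- base; tiny$sequencing_depth_mean <- 10
  expect_warning(res <- calibrate_singletons(tiny, target = 0.01),
                 "unreachable|stopped")
  expect_false(res$converged)
  # log-series world reports a fraction in range
  ls <- sim_params(n_otus_pool = 3000L, abundance_model = "logseries",
                   abundance_shape = 0.99,
                   n_samples = c("pelagic:coastal" = 8L,
                                 "benthic:coastal" = 8L),
                   sequencing_depth_mean = 5000, seed = 3)
  f <- singleton_fraction(generate_community(ls)$table)
  expect_true(f >= 0 && f <= 1)
})
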