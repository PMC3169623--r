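# Shared fixture builders. Everything is generated in code; no binary data.

tiny_counts <- function() {
  matrix(c(1L, 0L, 2L,
           0L, 3L, 0L),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
}

tiny_table <- function() otu_table(tiny_counts())

tiny_meta <- function() {
  data.frame(
    sample_id = c("s1", "s2"),
    latitude = c(54.1, -10.2), longitude = c(7.9, 120.5),
    water_depth = c(30, 2500), distance_to_coast = c(12, 900),
    sample_depth_kind = c("water", "sediment"),
    special_habitat = c("none", "none"),
    date = c("2003-06-14", "2004-06-14"),
    longhurst_productivity = c(4L, 2L), fisheries_class = c(3L, 1L),
    stringsAsFactors = FALSE)
}

# a small but non-trivial simulated world for fast tests
small_world <- function(seed = 1L, ...) {
  args <- list(
    n_otus_pool = 1500L,
    n_samples = c("pelagic:coastal" = 12L, "pelagic:surface_open_ocean" = 10L,
                  "benthic:coastal" = 10L, "benthic:deep_seafloor" = 12L),
    sequencing_depth_mean = 800,
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  generate_community(do.call(sim_params, args))
}

# random metadata grid for property tests
random_meta <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    sample_id = sprintf("r%03d", seq_len(n)),
    latitude = runif(n, -89, 89), longitude = runif(n, -179, 179),
    water_depth = sample(c(5, 150, 200, 250, 4000), n, replace = TRUE),
    distance_to_coast = sample(c(10, 150, 200, 210, 1500), n, replace = TRUE),
    sample_depth_kind = sample(c("water", "sediment"), n, replace = TRUE),
    special_habitat = sample(c("none", "none", "none", "vent", "anoxic"), n,
                             replace = TRUE),
    date = format(as.Date("2003-01-01") + sample.int(1000, n, replace = TRUE)),
    longhurst_productivity = sample.int(6, n, replace = TRUE),
    fisheries_class = sample.int(4, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# independent brute-force ANOSIM oracle: explicit rank lists and loops
anosim_oracle_R <- function(d, groups) {
  n <- nrow(d)
  dv <- c()
  within <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- c(dv, d[i, j])
      within <- c(within, groups[i] == groups[j])
    }
  }
  r <- rank(dv)
  (mean(r[!within]) - mean(r[within])) / (length(dv) / 2)
}

# exhaustive ANOSIM permutation p-value over all distinct group partitions
anosim_oracle_exact_p <- function(d, groups) {
  n <- nrow(d)
  obs <- anosim_oracle_R(d, groups)
  ga <- unique(groups)[1]
  na <- sum(groups == ga)
  combos <- utils::combn(n, na)
  rs <- apply(combos, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    anosim_oracle_R(d, g)
  })
  mean(rs >= obs - 1e-12)
}

# brute-force RDA R2 via explicit hat matrix
rda_oracle_r2 <- function(y, x) {
  yc <- sweep(y, 2, colMeans(y))
  xc <- sweep(x, 2, colMeans(x))
  h <- xc %*% solve(crossprod(xc)) %*% t(xc)
  sum((h %*% yc)^2) / sum(yc^2)
}
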