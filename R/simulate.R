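#' Simulation parameters for the synthetic community generator
#'
#' Defaults describe a desk-scale analogue of a global marine bacterial
#' pyrotag survey: two realms (pelagic, benthic) sharing a small fraction
#' of their OTU pool, five ecosystem types with sample counts proportional
#' to the survey's, a heavy-tailed (lognormal) abundance distribution
#' calibrated so that about half of the observed OTUs are dataset-wide
#' singletons, benthic communities more even than pelagic ones, a spatially
#' autocorrelated abundance field with a shorter range in the benthic realm
#' (stronger distance decay at the seafloor), and small productivity and
#' time effects.
#'
#' @param n_otus_pool size of the total OTU pool (union of both realms).
#' @param realm_overlap fraction of the pool shared by both realms.
#' @param shared_quantile_min shared (cosmopolitan) OTUs draw their
#'   abundance quantile uniformly from `[shared_quantile_min, 1]`, and use
#'   the *same* quantile in both realms; exclusive OTUs draw independent
#'   quantiles on `[0, 1]`. This encodes the abundance-occupancy
#'   relationship: taxa found across realms tend to be the abundant ones,
#'   which is what makes a 7 percent pool overlap detectable as a shared
#'   fraction of the same order in finite samples.
#' @param n_samples named integer vector of samples per realm:ecosystem
#'   combination.
#' @param abundance_model `"lognormal"` or `"logseries"`.
#' @param abundance_shape lognormal sd of log base abundance, or the
#'   log-series parameter in (0, 1). The default was fixed once by
#'   bisection ([calibrate_singletons()]) to meet `singleton_target`.
#' @param sequencing_depth_mean,sequencing_depth_dispersion negative
#'   binomial reads-per-sample model (mean, size).
#' @param evenness_contrast `c >= 1`; pelagic shape is multiplied by
#'   `sqrt(c)` and benthic divided by it, so larger `c` makes benthic
#'   communities more even (higher inverse Simpson) than pelagic ones.
#' @param spatial_decay_range named km ranges of the exponential spatial
#'   covariance per realm (benthic < pelagic mimics stronger benthic
#'   distance decay).
#' @param spatial_effect_size sd of the multiplicative (log-scale) spatial
#'   field per OTU.
#' @param ecosystem_effect_size sd of per-(OTU, ecosystem) log-abundance
#'   offsets.
#' @param productivity_effect_size,time_effect_size sds of per-OTU loadings
#'   on the standardized productivity class and days-since-first covariates.
#' @param sample_noise_sd sd of idiosyncratic per-(sample, OTU) log-normal
#'   abundance noise (overdispersion beyond multinomial sampling). This is
#'   what lets each sample express its own slice of the rare tail, making
#'   singleton-rich tables possible at realistic sequencing depths.
#' @param singleton_target target fraction of observed OTUs that are
#'   dataset-wide singletons.
#' @param unassigned_profile cumulative fraction of OTUs assigned at each
#'   rank (monotone non-increasing; prefix annotation).
#' @param n_spatial_factors latent spatial factors per realm.
#' @param seed integer master seed; same params + seed give identical
#'   output.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_otus_pool = 100000L,
                       realm_overlap = 0.07,
                       shared_quantile_min = 0.5,
                       n_samples = c("pelagic:coastal" = 76L,
                                     "pelagic:surface_open_ocean" = 28L,
                                     "pelagic:deep_open_ocean" = 24L,
                                     "pelagic:vent" = 6L,
                                     "pelagic:anoxic" = 7L,
                                     "benthic:coastal" = 28L,
                                     "benthic:deep_seafloor" = 27L,
                                     "benthic:vent" = 5L),
                       abundance_model = c("lognormal", "logseries"),
                       abundance_shape = 3,
                       sequencing_depth_mean = 1000,
                       sequencing_depth_dispersion = 5,
                       evenness_contrast = 1.5,
                       spatial_decay_range = c(pelagic = 8000, benthic = 2000),
                       spatial_effect_size = 0.5,
                       ecosystem_effect_size = 1.0,
                       productivity_effect_size = 0.3,
                       time_effect_size = 0.15,
                       sample_noise_sd = 2,
                       singleton_target = 0.5,
                       unassigned_profile = c(domain = 1, phylum = 0.23,
                                              class = 0.21, order = 0.19,
                                              family = 0.17, genus = 0.16),
                       n_spatial_factors = 5L,
                       seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  p <- as.list(environment())
  if (p$realm_overlap < 0 || p$realm_overlap > 1) stopf("realm_overlap in [0,1]")
  if (p$singleton_target < 0 || p$singleton_target > 1) {
    stopf("singleton_target in [0,1]")
  }
  if (p$sequencing_depth_mean < 1) stopf("sequencing depth must be >= 1")
  if (p$evenness_contrast < 1) stopf("evenness_contrast must be >= 1")
  if (any(diff(p$unassigned_profile) > 1e-12)) {
    stopf("unassigned_profile must be non-increasing (prefix annotation)")
  }
  if (is.null(names(p$n_samples))) stopf("n_samples must be named realm:ecosystem")
  structure(p, class = "sim_params")
}

# base abundance on the log scale from abundance-quantile draws, so shared
# OTUs can be made comonotone across realms (a cosmopolitan taxon occupies
# the same abundance quantile in both realms)
base_log_abundance <- function(u, model, shape) {
  if (model == "lognormal") {
    stats::qnorm(u, 0, shape)
  } else {
    if (shape <= 0 || shape >= 1) stopf("logseries shape must be in (0,1)")
    k_max <- 100000L
    k <- seq_len(k_max)
    pmf <- exp(k * log(shape) - log(k))
    cdf <- cumsum(pmf / sum(pmf))
    log(findInterval(u, cdf, left.open = TRUE) + 1L)
  }
}

# latent spatially autocorrelated factors: exponential covariance on
# great-circle distance, unit marginal variance
spatial_factors <- function(gc_km, range_km, n_factors) {
  n <- nrow(gc_km)
  k <- exp(-unclass(gc_km) / range_km) + diag(1e-8, n)
  l <- t(chol(k))
  f <- l %*% matrix(stats::rnorm(n * n_factors), n, n_factors)
  f
}

#' Generate a synthetic marine community dataset
#'
#' Draws the OTU table, sample metadata and taxonomy described by
#' [sim_params()], together with a ground-truth record of every latent
#' effect. Per-sample expected relative abundances are built
#' multiplicatively on the log scale from (i) the realm pool's base
#' abundance distribution, (ii) per-(OTU, ecosystem) offsets, (iii) per-OTU
#' loadings on the standardized productivity class and time covariates and
#' (iv) a latent Gaussian spatial field with exponential covariance on
#' great-circle distance; counts are then multinomial at a negative
#' binomially drawn sequencing depth. Metadata are generated so that
#' [classify_ecosystem()] recovers the intended labels.
#'
#' @param params a [sim_params()] object.
#' @return list of class `community_sim` with `table` ([otu_table()],
#'   observed OTUs only), `metadata` (classified), `taxonomy` (full pool),
#'   `truth` (pools, expected relative abundances over the full pool,
#'   latent effect components, depths, params).
#' @export
generate_community <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  local_seed(params$seed, {
    np <- params$n_otus_pool
    otu_ids <- sprintf("otu%05d", seq_len(np))
    n_shared <- round(params$realm_overlap * np)
    n_excl <- np - n_shared
    n_pel <- n_shared + floor(n_excl / 2)
    pool <- list(
      shared = otu_ids[seq_len(n_shared)],
      pelagic = otu_ids[seq_len(n_shared + floor(n_excl / 2))],
      benthic = otu_ids[c(seq_len(n_shared),
                          (n_shared + floor(n_excl / 2) + 1L):np)])
    if (n_shared == np) pool$benthic <- otu_ids

    combos <- names(params$n_samples)
    realm_of <- sub(":.*$", "", combos)
    eco_of <- sub("^.*:", "", combos)
    n_total <- sum(params$n_samples)
    sample_realm <- rep(realm_of, params$n_samples)
    sample_eco <- rep(eco_of, params$n_samples)
    sample_ids <- sprintf("s%03d", seq_len(n_total))

    meta <- generate_metadata(sample_ids, sample_realm, sample_eco)
    meta <- classify_ecosystem(meta)

    shape <- params$abundance_shape
    ec <- params$evenness_contrast
    shapes <- if (params$abundance_model == "lognormal") {
      # larger sd = less even; pelagic less even than benthic
      c(pelagic = shape * sqrt(ec), benthic = shape / sqrt(ec))
    } else {
      # log-series: x nearer 1 = heavier dominance tail = less even
      c(pelagic = shape^(1 / ec), benthic = shape^ec)
    }

    expected <- matrix(0, n_total, np, dimnames = list(sample_ids, otu_ids))
    effects <- list()
    prod_cov <- as.numeric(scale(meta$longhurst_productivity))
    if (anyNA(prod_cov)) prod_cov <- rep(0, n_total)
    time_cov <- as.numeric(scale(days_since_first(meta)))
    if (anyNA(time_cov)) time_cov <- rep(0, n_total)

    # abundance quantiles: shared OTUs draw one (upper-range) quantile used
    # in both realms; exclusive OTUs draw independently over [0, 1]
    u_pool <- stats::runif(np)
    if (n_shared > 0L) {
      u_pool[seq_len(n_shared)] <-
        stats::runif(n_shared, params$shared_quantile_min, 1)
    }
    for (realm in c("pelagic", "benthic")) {
      idx <- which(sample_realm == realm)
      if (!length(idx)) next
      pool_r <- match(pool[[realm]], otu_ids)
      nr <- length(pool_r)
      u_r <- u_pool[pool_r]
      excl <- pool_r > n_shared
      u_r[excl] <- stats::runif(sum(excl))
      log_a <- base_log_abundance(u_r, params$abundance_model, shapes[[realm]])
      ecos <- unique(sample_eco[idx])
      delta <- matrix(stats::rnorm(nr * length(ecos), 0,
                                   params$ecosystem_effect_size),
                      nr, length(ecos), dimnames = list(NULL, ecos))
      u_prod <- stats::rnorm(nr, 0, params$productivity_effect_size)
      v_time <- stats::rnorm(nr, 0, params$time_effect_size)
      gc <- great_circle(meta[idx, ])
      f <- spatial_factors(gc, params$spatial_decay_range[[realm]],
                           params$n_spatial_factors)
      w <- matrix(stats::rnorm(nr * params$n_spatial_factors, 0,
                               params$spatial_effect_size /
                                 sqrt(params$n_spatial_factors)),
                  nr, params$n_spatial_factors)
      loglam <- matrix(log_a, length(idx), nr, byrow = TRUE) +
        t(delta[, sample_eco[idx], drop = FALSE]) +
        outer(prod_cov[idx], u_prod) +
        outer(time_cov[idx], v_time) +
        f %*% t(w) +
        matrix(stats::rnorm(length(idx) * nr, 0, params$sample_noise_sd),
               length(idx), nr)
      # softmax per sample over the realm pool
      loglam <- loglam - apply(loglam, 1L, max)
      p <- exp(loglam)
      p <- p / rowSums(p)
      expected[idx, pool_r] <- p
      effects[[realm]] <- list(log_a = log_a, delta = delta,
                               prod_loading = u_prod, time_loading = v_time,
                               spatial_factors = f, spatial_loadings = w,
                               pool_index = pool_r)
    }

    depths <- pmax(1L, stats::rnbinom(n_total,
                                      size = params$sequencing_depth_dispersion,
                                      mu = params$sequencing_depth_mean))
    counts <- matrix(0L, n_total, np, dimnames = list(sample_ids, otu_ids))
    for (s in seq_len(n_total)) {
      pr <- expected[s, ]
      nz <- which(pr > 0)
      counts[s, nz] <- stats::rmultinom(1L, depths[s], pr[nz])[, 1L]
    }
    observed <- colSums(counts) > 0L
    t <- otu_table(counts[, observed, drop = FALSE])

    taxonomy <- generate_taxonomy(otu_ids, params$unassigned_profile)

    truth <- list(params = params, pools = pool,
                  expected_prop = expected, effects = effects,
                  depths = setNames(depths, sample_ids),
                  covariates = list(productivity = prod_cov, time = time_cov),
                  realm = setNames(sample_realm, sample_ids),
                  ecosystem = setNames(sample_eco, sample_ids))
    structure(list(table = t, metadata = meta, taxonomy = taxonomy,
                   truth = truth),
              class = "community_sim")
  })
}

# metadata consistent with the intended realm/ecosystem classification
generate_metadata <- function(ids, realm, eco) {
  n <- length(ids)
  lat <- asin(stats::runif(n, -0.95, 0.95)) * 180 / pi
  lon <- stats::runif(n, -180, 180)
  depth <- numeric(n); coast <- numeric(n)
  kind <- ifelse(realm == "benthic", "sediment", "water")
  special <- ifelse(eco %in% c("vent", "anoxic"), eco, "none")
  for (i in seq_len(n)) {
    if (eco[i] == "coastal" && realm[i] == "pelagic") {
      coast[i] <- stats::runif(1, 1, 199); depth[i] <- stats::runif(1, 1, 180)
    } else if (eco[i] == "surface_open_ocean") {
      coast[i] <- stats::runif(1, 210, 3000); depth[i] <- stats::runif(1, 1, 180)
    } else if (eco[i] == "deep_open_ocean") {
      coast[i] <- stats::runif(1, 210, 3000); depth[i] <- stats::runif(1, 250, 4000)
    } else if (eco[i] == "coastal") {           # benthic coastal sediment
      coast[i] <- stats::runif(1, 1, 199); depth[i] <- stats::runif(1, 1, 180)
    } else if (eco[i] == "deep_seafloor") {
      coast[i] <- stats::runif(1, 50, 3000); depth[i] <- stats::runif(1, 250, 5500)
    } else if (eco[i] == "vent") {
      coast[i] <- stats::runif(1, 50, 3000); depth[i] <- stats::runif(1, 800, 3500)
    } else {                                    # anoxic water
      coast[i] <- stats::runif(1, 1, 400); depth[i] <- stats::runif(1, 50, 2000)
    }
  }
  date <- as.Date("2003-01-01") + sample.int(4 * 365, n, replace = TRUE)
  # productivity proxy: higher towards coasts and high latitudes
  latent <- -0.5 * as.numeric(scale(coast)) +
    0.5 * as.numeric(scale(abs(lat))) + stats::rnorm(n, 0, 0.5)
  longhurst <- as.integer(cut(latent, stats::quantile(latent, 0:6 / 6),
                              include.lowest = TRUE, labels = FALSE))
  fisheries <- as.integer(cut(latent + stats::rnorm(n, 0, 0.4),
                              stats::quantile(latent, 0:4 / 4) +
                                c(-10, 0, 0, 0, 10),
                              include.lowest = TRUE, labels = FALSE))
  validate_metadata(data.frame(
    sample_id = ids, latitude = round(lat, 4), longitude = round(lon, 4),
    water_depth = round(depth, 1), distance_to_coast = round(coast, 1),
    sample_depth_kind = kind, special_habitat = special,
    date = format(date, "%Y-%m-%d"),
    longhurst_productivity = longhurst, fisheries_class = fisheries,
    stringsAsFactors = FALSE))
}

# nested random taxonomy over the pool with prefix-annotated unassigned ranks
generate_taxonomy <- function(otu_ids, profile) {
  n <- length(otu_ids)
  phylum <- sample.int(20L, n, replace = TRUE)
  class_ <- sample.int(3L, n, replace = TRUE)
  order_ <- sample.int(3L, n, replace = TRUE)
  family <- sample.int(3L, n, replace = TRUE)
  genus <- sample.int(4L, n, replace = TRUE)
  lin <- cbind(
    domain = rep("Bacteria", n),
    phylum = sprintf("Phy%02d", phylum),
    class = sprintf("Cla%02d_%d", phylum, class_),
    order = sprintf("Ord%02d_%d_%d", phylum, class_, order_),
    family = sprintf("Fam%02d_%d_%d_%d", phylum, class_, order_, family),
    genus = sprintf("Gen%02d_%d_%d_%d_%d", phylum, class_, order_, family,
                    genus))
  u <- stats::runif(n)
  for (r in seq_along(taxonomy_ranks)) {
    lin[u >= profile[[taxonomy_ranks[r]]], r] <- "UNASSIGNED"
  }
  data.frame(otu_id = otu_ids, lin, stringsAsFactors = FALSE)
}

#' @export
print.community_sim <- function(x, ...) {
  cat(sprintf("community_sim: %d samples, %d observed OTUs (pool %d), seed %d\n",
              nrow(x$table), ncol(x$table), x$truth$params$n_otus_pool,
              x$truth$params$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the three TSVs consumed by the readers plus a ground-truth JSON
#' (parameters, pools, depths, realized singleton fraction; the dense
#' expected-abundance matrix stays in memory only).
#'
#' @param sim a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(otu = file.path(dir, "otu_table.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             tax = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_otu_table(sim$table, paths[["otu"]])
  meta <- sim$metadata
  meta$date <- format(meta$date, "%Y-%m-%d")
  utils::write.table(meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_taxonomy(sim$taxonomy, paths[["tax"]])
  gt <- list(params = unclass(sim$truth$params),
             pools = sim$truth$pools,
             depths = as.list(sim$truth$depths),
             realized_singleton_fraction = singleton_fraction(sim$table))
  jsonlite::write_json(gt, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Realized singleton fraction of an OTU table
#'
#' @param t an [otu_table()].
#' @return fraction of observed OTUs whose dataset-wide total count is 1.
#' @export
singleton_fraction <- function(t) {
  length(singleton_ids(t)) / ncol(t)
}

#' Calibrate the abundance shape to a singleton target
#'
#' Bisects the generator's abundance-model shape parameter (at most
#' `max_iter` iterations, all with the same seed) until the realized
#' fraction of dataset-wide singleton OTUs is within 5 percentage points of
#' `target`. If the target is unreachable within the bracket, the best
#' achieved value is returned with a warning.
#'
#' @param params a [sim_params()] object (its `abundance_shape` is ignored).
#' @param target singleton fraction to aim for (default
#'   `params$singleton_target`).
#' @param lower,upper bisection bracket for the shape parameter.
#' @param max_iter maximum bisection iterations (default 20).
#' @param tol acceptance half-width on the realized fraction (default 0.05).
#' @return list with `shape`, `realized`, `target`, `iterations`,
#'   `converged`, `history` (data.frame of shape/fraction pairs).
#' @export
calibrate_singletons <- function(params, target = params$singleton_target,
                                 lower = if (params$abundance_model ==
                                             "lognormal") 0.5 else 0.5,
                                 upper = if (params$abundance_model ==
                                             "lognormal") 9 else 0.999999,
                                 max_iter = 20L, tol = 0.05) {
  evals <- list()
  frac_at <- function(shape) {
    p <- params; p$abundance_shape <- shape
    f <- singleton_fraction(generate_community(p)$table)
    evals[[length(evals) + 1L]] <<- data.frame(shape = shape, fraction = f)
    f
  }
  # the realized fraction is unimodal in the shape parameter, so probe a
  # coarse grid first and bisect within the bracketing interval
  grid <- seq(lower, upper, length.out = 5L)
  fg <- vapply(grid, frac_at, numeric(1))
  done <- function(converged) {
    hist <- do.call(rbind, evals)
    best <- which.min(abs(hist$fraction - target))
    list(shape = hist$shape[best], realized = hist$fraction[best],
         target = target, iterations = nrow(hist), converged = converged,
         history = hist)
  }
  if (min(abs(fg - target)) <= tol) return(done(TRUE))
  crossing <- which(diff(sign(fg - target)) != 0)
  if (!length(crossing)) {
    warnf("singleton target %.2f unreachable in [%.3g, %.3g]; best %.3f",
          target, lower, upper, fg[which.min(abs(fg - target))])
    return(done(FALSE))
  }
  lo <- grid[crossing[1L]]; f_lo <- fg[crossing[1L]]
  hi <- grid[crossing[1L] + 1L]
  f_mid <- f_lo
  while (abs(f_mid - target) > tol && length(evals) < max_iter) {
    mid <- (lo + hi) / 2
    f_mid <- frac_at(mid)
    if ((f_mid - target) * (f_lo - target) > 0) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  if (abs(f_mid - target) > tol) {
    warnf("singleton calibration stopped after %d evaluations at %.3f",
          length(evals), f_mid)
  }
  done(abs(f_mid - target) <= tol)
}
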