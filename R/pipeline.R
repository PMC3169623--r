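#' Read a pipeline run configuration
#'
#' Configurations are YAML (or JSON) mappings with keys `seed`,
#' `output_dir`, either `simulate` (arguments for [sim_params()]) or
#' `input` (paths `otu_table`, `metadata`, `taxonomy`), `stages` (subset of
#' the stage names, in any order; dependencies are resolved), and optional
#' per-stage parameter blocks under `params`.
#'
#' @param path YAML or JSON file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_run_config(cfg)
}

pipeline_stages <- c("summary", "transforms", "ordination", "anosim",
                     "dispersion", "shared_otus", "robustness", "varpart",
                     "rank_consistency")

#' @rdname read_run_config
#' @param cfg config list to validate.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$output_dir)) stopf("config needs `output_dir`")
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stopf("config needs `simulate` parameters or `input` paths")
  }
  if (!is.null(cfg$input)) {
    need <- c("otu_table", "metadata")
    missing <- setdiff(need, names(cfg$input))
    if (length(missing)) stopf("input config missing: %s",
                               paste(missing, collapse = ", "))
    for (p in unlist(cfg$input)) {
      if (!file.exists(p)) stopf("input file not found: %s", p)
    }
  }
  cfg$stages <- cfg$stages %||% pipeline_stages
  bad <- setdiff(cfg$stages, pipeline_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if ("rank_consistency" %in% cfg$stages || "varpart" %in% cfg$stages) {
    if (is.null(cfg$simulate) && is.null(cfg$input$metadata)) {
      stopf("varpart / rank consistency need sample metadata")
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$params <- cfg$params %||% list()
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order (io, summary,
#' transforms, ordination, group statistics, resampling, variation
#' partitioning, rank consistency), writing TSV/JSON outputs, a run log and
#' a manifest with parameters, per-stage seeds and output checksums into
#' `output_dir`. A stage failure aborts with the failing stage named in the
#' log.
#'
#' @param config config list (see [read_run_config()]) or a path to one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("marbeta")),
                   seed = cfg$seed, stages = cfg$stages, params = cfg$params,
                   outputs = list(), stage_seeds = list())
  outputs <- character()
  par_of <- function(stage, key, default) {
    cfg$params[[stage]][[key]] %||% default
  }
  run_stage <- function(name, code) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    logf("stage %s: start", name)
    ok <- tryCatch({ code; TRUE }, error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      stopf("pipeline aborted at stage '%s': %s", name, conditionMessage(e))
    })
    logf("stage %s: done", name)
  }

  # --- io ----------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_seed <- derive_seed(cfg$seed, 1L)
    manifest$stage_seeds$simulate <- sim_seed
    sp_args <- cfg$simulate
    if (isTRUE(sp_args) || length(sp_args) == 0L) sp_args <- list()
    sp_args$seed <- sp_args$seed %||% sim_seed
    if (!is.null(sp_args$n_samples)) {
      sp_args$n_samples <- unlist(sp_args$n_samples)
    }
    sp <- do.call(sim_params, sp_args)
    logf("simulating community (pool %d, %d samples)", sp$n_otus_pool,
         sum(sp$n_samples))
    sim <- generate_community(sp)
    paths <- write_community(sim, file.path(cfg$output_dir, "simulated"))
    outputs <- c(outputs, paths)
    t <- sim$table; meta <- sim$metadata; tax <- sim$taxonomy
  } else {
    logf("reading inputs")
    t <- read_otu_table(cfg$input$otu_table,
                        format = cfg$input$format %||% "tsv")
    meta <- read_metadata(cfg$input$metadata)
    tax <- if (!is.null(cfg$input$taxonomy)) read_taxonomy(cfg$input$taxonomy)
  }
  meta <- classify_ecosystem(meta)
  meta <- meta[match(rownames(t), meta$sample_id), ]
  groups_realm <- as.character(meta$realm)
  groups_eco <- realm_ecosystem(meta)

  save_tsv <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  save_json <- function(x, name) {
    p <- file.path(cfg$output_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
    p
  }

  d <- NULL
  ensure_dissim <- function() {
    if (is.null(d)) d <<- bray_curtis(hellinger(t))
    d
  }

  run_stage("summary", {
    save_tsv(summarize_dataset(t, meta), "summary.tsv")
  })
  run_stage("transforms", {
    write_dissim(ensure_dissim(), file.path(cfg$output_dir, "bray_curtis.tsv"))
    outputs <- c(outputs, file.path(cfg$output_dir, "bray_curtis.tsv"))
  })
  ord <- NULL
  run_stage("ordination", {
    seed <- derive_seed(cfg$seed, 2L)
    manifest$stage_seeds$ordination <- seed
    ord <- nmds(ensure_dissim(), k = par_of("nmds", "k", 2L),
                 n_starts = par_of("nmds", "n_starts", 20L), seed = seed)
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE)
    save_tsv(coords, "nmds_coordinates.tsv")
    save_json(list(stress = ord$stress, converged = ord$converged,
                   n_starts = ord$n_starts, seed = seed,
                   stress_by_start = ord$stress_by_start), "nmds_run.json")
  })
  run_stage("anosim", {
    seed <- derive_seed(cfg$seed, 3L)
    manifest$stage_seeds$anosim <- seed
    n_perm <- par_of("anosim", "n_perm", 1000L)
    a <- anosim(ensure_dissim(), groups_realm, n_perm = n_perm, seed = seed)
    save_json(list(grouping = "realm", R = a$R, p_value = a$p_value,
                   n_perm = n_perm), "anosim_realm.json")
    save_tsv(pairwise_anosim(ensure_dissim(), groups_eco, n_perm = n_perm,
                             seed = seed), "anosim_pairwise.tsv")
  })
  run_stage("dispersion", {
    disp <- beta_dispersion(ensure_dissim(), groups_eco)
    save_tsv(data.frame(sample_id = names(disp$distances),
                        group = groups_eco,
                        distance_to_centroid = disp$distances),
             "dispersion_distances.tsv")
    save_tsv(disp$comparisons, "dispersion_tests.tsv")
  })
  run_stage("shared_otus", {
    seed <- derive_seed(cfg$seed, 4L)
    manifest$stage_seeds$shared_otus <- seed
    so <- shared_otus(t, groups_eco,
                      n_iter = par_of("shared_otus", "n_iter", 100L),
                      design = par_of("shared_otus", "design", "equal_samples"),
                      seed = seed)
    save_tsv(so$pairs, "shared_otus.tsv")
  })
  run_stage("robustness", {
    seed <- derive_seed(cfg$seed, 5L)
    manifest$stage_seeds$robustness <- seed
    save_tsv(robustness_procrustes(t, n_starts = par_of("nmds", "n_starts", 20L),
                                   n_perm = par_of("anosim", "n_perm", 1000L),
                                   seed = seed),
             "robustness_procrustes.tsv")
  })
  run_stage("varpart", {
    seed <- derive_seed(cfg$seed, 6L)
    manifest$stage_seeds$varpart <- seed
    min_n <- par_of("varpart", "min_eco_samples", 10L)
    n_perm <- par_of("varpart", "n_perm", 1000L)
    for (realm in unique(groups_realm)) {
      idx <- which(groups_realm == realm)
      eco_n <- table(droplevels(meta$ecosystem[idx]))
      keep_eco <- names(eco_n)[eco_n >= min_n]
      idx <- idx[meta$ecosystem[idx] %in% keep_eco]
      if (length(idx) < 10L) next
      sub_t <- unclass(t)[idx, , drop = FALSE]
      sub_t <- sub_t[, colSums(sub_t) > 0, drop = FALSE]
      dd <- bray_curtis(hellinger(sub_t))
      # "main axes" spatial representation by default: all positive PCoA
      # axes of the geodesic matrix would exhaust the residual degrees of
      # freedom at desk-scale realm sizes
      sets <- build_design(meta[idx, ],
                           spatial_axes = par_of("varpart", "spatial_axes",
                                                 "first_k"),
                           k_spatial = par_of("varpart", "k_spatial", 3L),
                           productivity = par_of("varpart", "productivity",
                                                 "both"))
      sets <- Filter(function(s) ncol(s) > 0, sets)
      vp <- variation_partition(dd, sets, n_perm = n_perm,
                                seed = derive_seed(seed, match(realm,
                                                               unique(groups_realm))))
      save_tsv(vp$fractions, sprintf("varpart_%s.tsv", realm))
    }
  })
  run_stage("rank_consistency", {
    if (is.null(tax)) stopf("rank consistency needs a taxonomy table")
    seed <- derive_seed(cfg$seed, 7L)
    manifest$stage_seeds$rank_consistency <- seed
    ranks <- par_of("rank_consistency", "ranks", c("phylum", "class"))
    tables <- list(otu = t)
    for (r in ranks) {
      agg <- suppressWarnings(aggregate_by_rank(t, tax, r))
      if (is.matrix(agg$table) && ncol(agg$table) == 0L) next
      tables[[r]] <- agg$table
    }
    rc <- rank_consistency(tables,
                           n_starts = par_of("nmds", "n_starts", 20L),
                           n_perm = par_of("anosim", "n_perm", 1000L),
                           seed = seed)
    save_tsv(rc$comparisons, "rank_consistency.tsv")
  })

  manifest$outputs <- lapply(unique(outputs), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete: %d outputs", length(manifest$outputs))
  invisible(manifest)
}
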