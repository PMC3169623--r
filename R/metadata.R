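#' Sample metadata
#'
#' Per-sample geospatial, temporal, categorical and productivity fields.
#' Required columns: `sample_id`, `latitude` (decimal degrees, -90..90),
#' `longitude` (decimal degrees, -180..180), `water_depth` (m, >= 0),
#' `distance_to_coast` (nautical miles, >= 0), `sample_depth_kind`
#' (`water`/`sediment`), `special_habitat` (`none`/`vent`/`anoxic`),
#' `date` (ISO-8601), `longhurst_productivity` and `fisheries_class`
#' (ordinal integer classes). Unknown columns are preserved as opaque
#' covariates.
#'
#' @param path TSV path.
#' @return A validated `data.frame` with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

metadata_required_cols <- c(
  "sample_id", "latitude", "longitude", "water_depth", "distance_to_coast",
  "sample_depth_kind", "special_habitat", "date",
  "longhurst_productivity", "fisheries_class")

#' @rdname read_metadata
#' @param df data.frame of metadata to validate in place.
#' @export
validate_metadata <- function(df) {
  missing <- setdiff(metadata_required_cols, names(df))
  if (length(missing)) stopf("missing metadata column(s): %s",
                             paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in metadata")
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stopf("unparseable %s for sample(s): %s", col,
                        paste(df$sample_id[is.na(v)], collapse = ", "))
    v
  }
  df$latitude <- num("latitude"); df$longitude <- num("longitude")
  df$water_depth <- num("water_depth")
  df$distance_to_coast <- num("distance_to_coast")
  if (any(abs(df$latitude) > 90)) stopf("latitude out of [-90, 90]")
  if (any(abs(df$longitude) > 180)) stopf("longitude out of [-180, 180]")
  if (any(df$water_depth < 0)) stopf("negative water_depth")
  if (any(df$distance_to_coast < 0)) stopf("negative distance_to_coast")
  if (!all(df$sample_depth_kind %in% c("water", "sediment"))) {
    stopf("sample_depth_kind must be 'water' or 'sediment'")
  }
  if (!all(df$special_habitat %in% c("none", "vent", "anoxic"))) {
    stopf("special_habitat must be 'none', 'vent' or 'anoxic'")
  }
  d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(d)) stopf("unparseable date for sample(s): %s",
                      paste(df$sample_id[is.na(d)], collapse = ", "))
  df$date <- d
  df$longhurst_productivity <- as.integer(df$longhurst_productivity)
  df$fisheries_class <- as.integer(df$fisheries_class)
  df
}

#' Days since the earliest sampling date
#'
#' @param meta metadata data.frame with a `date` column.
#' @return integer vector of day offsets from the earliest date.
#' @export
days_since_first <- function(meta) {
  d <- as.Date(meta$date)
  as.integer(d - min(d))
}

#' Classify samples into ecosystem types and realms
#'
#' Realm is `benthic` iff the sample is a sediment sample, else `pelagic`.
#' Special habitats (vent, anoxic, taken from sample descriptions) override
#' the depth/distance rules. Water samples: `coastal` when within 200
#' nautical miles of the littoral and above 200 m depth;
#' `surface_open_ocean` when offshore (>= 200 nmi) and above 200 m;
#' `deep_open_ocean` when offshore and at or below 200 m. Sediment samples:
#' `coastal` above 200 m water depth, else `deep_seafloor`. Boundary
#' convention: coastal/surface are strict `<` on both thresholds, deep uses
#' `>=`, so the partition is total.
#'
#' @param meta validated metadata (see [read_metadata()]).
#' @return `meta` with `realm` and `ecosystem` factor columns appended.
#' @export
classify_ecosystem <- function(meta) {
  need <- c("sample_depth_kind", "special_habitat", "distance_to_coast",
            "water_depth")
  missing <- setdiff(need, names(meta))
  if (length(missing)) stopf("classification requires column(s): %s",
                             paste(missing, collapse = ", "))
  bad <- is.na(meta$sample_depth_kind) | is.na(meta$special_habitat) |
    is.na(meta$distance_to_coast) | is.na(meta$water_depth)
  if (any(bad)) stopf("missing classification field for sample(s): %s",
                      paste(meta$sample_id[bad], collapse = ", "))
  sediment <- meta$sample_depth_kind == "sediment"
  realm <- ifelse(sediment, "benthic", "pelagic")
  eco <- character(nrow(meta))
  special <- meta$special_habitat != "none"
  eco[special] <- meta$special_habitat[special]
  offshore <- meta$distance_to_coast >= 200
  deep <- meta$water_depth >= 200
  w <- !special & !sediment
  eco[w & !offshore & !deep] <- "coastal"
  eco[w & offshore & !deep] <- "surface_open_ocean"
  eco[w & offshore & deep] <- "deep_open_ocean"
  # nearshore deep water has no class of its own; treated as deep open ocean
  eco[w & !offshore & deep] <- "deep_open_ocean"
  s <- !special & sediment
  eco[s & !deep] <- "coastal"
  eco[s & deep] <- "deep_seafloor"
  meta$realm <- factor(realm, levels = c("pelagic", "benthic"))
  meta$ecosystem <- factor(eco, levels = c(
    "coastal", "surface_open_ocean", "deep_open_ocean", "deep_seafloor",
    "vent", "anoxic"))
  meta
}

#' Combined realm/ecosystem group labels
#'
#' @param meta classified metadata.
#' @return character vector like `"pelagic:coastal"`.
#' @export
realm_ecosystem <- function(meta) {
  if (is.null(meta$realm)) meta <- classify_ecosystem(meta)
  paste(meta$realm, meta$ecosystem, sep = ":")
}
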