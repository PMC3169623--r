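#' Summarize a dataset by realm and ecosystem type
#'
#' Builds the classic survey summary: per (realm, ecosystem) group the
#' number of samples, sequences, OTUs observed in the group, and singleton
#' OTUs, plus per-realm and grand totals.
#'
#' Singletons are OTUs with a dataset-wide total of exactly one sequence.
#' With `singleton_scope = "dataset"` (default) each singleton is
#' attributed to the unique group containing its single occurrence, so
#' group singleton counts sum to the grand total. The experimental
#' `"within_group"` scope instead counts OTUs occurring exactly once
#' *within* the group (the convention that makes published per-ecosystem
#' singleton counts exceed the dataset-wide total, since an OTU can be a
#' within-group singleton in several groups).
#'
#' @param t an [otu_table()].
#' @param meta classified metadata covering every sample of `t`.
#' @param singleton_scope `"dataset"` or `"within_group"`.
#' @return data.frame with columns `realm`, `ecosystem`, `n_samples`,
#'   `n_sequences`, `n_otus`, `n_singletons`; realm totals have
#'   `ecosystem = "total"` and the last row is the grand total.
#' @export
summarize_dataset <- function(t, meta,
                              singleton_scope = c("dataset", "within_group")) {
  singleton_scope <- match.arg(singleton_scope)
  if (is.null(meta$realm) || is.null(meta$ecosystem)) {
    meta <- classify_ecosystem(meta)
  }
  missing <- setdiff(rownames(t), meta$sample_id)
  if (length(missing)) stopf("metadata missing for sample(s): %s",
                             paste(missing, collapse = ", "))
  meta <- meta[match(rownames(t), meta$sample_id), ]
  dataset_singletons <- colSums(t) == 1L

  row_for <- function(idx, realm, eco) {
    sub <- unclass(t)[idx, , drop = FALSE]
    tot <- colSums(sub)
    present <- tot > 0
    n_single <- if (singleton_scope == "dataset") {
      sum(present & dataset_singletons)
    } else {
      sum(tot == 1L)
    }
    data.frame(realm = realm, ecosystem = eco,
               n_samples = length(idx), n_sequences = sum(as.numeric(sub)),
               n_otus = sum(present), n_singletons = n_single,
               stringsAsFactors = FALSE)
  }

  out <- list()
  grp <- interaction(meta$realm, meta$ecosystem, drop = TRUE, sep = ":")
  for (realm in levels(meta$realm)) {
    in_realm <- which(meta$realm == realm)
    if (!length(in_realm)) next
    for (eco in levels(droplevels(meta$ecosystem[in_realm]))) {
      idx <- which(meta$realm == realm & meta$ecosystem == eco)
      out[[length(out) + 1L]] <- row_for(idx, realm, eco)
    }
    out[[length(out) + 1L]] <- row_for(in_realm, realm, "total")
  }
  out[[length(out) + 1L]] <- row_for(seq_len(nrow(t)), "all", "grand_total")
  do.call(rbind, out)
}

#' Write a dataset summary as TSV
#' @param summary output of [summarize_dataset()].
#' @param path output path.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
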