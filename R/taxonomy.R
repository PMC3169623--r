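#' Taxonomy tables
#'
#' A taxonomy table maps OTU ids to a six-rank lineage (domain, phylum,
#' class, order, family, genus). Unassigned ranks carry the sentinel
#' `"UNASSIGNED"` and must form a suffix of the lineage (prefix annotation):
#' once a rank is unassigned, all finer ranks are too. Rows violating this
#' are repaired on read by truncating the lineage at the first unassigned
#' rank, with a warning.
#'
#' @param path TSV path with columns `otu_id`, `domain`, ..., `genus`.
#' @return data.frame with one row per OTU.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  validate_taxonomy(df)
}

#' Taxonomic ranks, coarsest to finest
#' @format character vector of the six lineage ranks.
#' @export
taxonomy_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' @rdname read_taxonomy
#' @param df taxonomy data.frame to validate/repair.
#' @export
validate_taxonomy <- function(df) {
  missing <- setdiff(c("otu_id", taxonomy_ranks), names(df))
  if (length(missing)) stopf("missing taxonomy column(s): %s",
                             paste(missing, collapse = ", "))
  if (anyDuplicated(df$otu_id)) stopf("duplicate otu_id in taxonomy")
  m <- as.matrix(df[, taxonomy_ranks])
  m[is.na(m) | m == ""] <- "UNASSIGNED"
  un <- m == "UNASSIGNED"
  # prefix-annotation repair: blank everything below the first unassigned rank
  first_un <- apply(un, 1L, function(z) {
    w <- which(z); if (length(w)) w[1L] else ncol(m) + 1L
  })
  repaired <- 0L
  for (r in seq_along(taxonomy_ranks)) {
    bad <- first_un < r & m[, r] != "UNASSIGNED"
    if (any(bad)) {
      m[bad, r] <- "UNASSIGNED"
      repaired <- repaired + sum(bad)
    }
  }
  if (repaired > 0L) {
    warnf("repaired %d lineage entr%s violating prefix annotation",
          repaired, if (repaired == 1L) "y" else "ies")
  }
  df[, taxonomy_ranks] <- m
  df
}

#' Write a taxonomy table as TSV
#' @param tax taxonomy data.frame.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Counts of OTUs sharing a named taxon at `rank` are summed into one
#' column per taxon. OTUs unassigned at `rank` are dropped from the
#' aggregated table but reported; OTUs absent from the taxonomy are, by
#' default, dropped with a warning.
#'
#' @param t an [otu_table()].
#' @param tax taxonomy data.frame (see [read_taxonomy()]).
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @param missing_otus `"drop"` (default, warns) or `"error"`.
#' @return list with `table` (aggregated [otu_table()], taxa as columns; or
#'   a 0-column matrix when nothing is assigned) and `report`: fractions of
#'   OTUs and of sequences assigned at `rank`.
#' @export
aggregate_by_rank <- function(t, tax, rank, missing_otus = c("drop", "error")) {
  missing_otus <- match.arg(missing_otus)
  if (!rank %in% setdiff(taxonomy_ranks, "domain")) {
    stopf("rank must be one of: %s",
          paste(setdiff(taxonomy_ranks, "domain"), collapse = ", "))
  }
  lineage <- setNames(tax[[rank]], tax$otu_id)
  absent <- setdiff(colnames(t), tax$otu_id)
  if (length(absent)) {
    if (missing_otus == "error") stopf("%d OTU(s) missing from taxonomy",
                                       length(absent))
    warnf("%d OTU(s) missing from taxonomy; dropped", length(absent))
  }
  taxon <- lineage[colnames(t)]
  taxon[is.na(taxon)] <- "UNASSIGNED"
  assigned <- taxon != "UNASSIGNED"
  total_seqs <- sum(as.numeric(t))
  assigned_seqs <- sum(as.numeric(t[, assigned, drop = FALSE]))
  report <- list(
    rank = rank,
    n_otus = ncol(t), n_otus_assigned = sum(assigned),
    frac_otus_assigned = sum(assigned) / ncol(t),
    n_sequences = total_seqs, n_sequences_assigned = assigned_seqs,
    frac_sequences_assigned = assigned_seqs / total_seqs)
  if (!any(assigned)) {
    warnf("no OTU assigned at rank '%s'; aggregated table is empty", rank)
    empty <- matrix(0L, nrow = nrow(t), ncol = 0L,
                    dimnames = list(rownames(t), character()))
    return(list(table = empty, report = report))
  }
  sub <- unclass(t)[, assigned, drop = FALSE]
  f <- factor(taxon[assigned])
  agg <- sapply(levels(f), function(lv) {
    rowSums(sub[, f == lv, drop = FALSE])
  })
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = nrow(t),
                                       dimnames = list(rownames(t), levels(f)))
  rownames(agg) <- rownames(t)
  keep_rows <- rowSums(agg) > 0
  if (!all(keep_rows)) {
    warnf("%d sample(s) with no assigned sequences dropped from the %s table",
          sum(!keep_rows), rank)
    agg <- agg[keep_rows, , drop = FALSE]
  }
  list(table = otu_table(agg), report = report)
}

#' Per-group mean and standard deviation of relative abundances
#'
#' Per sample, counts are converted to relative abundances (summing to 1);
#' per group, the mean and sample standard deviation of each taxon's
#' relative abundance are reported. Taxa are ordered by decreasing global
#' mean; optionally only the `top` taxa are kept, the rest summed into an
#' `"other"` bucket.
#'
#' @param t_agg [otu_table()] (typically rank-aggregated).
#' @param groups group label per sample (recycled against rows of `t_agg`).
#' @param top optional integer; keep the `top` most abundant taxa.
#' @return list of per-group data.frames with columns `taxon`, `mean`, `sd`.
#' @export
mean_composition <- function(t_agg, groups, top = NULL) {
  groups <- as.character(groups)
  if (length(groups) != nrow(t_agg)) stopf("one group label per sample required")
  if (any(table(groups) < 1L)) stopf("empty group")
  rel <- unclass(t_agg) / rowSums(t_agg)
  ord <- order(colMeans(rel), decreasing = TRUE)
  rel <- rel[, ord, drop = FALSE]
  if (!is.null(top) && ncol(rel) > top) {
    other <- rowSums(rel[, -seq_len(top), drop = FALSE])
    rel <- cbind(rel[, seq_len(top), drop = FALSE], other = other)
  }
  lapply(split(seq_along(groups), groups), function(idx) {
    sub <- rel[idx, , drop = FALSE]
    s <- apply(sub, 2L, stats::sd)
    s[is.na(s)] <- 0  # sd of a single-sample group is reported as 0
    data.frame(taxon = colnames(sub),
               mean = colMeans(sub),
               sd = s,
               row.names = NULL)
  })
}
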