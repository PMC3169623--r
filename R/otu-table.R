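#' OTU count tables
#'
#' An `otu_table` is an integer matrix of sequence counts with samples as
#' rows and OTUs as columns, carrying unique sample and OTU identifiers as
#' dimnames. All counts are non-negative integers and every sample has at
#' least one sequence.
#'
#' @param counts numeric matrix (samples x OTUs) of non-negative integers
#'   with unique, non-empty rownames (sample ids) and colnames (OTU ids).
#' @return An object of class `otu_table` (an integer matrix).
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 3, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
#' t <- otu_table(m)
#' rowSums(t)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) stopf("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("`counts` must carry sample ids (rownames) and OTU ids (colnames)")
  }
  validate_otu_table(counts)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("otu_table", "matrix", "array"))
}

validate_otu_table <- function(counts) {
  sid <- rownames(counts); oid <- colnames(counts)
  if (anyDuplicated(sid)) stopf("duplicate sample ids: %s",
                                paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(oid)) stopf("duplicate OTU ids: %s",
                                paste(unique(oid[duplicated(oid)]), collapse = ", "))
  if (any(!nzchar(c(sid, oid)))) stopf("empty sample or OTU id")
  if (any(grepl(".", c(sid, oid), fixed = TRUE))) {
    stopf("'.' is not allowed in sample or OTU ids")
  }
  if (anyNA(counts)) stopf("counts contain NA")
  if (any(counts < 0)) stopf("negative counts")
  if (any(counts != round(counts))) stopf("non-integer counts")
  zero <- rowSums(counts) == 0
  if (any(zero)) stopf("sample(s) with zero total count: %s",
                       paste(sid[zero], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s sequences\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# keep class when subsetting with drop = FALSE matrices
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && all(rowSums(out) > 0)) {
    class(out) <- c("otu_table", "matrix", "array")
  }
  out
}

#' Read an OTU table
#'
#' Reads a samples-by-OTUs count table. The TSV dialect is tab-separated
#' UTF-8 with a header row of OTU ids and sample ids in the first column.
#' If the file appears transposed (OTUs as rows), set `transpose = TRUE`.
#' A dense BIOM-style JSON (`format = "biom_dense"`) with `rows` (OTUs),
#' `columns` (samples) and a dense `data` matrix is accepted read-only and
#' re-oriented to samples x OTUs.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom_dense"`.
#' @param transpose logical; TSV only, set if rows are OTUs.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom_dense"),
                           transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, comment.char = "",
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- ids
    if (transpose) m <- t(m)
    if (!is.numeric(m)) stopf("non-numeric counts in %s", path)
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!identical(b$matrix_type %||% "dense", "dense")) {
      stopf("only dense BIOM-style JSON is supported")
    }
    m <- t(as.matrix(b$data))           # BIOM stores OTUs x samples
    rownames(m) <- as.character(b$columns$id)
    colnames(m) <- as.character(b$rows$id)
  }
  otu_table(m)
}

#' Write an OTU table as TSV
#'
#' @param t an [otu_table()].
#' @param path output path.
#' @param id_column name of the first (sample id) column.
#' @export
write_otu_table <- function(t, path, id_column = "sample_id") {
  df <- data.frame(rownames(t), as.data.frame(unclass(t), check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identify and remove dataset-wide singleton OTUs
#'
#' A singleton is an OTU represented by exactly one sequence in the whole
#' dataset (total count across all samples equal to 1), not per sample.
#'
#' @param t an [otu_table()].
#' @return `singleton_ids`: character vector of singleton OTU ids.
#' @export
singleton_ids <- function(t) {
  colnames(t)[colSums(t) == 1L]
}

#' @rdname singleton_ids
#' @return `remove_singletons`: the table without singleton OTUs. Samples
#'   whose every sequence was a singleton would become empty and trigger a
#'   validation error.
#' @export
remove_singletons <- function(t) {
  keep <- colSums(t) != 1L
  if (all(keep)) return(t)
  otu_table(unclass(t)[, keep, drop = FALSE])
}

#' Presence/absence transformation
#'
#' @param t an [otu_table()] or numeric matrix.
#' @return numeric matrix with entry 1 where the count is positive, else 0.
#'   Idempotent.
#' @export
presence_absence <- function(t) {
  m <- unclass(t)
  out <- (m > 0) + 0
  dimnames(out) <- dimnames(m)
  out
}
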