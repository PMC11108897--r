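#' Construct and validate an ASV table
#'
#' An `asv_table` bundles a sample-by-ASV count matrix with per-sample
#' metadata and a seven-rank taxonomy for every ASV. Rows are samples
#' throughout the package; columns are ASVs.
#'
#' @param counts Integer matrix, samples in rows, ASVs in columns. Row names
#'   are sample ids, column names ASV ids; both must be unique.
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample_id`, `compartment` (`"bulk"` or `"rhizosphere"`), `host_family`
#'   and `kingdom` (`"bacteria"` or `"fungi"`). Samples present in `counts`
#'   but absent here are an error.
#' @param taxonomy Data frame with one row per ASV: `asv_id` plus the seven
#'   ranks `kingdom`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species`. Ranks may be `"unassigned"`. ASVs without a taxonomy row get
#'   an all-`"unassigned"` lineage.
#'
#' @return An object of class `asv_table` with elements `counts`,
#'   `sample_meta`, `taxonomy`.
#' @export
asv_table <- function(counts, sample_meta, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("counts must have sample ids as row names")
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("counts must have ASV ids as column names")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids in counts")
  if (!is.numeric(counts) || any(is.na(counts))) {
    stop("counts must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("non-integer counts are not allowed")
  storage.mode(counts) <- "integer"

  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "compartment", "host_family", "kingdom")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss)) stop("sample_meta is missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(rownames(counts), sample_meta$sample_id)
  if (length(absent)) {
    stop("samples missing from metadata: ", paste(absent, collapse = ", "))
  }
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(is.na(sample_meta$compartment)) ||
      !all(sample_meta$compartment %in% c("bulk", "rhizosphere"))) {
    stop("compartment must be 'bulk' or 'rhizosphere' for every sample")
  }
  if (!all(sample_meta$kingdom %in% c("bacteria", "fungi"))) {
    stop("kingdom must be 'bacteria' or 'fungi' for every sample")
  }

  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(asv_id = colnames(counts), stringsAsFactors = FALSE)
    for (r in ranks) taxonomy[[r]] <- "unassigned"
  } else {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (!"asv_id" %in% names(taxonomy)) stop("taxonomy needs an asv_id column")
    miss <- setdiff(ranks, names(taxonomy))
    if (length(miss)) stop("taxonomy is missing ranks: ", paste(miss, collapse = ", "))
    if (anyDuplicated(taxonomy$asv_id)) stop("duplicate ASV ids in taxonomy")
    idx <- match(colnames(counts), taxonomy$asv_id)
    taxonomy <- taxonomy[, c("asv_id", ranks)]
    filled <- data.frame(asv_id = colnames(counts), stringsAsFactors = FALSE)
    for (r in ranks) {
      v <- taxonomy[[r]][idx]
      v[is.na(v)] <- "unassigned"
      filled[[r]] <- v
    }
    taxonomy <- filled
  }
  rownames(taxonomy) <- NULL

  structure(
    list(counts = counts, sample_meta = sample_meta, taxonomy = taxonomy),
    class = "asv_table"
  )
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf(
    "asv_table: %d samples x %d ASVs (%d bulk, %d rhizosphere)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$sample_meta$compartment == "bulk"),
    sum(x$sample_meta$compartment == "rhizosphere")
  ))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Sample ids and ASV ids of a table
#' @param table An `asv_table`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
asv_ids <- function(table) colnames(table$counts)

#' Subset an ASV table by samples and/or ASVs
#'
#' @param table An `asv_table`.
#' @param samples,asvs Character vectors of ids (or logical/integer indices)
#'   to keep; `NULL` keeps all.
#' @return A validated `asv_table`.
#' @export
subset_asv_table <- function(table, samples = NULL, asvs = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  asv_table(counts, table$sample_meta, table$taxonomy)
}

#' Read an ASV count table and its sample metadata
#'
#' Count tables are tab-separated with ASV ids in the first column and sample
#' ids in the header (ASVs in rows on disk, the conventional amplicon layout);
#' the in-memory object is transposed to samples-by-ASVs. Metadata is
#' tab-separated keyed by `sample_id`. An optional taxonomy file has
#' `asv_id` plus seven rank columns.
#'
#' @param path Count table TSV.
#' @param meta_path Sample metadata TSV.
#' @param taxonomy_path Optional taxonomy TSV.
#' @return An `asv_table`.
#' @export
read_asv_table <- function(path, meta_path, taxonomy_path = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1, stringsAsFactors = FALSE)
  counts <- t(as.matrix(raw))
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    taxonomy <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                                  check.names = FALSE, stringsAsFactors = FALSE)
  }
  asv_table(counts, meta, taxonomy)
}

#' Write an ASV table (counts, metadata, taxonomy) as TSV files
#'
#' Writers round-trip losslessly with [read_asv_table()].
#'
#' @param table An `asv_table`.
#' @param path Count table destination (ASVs in rows).
#' @param meta_path,taxonomy_path Optional destinations for metadata and
#'   taxonomy.
#' @return Invisibly, `table`.
#' @export
write_asv_table <- function(table, path, meta_path = NULL, taxonomy_path = NULL) {
  m <- t(table$counts)
  df <- data.frame(asv_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(table$sample_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(taxonomy_path)) {
    utils::write.table(table$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(table)
}

#' Construct a set of ASV sequences
#'
#' @param records Named character vector, `asv_id -> DNA string` over
#'   `A`,`C`,`G`,`T`,`N`,`-` (case-insensitive).
#' @param aligned Logical; if `TRUE` all sequences must have equal length.
#' @return An object of class `sequence_set`.
#' @export
sequence_set <- function(records, aligned = FALSE) {
  if (is.null(names(records)) || anyDuplicated(names(records))) {
    stop("records must be uniquely named by ASV id")
  }
  records <- stats::setNames(toupper(as.character(records)), names(records))
  if (any(nchar(records) == 0)) stop("empty sequences are not allowed")
  bad <- grepl("[^ACGTN-]", records)
  if (any(bad)) {
    stop("invalid characters in sequences: ", paste(names(records)[bad], collapse = ", "))
  }
  if (aligned && length(unique(nchar(records))) > 1) {
    stop("aligned sequence sets must have equal lengths")
  }
  structure(list(records = records, aligned = aligned), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d sequences%s, lengths %s\n",
              length(x$records), if (x$aligned) " (aligned)" else "",
              paste(range(nchar(x$records)), collapse = "-")))
  invisible(x)
}

#' Read / write FASTA sequence sets
#'
#' @param path FASTA file.
#' @param aligned Whether to treat (and validate) the set as aligned.
#' @return `read_fasta`: a `sequence_set`; `write_fasta`: invisibly the set.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(starts[i], ends[i])], collapse = "")
  }, character(1))
  sequence_set(stats::setNames(seqs, ids), aligned = aligned)
}

#' @rdname read_fasta
#' @param seqs A `sequence_set`.
#' @export
write_fasta <- function(seqs, path) {
  out <- character(2L * length(seqs$records))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs$records))
  out[c(FALSE, TRUE)] <- unname(seqs$records)
  writeLines(out, path)
  invisible(seqs)
}
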