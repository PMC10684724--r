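#' Read a per-sample amplicon read-count table
#'
#' Reads a TSV with columns `sample_id`, `gene`, `amplicon`, `read_count`,
#' the raw input of ratio-based copy-number calling. Each sample must carry
#' exactly six cells (2 genes x 3 amplicons).
#'
#' @param path Path to a tab-separated file.
#' @param validate Check the 6-cell-per-sample invariant (default `TRUE`).
#' @return A tibble with columns `sample_id`, `gene`, `amplicon`,
#'   `read_count`.
#' @export
read_counts_tsv <- function(path, validate = TRUE) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "integer"))
  required <- c("sample_id", "gene", "amplicon", "read_count")
  if (!all(required %in% names(df))) {
    stop("counts TSV must have columns: ", paste(required, collapse = ", "))
  }
  df <- df[required]
  bad_gene <- which(!df$gene %in% GENES)
  if (length(bad_gene)) {
    stop("unknown gene at line(s) ",
         paste(head(bad_gene + 1L, 5), collapse = ", "),
         " (expected MICA or MICB)")
  }
  bad_amp <- which(!df$amplicon %in% AMPLICONS)
  if (length(bad_amp)) {
    stop("unknown amplicon at line(s) ",
         paste(head(bad_amp + 1L, 5), collapse = ", "),
         " (expected exon2, exon3 or exon45)")
  }
  bad_count <- which(is.na(df$read_count) | df$read_count < 0)
  if (length(bad_count)) {
    stop("missing or negative read_count at line(s) ",
         paste(head(bad_count + 1L, 5), collapse = ", "))
  }
  if (validate) {
    cells <- table(df$sample_id)
    off <- names(cells)[cells != 6L]
    if (length(off)) {
      stop("samples without exactly 6 count cells: ",
           paste(head(off, 5), collapse = ", "))
    }
  }
  as_tibble(df)
}

#' Write a per-sample amplicon read-count table
#'
#' @param counts Tibble as returned by [simulate_counts()] or
#'   [read_counts_tsv()].
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file (60-column wrapped)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width, default 60.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  x <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(intervals))) {
    stop("intervals need columns chrom, start, end")
  }
  if (any(intervals$end <= intervals$start)) {
    stop("BED intervals must satisfy start < end")
  }
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  write.table(intervals[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path Path to a 3- or 4-column BED file.
#' @return Tibble with columns `chrom`, `start`, `end` (and `name`).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name")[seq_along(df)]
  as_tibble(df)
}

#' Write a result table as TSV or JSON
#'
#' @param rows Data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_table_output <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Convert between BED and 1-based inclusive interval conventions
#'
#' File output uses 0-based half-open intervals (BED); human-readable
#' reports use 1-based inclusive coordinates. These two helpers own the
#' off-by-one in both directions; composing them is the identity.
#'
#' @param start,end 0-based half-open interval.
#' @return `interval_to_report()`: named vector `c(first, last)` (1-based
#'   inclusive). `interval_from_report()`: named vector `c(start, end)`
#'   (0-based half-open).
#' @export
interval_to_report <- function(start, end) {
  stopifnot(end > start)
  c(first = start + 1L, last = end)
}

#' @rdname interval_to_report
#' @param first,last 1-based inclusive interval.
#' @export
interval_from_report <- function(first, last) {
  stopifnot(last >= first)
  c(start = first - 1L, end = last)
}
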