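#' Read a FASTA file into sequence records
#'
#' Wraps [Biostrings::readBStringSet()] and validates each entry against the
#' declared alphabet. Header lines are split at the first whitespace into
#' identifier and description; sequences are upper-cased and line breaks
#' removed. Duplicate identifiers and characters outside the alphabet are
#' errors; an empty file yields an empty list.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A list of [seq_record] objects, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate identifier in ", path, ": ", sQuote(dup[1L]))
  }
  seqs <- toupper(as.character(set))
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    records[[i]] <- seq_record(ids[i], seqs[i], alphabet, descs[i])
  }
  records
}

#' Write sequence records to a FASTA file
#'
#' @param records List of [seq_record] objects.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.numeric(width), width >= 1)
  if (length(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  for (r in records) {
    if (!inherits(r, "seq_record")) stop("records must be seq_record objects")
  }
  headers <- vapply(records, function(r) {
    if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
  }, character(1))
  seqs <- vapply(records, `[[`, character(1), "seq")
  set <- Biostrings::BStringSet(stats::setNames(seqs, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

# numeric columns expected per table kind; used both for header detection
# and for parsing. Column indices refer to the physical column order.
TABLE_KINDS <- list(
  signal_peptide = list(names = c("protein_id", "sp_end", "score"),
                        numeric = c(2L, 3L), min_cols = 2L),
  domain_hit = list(names = c("protein_id", "domain_name", "start", "end"),
                    numeric = c(3L, 4L), min_cols = 4L),
  similarity_hit = list(names = c("query_id", "subject_id", "pident",
                                  "length", "mismatch", "gapopen", "qstart",
                                  "qend", "sstart", "send", "evalue",
                                  "bitscore"),
                        numeric = 3:12, min_cols = 12L),
  ms_peptide = list(names = c("sequence", "amidated", "pyroglu"),
                    numeric = c(2L, 3L), min_cols = 1L),
  counts = list(names = NULL, numeric = NULL, min_cols = 2L),
  library_size = list(names = c("stage", "total_reads"),
                      numeric = 2L, min_cols = 2L)
)

#' Read a tab-separated annotation table
#'
#' Reads the plain-text tables the pipeline imports: signal-peptide calls,
#' protein-domain hits, pairwise similarity hits in the 12-column BLAST
#' tabular ("m8") dialect, observed MS peptide lists, per-stage read counts,
#' and per-stage library sizes. Lines starting with `#` are ignored. A
#' header line is detected when a cell in a column expected to be numeric is
#' not parseable as a number. Ragged rows and unparseable numeric cells
#' (including e-values) are errors reporting the offending line.
#'
#' @param path Path to a tab-separated file.
#' @param table_kind One of `"signal_peptide"`, `"domain_hit"`,
#'   `"similarity_hit"`, `"ms_peptide"`, `"counts"`, `"library_size"`.
#' @return A `data.frame`, one row per data line, in file order, with an
#'   attribute `table_kind`. For `counts` the first column holds gene
#'   identifiers and all remaining columns are numeric.
#' @export
read_table <- function(path, table_kind = names(TABLE_KINDS)) {
  table_kind <- match.arg(table_kind)
  spec <- TABLE_KINDS[[table_kind]]
  if (!file.exists(path)) stop("table file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_table(table_kind, spec))

  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(cells)
  if (any(ncols != ncols[1L])) {
    bad <- which(ncols != ncols[1L])[1L]
    stop("ragged row in ", path, " at line ", line_no[bad], ": expected ",
         ncols[1L], " columns, found ", ncols[bad])
  }
  nc <- ncols[1L]
  if (nc < spec$min_cols) {
    stop(table_kind, " table requires at least ", spec$min_cols,
         " columns, found ", nc)
  }
  num_cols <- if (table_kind == "counts") seq(2L, nc) else
    spec$numeric[spec$numeric <= nc]

  # header detection: every expected-numeric cell of line 1 is non-numeric
  # (a single unparseable cell in an otherwise numeric row is an error,
  # not a header)
  header <- NULL
  if (length(num_cols)) {
    first <- cells[[1L]]
    if (all(is.na(suppressWarnings(as.numeric(first[num_cols]))))) {
      header <- first
      cells <- cells[-1L]
      line_no <- line_no[-1L]
    }
  }
  if (length(cells) == 0L) return(empty_table(table_kind, spec, header))

  mat <- do.call(rbind, cells)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  for (j in num_cols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("column ", j, " of ", path, " is not numeric at line ",
           line_no[bad], ": ", sQuote(df[[j]][bad]))
    }
    df[[j]] <- v
  }
  names(df) <- table_columns(table_kind, spec, nc, header)
  attr(df, "table_kind") <- table_kind
  df
}

table_columns <- function(table_kind, spec, nc, header) {
  if (table_kind == "counts") {
    if (!is.null(header)) return(make.unique(header))
    return(c("gene_id", paste0("stage", seq_len(nc - 1L))))
  }
  nm <- spec$names
  if (nc <= length(nm)) nm[seq_len(nc)]
  else c(nm, paste0("extra", seq_len(nc - length(nm))))
}

empty_table <- function(table_kind, spec, header = NULL) {
  nc <- if (!is.null(header)) length(header) else max(spec$min_cols,
                                                      length(spec$names))
  df <- as.data.frame(matrix(character(0), nrow = 0, ncol = nc),
                      stringsAsFactors = FALSE)
  names(df) <- table_columns(table_kind, spec, nc, header)
  attr(df, "table_kind") <- table_kind
  df
}

#' Write a data frame as a tab-separated table
#'
#' Counterpart of [read_table()]; writes a header line and no quoting.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
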