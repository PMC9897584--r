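#' Parse 12-column BLAST tabular output
#'
#' Reads `-outfmt 6` style tab-separated BLAST results. Rows are returned in
#' file order with numeric fields typed; a row with the wrong column count is
#' an error reporting the row index.
#'
#' @param x path to a BLAST tabular file, or its text.
#' @return data frame with the standard 12 columns (`query_id`, `target_id`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
parse_blast_tabular <- function(x) {
  lines <- .read_stream_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(
      query_id = character(), target_id = character(), pident = numeric(),
      length = integer(), mismatch = integer(), gapopen = integer(),
      qstart = integer(), qend = integer(), sstart = integer(),
      send = integer(), evalue = numeric(), bitscore = numeric(),
      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("BLAST tabular row ", which(nf != 12L)[1],
         " has ", nf[nf != 12L][1], " columns (expected 12)")
  }
  m <- do.call(rbind, fields)
  out <- data.frame(query_id = m[, 1], target_id = m[, 2],
                    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  out
}

#' Parse a transmembrane-segment table
#'
#' Reads TMHMM-style long-format lines (`protein  source  kind  start  end`,
#' whitespace-separated; `#` comment lines ignored) into typed segments.
#' `kind` is one of `TMhelix`, `inside`, `outside`. Overlapping segments for
#' one protein are an error.
#'
#' @param x path to a table, or its text.
#' @return data frame with columns `protein_id`, `source`, `kind`, `start`,
#'   `end`, ordered as in the file.
#' @export
parse_tm_table <- function(x) {
  lines <- .read_stream_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(data.frame(protein_id = character(), source = character(),
                      kind = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    stop("transmembrane table line ", which(nf != 5L)[1], " does not have 5 fields")
  }
  m <- do.call(rbind, fields)
  out <- data.frame(protein_id = m[, 1], source = m[, 2], kind = m[, 3],
                    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                    stringsAsFactors = FALSE)
  bad <- !out$kind %in% c("TMhelix", "inside", "outside")
  if (any(bad)) {
    stop("unknown segment kind '", out$kind[bad][1], "' in transmembrane table")
  }
  if (any(out$start > out$end)) stop("segment with start > end in transmembrane table")
  for (p in unique(out$protein_id)) {
    seg <- out[out$protein_id == p, ]
    seg <- seg[order(seg$start), ]
    if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)])) {
      stop("overlapping segments for protein ", p)
    }
  }
  out
}

#' Write a transmembrane-segment table
#'
#' @param segments data frame as returned by [parse_tm_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tm_table <- function(segments, path) {
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d", segments$protein_id,
                     segments$source, segments$kind, segments$start,
                     segments$end), path)
  invisible(path)
}
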