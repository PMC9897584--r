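# The 20 standard residues plus X; B/Z/U are collapsed to X on input.
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALLOWED <- c(AA_STANDARD, "X")

# Resolve a "stream" argument: a path to an existing file is used as-is,
# anything else is treated as literal text and spooled to a temp file.
.as_input_file <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(list(path = x, temp = FALSE))
  }
  tf <- tempfile()
  writeLines(paste(x, collapse = "\n"), tf)
  list(path = tf, temp = TRUE)
}

.read_stream_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE), use.names = FALSE)
}

#' Shorten a proteome accession to its bare numeric form
#'
#' Coral gene-model accessions such as `pdam_00017423-RA` are conventionally
#' referred to by their bare numbers (here `"17423"`). The shortener strips a
#' lowercase organism prefix, leading zeros, and a trailing transcript suffix;
#' identifiers not of that shape are returned unchanged.
#'
#' @param id character vector of sequence identifiers.
#' @return character vector of the same length.
#' @examples
#' short_protein_id("pdam_00017423-RA") # "17423"
#' short_protein_id("OPSD_HUMAN")       # unchanged
#' @export
short_protein_id <- function(id) {
  m <- regmatches(id, regexec("^[a-z]+_0*([0-9]+)(-R[A-Z0-9]+)?$", id))
  vapply(seq_along(id), function(i) {
    if (length(m[[i]]) >= 2L) m[[i]][2L] else id[i]
  }, character(1))
}

#' Read a FASTA protein collection
#'
#' Parses FASTA text into a data frame of protein records. Sequences are
#' uppercased; the ambiguity codes B, Z and U are mapped to X with a warning,
#' and any other non-standard letter is an error naming the offending record.
#' Record ids (the first whitespace-delimited header token) must be unique.
#'
#' @param x path to a FASTA file, or FASTA text.
#' @return a `protein_set` data frame with columns `id`, `description`,
#'   `sequence` and `short_id` (see [short_protein_id()]).
#' @seealso [write_fasta()]
#' @export
parse_fasta <- function(x) {
  inp <- .as_input_file(x)
  on.exit(if (inp$temp) unlink(inp$path))
  if (file.size(inp$path) == 0) {
    return(.protein_set(character(), character(), character()))
  }
  aa <- Biostrings::readBStringSet(inp$path, format = "fasta")
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  mapped <- grepl("[BZU]", seqs)
  if (any(mapped)) {
    warning("ambiguous residue letters B/Z/U mapped to X in: ",
            paste(ids[mapped], collapse = ", "))
    seqs <- gsub("[BZU]", "X", seqs)
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs)
  if (any(bad)) {
    stop("sequence letters outside the amino-acid alphabet in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  .protein_set(ids, desc, seqs)
}

.protein_set <- function(id, description, sequence) {
  out <- data.frame(id = id, description = description, sequence = sequence,
                    short_id = short_protein_id(id), stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Write protein records as FASTA
#'
#' @param records a `protein_set` data frame (or any data frame with `id`,
#'   `description`, `sequence` columns).
#' @param path output file path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description), records$id)
  aa <- Biostrings::BStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("Protein set: %d record(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    cat(sprintf("  %s (%d aa)\n", show$id, nchar(show$sequence)), sep = "")
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}
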