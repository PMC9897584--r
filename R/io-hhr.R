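# HHR result files: a header, a fixed-ish summary hit list
# (" No Hit ... Prob E-value P-value Score SS Cols Query-HMM Template-HMM"),
# then one alignment block per hit introduced by "No <rank>".

#' Construct a remote-homology hit table
#'
#' A hit table is one query's ranked list of remote-homology hits, as produced
#' by an HHblits-style search. Ranks must be consecutive from 1 in source
#' order; probabilities are on the printed 0-100 scale.
#'
#' @param query_id the query protein id.
#' @param hits data frame with columns `rank`, `target_id`, `probability`,
#'   `evalue`, `pvalue`, `score`, `cols_matched`, `query_start`, `query_end`,
#'   `target_start`, `target_end`, `query_aln`, `target_aln`. Missing columns
#'   are filled with `NA` / empty alignments.
#' @return an object of class `hit_table`.
#' @export
hit_table <- function(query_id, hits) {
  stopifnot(is.character(query_id), length(query_id) == 1L)
  template <- data.frame(
    rank = integer(), target_id = character(), probability = numeric(),
    evalue = numeric(), pvalue = numeric(), score = numeric(),
    cols_matched = integer(), query_start = integer(), query_end = integer(),
    target_start = integer(), target_end = integer(),
    query_aln = character(), target_aln = character(),
    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    for (col in names(template)) {
      if (is.null(hits[[col]])) {
        hits[[col]] <- if (is.character(template[[col]])) "" else NA
      }
    }
    hits <- hits[names(template)]
    if (!identical(as.integer(hits$rank), seq_len(nrow(hits)))) {
      stop("hit ranks must be consecutive from 1 for query ", query_id)
    }
    if (any(hits$probability < 0 | hits$probability > 100, na.rm = TRUE)) {
      stop("probabilities must lie in [0, 100] for query ", query_id)
    }
  } else {
    hits <- template
  }
  structure(list(query_id = query_id, hits = hits), class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("Hit table for query '%s': %d hit(s)\n", x$query_id, nrow(x$hits)))
  if (nrow(x$hits)) {
    print(utils::head(x$hits[c("rank", "target_id", "probability", "evalue", "score")], 10L))
  }
  invisible(x)
}

.HHR_SUMMARY_RE <- paste0(
  "^\\s*(\\d+)\\s+(.*?)\\s+([0-9.]+)\\s+(\\S+)\\s+(\\S+)\\s+",
  "(-?[0-9.]+)\\s+(-?[0-9.]+)\\s+(\\d+)\\s+(\\d+)-(\\d+)\\s+",
  "(\\d+)-(\\d+)\\s*\\((\\d+)\\)\\s*$")

#' Parse an HHR remote-homology result file
#'
#' Reads the summary hit list (ranks, probabilities, E-/P-values, scores,
#' matched columns, alignment spans) and the per-hit alignment blocks of an
#' HHR-format search result. Hits are kept in file order with `rank` taken
#' from the listed "No" column; scientific-notation E-values are accepted.
#' A hit listed in the summary but lacking an alignment block is retained
#' with empty alignment fields and a warning.
#'
#' @param x path to an HHR file, or its text.
#' @return a [hit_table()].
#' @export
parse_hhr <- function(x) {
  lines <- .read_stream_lines(x)
  qline <- grep("^Query\\s+", lines, value = TRUE)
  query_id <- if (length(qline)) sub("^Query\\s+(\\S+).*$", "\\1", qline[1]) else NA_character_
  hdr <- grep("^\\s*No Hit", lines)
  if (!length(hdr)) {
    if (any(grepl("No hits found", lines, fixed = TRUE))) {
      return(hit_table(query_id, data.frame()))
    }
    stop("not an HHR result: summary header line ' No Hit ...' not found")
  }
  hdr <- hdr[1]
  # summary block: until the first blank line / first alignment block
  i <- hdr + 1L
  rows <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^No\\s+\\d+\\s*$", ln)) break
    if (grepl("No hits found", ln, fixed = TRUE)) break
    m <- regmatches(ln, regexec(.HHR_SUMMARY_RE, ln))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed HHR summary line %d: '%s'", i, ln))
    }
    target_id <- sub("\\s.*$", "", m[3])
    rows[[length(rows) + 1L]] <- data.frame(
      rank = as.integer(m[2]), target_id = target_id,
      probability = as.numeric(m[4]), evalue = as.numeric(m[5]),
      pvalue = as.numeric(m[6]), score = as.numeric(m[7]),
      cols_matched = as.integer(m[9]),
      query_start = as.integer(m[10]), query_end = as.integer(m[11]),
      target_start = as.integer(m[12]), target_end = as.integer(m[13]),
      stringsAsFactors = FALSE)
    i <- i + 1L
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!nrow(hits)) return(hit_table(query_id, data.frame()))

  aln <- .parse_hhr_alignments(lines)
  hits$query_aln <- ""
  hits$target_aln <- ""
  for (j in seq_len(nrow(hits))) {
    blk <- aln[[as.character(hits$rank[j])]]
    if (is.null(blk)) next
    hits$query_aln[j] <- blk$query_aln
    hits$target_aln[j] <- blk$target_aln
    # spans from the alignment block take precedence when present
    if (!is.na(blk$query_start)) {
      hits$query_start[j] <- blk$query_start; hits$query_end[j] <- blk$query_end
      hits$target_start[j] <- blk$target_start; hits$target_end[j] <- blk$target_end
    }
  }
  missing <- hits$rank[!nzchar(hits$query_aln)]
  if (length(missing)) {
    warning("no alignment block for listed hit(s) ",
            paste(missing, collapse = ", "), " of query ", query_id)
  }
  hit_table(query_id, hits)
}

.parse_hhr_alignments <- function(lines) {
  starts <- grep("^No\\s+\\d+\\s*$", lines)
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  skip_names <- c("Consensus", "ss_pred", "ss_conf", "ss_dssp")
  for (b in seq_along(starts)) {
    rank <- sub("^No\\s+(\\d+)\\s*$", "\\1", lines[starts[b]])
    blk <- lines[starts[b]:(bounds[b + 1L] - 1L)]
    q_seq <- character(); t_seq <- character()
    qs <- qe <- ts <- te <- NA_integer_
    for (ln in blk) {
      m <- regmatches(ln, regexec(
        "^([QT])\\s+(\\S+)\\s+(\\d+)\\s+(\\S+)\\s+(\\d+)", ln))[[1]]
      if (length(m) == 0L || m[3] %in% skip_names) next
      if (m[2] == "Q") {
        q_seq <- c(q_seq, m[5])
        if (is.na(qs)) qs <- as.integer(m[4])
        qe <- as.integer(m[6])
      } else {
        t_seq <- c(t_seq, m[5])
        if (is.na(ts)) ts <- as.integer(m[4])
        te <- as.integer(m[6])
      }
    }
    out[[rank]] <- list(query_aln = paste(q_seq, collapse = ""),
                        target_aln = paste(t_seq, collapse = ""),
                        query_start = qs, query_end = qe,
                        target_start = ts, target_end = te)
  }
  out
}

#' Write a hit table as an HHR result file
#'
#' Emits the summary hit list and per-hit alignment blocks in the HHR layout
#' accepted by [parse_hhr()]; mainly used by the synthetic-corpus generators.
#'
#' @param table a [hit_table()].
#' @param path output file path.
#' @param match_columns query length reported in the header.
#' @return `path`, invisibly.
#' @export
write_hhr <- function(table, path, match_columns = NULL) {
  h <- table$hits
  if (is.null(match_columns)) {
    match_columns <- if (nrow(h)) max(h$query_end, na.rm = TRUE) else 0L
  }
  out <- c(
    sprintf("Query         %s", table$query_id),
    sprintf("Match_columns %d", as.integer(match_columns)),
    "No_of_seqs    1 out of 1",
    "",
    paste(" No Hit                             Prob E-value P-value  Score",
          "   SS Cols Query HMM  Template HMM"))
  if (!nrow(h)) {
    out <- c(out, "No hits found", "")
    writeLines(out, path)
    return(invisible(path))
  }
  tlen <- ifelse(is.na(h$target_end), 0L, h$target_end)
  for (j in seq_len(nrow(h))) {
    out <- c(out, sprintf(
      "%3d %-30.30s %5.1f %7.2G %7.2G %6.1f %5.1f %4d %4d-%-4d %4d-%-4d (%d)",
      h$rank[j], h$target_id[j], h$probability[j], h$evalue[j], h$pvalue[j],
      h$score[j], 0, h$cols_matched[j], h$query_start[j], h$query_end[j],
      h$target_start[j], h$target_end[j], tlen[j]))
  }
  out <- c(out, "")
  for (j in seq_len(nrow(h))) {
    if (!nzchar(h$query_aln[j])) next
    out <- c(out,
      sprintf("No %d", h$rank[j]),
      sprintf(">%s", h$target_id[j]),
      sprintf("Probab=%.2f  E-value=%.3G  Score=%.2f  Aligned_cols=%d  Identities=0%%",
              h$probability[j], h$evalue[j], h$score[j], h$cols_matched[j]),
      "",
      .hhr_aln_lines(table$query_id, "Q", h$query_aln[j], h$query_start[j]),
      .hhr_aln_lines(h$target_id[j], "T", h$target_aln[j], h$target_start[j]),
      "")
  }
  writeLines(out, path)
  invisible(path)
}

.hhr_aln_lines <- function(id, side, aln, start, width = 60L) {
  n <- nchar(aln)
  pos <- start
  lines <- character()
  for (off in seq(1L, n, by = width)) {
    chunk <- substr(aln, off, min(off + width - 1L, n))
    nres <- nchar(gsub("-", "", chunk))
    end <- pos + max(nres - 1L, 0L)
    lines <- c(lines, sprintf("%s %-14.14s %4d %s %4d (%d)",
                              side, id, pos, chunk, end, 0L))
    pos <- end + if (nres > 0) 1L else 0L
  }
  lines
}
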