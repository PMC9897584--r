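# Domain-architecture logic for type I receptor candidates: scan sequences
# with PROSITE patterns, place the hits on the extracellular or cytoplasmic
# side of the (predicted, externally supplied) transmembrane helix, and
# classify the composition against the TLR archetype (extracellular
# leucine-rich repeats + cytoplasmic TIR domain).

#' Scan a sequence with a PROSITE pattern
#'
#' Matches use standard PROSITE semantics: variable repeats are greedy with
#' backtracking, so every distinct start position yields at most one hit.
#' `mode = "all"` reports a hit at every start position where the pattern
#' matches; `mode = "scan"` reports non-overlapping hits left to right.
#' `<`/`>` anchors restrict hits to the sequence start/end.
#'
#' @param seq a one-row `protein_set` data frame, or a sequence string.
#' @param pattern a [prosite_pattern()].
#' @param mode `"all"` (default) or `"scan"`.
#' @param protein_id id recorded in the hits (taken from `seq` if a record).
#' @return data frame with columns `pattern_id`, `protein_id`, `start`,
#'   `end`, `matched_text` (the hit's sequence slice).
#' @export
scan_pattern <- function(seq, pattern, mode = c("all", "scan"),
                         protein_id = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(seq)) {
    protein_id <- seq$id[1]
    seq <- seq$sequence[1]
  }
  if (is.null(protein_id)) protein_id <- "seq"
  n <- nchar(seq)
  rx <- paste0("^(", .pattern_regex(pattern), ")")
  starts <- if (pattern$anchored_start) 1L else seq_len(n)
  hits <- list()
  i <- 1L
  while (i <= length(starts)) {
    s <- starts[i]
    m <- regexpr(rx, substring(seq, s), perl = TRUE)
    len <- attr(m, "match.length")
    ok <- m == 1L && len > 0L
    if (ok && pattern$anchored_end && s + len - 1L != n) {
      # greedy match not flush with the end: try the longest end-flush length
      ok <- .matches_exact(pattern, substring(seq, s, n))
      len <- n - s + 1L
    }
    if (ok) {
      hits[[length(hits) + 1L]] <- c(start = s, end = s + len - 1L)
      if (mode == "scan") {
        i <- which(starts > s + len - 1L)[1]
        if (is.na(i)) break
        next
      }
    }
    i <- i + 1L
  }
  if (!length(hits)) {
    return(data.frame(pattern_id = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  data.frame(pattern_id = pattern$pattern_id, protein_id = protein_id,
             start = unname(h[, "start"]), end = unname(h[, "end"]),
             matched_text = substring(seq, h[, "start"], h[, "end"]),
             stringsAsFactors = FALSE)
}

# Does the pattern match `text` exactly (whole string)?
.matches_exact <- function(pattern, text) {
  grepl(paste0("^(", .pattern_regex(pattern), ")$"), text, perl = TRUE)
}

#' Scan several sequences with several patterns
#'
#' @param seqs a `protein_set` data frame.
#' @param patterns list of [prosite_pattern()]s.
#' @param mode passed to [scan_pattern()].
#' @return row-bound hit data frame over all (sequence, pattern) pairs.
#' @export
scan_patterns <- function(seqs, patterns, mode = "all") {
  out <- list()
  for (i in seq_len(nrow(seqs))) {
    for (p in patterns) {
      out[[length(out) + 1L]] <- scan_pattern(seqs[i, , drop = FALSE], p,
                                              mode = mode)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Place domain hits relative to the transmembrane helix
#'
#' For a single-TM (type I) receptor with the default `n_term_out`
#' orientation, domains ending before the TM helix are extracellular and
#' domains starting after it are cytoplasmic; domains overlapping the helix
#' are straddling. `n_term_in` swaps the two sides. With no TM segment all
#' domains are returned unplaced, with a warning.
#'
#' @param hits domain-hit data frame from [scan_pattern()].
#' @param tms transmembrane segments from [parse_tm_table()] (only `TMhelix`
#'   rows are used); more than one helix is an error for type-I logic.
#' @param orientation `"n_term_out"` (type I convention, default) or
#'   `"n_term_in"`.
#' @return list of data frames `ec`, `cp`, `straddling`, `unplaced`; every
#'   hit appears in exactly one of them. `tm_count` is attached as an
#'   attribute.
#' @export
place_domains <- function(hits, tms, orientation = c("n_term_out", "n_term_in")) {
  orientation <- match.arg(orientation)
  helices <- tms[tms$kind == "TMhelix", , drop = FALSE]
  empty <- hits[0, , drop = FALSE]
  if (nrow(helices) > 1L) {
    stop("type-I placement requires at most one TM helix (found ",
         nrow(helices), ")")
  }
  if (nrow(helices) == 0L) {
    warning("no TM segment: domains left unplaced")
    return(structure(list(ec = empty, cp = empty, straddling = empty,
                          unplaced = hits), tm_count = 0L))
  }
  tm <- helices[1L, ]
  before <- hits$end < tm$start
  after <- hits$start > tm$end
  straddling <- !before & !after
  n_side <- hits[before, , drop = FALSE]
  c_side <- hits[after, , drop = FALSE]
  out <- if (orientation == "n_term_out") {
    list(ec = n_side, cp = c_side)
  } else {
    list(ec = c_side, cp = n_side)
  }
  out$straddling <- hits[straddling, , drop = FALSE]
  out$unplaced <- empty
  structure(out, tm_count = 1L)
}

#' Classify a placed domain architecture against the TLR archetype
#'
#' Categories: `canonical_TLR` (>= `min_lrr` extracellular LRRs, cytoplasmic
#' TIR, no extra extracellular domain classes); `TLR_with_extra_domains`
#' (canonical plus extra extracellular domain classes such as cadherin or
#' calcium-binding EGF); `TIR_only` (TIR present, no LRRs anywhere);
#' `LRR_only` (LRRs present, no TIR - rejected as a TLR); otherwise
#' `not_TLR`. The category is a pure function of the placed domain sets;
#' hit order never matters.
#'
#' @param placed result of [place_domains()].
#' @param protein_id id recorded in the call.
#' @param lrr_ids,tir_ids pattern ids counted as LRR / TIR evidence.
#' @param extra_classes pattern ids of recognised extra ectodomain classes.
#' @param min_lrr minimum number of extracellular LRR hits for the canonical
#'   call (default 1; the LRR count is reported so stricter cutoffs can be
#'   applied downstream).
#' @return object of class `architecture_call`: `protein_id`, `ec_domains`,
#'   `cp_domains`, `tm_count`, `lrr_count`, `category`, `evidence`.
#' @export
classify_tlr <- function(placed, protein_id = NULL, lrr_ids = "LRR",
                         tir_ids = "TIR",
                         extra_classes = c("CADHERIN", "EGF_CA", "TSP3",
                                           "TSP_CTER"),
                         min_lrr = 1L) {
  all_hits <- rbind(placed$ec, placed$cp, placed$straddling, placed$unplaced)
  if (is.null(protein_id)) {
    protein_id <- if (nrow(all_hits)) all_hits$protein_id[1] else "protein"
  }
  ec <- placed$ec$pattern_id
  cp <- placed$cp$pattern_id
  n_lrr_ec <- sum(ec %in% lrr_ids)
  n_lrr_any <- sum(all_hits$pattern_id %in% lrr_ids)
  has_tir_cp <- any(cp %in% tir_ids)
  has_tir_any <- any(all_hits$pattern_id %in% tir_ids)
  extra_ec <- sort(unique(ec[ec %in% extra_classes]))
  other_ec <- sort(unique(ec[!ec %in% c(lrr_ids, tir_ids)]))

  category <- if (n_lrr_ec >= min_lrr && has_tir_cp && length(other_ec) == 0L) {
    "canonical_TLR"
  } else if (n_lrr_ec >= min_lrr && has_tir_cp && length(extra_ec) > 0L &&
             setequal(other_ec, extra_ec)) {
    "TLR_with_extra_domains"
  } else if (has_tir_any && n_lrr_any == 0L) {
    "TIR_only"
  } else if (n_lrr_any > 0L && !has_tir_any) {
    "LRR_only"
  } else {
    "not_TLR"
  }
  evidence <- sprintf(
    "EC: %s | CP: %s | TM helices: %d | LRR(ec)=%d TIR(cp)=%s extra(ec)=%s",
    if (length(ec)) paste(ec, collapse = ",") else "none",
    if (length(cp)) paste(cp, collapse = ",") else "none",
    attr(placed, "tm_count"), n_lrr_ec, has_tir_cp,
    if (length(extra_ec)) paste(extra_ec, collapse = ",") else "none")
  structure(list(protein_id = protein_id, ec_domains = ec, cp_domains = cp,
                 tm_count = attr(placed, "tm_count"), lrr_count = n_lrr_ec,
                 category = category, evidence = evidence),
            class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat(sprintf("%s: %s\n  %s\n", x$protein_id, x$category, x$evidence))
  invisible(x)
}

#' Scan, place and classify a set of candidate receptors
#'
#' Convenience wrapper running [scan_patterns()], [place_domains()] and
#' [classify_tlr()] per protein.
#'
#' @param seqs a `protein_set` data frame.
#' @param patterns list of [prosite_pattern()]s.
#' @param tms transmembrane-segment table covering the proteins.
#' @param ... passed to [classify_tlr()].
#' @return data frame with one row per protein: `protein_id`, `category`,
#'   `lrr_count`, `tm_count`, `evidence`.
#' @export
classify_architectures <- function(seqs, patterns, tms, ...) {
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    hits <- scan_patterns(seqs[i, , drop = FALSE], patterns)
    ptms <- tms[tms$protein_id == id, , drop = FALSE]
    placed <- if (nrow(ptms[ptms$kind == "TMhelix", ])) {
      place_domains(hits, ptms)
    } else {
      suppressWarnings(place_domains(hits, ptms))
    }
    call <- classify_tlr(placed, protein_id = id, ...)
    data.frame(protein_id = id, category = call$category,
               lrr_count = call$lrr_count, tm_count = call$tm_count,
               evidence = call$evidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
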