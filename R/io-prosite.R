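# PROSITE PA-line pattern syntax: dash-separated elements, each a literal
# residue, `x` (any), `[..]` (allowed set) or `{..}` (forbidden set), with an
# optional repeat `(n)` or `(n,m)`; `<` anchors the match to the sequence
# start, `>` to the end; a trailing `.` closes the pattern.

#' Parse a single PROSITE pattern
#'
#' @param text pattern in PA syntax, e.g. `"C-x(2)-[DE]-{P}."`.
#' @param pattern_id identifier attached to the pattern (and to its hits).
#' @return an object of class `prosite_pattern` with fields `pattern_id`,
#'   `elements` (list of `type`/`residues`/`min`/`max`), `anchored_start`,
#'   `anchored_end`.
#' @seealso [parse_prosite_patterns()], [scan_pattern()]
#' @export
prosite_pattern <- function(text, pattern_id = "pattern") {
  raw <- gsub("\\s", "", text)
  pat <- sub("\\.$", "", raw)
  anchored_start <- startsWith(pat, "<")
  if (anchored_start) pat <- substring(pat, 2L)
  anchored_end <- endsWith(pat, ">")
  if (anchored_end) pat <- substring(pat, 1L, nchar(pat) - 1L)
  if (!nzchar(pat)) stop("empty PROSITE pattern: '", text, "'")
  toks <- strsplit(pat, "-", fixed = TRUE)[[1]]
  elements <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- toks[i]
    m <- regmatches(tok, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\((\\d+)(,(\\d+))?\\))?$", tok))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("cannot parse PROSITE element %d ('%s') of '%s'", i, tok, text))
    }
    core <- m[2]
    n <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    mx <- if (nzchar(m[6])) as.integer(m[6]) else n
    if (n > mx) stop("repeat bounds reversed in element ", i, " of '", text, "'")
    el <- if (core == "x") {
      list(type = "any", residues = "")
    } else if (startsWith(core, "[")) {
      list(type = "set", residues = substr(core, 2L, nchar(core) - 1L))
    } else if (startsWith(core, "{")) {
      list(type = "notset", residues = substr(core, 2L, nchar(core) - 1L))
    } else {
      list(type = "literal", residues = core)
    }
    el$min <- n
    el$max <- mx
    elements[[i]] <- el
  }
  structure(list(pattern_id = pattern_id, elements = elements,
                 anchored_start = anchored_start, anchored_end = anchored_end),
            class = "prosite_pattern")
}

#' Parse a PROSITE pattern file
#'
#' Accepts either bare PA-syntax lines (one pattern per line, optionally
#' `id<TAB>pattern`) or PROSITE flat-file style `ID`/`PA` line pairs.
#' Multi-line `PA` continuation records are concatenated.
#'
#' @param x path to a pattern file, or its text.
#' @return list of [prosite_pattern()] objects.
#' @export
parse_prosite_patterns <- function(x) {
  lines <- .read_stream_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  if (any(grepl("^(ID|PA)\\s", lines))) {
    cur_id <- "pattern"
    cur_pa <- character()
    flush <- function() {
      if (length(cur_pa)) {
        out[[length(out) + 1L]] <<- prosite_pattern(paste(cur_pa, collapse = ""), cur_id)
      }
      cur_pa <<- character()
    }
    for (ln in lines) {
      if (grepl("^ID\\s", ln)) {
        flush()
        cur_id <- sub("[;.].*$", "", sub("^ID\\s+", "", ln))
        cur_id <- trimws(strsplit(cur_id, "\\s+")[[1]][1])
      } else if (grepl("^PA\\s", ln)) {
        cur_pa <- c(cur_pa, trimws(sub("^PA\\s+", "", ln)))
      }
    }
    flush()
  } else {
    for (i in seq_along(lines)) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2L) {
        out[[length(out) + 1L]] <- prosite_pattern(parts[2], parts[1])
      } else {
        out[[length(out) + 1L]] <- prosite_pattern(parts[1], sprintf("pattern%d", i))
      }
    }
  }
  out
}

#' Render a parsed PROSITE pattern back to PA syntax
#'
#' `format()` is the inverse of [prosite_pattern()]: parsing its output gives
#' back an identical pattern object.
#'
#' @param x a `prosite_pattern`.
#' @param ... unused.
#' @return the PA-syntax string, with trailing `.`.
#' @export
format.prosite_pattern <- function(x, ...) {
  toks <- vapply(x$elements, function(el) {
    core <- switch(el$type,
                   any = "x",
                   literal = el$residues,
                   set = sprintf("[%s]", el$residues),
                   notset = sprintf("{%s}", el$residues))
    if (el$min == 1L && el$max == 1L) core
    else if (el$min == el$max) sprintf("%s(%d)", core, el$min)
    else sprintf("%s(%d,%d)", core, el$min, el$max)
  }, character(1))
  paste0(if (x$anchored_start) "<" else "", paste(toks, collapse = "-"),
         if (x$anchored_end) ">" else "", ".")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat(sprintf("PROSITE pattern %s: %s\n", x$pattern_id, format(x)))
  invisible(x)
}

# Translate one element to a PCRE fragment.
.element_regex <- function(el) {
  core <- switch(el$type,
                 any = ".",
                 literal = el$residues,
                 set = sprintf("[%s]", el$residues),
                 notset = sprintf("[^%s]", el$residues))
  if (el$min == 1L && el$max == 1L) core
  else if (el$min == el$max) sprintf("%s{%d}", core, el$min)
  else sprintf("%s{%d,%d}", core, el$min, el$max)
}

.pattern_regex <- function(pattern) {
  paste0(vapply(pattern$elements, .element_regex, character(1)), collapse = "")
}
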