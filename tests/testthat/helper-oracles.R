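# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein_set <- function(n, len = 40, alphabet = AA20, prefix = "p") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
  df <- data.frame(id = ids, description = "", sequence = seqs,
                   stringsAsFactors = FALSE)
  df$short_id <- ids
  class(df) <- c("protein_set", "data.frame")
  df
}

# --- PROSITE ---------------------------------------------------------------

# random pattern with a small concrete expansion over `alphabet`
random_pattern <- function(alphabet, max_elements = 4L) {
  n_el <- sample(2:max_elements, 1L)
  toks <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("literal", "any", "set", "notset"), 1L,
                   prob = c(0.4, 0.25, 0.2, 0.15))
    core <- switch(kind,
      literal = sample(alphabet, 1L),
      any = "x",
      set = sprintf("[%s]", paste(sample(alphabet, sample(2:3, 1L)), collapse = "")),
      notset = sprintf("{%s}", paste(sample(alphabet, sample(1:2, 1L)), collapse = "")))
    rep_kind <- sample(c("none", "fixed", "range"), 1L, prob = c(0.6, 0.25, 0.15))
    if (rep_kind == "fixed") core <- sprintf("%s(%d)", core, sample(1:2, 1L))
    if (rep_kind == "range") core <- sprintf("%s(%d,%d)", core, sample(0:1, 1L),
                                             sample(2:3, 1L))
    core
  }, character(1))
  anchored_start <- stats::runif(1) < 0.15
  anchored_end <- stats::runif(1) < 0.15
  paste0(if (anchored_start) "<" else "", paste(toks, collapse = "-"),
         if (anchored_end) ">" else "", ".")
}

# expand a parsed pattern to every concrete string over `alphabet`
expand_pattern <- function(pattern, alphabet, max_expansion = 1e5) {
  per_element <- lapply(pattern$elements, function(el) {
    opts <- switch(el$type,
      literal = el$residues,
      any = alphabet,
      set = intersect(strsplit(el$residues, "")[[1]], alphabet),
      notset = setdiff(alphabet, strsplit(el$residues, "")[[1]]))
    out <- character()
    for (k in el$min:el$max) {
      if (k == 0L) { out <- c(out, ""); next }
      grids <- do.call(expand.grid, c(rep(list(opts), k),
                                      stringsAsFactors = FALSE))
      out <- c(out, do.call(paste0, grids))
    }
    unique(out)
  })
  strs <- ""
  for (opts in per_element) {
    strs <- as.vector(outer(strs, opts, paste0))
    if (length(strs) > max_expansion) stop("expansion too large")
  }
  unique(strs)
}

# oracle: all start positions where some expansion matches (anchors honoured)
oracle_scan_starts <- function(seq, pattern, alphabet) {
  exps <- expand_pattern(pattern, alphabet)
  n <- nchar(seq)
  starts <- if (pattern$anchored_start) 1L else seq_len(n)
  found <- integer()
  for (s in starts) {
    for (e in exps) {
      le <- nchar(e)
      if (le == 0L || s + le - 1L > n) next
      if (pattern$anchored_end && s + le - 1L != n) next
      if (substr(seq, s, s + le - 1L) == e) {
        found <- c(found, s)
        break
      }
    }
  }
  found
}

# --- homology set logic ----------------------------------------------------

random_hit_table <- function(query_id, targets, n_hits) {
  if (n_hits == 0L) return(hit_table(query_id, data.frame()))
  hit_table(query_id, data.frame(
    rank = seq_len(n_hits),
    target_id = sample(targets, n_hits, replace = TRUE),
    probability = round(stats::runif(n_hits, 0, 100), 1),
    evalue = 10^stats::runif(n_hits, -8, 0),
    pvalue = 10^stats::runif(n_hits, -9, -1),
    score = round(stats::runif(n_hits, 10, 400), 1),
    cols_matched = sample(50:200, n_hits, replace = TRUE),
    query_start = 1L, query_end = 100L, target_start = 1L, target_end = 100L,
    query_aln = "", target_aln = "", stringsAsFactors = FALSE))
}

oracle_filter <- function(table, cfg) {
  kept <- list()
  for (i in seq_len(nrow(table$hits))) {
    h <- table$hits[i, ]
    if (h$evalue <= cfg$evalue_max && h$probability >= cfg$probability_min) {
      kept[[length(kept) + 1L]] <- h
    }
  }
  if (length(kept) > cfg$max_hits) kept <- kept[seq_len(cfg$max_hits)]
  if (!length(kept)) return(character())
  do.call(rbind, kept)$target_id
}

oracle_invert <- function(top_map) {
  out <- list()
  for (i in seq_len(nrow(top_map$hits))) {
    t <- top_map$hits$target_id[i]
    out[[t]] <- sort(c(out[[t]], top_map$hits$query_id[i]))
  }
  if (!length(out)) return(structure(list(), names = character()))
  out[order(names(out))]
}

oracle_bbh <- function(forward, reverse) {
  pairs <- list()
  for (i in seq_len(nrow(forward$hits))) {
    a <- forward$hits$query_id[i]; b <- forward$hits$target_id[i]
    for (j in seq_len(nrow(reverse$hits))) {
      if (reverse$hits$query_id[j] == b && reverse$hits$target_id[j] == a) {
        pairs[[length(pairs) + 1L]] <- c(a, b)
      }
    }
  }
  if (!length(pairs)) return(data.frame(id_a = character(), id_b = character()))
  m <- do.call(rbind, pairs)
  out <- data.frame(id_a = m[, 1], id_b = m[, 2], stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

# --- geometry / networks ---------------------------------------------------

oracle_interface <- function(atoms_a, atoms_b, cutoff) {
  keep <- rep(FALSE, nrow(atoms_a))
  for (i in seq_len(nrow(atoms_a))) {
    for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                (atoms_a$y[i] - atoms_b$y[j])^2 +
                (atoms_a$z[i] - atoms_b$z[j])^2)
      if (d <= cutoff) { keep[i] <- TRUE; break }
    }
  }
  res <- unique(atoms_a[keep, c("chain", "residue_number")])
  res <- res[order(res$chain, res$residue_number), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_triangles <- function(net) {
  role <- setNames(net$nodes$role, net$nodes$id)
  ek <- c(paste(net$edges$a, net$edges$b), paste(net$edges$b, net$edges$a))
  out <- list()
  for (a in net$nodes$id[net$nodes$role == "alpha"]) {
    for (b in net$nodes$id[net$nodes$role == "beta"]) {
      for (g in net$nodes$id[net$nodes$role == "gamma"]) {
        if (all(c(paste(a, b), paste(b, g), paste(a, g)) %in% ek)) {
          out[[length(out) + 1L]] <- c(a, b, g)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(alpha = character(), beta = character(),
                                      gamma = character()))
  m <- do.call(rbind, out)
  df <- data.frame(alpha = m[, 1], beta = m[, 2], gamma = m[, 3],
                   stringsAsFactors = FALSE)
  df <- df[order(df$alpha, df$beta, df$gamma), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# id-keyed mock scorer for screens: scores looked up in a named list
lookup_scorer <- function(score_table, default = 0.05) {
  function(a, b) {
    key <- paste(a$id[1], b$id[1], sep = "|")
    if (!is.null(score_table[[key]])) score_table[[key]] else default
  }
}
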