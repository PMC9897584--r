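# Stage 1 of the transfer pipeline: threshold filtering of remote-homology
# hit tables, top-hit retrieval per query, inversion to non-redundant target
# maps, best-bidirectional-hit resolution, and the multi-organism consensus
# tally used for candidate selection.

#' Hit-filtering configuration
#'
#' Defaults follow the standard remote-homology search settings: E-value
#' cutoff 1e-3, minimum probability 20 (on the printed 0-100 scale), hit list
#' capped at 250. `probability_select` (default 100) is the stricter
#' threshold used only by [consensus_matrix()]; because result files print
#' probabilities with one decimal, "100%" is interpreted as >= 99.95.
#'
#' @param evalue_max maximum E-value for a hit to pass.
#' @param probability_min minimum probability (0-100) for a hit to pass.
#' @param max_hits truncate each filtered table to this many hits.
#' @param probability_select consensus-selection probability threshold.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(evalue_max = 1e-3, probability_min = 20,
                          max_hits = 250L, probability_select = 100) {
  stopifnot(evalue_max > 0, probability_min >= 0, probability_min <= 100,
            max_hits >= 1)
  structure(list(evalue_max = evalue_max, probability_min = probability_min,
                 max_hits = as.integer(max_hits),
                 probability_select = probability_select),
            class = "filter_config")
}

# Probabilities are printed with one decimal: a displayed "100.0" means
# anything >= 99.95, so thresholds are applied with half-ULP slack.
.prob_passes <- function(probability, threshold) {
  probability >= threshold - 0.05
}

#' Filter a hit table by E-value and probability
#'
#' Keeps hits with `evalue <= evalue_max` and `probability >= probability_min`
#' in their original order, truncates to `max_hits`, and renumbers ranks
#' from 1.
#'
#' @param table a [hit_table()].
#' @param cfg a [filter_config()].
#' @return a filtered [hit_table()].
#' @export
filter_hits <- function(table, cfg = filter_config()) {
  h <- table$hits
  keep <- h$evalue <= cfg$evalue_max & h$probability >= cfg$probability_min
  h <- h[keep, , drop = FALSE]
  if (nrow(h) > cfg$max_hits) h <- h[seq_len(cfg$max_hits), , drop = FALSE]
  h$rank <- seq_len(nrow(h))
  rownames(h) <- NULL
  hit_table(table$query_id, h)
}

#' Top passing hit per query
#'
#' Applies [filter_hits()] to each table and retrieves the rank-1 surviving
#' hit per query ("top ranked" means the search tool's own ranking, not a
#' re-sort by any single statistic). Queries with no passing hit are listed
#' in `unmapped`. With `rerank = TRUE` the passing hits are instead ordered
#' by (probability desc, evalue asc, score desc, target id) before taking the
#' top hit, for tabular inputs whose source ranking is not meaningful.
#'
#' @param tables a [hit_table()] or list of them, one per query.
#' @param cfg a [filter_config()].
#' @param rerank re-sort passing hits before taking the top one.
#' @return an object of class `top_hit_map`: list with `hits` (data frame,
#'   one row per mapped query) and `unmapped` (character vector). Entries and
#'   unmapped queries partition the query set.
#' @export
top_hits <- function(tables, cfg = filter_config(), rerank = FALSE) {
  if (inherits(tables, "hit_table")) tables <- list(tables)
  qids <- vapply(tables, function(t) t$query_id, character(1))
  if (anyDuplicated(qids)) {
    stop("duplicate query id(s) across hit tables: ",
         paste(unique(qids[duplicated(qids)]), collapse = ", "))
  }
  rows <- list()
  unmapped <- character()
  for (t in tables) {
    f <- filter_hits(t, cfg)$hits
    if (!nrow(f)) {
      unmapped <- c(unmapped, t$query_id)
      next
    }
    if (rerank) {
      f <- f[order(-f$probability, f$evalue, -f$score, f$target_id), , drop = FALSE]
    }
    top <- f[1L, c("target_id", "probability", "evalue", "pvalue", "score",
                   "cols_matched"), drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(data.frame(query_id = t$query_id,
                                                  stringsAsFactors = FALSE), top)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), target_id = character(),
               probability = numeric(), evalue = numeric(), pvalue = numeric(),
               score = numeric(), cols_matched = integer(),
               stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  structure(list(hits = hits, unmapped = unmapped), class = "top_hit_map")
}

#' @export
print.top_hit_map <- function(x, ...) {
  cat(sprintf("Top-hit map: %d mapped, %d unmapped quer%s\n", nrow(x$hits),
              length(x$unmapped), if (length(x$unmapped) == 1) "y" else "ies"))
  invisible(x)
}

#' Invert a top-hit map into non-redundant target groups
#'
#' Several queries commonly share one target (receptor superfamilies have
#' diverged within the model organism); the inversion groups queries by their
#' top-hit target, yielding the non-redundant target list.
#'
#' @param thm a [top_hits()] map.
#' @return an object of class `nonredundant_map`: named list `groups` mapping
#'   each target id to the sorted query ids for which it is the top hit.
#' @export
nonredundant_targets <- function(thm) {
  groups <- split(thm$hits$query_id, thm$hits$target_id)
  groups <- lapply(groups, function(g) sort(unique(g)))
  groups <- groups[order(names(groups))]
  structure(list(groups = groups), class = "nonredundant_map")
}

#' @export
print.nonredundant_map <- function(x, ...) {
  cat(sprintf("Non-redundant target map: %d unique target(s), %d quer%s\n",
              length(x$groups), sum(lengths(x$groups)),
              if (sum(lengths(x$groups)) == 1) "y" else "ies"))
  invisible(x)
}

#' Merge non-redundant target maps and report overlaps
#'
#' Unions the target sets of several non-redundant maps (e.g. one per source
#' receptor list) and reports all pairwise intersections plus, for each pair,
#' the targets exclusive to either side, supporting "how many receptors does
#' list A miss relative to list B" style comparisons in both directions.
#'
#' @param maps list of [nonredundant_targets()] maps.
#' @param names optional names for the maps.
#' @return list with `targets` (sorted union), `sizes`, `intersections`
#'   (named matrix), and `exclusives` (named list, both directions per pair).
#' @export
merge_nonredundant <- function(maps, names = NULL) {
  stopifnot(length(maps) >= 1L)
  if (is.null(names)) names <- paste0("map", seq_along(maps))
  sets <- lapply(maps, function(m) names(m$groups))
  names(sets) <- names
  union_all <- sort(unique(unlist(sets, use.names = FALSE)))
  k <- length(sets)
  inter <- matrix(0L, k, k, dimnames = list(names, names))
  exclusives <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      inter[i, j] <- length(intersect(sets[[i]], sets[[j]]))
      if (i < j) {
        exclusives[[sprintf("%s_not_%s", names[i], names[j])]] <-
          sort(setdiff(sets[[i]], sets[[j]]))
        exclusives[[sprintf("%s_not_%s", names[j], names[i])]] <-
          sort(setdiff(sets[[j]], sets[[i]]))
      }
    }
  }
  list(targets = union_all, sizes = lengths(sets), intersections = inter,
       exclusives = exclusives)
}

#' Best-bidirectional pairs between two top-hit maps
#'
#' A pair (a, b) is kept iff b is a's top hit in the forward direction and a
#' is b's top hit in the reverse direction; this symmetry is the standard
#' orthology proxy used to shortlist candidates.
#'
#' @param forward [top_hits()] map from organism A queries to organism B.
#' @param reverse [top_hits()] map from organism B queries to organism A.
#' @return data frame with columns `id_a`, `id_b`, `probability_forward`,
#'   `probability_reverse`, sorted by `id_a`.
#' @export
bidirectional_best <- function(forward, reverse) {
  f <- forward$hits
  r <- reverse$hits
  rev_target <- setNames(r$target_id, r$query_id)
  keep <- !is.na(rev_target[f$target_id]) & rev_target[f$target_id] == f$query_id
  keep[is.na(keep)] <- FALSE
  out <- data.frame(id_a = f$query_id[keep], id_b = f$target_id[keep],
                    probability_forward = f$probability[keep],
                    probability_reverse = unname(
                      setNames(r$probability, r$query_id)[f$target_id[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-organism consensus tally
#'
#' Counts, for each organism and each target, how many of that organism's
#' queries have at least one hit to the target at probability >=
#' `probability_select` (default 100, i.e. printed "100.0"). Queries hitting
#' the same target through several alignment blocks are counted once per
#' (query, target). Targets with all-zero columns are dropped; columns are
#' ordered by total count descending, then target id.
#'
#' @param per_organism_tables named list: organism -> list of [hit_table()]s.
#' @param cfg a [filter_config()]; only `probability_select` is used.
#' @return integer matrix (organisms x targets) of class `consensus_matrix`.
#' @export
consensus_matrix <- function(per_organism_tables, cfg = filter_config()) {
  organisms <- names(per_organism_tables)
  stopifnot(!is.null(organisms), all(nzchar(organisms)))
  cells <- list()
  for (org in organisms) {
    for (t in per_organism_tables[[org]]) {
      h <- t$hits
      pass <- .prob_passes(h$probability, cfg$probability_select)
      for (tgt in unique(h$target_id[pass])) {
        cells[[length(cells) + 1L]] <- data.frame(
          organism = org, query = t$query_id, target = tgt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cells)) {
    m <- matrix(0L, nrow = length(organisms), ncol = 0L,
                dimnames = list(organisms, character()))
    return(structure(m, class = c("consensus_matrix", class(m))))
  }
  df <- unique(do.call(rbind, cells))
  targets <- sort(unique(df$target))
  m <- matrix(0L, length(organisms), length(targets),
              dimnames = list(organisms, targets))
  for (i in seq_len(nrow(df))) {
    m[df$organism[i], df$target[i]] <- m[df$organism[i], df$target[i]] + 1L
  }
  m <- m[, colSums(m) > 0L, drop = FALSE]
  ord <- order(-colSums(m), colnames(m))
  m <- m[, ord, drop = FALSE]
  structure(m, class = c("consensus_matrix", class(m)))
}

#' Select targets represented in every required organism
#'
#' @param m a [consensus_matrix()] (any organisms-by-targets count matrix
#'   with dimnames works).
#' @param required_organisms organisms in which a target needs at least one
#'   counted query; empty set selects all targets.
#' @return character vector of target ids, ordered by total count (over all
#'   organisms in `m`) descending, ties broken by id.
#' @export
select_consensus_targets <- function(m, required_organisms = character()) {
  unknown <- setdiff(required_organisms, rownames(m))
  if (length(unknown)) {
    stop("unknown organism(s): ", paste(unknown, collapse = ", "))
  }
  if (ncol(m) == 0L) return(character())
  ok <- if (length(required_organisms)) {
    colSums(m[required_organisms, , drop = FALSE] >= 1L) == length(required_organisms)
  } else rep(TRUE, ncol(m))
  sel <- colnames(m)[ok]
  tot <- colSums(m)[sel]
  sel[order(-tot, sel)]
}
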