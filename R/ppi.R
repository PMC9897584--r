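# Protein-protein-interaction evidence for G-protein candidates. The
# interaction predictor itself is external: any function (seq_a, seq_b) ->
# probability in [0, 1] satisfies the pair-scorer contract, where each
# argument is a one-row protein record (id + sequence). Callers pass the
# subunits in a documented role order (alpha first, then beta, then gamma).

# run code with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.as_record <- function(x, id = "seq") {
  if (is.data.frame(x)) return(x[1L, , drop = FALSE])
  data.frame(id = id, description = "", sequence = x, stringsAsFactors = FALSE)
}

#' Interface residues between two chains
#'
#' A residue of chain `a` is an interface residue iff any of its atoms lies
#' within `cutoff` Angstrom (Euclidean) of any atom of chain `b`.
#'
#' @param atoms_a,atoms_b atom tables from [parse_pdb_atoms()] (non-empty).
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return data frame with columns `chain`, `residue_number`, one row per
#'   interface residue on side `a`, sorted.
#' @export
interface_residues <- function(atoms_a, atoms_b, cutoff = 5.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  stopifnot(nrow(atoms_a) > 0L, nrow(atoms_b) > 0L)
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  # squared cross-distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  near <- rowSums(d2 <= cutoff^2 + 1e-12) > 0L
  res <- unique(atoms_a[near, c("chain", "residue_number"), drop = FALSE])
  res <- res[order(res$chain, res$residue_number), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' All-vs-all cross-role interaction screen
#'
#' Scores every alpha-beta, beta-gamma and alpha-gamma pair exactly once
#' with the supplied pair scorer and keeps edges whose probability reaches
#' `edge_threshold`. The full score table is retained alongside the edges.
#'
#' @param alphas,betas,gammas `protein_set` data frames (disjoint ids).
#' @param scorer pair-scorer function `(record_a, record_b) -> [0, 1]`.
#' @param edge_threshold minimum probability for an edge (default 0.5).
#' @return object of class `ppi_network`: `nodes` (id, role), `edges`
#'   (a, b, probability), `scores` (all scored pairs).
#' @export
screen <- function(alphas, betas, gammas = NULL, scorer, edge_threshold = 0.5) {
  if (is.null(gammas)) gammas <- alphas[0, , drop = FALSE]
  roles <- list(alpha = alphas, beta = betas, gamma = gammas)
  ids <- unlist(lapply(roles, function(r) r$id), use.names = FALSE)
  if (anyDuplicated(ids)) stop("role lists must have disjoint protein ids")
  nodes <- do.call(rbind, lapply(names(roles), function(role) {
    if (nrow(roles[[role]]) == 0L) return(NULL)
    data.frame(id = roles[[role]]$id, role = role, stringsAsFactors = FALSE)
  }))
  pairs <- list(c("alpha", "beta"), c("beta", "gamma"), c("alpha", "gamma"))
  scores <- list()
  for (pr in pairs) {
    ra <- roles[[pr[1]]]; rb <- roles[[pr[2]]]
    if (nrow(ra) == 0L || nrow(rb) == 0L) next
    idx <- expand.grid(j = seq_len(nrow(rb)), i = seq_len(nrow(ra)))
    p <- vapply(seq_len(nrow(idx)), function(k)
      scorer(ra[idx$i[k], , drop = FALSE], rb[idx$j[k], , drop = FALSE]),
      numeric(1))
    scores[[length(scores) + 1L]] <- data.frame(
      a = ra$id[idx$i], b = rb$id[idx$j], role_a = pr[1], role_b = pr[2],
      probability = p, stringsAsFactors = FALSE)
  }
  scores <- if (length(scores)) do.call(rbind, scores) else
    data.frame(a = character(), b = character(), role_a = character(),
               role_b = character(), probability = numeric(),
               stringsAsFactors = FALSE)
  edges <- scores[scores$probability >= edge_threshold,
                  c("a", "b", "probability"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, scores = scores,
                 edge_threshold = edge_threshold), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d node(s), %d edge(s) at threshold %.2f (%d pairs scored)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_threshold, nrow(x$scores)))
  invisible(x)
}

#' Best-bidirectional-hit map from two BLAST tables
#'
#' Per query, the best hit is the maximum bitscore (ties broken by minimum
#' E-value, then lexicographic target id); a pair is kept iff the two
#' directions agree. Each id appears in at most one pair.
#'
#' @param blast_forward,blast_reverse tables from [parse_blast_tabular()].
#' @return data frame with columns `id_a`, `id_b`, sorted by `id_a`, of
#'   class `cross_species_map`.
#' @export
bbh_map <- function(blast_forward, blast_reverse) {
  best <- function(tab) {
    if (!nrow(tab)) return(setNames(character(), character()))
    ord <- order(tab$query_id, -tab$bitscore, tab$evalue, tab$target_id)
    tab <- tab[ord, , drop = FALSE]
    first <- !duplicated(tab$query_id)
    setNames(tab$target_id[first], tab$query_id[first])
  }
  f <- best(blast_forward)
  r <- best(blast_reverse)
  mutual <- names(f)[!is.na(r[f]) & r[f] == names(f)]
  mutual <- mutual[!is.na(mutual)]
  out <- data.frame(id_a = mutual, id_b = unname(f[mutual]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cross_species_map", "data.frame")
  out
}

#' Overlay two networks through a cross-species map
#'
#' An edge (a, b) of `net_1` is conserved iff both endpoints map across
#' species and (map(a), map(b)) is an edge of `net_2` (in either stored
#' orientation).
#'
#' @param net_1,net_2 [screen()] networks.
#' @param map a [bbh_map()] (columns `id_a` in `net_1`, `id_b` in `net_2`).
#' @return the edges of `net_1` with a logical `conserved` column.
#' @export
overlay <- function(net_1, net_2, map) {
  trans <- setNames(map$id_b, map$id_a)
  e2 <- paste(net_2$edges$a, net_2$edges$b, sep = "\r")
  e2 <- c(e2, paste(net_2$edges$b, net_2$edges$a, sep = "\r"))
  ta <- trans[net_1$edges$a]
  tb <- trans[net_1$edges$b]
  conserved <- !is.na(ta) & !is.na(tb) & paste(ta, tb, sep = "\r") %in% e2
  out <- net_1$edges
  out$conserved <- conserved
  out
}

#' Alpha-beta-gamma triangles in a screened network
#'
#' Network-evidence candidates are triples where all three role-respecting
#' pairwise edges (alpha-beta, beta-gamma, alpha-gamma) are present.
#'
#' @param net a [screen()] network.
#' @return data frame with columns `alpha`, `beta`, `gamma`, sorted.
#' @export
triangle_evidence <- function(net) {
  role <- setNames(net$nodes$role, net$nodes$id)
  ek <- paste(net$edges$a, net$edges$b, sep = "\r")
  ek <- c(ek, paste(net$edges$b, net$edges$a, sep = "\r"))
  has_edge <- function(u, v) paste(u, v, sep = "\r") %in% ek
  ab <- net$edges[role[net$edges$a] == "alpha" & role[net$edges$b] == "beta", ,
                  drop = FALSE]
  gammas <- net$nodes$id[net$nodes$role == "gamma"]
  out <- list()
  for (i in seq_len(nrow(ab))) {
    for (g in gammas) {
      if (has_edge(ab$b[i], g) && has_edge(ab$a[i], g)) {
        out[[length(out) + 1L]] <- data.frame(alpha = ab$a[i], beta = ab$b[i],
                                              gamma = g, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(alpha = character(), beta = character(), gamma = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$alpha, out$beta, out$gamma), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico binding-site perturbation test
#'
#' Compares the predicted interaction probability of a pair before and after
#' random mutations: per trial, `k` positions are sampled without
#' replacement from the putative binding-site positions of `seq_a` (site
#' arm) or from all positions of `seq_a` (random-site control arm), and each
#' sampled residue is substituted by one of the 19 non-identical standard
#' residues, uniformly. Means and standard deviations are taken over exactly
#' `n_trials` re-scores per arm. The whole procedure is reproducible from
#' `seed` and leaves the caller's RNG state untouched.
#'
#' @param seq_a,seq_b one-row protein records (or sequence strings);
#'   mutations are applied to `seq_a`.
#' @param scorer pair-scorer function.
#' @param site_positions 1-based binding-site positions on `seq_a`.
#' @param k number of positions perturbed per trial (default 25; if the site
#'   set is smaller, `k` is lowered to its size with a warning).
#' @param n_trials trials per arm (default 50).
#' @param seed integer seed.
#' @param sample_sites if `FALSE`, the site arm perturbs exactly
#'   `site_positions` (which must then have length `k`) instead of sampling.
#' @return object of class `perturbation_result`: `original`,
#'   `permuted_mean`, `permuted_sd` (site arm), `random_mean`, `random_sd`
#'   (control arm), `n_trials`, `k`, `seed`.
#' @export
perturbation_test <- function(seq_a, seq_b, scorer, site_positions, k = 25L,
                              n_trials = 50L, seed = 1L, sample_sites = TRUE) {
  a <- .as_record(seq_a, "a")
  b <- .as_record(seq_b, "b")
  len <- nchar(a$sequence)
  site_positions <- sort(unique(as.integer(site_positions)))
  if (length(site_positions) && max(site_positions) > len) {
    stop("site positions exceed the sequence length")
  }
  if (k > 0L && length(site_positions) < k) {
    if (sample_sites && length(site_positions) > 0L) {
      warning("site set smaller than k; lowering k to ", length(site_positions))
      k <- length(site_positions)
    } else {
      stop("k exceeds the number of available site positions")
    }
  }
  if (k > len) stop("k exceeds the sequence length")
  original <- scorer(a, b)
  mutate_at <- function(chars, pos) {
    for (p in pos) {
      alt <- setdiff(AA_STANDARD, chars[p])
      chars[p] <- alt[sample.int(length(alt), 1L)]
    }
    chars
  }
  run_arm <- function(pool, arm_seed, fixed = FALSE) {
    .with_seed(arm_seed, {
      vapply(seq_len(n_trials), function(i) {
        pos <- if (k == 0L) integer() else if (fixed) pool else
          pool[sample.int(length(pool), k)]
        chars <- strsplit(a$sequence, "")[[1]]
        mut <- a
        mut$sequence <- paste(mutate_at(chars, pos), collapse = "")
        scorer(mut, b)
      }, numeric(1))
    })
  }
  site_scores <- run_arm(site_positions, seed,
                         fixed = !sample_sites && length(site_positions) == k)
  random_scores <- run_arm(seq_len(len), seed + 1L)
  structure(list(original = original,
                 permuted_mean = mean(site_scores),
                 permuted_sd = stats::sd(site_scores),
                 random_mean = mean(random_scores),
                 random_sd = stats::sd(random_scores),
                 n_trials = as.integer(n_trials), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf(
    "Perturbation test (k=%d, %d trials, seed %d)\n  original       %.4f\n  site-permuted  %.4f (sd %.4f)\n  random control %.4f (sd %.4f)\n",
    x$k, x$n_trials, x$seed, x$original, x$permuted_mean, x$permuted_sd,
    x$random_mean, x$random_sd))
  invisible(x)
}

#' Map reference binding-site positions onto a candidate
#'
#' Given a pairwise alignment of a candidate against a reference, returns
#' the candidate positions aligned (non-gap on both sides) to the given
#' reference positions; reference positions falling in candidate gaps are
#' dropped with a warning.
#'
#' @param ref_aln,cand_aln aligned reference and candidate sequences.
#' @param reference_site 1-based reference positions.
#' @return sorted integer vector of candidate positions.
#' @export
site_positions_from_alignment <- function(ref_aln, cand_aln, reference_site) {
  stopifnot(nchar(ref_aln) == nchar(cand_aln))
  rc <- strsplit(ref_aln, "")[[1]]
  cc <- strsplit(cand_aln, "")[[1]]
  ref_pos <- cumsum(rc != "-")
  ref_pos[rc == "-"] <- NA_integer_
  cand_pos <- cumsum(cc != "-")
  cand_pos[cc == "-"] <- NA_integer_
  idx <- match(as.integer(reference_site), ref_pos)
  mapped <- cand_pos[idx]
  dropped <- reference_site[is.na(idx) | is.na(mapped)]
  if (length(dropped)) {
    warning("reference site position(s) not alignable to the candidate: ",
            paste(dropped, collapse = ", "))
  }
  sort(unique(mapped[!is.na(mapped)]))
}
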