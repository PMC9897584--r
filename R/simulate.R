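# Deterministic synthetic corpora. These generators emulate, at toy scale,
# the inputs the pipeline consumes in production: a model-organism query set
# with planted homolog families in a target proteome, HHR result files
# consistent with the planted homology, domain-bearing type-I receptor
# sequences with TM segments, and alpha/beta pairs with a planted binding
# interface plus a mock pair scorer and toy coordinates. Every corpus is a
# pure function of its configuration (seed included).

#' Synthetic-corpus configuration
#'
#' Defaults describe the regime the pipeline is designed for: remote
#' homology in the "twilight zone" (about 25% residue identity between
#' query and target, i.e. `mutation_rate = 0.75` per residue per lineage,
#' substitutions drawn uniformly over the 19 alternatives), a planted top
#' hit per query with search probability in \[95, 100\] of which a fraction
#' prints as 100.0, and a handful of lower-ranked decoy hits.
#'
#' @param seed integer seed; identical configurations give byte-identical
#'   corpora.
#' @param n_families number of planted homolog families.
#' @param n_queries total model-organism queries spread over the families
#'   (each family gets at least one; one member per family is designated as
#'   the bidirectional partner).
#' @param mutation_rate per-residue substitution probability between target
#'   and each model-organism member.
#' @param sequence_length length of generated protein sequences.
#' @param n_decoys decoy hits added per HHR file.
#' @param prob100_fraction fraction of planted hits printed at probability
#'   100.0 (exercises the consensus-selection path).
#' @param organisms names for the model and target organisms.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_families = 60L, n_queries = 200L,
                             mutation_rate = 0.75, sequence_length = 200L,
                             n_decoys = 3L, prob100_fraction = 0.5,
                             organisms = c("model", "coral")) {
  stopifnot(n_queries >= n_families, mutation_rate >= 0, mutation_rate <= 1)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 n_queries = as.integer(n_queries),
                 mutation_rate = mutation_rate,
                 sequence_length = as.integer(sequence_length),
                 n_decoys = as.integer(n_decoys),
                 prob100_fraction = prob100_fraction, organisms = organisms),
            class = "synthetic_config")
}

.random_seq <- function(n, alphabet = AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) {
    alt <- setdiff(AA_STANDARD, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

#' Generate a planted homolog corpus
#'
#' Each family has one target-organism protein and one or more
#' model-organism queries derived from it by point substitution at
#' `mutation_rate`. The truth table records the intended top hit for every
#' query and flags, per family, the designated best-bidirectional partner.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `model` and `target` (`protein_set` data frames) and
#'   `truth` (data frame `query_id`, `target_id`, `family`,
#'   `is_bbh_partner`).
#' @export
make_homolog_corpus <- function(cfg) {
  .with_seed(cfg$seed, {
    fam_of_query <- sort(c(seq_len(cfg$n_families),
                           sample.int(cfg$n_families,
                                      cfg$n_queries - cfg$n_families,
                                      replace = TRUE)))
    targets <- data.frame(
      id = sprintf("t%04d", seq_len(cfg$n_families)),
      description = sprintf("%s family %d", cfg$organisms[2], seq_len(cfg$n_families)),
      sequence = vapply(seq_len(cfg$n_families), function(i)
        .random_seq(cfg$sequence_length), character(1)),
      stringsAsFactors = FALSE)
    queries <- data.frame(
      id = sprintf("q%04d", seq_len(cfg$n_queries)),
      description = sprintf("%s query (family %d)", cfg$organisms[1], fam_of_query),
      sequence = vapply(seq_len(cfg$n_queries), function(i)
        .mutate_seq(targets$sequence[fam_of_query[i]], cfg$mutation_rate),
        character(1)),
      stringsAsFactors = FALSE)
    truth <- data.frame(query_id = queries$id,
                        target_id = targets$id[fam_of_query],
                        family = fam_of_query,
                        is_bbh_partner = !duplicated(fam_of_query),
                        stringsAsFactors = FALSE)
    list(model = .protein_set(queries$id, queries$description, queries$sequence),
         target = .protein_set(targets$id, targets$description, targets$sequence),
         truth = truth)
  })
}

.planted_hit_row <- function(rank, target_id, probability, evalue, qlen) {
  data.frame(rank = rank, target_id = target_id, probability = probability,
             evalue = evalue, pvalue = evalue / 10, score = 300 - 20 * rank,
             cols_matched = qlen, query_start = 1L, query_end = qlen,
             target_start = 1L, target_end = qlen,
             query_aln = "", target_aln = "", stringsAsFactors = FALSE)
}

# Build one synthetic hit table: planted top hit (unless planted_target is
# NA, giving a decoy-only table), then decoys with lower probability.
.synthetic_hit_table <- function(query, planted_target, decoy_pool, cfg,
                                 seqs = NULL) {
  qlen <- cfg$sequence_length
  rows <- list()
  if (!is.na(planted_target)) {
    prob <- if (stats::runif(1) < cfg$prob100_fraction) 100.0 else
      round(stats::runif(1, 95, 99.8), 1)
    rows[[1L]] <- .planted_hit_row(1L, planted_target, prob,
                                   10^stats::runif(1, -40, -10), qlen)
  }
  n_decoys <- min(cfg$n_decoys, length(decoy_pool))
  if (n_decoys > 0L) {
    decoys <- sample(decoy_pool, n_decoys)
    for (d in seq_len(n_decoys)) {
      rank <- length(rows) + 1L
      # decoys pass the default filter but rank (and score) below the
      # planted hit; the last decoy fails the E-value cutoff, and in a
      # decoy-only table (no planted target) every decoy fails it
      fail <- is.na(planted_target) || d == n_decoys
      ev <- if (fail) 10^stats::runif(1, -2.5, -1.5) else
        10^stats::runif(1, -8, -4)
      rows[[rank]] <- .planted_hit_row(rank, decoys[d],
                                       round(stats::runif(1, 25, 80), 1), ev, qlen)
    }
  }
  h <- do.call(rbind, rows)
  if (!is.null(seqs)) {
    h$query_aln <- seqs$query
    h$target_aln <- vapply(h$target_id, function(t)
      if (!is.null(seqs$targets[[t]])) seqs$targets[[t]] else seqs$query,
      character(1))
  }
  hit_table(query, h)
}

#' Write HHR result files for a planted corpus
#'
#' Emits one forward HHR file per model query (rank-1 hit = the planted
#' target, probability in \[95, 100\], E-value well below the cutoff, plus
#' decoys) and one reverse HHR file per target (rank-1 hit = the family's
#' designated bidirectional partner). All files parse with [parse_hhr()].
#'
#' @param corpus a [make_homolog_corpus()] result.
#' @param cfg the same [synthetic_config()].
#' @param dir output directory; `forward/` and `reverse/` subdirectories are
#'   created.
#' @return list with the two directory paths, invisibly.
#' @export
make_hhr_files <- function(corpus, cfg, dir) {
  fwd <- file.path(dir, "forward")
  rev <- file.path(dir, "reverse")
  dir.create(fwd, recursive = TRUE, showWarnings = FALSE)
  dir.create(rev, recursive = TRUE, showWarnings = FALSE)
  .with_seed(cfg$seed + 1L, {
    for (i in seq_len(nrow(corpus$truth))) {
      q <- corpus$truth$query_id[i]
      tgt <- corpus$truth$target_id[i]
      pool <- setdiff(corpus$target$id, tgt)
      tab <- .synthetic_hit_table(
        q, tgt, pool, cfg,
        seqs = list(query = corpus$model$sequence[corpus$model$id == q],
                    targets = setNames(as.list(corpus$target$sequence),
                                       corpus$target$id)))
      write_hhr(tab, file.path(fwd, paste0(q, ".hhr")),
                match_columns = cfg$sequence_length)
    }
    partners <- corpus$truth[corpus$truth$is_bbh_partner, ]
    for (i in seq_len(nrow(partners))) {
      tgt <- partners$target_id[i]
      partner <- partners$query_id[i]
      pool <- setdiff(corpus$model$id, partner)
      tab <- .synthetic_hit_table(
        tgt, partner, pool, cfg,
        seqs = list(query = corpus$target$sequence[corpus$target$id == tgt],
                    targets = setNames(as.list(corpus$model$sequence),
                                       corpus$model$id)))
      write_hhr(tab, file.path(rev, paste0(tgt, ".hhr")),
                match_columns = cfg$sequence_length)
    }
  })
  invisible(list(forward = fwd, reverse = rev))
}

#' Build hit tables realising a prescribed consensus tally
#'
#' Given an organisms-by-targets count matrix, constructs per-organism hit
#' tables whose [consensus_matrix()] reproduces exactly those counts: for
#' each cell (o, t) with count c, c distinct queries of organism o receive a
#' printed-100.0 hit to t; additional sub-threshold noise hits are added.
#'
#' @param counts integer matrix, rownames = organisms, colnames = targets.
#' @param seed integer seed for the noise hits.
#' @return named list organism -> list of [hit_table()]s.
#' @export
make_consensus_tables <- function(counts, seed = 1L) {
  .with_seed(seed, {
    out <- list()
    for (org in rownames(counts)) {
      n_queries <- max(counts[org, ], 0L)
      if (n_queries == 0L) {
        out[[org]] <- list()
        next
      }
      per_query_hits <- vector("list", n_queries)
      for (t in colnames(counts)) {
        c_ot <- counts[org, t]
        if (c_ot > 0L) {
          for (q in seq_len(c_ot)) {  # queries 1..c get a 100.0 hit to t
            per_query_hits[[q]] <- c(per_query_hits[[q]], t)
          }
        }
      }
      tables <- lapply(seq_len(n_queries), function(q) {
        tgts <- per_query_hits[[q]]
        rows <- list()
        for (j in seq_along(tgts)) {
          rows[[j]] <- .planted_hit_row(j, tgts[j], 100.0,
                                        10^stats::runif(1, -40, -20), 100L)
        }
        # sub-threshold noise hit (probability < 100) to a random target
        noise <- sample(colnames(counts), 1L)
        rows[[length(rows) + 1L]] <- .planted_hit_row(
          length(rows) + 1L, noise, round(stats::runif(1, 40, 99), 1),
          10^stats::runif(1, -8, -4), 100L)
        hit_table(sprintf("%s_q%02d", org, q), do.call(rbind, rows))
      })
      out[[org]] <- tables
    }
    out
  })
}

# concrete pattern instances planted by make_domain_proteins; the background
# alphabet excludes N, Y and G so none of these can arise by chance
.DOMAIN_MOTIFS <- list(
  LRR = list(pattern = "L-x(2)-L-x-L-x(2)-N-x-L.", instance = "LKQLDLSGNKL"),
  TIR = list(pattern = "F-[DE]-A-F-[ILV]-S-Y.", instance = "FDAFISY"),
  CADHERIN = list(pattern = "D-x-D-x-D-G.", instance = "DADTDG"),
  EGF_CA = list(pattern = "C-x-C-x(2)-G-[FY].", instance = "CACDEGF"),
  TSP3 = list(pattern = "D-x-D-G-x(2)-C.", instance = "DTDGKLC"),
  TSP_CTER = list(pattern = "W-x(2)-W-x(2)-G.", instance = "WSPWSEG")
)
.DOMAIN_BG_ALPHABET <- setdiff(AA_STANDARD, c("N", "Y", "G"))

#' Generate type-I receptor candidates with planted architectures
#'
#' Builds one synthetic protein per requested architecture category, with
#' concrete motif instances embedded at recorded coordinates on the recorded
#' side of a planted TM helix, plus the matching PROSITE pattern set and TM
#' table. The background alphabet excludes residues required by every
#' planted motif, so pattern hits occur exactly at the planted coordinates.
#'
#' @param cfg a [synthetic_config()] (only `seed` is used).
#' @param categories architecture categories to plant (possibly repeated).
#' @return list with `proteins` (`protein_set`), `tm` (segment table),
#'   `patterns` (list of [prosite_pattern()]), `truth` (data frame
#'   `protein_id`, `category`).
#' @export
make_domain_proteins <- function(cfg = synthetic_config(),
                                 categories = c("canonical_TLR", "TIR_only",
                                                "LRR_only",
                                                "TLR_with_extra_domains",
                                                "not_TLR")) {
  .with_seed(cfg$seed + 2L, {
    tm_start <- 301L; tm_end <- 323L; total <- 600L
    place <- function(base, instance, at) {
      paste0(substr(base, 1L, at - 1L), instance,
             substr(base, at + nchar(instance), nchar(base)))
    }
    seqs <- character(); ids <- character(); tm_rows <- list()
    for (i in seq_along(categories)) {
      cat_i <- categories[i]
      id <- sprintf("dp%02d_%s", i, cat_i)
      s <- .random_seq(total, .DOMAIN_BG_ALPHABET)
      ec_at <- c(20L, 60L, 100L, 160L, 220L)  # all well before the TM helix
      cp_at <- 420L                           # well after it
      if (cat_i %in% c("canonical_TLR", "TLR_with_extra_domains", "LRR_only")) {
        for (a in ec_at[1:3]) s <- place(s, .DOMAIN_MOTIFS$LRR$instance, a)
      }
      if (cat_i == "TLR_with_extra_domains") {
        s <- place(s, .DOMAIN_MOTIFS$CADHERIN$instance, ec_at[4])
        s <- place(s, .DOMAIN_MOTIFS$EGF_CA$instance, ec_at[5])
      }
      if (cat_i %in% c("canonical_TLR", "TLR_with_extra_domains", "TIR_only")) {
        s <- place(s, .DOMAIN_MOTIFS$TIR$instance, cp_at)
      }
      ids <- c(ids, id); seqs <- c(seqs, s)
      tm_rows[[i]] <- data.frame(protein_id = id, source = "synthetic",
                                 kind = "TMhelix", start = tm_start,
                                 end = tm_end, stringsAsFactors = FALSE)
    }
    patterns <- lapply(names(.DOMAIN_MOTIFS), function(nm)
      prosite_pattern(.DOMAIN_MOTIFS[[nm]]$pattern, nm))
    list(proteins = .protein_set(ids, paste("synthetic", categories), seqs),
         tm = do.call(rbind, tm_rows),
         patterns = patterns,
         truth = data.frame(protein_id = ids, category = categories,
                            stringsAsFactors = FALSE))
  })
}

#' Generate an alpha/beta pair with a planted binding interface
#'
#' Produces a sequence pair, a deterministic mock pair scorer whose output
#' is a logistic function of how many residues at the planted interface
#' positions of the alpha sequence are preserved, and toy two-chain
#' coordinates in which exactly the planted alpha residues lie within the
#' interface cutoff of chain B (all others are far away).
#'
#' @param cfg a [synthetic_config()] (seed and sequence length are used).
#' @param n_interface number of planted interface positions (default 30).
#' @return list with `pair` (`protein_set`: alpha then beta), `scorer`,
#'   `interface` (integer positions on alpha), `atoms_a`, `atoms_b` (atom
#'   tables), `pdb_text` (the same coordinates as PDB ATOM records).
#' @export
make_interface_complex <- function(cfg = synthetic_config(), n_interface = 30L) {
  .with_seed(cfg$seed + 3L, {
    len <- cfg$sequence_length
    a_seq <- .random_seq(len)
    b_seq <- .random_seq(len)
    interface <- sort(sample.int(len, n_interface))
    orig_chars <- strsplit(a_seq, "")[[1]]
    orig_at_site <- orig_chars[interface]
    scorer <- function(rec_a, rec_b) {
      chars <- strsplit(rec_a$sequence[1], "")[[1]]
      frac <- mean(chars[interface] == orig_at_site)
      stats::plogis(8 * (frac - 0.6))
    }
    atoms_a <- data.frame(chain = "A", residue_number = seq_len(len),
                          residue_name = "ALA", atom_name = "CA",
                          x = 8 * seq_len(len), y = 0, z = 0,
                          stringsAsFactors = FALSE)
    # chain B: one atom 4 A from each planted interface residue, plus a
    # remote residue 100 A away so non-interface positions stay excluded
    atoms_b <- data.frame(chain = "B",
                          residue_number = seq_along(interface),
                          residue_name = "GLY", atom_name = "CA",
                          x = 8 * interface, y = 4, z = 0,
                          stringsAsFactors = FALSE)
    atoms_b <- rbind(atoms_b, data.frame(chain = "B",
                                         residue_number = length(interface) + 1L,
                                         residue_name = "GLY", atom_name = "CA",
                                         x = 0, y = 100, z = 0,
                                         stringsAsFactors = FALSE))
    tf <- tempfile(fileext = ".pdb")
    write_pdb_atoms(rbind(atoms_a, atoms_b), tf)
    pdb_text <- readLines(tf)
    unlink(tf)
    list(pair = .protein_set(c("alpha_syn", "beta_syn"),
                             c("synthetic alpha", "synthetic beta"),
                             c(a_seq, b_seq)),
         scorer = scorer, interface = interface,
         atoms_a = atoms_a, atoms_b = atoms_b, pdb_text = pdb_text)
  })
}
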