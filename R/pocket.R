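# GPCR ligand-pocket logic. Positions are compared across receptors via
# Ballesteros-Weinstein (BW) labels "h.nn": helix h, offset nn relative to
# the helix's most conserved residue, which is defined to be x.50. Anchors,
# helix bounds and the cavity-facing position list are configuration, read
# from YAML, never hard-coded.

#' Ballesteros-Weinstein anchor set
#'
#' @param anchors named vector/list mapping helix index `"1"`..`"7"` to the
#'   1-based reference-sequence position of that helix's x.50 residue.
#' @param reference_id id of the reference receptor the positions refer to.
#' @return object of class `bw_anchor_set`.
#' @export
bw_anchor_set <- function(anchors, reference_id) {
  pos <- as.integer(unlist(anchors))
  names(pos) <- as.character(seq_along(pos))
  if (length(pos) != 7L) stop("exactly 7 helix anchors are required")
  if (any(diff(pos) <= 0L)) stop("anchor positions must be strictly increasing")
  structure(list(anchors = pos, reference_id = reference_id),
            class = "bw_anchor_set")
}

#' Read BW numbering configuration from YAML
#'
#' The file supplies `reference_id`, `anchors` (helix -> x.50 reference
#' position) and `helix_bounds` (helix -> `[start, end]` reference span).
#'
#' @param path YAML file; defaults to the rhodopsin configuration shipped
#'   with the package.
#' @return list with `anchors` (a [bw_anchor_set()]) and `helix_bounds`
#'   (list of integer pairs, names `"1"`..`"7"`).
#' @export
read_bw_config <- function(path = system.file("extdata", "rhodopsin_bw.yaml",
                                              package = "homolot")) {
  cfg <- yaml::read_yaml(path)
  anchors <- bw_anchor_set(cfg$anchors[as.character(1:7)], cfg$reference_id)
  bounds <- lapply(cfg$helix_bounds[as.character(1:7)], as.integer)
  names(bounds) <- as.character(1:7)
  list(anchors = anchors, helix_bounds = bounds)
}

#' Assign Ballesteros-Weinstein labels to a candidate sequence
#'
#' Given a pairwise alignment of a candidate against the anchor reference,
#' each reference position inside a helix span gets the label
#' `helix.(50 + position - anchor)`; candidate positions aligned (non-gap) to
#' a labelled reference position inherit its label. Candidate positions
#' aligned to reference gaps, or outside the helix spans, get no label.
#'
#' @param ref_aln,cand_aln aligned reference and candidate sequences (equal
#'   length, gaps as `-`).
#' @param anchors a [bw_anchor_set()].
#' @param helix_bounds per-helix `[start, end]` reference spans (names
#'   `"1"`..`"7"`).
#' @return named character vector: names are 1-based candidate positions,
#'   values are BW labels such as `"7.43"`.
#' @export
assign_bw <- function(ref_aln, cand_aln, anchors, helix_bounds) {
  stopifnot(nchar(ref_aln) == nchar(cand_aln))
  rc <- strsplit(ref_aln, "")[[1]]
  cc <- strsplit(cand_aln, "")[[1]]
  ref_pos <- cumsum(rc != "-")
  ref_pos[rc == "-"] <- NA_integer_
  cand_pos <- cumsum(cc != "-")
  cand_pos[cc == "-"] <- NA_integer_

  # label reference positions helix by helix
  max_ref <- max(ref_pos, na.rm = TRUE)
  ref_label <- rep(NA_character_, max_ref)
  for (h in names(anchors$anchors)) {
    a <- anchors$anchors[[h]]
    b <- helix_bounds[[h]]
    if (is.null(b)) stop("missing helix bounds for helix ", h)
    if (!a %in% ref_pos) {
      stop("anchor ", h, ".50 (reference position ", a,
           ") is not covered by the alignment")
    }
    span <- seq.int(b[1], b[2])
    span <- span[span <= max_ref]
    ref_label[span] <- sprintf("%s.%d", h, 50L + span - a)
  }

  both <- !is.na(ref_pos) & !is.na(cand_pos)
  lab <- ref_label[ref_pos[both]]
  out <- setNames(lab, cand_pos[both])
  out[!is.na(out)]
}

#' Cavity-facing pocket definition
#'
#' @param labels ordered BW labels (e.g. `"3.28"`); must be unique.
#' @param source free-text provenance of the list.
#' @return object of class `pocket_definition`.
#' @export
pocket_definition <- function(labels, source = "user") {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("pocket labels must be unique")
  structure(list(labels = labels, source = source), class = "pocket_definition")
}

#' Read a pocket definition from YAML
#'
#' @param path YAML file with fields `labels` and `source`; defaults to the
#'   30-position cavity-facing list shipped with the package.
#' @return a [pocket_definition()].
#' @export
read_pocket_config <- function(path = system.file("extdata", "pocket30.yaml",
                                                  package = "homolot")) {
  cfg <- yaml::read_yaml(path)
  pocket_definition(as.character(cfg$labels),
                    if (is.null(cfg$source)) "config" else cfg$source)
}

#' Extract a pocket profile from a sequence
#'
#' Reads the residue at each pocket position off the sequence using a BW
#' label map; pocket positions with no labelled candidate position yield the
#' gap symbol `-`.
#'
#' @param seq a one-row `protein_set` data frame, or a plain sequence string.
#' @param bw_map label map from [assign_bw()] for this sequence.
#' @param pocket a [pocket_definition()].
#' @param protein_id id recorded in the profile (taken from `seq` if a
#'   record).
#' @return object of class `pocket_profile`: `protein_id`, `residues` (named
#'   character vector in pocket order), `definition`.
#' @export
extract_profile <- function(seq, bw_map, pocket, protein_id = NULL) {
  if (is.data.frame(seq)) {
    protein_id <- seq$id[1]
    seq <- seq$sequence[1]
  }
  if (is.null(protein_id)) protein_id <- "candidate"
  chars <- strsplit(seq, "")[[1]]
  label_to_pos <- setNames(as.integer(names(bw_map)), bw_map)
  res <- vapply(pocket$labels, function(lab) {
    p <- unname(label_to_pos[lab])
    if (is.na(p) || p > length(chars)) "-" else chars[p]
  }, character(1))
  structure(list(protein_id = protein_id,
                 residues = setNames(res, pocket$labels),
                 definition = pocket$labels),
            class = "pocket_profile")
}

#' @export
print.pocket_profile <- function(x, ...) {
  cat(sprintf("Pocket profile %s (%d positions, %d gaps)\n", x$protein_id,
              length(x$residues), sum(x$residues == "-")))
  cat(paste(sprintf("%s:%s", names(x$residues), x$residues), collapse = " "), "\n")
  invisible(x)
}

#' Positional identity between two pocket profiles
#'
#' @param a,b [extract_profile()] results over the same pocket definition.
#' @param strict if `FALSE` (default), positions with a gap on either side
#'   are excluded from `n_compared`; if `TRUE`, positions where at least one
#'   side is non-gap are compared and gaps count as mismatches.
#' @return named integer vector `c(n_identical, n_compared)`.
#' @export
profile_identity <- function(a, b, strict = FALSE) {
  if (!identical(a$definition, b$definition)) {
    stop("profiles use different pocket definitions")
  }
  ra <- a$residues; rb <- b$residues
  if (strict) {
    cmp <- ra != "-" | rb != "-"
  } else {
    cmp <- ra != "-" & rb != "-"
  }
  ident <- cmp & ra == rb & ra != "-"
  c(n_identical = sum(ident), n_compared = sum(cmp))
}

#' Retinal-binding rule
#'
#' Visual opsins attach retinal through a Schiff-base lysine (rhodopsin
#' K296, BW 7.43) stabilised by a counter-ion (rhodopsin E113, BW 3.28).
#' The optional 4-position minimal pocket supports a conservation check
#' against a reference profile; it is configuration and defaults to empty.
#'
#' @param schiff_position BW label of the Schiff-base lysine.
#' @param counterion_position BW label of the counter-ion.
#' @param minimal_pocket character vector of 4 BW labels, or empty.
#' @return object of class `retinal_rule`.
#' @export
retinal_rule <- function(schiff_position = "7.43", counterion_position = "3.28",
                         minimal_pocket = character()) {
  if (schiff_position == counterion_position) {
    stop("Schiff-base and counter-ion positions must differ")
  }
  if (length(minimal_pocket) && length(minimal_pocket) != 4L) {
    stop("the minimal pocket must list exactly 4 positions (or be empty)")
  }
  structure(list(schiff_position = schiff_position,
                 counterion_position = counterion_position,
                 minimal_pocket = as.character(minimal_pocket)),
            class = "retinal_rule")
}

#' Read a retinal rule from YAML
#'
#' @param path YAML file with `schiff_position`, `counterion_position` and
#'   optional `minimal_pocket`; defaults to the configuration shipped with
#'   the package.
#' @return a [retinal_rule()].
#' @export
read_retinal_rule <- function(path = system.file("extdata", "retinal_rule.yaml",
                                                 package = "homolot")) {
  cfg <- yaml::read_yaml(path)
  retinal_rule(cfg$schiff_position, cfg$counterion_position,
               if (is.null(cfg$minimal_pocket)) character() else
                 as.character(cfg$minimal_pocket))
}

#' Check the retinal-binding rule on a pocket profile
#'
#' Reports whether the Schiff-base position carries a lysine, the residue at
#' the counter-ion position and its class (`acidic` for D/E; substitutions
#' to tyrosine or serine are known absorbance-shifting variants), and, when a
#' 4-position minimal pocket and a reference profile are supplied, how many
#' of those 4 residues match the reference.
#'
#' @param profile a [extract_profile()] result.
#' @param rule a [retinal_rule()].
#' @param reference optional reference profile for the minimal-pocket count.
#' @return list with `has_schiff_lysine`, `counterion_residue`,
#'   `counterion_class` and `minimal_pocket_conserved` (NA unless both the
#'   rule's minimal pocket and `reference` are given).
#' @export
check_retinal <- function(profile, rule, reference = NULL) {
  need <- c(rule$schiff_position, rule$counterion_position, rule$minimal_pocket)
  missing <- setdiff(need, profile$definition)
  if (length(missing)) {
    stop("rule position(s) not in the pocket definition: ",
         paste(missing, collapse = ", "))
  }
  schiff <- profile$residues[[rule$schiff_position]]
  ci <- profile$residues[[rule$counterion_position]]
  ci_class <- if (ci %in% c("D", "E")) "acidic"
    else if (ci == "Y") "tyrosine"
    else if (ci == "S") "serine"
    else "other"
  mp <- NA_integer_
  if (length(rule$minimal_pocket) && !is.null(reference)) {
    pr <- profile$residues[rule$minimal_pocket]
    rr <- reference$residues[rule$minimal_pocket]
    mp <- sum(pr == rr & pr != "-")
  }
  list(has_schiff_lysine = identical(schiff, "K"),
       counterion_residue = ci,
       counterion_class = ci_class,
       minimal_pocket_conserved = mp)
}

#' Rank opsin candidates against reference pocket profiles
#'
#' For each candidate profile, finds the best-matching reference (most
#' identical pocket positions), evaluates the retinal rule, and flags the
#' candidate as passing iff the Schiff-base lysine is present. The pass flag
#' is a hard functional requirement; interpretation of counter-ion
#' substitutions is left to the analyst.
#'
#' @param candidates list of candidate [extract_profile()] results.
#' @param references list of reference profiles (same pocket definition).
#' @param rule a [retinal_rule()].
#' @param strict passed to [profile_identity()].
#' @return data frame, one row per candidate, ordered by `pass` then
#'   `n_identical` (both descending): `protein_id`, `best_reference`,
#'   `n_identical`, `n_compared`, `has_schiff_lysine`, `counterion_residue`,
#'   `counterion_class`, `minimal_pocket_conserved`, `pass`.
#' @export
rank_opsin_candidates <- function(candidates, references, rule = retinal_rule(),
                                  strict = FALSE) {
  stopifnot(length(candidates) >= 1L, length(references) >= 1L)
  rows <- lapply(candidates, function(cand) {
    ids <- vapply(references, function(r) r$protein_id, character(1))
    idm <- vapply(references, function(r) profile_identity(cand, r, strict),
                  integer(2))
    best <- which.max(idm["n_identical", ])
    best_ref <- references[[best]]
    v <- check_retinal(cand, rule, reference = best_ref)
    data.frame(protein_id = cand$protein_id, best_reference = ids[best],
               n_identical = idm["n_identical", best],
               n_compared = idm["n_compared", best],
               has_schiff_lysine = v$has_schiff_lysine,
               counterion_residue = v$counterion_residue,
               counterion_class = v$counterion_class,
               minimal_pocket_conserved = v$minimal_pocket_conserved,
               pass = v$has_schiff_lysine,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pass, -out$n_identical, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
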