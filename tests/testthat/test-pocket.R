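# toy anchor set used by the arithmetic tests: 7 anchors, helix h spanning
# [100h - 10, 100h + 10] with the x.50 residue at 100h
toy_anchors <- bw_anchor_set(setNames(as.list((1:7) * 100), 1:7), "toyref")
toy_bounds <- setNames(lapply(1:7, function(h) c(100L * h - 10L, 100L * h + 10L)),
                       as.character(1:7))

test_that("BW labels follow helix.(50 + offset) arithmetic on identity alignments", {
  ref <- paste(sample(AA20, 720, replace = TRUE), collapse = "")
  map <- assign_bw(ref, ref, toy_anchors, toy_bounds)
  expect_equal(unname(map["200"]), "2.50")
  expect_equal(unname(map["203"]), "2.53")   # +3 after the 2.50 anchor
  expect_equal(unname(map["193"]), "2.43")
  expect_false("50" %in% names(map))         # outside all helix spans
})

test_that("insertions in the candidate shift positions but not labels", {
  ref <- strrep("A", 250)
  # 2-residue insertion in the candidate before the helix-2 anchor
  ref_aln <- paste0(substr(ref, 1, 150), "--", substr(ref, 151, 250))
  cand_aln <- paste0(strrep("C", 152), substr(ref, 151, 250))
  anchors <- bw_anchor_set(setNames(as.list(c(20, 200, 210, 220, 230, 240, 250)), 1:7), "r")
  bounds <- list("1" = c(15, 25), "2" = c(195, 205), "3" = c(208, 211),
                 "4" = c(218, 221), "5" = c(228, 231), "6" = c(238, 241),
                 "7" = c(248, 250))
  map <- assign_bw(ref_aln, cand_aln, anchors, bounds)
  # reference position 200 sits at candidate position 202 after the insertion
  expect_equal(unname(map["202"]), "2.50")
  expect_equal(unname(map["22"]), "1.52")    # upstream of the insertion: unshifted
})

test_that("shipped rhodopsin configuration labels the retinal positions", {
  bw <- read_bw_config()
  ref <- opsd_reference()
  map <- assign_bw(ref$sequence, ref$sequence, bw$anchors, bw$helix_bounds)
  expect_equal(unname(map["296"]), "7.43")
  expect_equal(unname(map["113"]), "3.28")
  expect_equal(unname(map["303"]), "7.50")
  # labels strictly increasing within each helix
  labs <- data.frame(pos = as.integer(names(map)),
                     helix = sub("\\..*", "", map),
                     off = as.integer(sub(".*\\.", "", map)))
  for (h in unique(labs$helix)) {
    sub <- labs[labs$helix == h, ]
    expect_true(all(diff(sub$off[order(sub$pos)]) > 0))
  }
})

test_that("anchors falling outside the alignment are reported by helix", {
  expect_error(assign_bw("AAAA", "AAAA", toy_anchors, toy_bounds), "anchor 1")
})

test_that("self-extraction of the reference pocket has no gaps (fixed point)", {
  bw <- read_bw_config()
  ref <- opsd_reference()
  map <- assign_bw(ref$sequence, ref$sequence, bw$anchors, bw$helix_bounds)
  pocket <- read_pocket_config()
  prof <- extract_profile(ref, map, pocket)
  expect_equal(length(prof$residues), 30L)
  expect_equal(sum(prof$residues == "-"), 0L)
  expect_equal(unname(prof$residues["7.43"]), "K")
  expect_equal(unname(prof$residues["3.28"]), "E")
  expect_equal(unname(profile_identity(prof, prof)),
               c(30L, 30L))
})

test_that("candidates missing a helix get gaps at its pocket positions", {
  bw <- read_bw_config()
  ref <- opsd_reference()
  n <- nchar(ref$sequence)
  # candidate aligned only up to the end of helix 6: helix 7 unaligned
  cand_aln <- paste0(substr(ref$sequence, 1, 280), strrep("-", n - 280))
  map <- assign_bw(ref$sequence, cand_aln, bw$anchors, bw$helix_bounds)
  prof <- extract_profile(substr(ref$sequence, 1, 280), map,
                          read_pocket_config(), protein_id = "trunc")
  labs7 <- grep("^7\\.", names(prof$residues), value = TRUE)
  expect_true(all(prof$residues[labs7] == "-"))
  expect_true(all(prof$residues[grep("^6\\.", names(prof$residues))] != "-"))
})

test_that("profile identity is symmetric, bounded, and gap-mode aware", {
  def <- pocket_definition(sprintf("1.%d", 40:49))
  mk <- function(res) structure(list(protein_id = "x",
                                     residues = setNames(res, def$labels),
                                     definition = def$labels),
                                class = "pocket_profile")
  set.seed(3)
  for (i in 1:25) {
    a <- mk(sample(c(AA20[1:4], "-"), 10, replace = TRUE))
    b <- mk(sample(c(AA20[1:4], "-"), 10, replace = TRUE))
    ab <- profile_identity(a, b)
    ba <- profile_identity(b, a)
    expect_equal(ab, ba)
    expect_lte(ab["n_identical"], ab["n_compared"])
    # brute force positional comparison
    both <- a$residues != "-" & b$residues != "-"
    expect_equal(unname(ab), c(sum(both & a$residues == b$residues), sum(both)))
    strict <- profile_identity(a, b, strict = TRUE)
    expect_equal(unname(strict["n_compared"]),
                 sum(a$residues != "-" | b$residues != "-"))
  }
  other <- structure(list(protein_id = "y", residues = c("1.1" = "A"),
                          definition = "1.1"), class = "pocket_profile")
  expect_error(profile_identity(mk(rep("A", 10)), other), "definition")
})

test_that("retinal rule classifies the printed residue facts", {
  bw <- read_bw_config()
  ref <- opsd_reference()
  map <- assign_bw(ref$sequence, ref$sequence, bw$anchors, bw$helix_bounds)
  pocket <- read_pocket_config()
  rule <- read_retinal_rule()

  rho <- extract_profile(ref, map, pocket)
  v <- check_retinal(rho, rule)
  expect_true(v$has_schiff_lysine)
  expect_equal(v$counterion_residue, "E")
  expect_equal(v$counterion_class, "acidic")

  # synthetic coral-style candidate: counter-ion E -> Y, Schiff lysine kept
  mutate_at <- function(seq, pos, res) {
    substr(seq, pos, pos) <- res
    seq
  }
  cand_y <- mutate_at(ref$sequence, 113, "Y")
  py <- extract_profile(cand_y, map, pocket, protein_id = "coral_opsin_syn")
  vy <- check_retinal(py, rule)
  expect_true(vy$has_schiff_lysine)
  expect_equal(vy$counterion_residue, "Y")
  expect_equal(vy$counterion_class, "tyrosine")

  # synthetic candidate in the style of the serine-substituted homologue
  ps <- extract_profile(mutate_at(ref$sequence, 113, "S"), map, pocket,
                        protein_id = "19775_syn")
  expect_equal(check_retinal(ps, rule)$counterion_class, "serine")

  # losing the Schiff lysine fails the hard requirement
  pk <- extract_profile(mutate_at(ref$sequence, 296, "R"), map, pocket)
  expect_false(check_retinal(pk, rule)$has_schiff_lysine)

  expect_error(check_retinal(rho, retinal_rule("9.99", "3.28")), "9.99")
})

test_that("minimal-pocket conservation counts against a reference", {
  bw <- read_bw_config()
  ref <- opsd_reference()
  map <- assign_bw(ref$sequence, ref$sequence, bw$anchors, bw$helix_bounds)
  pocket <- read_pocket_config()
  rule <- retinal_rule(minimal_pocket = c("3.28", "6.48", "6.51", "7.43"))
  rho <- extract_profile(ref, map, pocket)
  # mutate one of the four minimal-pocket positions (6.48, rhodopsin W265)
  seq2 <- ref$sequence
  substr(seq2, 265, 265) <- "A"
  cand <- extract_profile(seq2, map, pocket, protein_id = "mut")
  v <- check_retinal(cand, rule, reference = rho)
  expect_equal(v$minimal_pocket_conserved, 3L)
  expect_equal(check_retinal(rho, rule, reference = rho)$minimal_pocket_conserved, 4L)
})

test_that("candidate ranking recovers a planted pocket and applies the lysine filter", {
  bw <- read_bw_config()
  ref <- opsd_reference()
  map <- assign_bw(ref$sequence, ref$sequence, bw$anchors, bw$helix_bounds)
  pocket <- read_pocket_config()
  rho <- extract_profile(ref, map, pocket)
  set.seed(13)
  random_profile <- function(id) {
    res <- sample(AA20, 30, replace = TRUE)
    structure(list(protein_id = id, residues = setNames(res, pocket$labels),
                   definition = pocket$labels), class = "pocket_profile")
  }
  for (rep in 1:10) {
    planted <- rho
    planted$protein_id <- "planted"
    decoys <- lapply(sprintf("decoy%d", 1:5), random_profile)
    ranked <- rank_opsin_candidates(c(list(planted), decoys), list(rho))
    expect_equal(ranked$protein_id[1], "planted")
    expect_equal(ranked$n_identical[1], 30L)
  }
  # candidate without the Schiff lysine never passes
  nok <- rho
  nok$protein_id <- "no_lysine"
  nok$residues["7.43"] <- "R"
  ranked <- rank_opsin_candidates(list(nok), list(rho))
  expect_false(ranked$pass[1])
})
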