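single_atom <- function(chain, resno, x, y = 0, z = 0) {
  data.frame(chain = chain, residue_number = resno, residue_name = "ALA",
             atom_name = "CA", x = x, y = y, z = z, stringsAsFactors = FALSE)
}

test_that("interface residues follow the any-atom distance rule", {
  a <- single_atom("A", 1, 0)
  expect_equal(nrow(interface_residues(a, single_atom("B", 1, 4.0))), 1L)
  expect_equal(nrow(interface_residues(a, single_atom("B", 1, 6.0))), 0L)
  # one atom at 4.9 A, the rest far away: residue still included
  a2 <- rbind(single_atom("A", 7, 4.9), single_atom("A", 7, 500),
              single_atom("A", 8, 300))
  got <- interface_residues(a2, single_atom("B", 1, 0))
  expect_equal(got$residue_number, 7L)
  expect_error(interface_residues(a, a, cutoff = 0), "positive")
})

test_that("interface extraction equals the all-pairs distance scan on random toys", {
  set.seed(31)
  for (i in 1:20) {
    a <- data.frame(chain = "A", residue_number = sample(1:12, 25, replace = TRUE),
                    residue_name = "ALA", atom_name = "CA",
                    x = runif(25, 0, 20), y = runif(25, 0, 20), z = runif(25, 0, 20),
                    stringsAsFactors = FALSE)
    b <- data.frame(chain = "B", residue_number = sample(1:12, 25, replace = TRUE),
                    residue_name = "GLY", atom_name = "CA",
                    x = runif(25, 0, 20), y = runif(25, 0, 20), z = runif(25, 0, 20),
                    stringsAsFactors = FALSE)
    expect_equal(interface_residues(a, b, 5), oracle_interface(a, b, 5))
  }
})

test_that("interface extraction is rigid-motion invariant", {
  set.seed(37)
  a <- data.frame(chain = "A", residue_number = 1:20, residue_name = "ALA",
                  atom_name = "CA", x = runif(20, 0, 30), y = runif(20, 0, 30),
                  z = runif(20, 0, 30), stringsAsFactors = FALSE)
  b <- data.frame(chain = "B", residue_number = 1:20, residue_name = "GLY",
                  atom_name = "CA", x = runif(20, 0, 30), y = runif(20, 0, 30),
                  z = runif(20, 0, 30), stringsAsFactors = FALSE)
  base <- interface_residues(a, b, 6)
  for (i in 1:5) {
    # random rotation (QR of a random matrix) + translation, applied to both
    qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
    shift <- rnorm(3, sd = 50)
    tr <- function(df) {
      xyz <- as.matrix(df[, c("x", "y", "z")]) %*% qr_r
      df$x <- xyz[, 1] + shift[1]; df$y <- xyz[, 2] + shift[2]
      df$z <- xyz[, 3] + shift[3]
      df
    }
    expect_equal(interface_residues(tr(a), tr(b), 6), base)
  }
})

test_that("the screen scores every cross-role pair once and thresholds edges", {
  set.seed(41)
  alphas <- random_protein_set(3, prefix = "a")
  betas <- random_protein_set(2, prefix = "b")
  gammas <- random_protein_set(2, prefix = "g")
  planted <- list("a001|b001" = 0.9, "b001|g001" = 0.8)
  net <- screen(alphas, betas, gammas, lookup_scorer(planted))
  expect_equal(nrow(net$scores), 3 * 2 + 2 * 2 + 3 * 2)
  expect_equal(sort(paste(net$edges$a, net$edges$b)), c("a001 b001", "b001 g001"))

  # empty gamma list: only alpha-beta pairs scored
  net2 <- screen(alphas, betas, NULL, lookup_scorer(planted))
  expect_equal(nrow(net2$scores), 6L)
  expect_error(screen(alphas, alphas, gammas, lookup_scorer(planted)), "disjoint")
})

test_that("screen pair counts scale as |A||B| + |B||G| + |A||G|", {
  alphas <- random_protein_set(124, len = 5, prefix = "pa")
  betas <- random_protein_set(207, len = 5, prefix = "pb")
  gammas <- random_protein_set(5, len = 5, prefix = "pg")
  net <- screen(alphas, betas, gammas, function(a, b) 0)
  expect_equal(nrow(net$scores), 124 * 207 + 207 * 5 + 124 * 5)
  expect_equal(nrow(net$edges), 0L)
})

test_that("BLAST best-bidirectional mapping keeps mutual best hits only", {
  row <- function(q, t, bits, ev = 1e-30) {
    sprintf("%s\t%s\t90\t100\t1\t0\t1\t100\t1\t100\t%g\t%g", q, t, ev, bits)
  }
  fwd <- parse_blast_tabular(paste(c(row("P1", "M1", 300), row("P1", "M2", 100),
                                     row("P2", "M2", 250)), collapse = "\n"))
  rev <- parse_blast_tabular(paste(c(row("M1", "P1", 280),
                                     row("M2", "P9", 260)), collapse = "\n"))
  pairs <- bbh_map(fwd, rev)
  expect_equal(nrow(pairs), 1L)
  expect_equal(c(pairs$id_a, pairs$id_b), c("P1", "M1"))
})

test_that("BBH tie-breaking is bitscore, then evalue, then target id", {
  mk <- function(rows) parse_blast_tabular(paste(rows, collapse = "\n"))
  r <- function(q, t, bits, ev) sprintf("%s\t%s\t90\t100\t1\t0\t1\t100\t1\t100\t%g\t%g",
                                        q, t, ev, bits)
  fwd <- mk(c(r("P1", "M2", 200, 1e-20), r("P1", "M1", 200, 1e-30)))
  rev <- mk(c(r("M1", "P1", 150, 1e-10)))
  # equal bitscores: M1 wins on evalue; pair (P1, M1) is mutual
  expect_equal(bbh_map(fwd, rev)$id_b, "M1")
  fwd2 <- mk(c(r("P1", "M2", 200, 1e-20), r("P1", "M1", 200, 1e-20)))
  rev2 <- mk(c(r("M1", "P1", 150, 1e-10)))
  # full tie: lexicographic target id
  expect_equal(bbh_map(fwd2, rev2)$id_b, "M1")
})

test_that("random mutual-best maps equal the brute-force double loop", {
  set.seed(43)
  for (i in 1:30) {
    ps <- sprintf("P%d", 1:6); ms <- sprintf("M%d", 1:6)
    mkrows <- function(qs, ts) {
      rows <- c()
      for (q in qs) {
        for (t in sample(ts, sample(1:4, 1))) {
          rows <- c(rows, sprintf("%s\t%s\t90\t100\t1\t0\t1\t100\t1\t100\t%g\t%g",
                                  q, t, 10^runif(1, -40, -5), round(runif(1, 50, 400))))
        }
      }
      parse_blast_tabular(paste(rows, collapse = "\n"))
    }
    fwd <- mkrows(ps, ms); rev <- mkrows(ms, ps)
    got <- bbh_map(fwd, rev)
    # oracle: recompute best hits by explicit sort and check mutuality
    best <- function(tab) {
      sapply(split(tab, tab$query_id), function(d) {
        d <- d[order(-d$bitscore, d$evalue, d$target_id), ]
        d$target_id[1]
      })
    }
    bf <- best(fwd); br <- best(rev)
    want <- sort(names(bf)[!is.na(br[bf]) & br[bf] == names(bf)])
    expect_equal(got$id_a, want)
    # each id appears at most once
    expect_false(anyDuplicated(c(got$id_a, got$id_b)) > 0)
  }
})

test_that("network overlay marks conserved edges through the species map", {
  alphas <- random_protein_set(2, prefix = "a")
  betas <- random_protein_set(2, prefix = "b")
  sc <- lookup_scorer(list("a001|b001" = 0.9, "a002|b002" = 0.9))
  net1 <- screen(alphas, betas, NULL, sc)
  # identity map: everything conserved against itself
  idmap <- data.frame(id_a = c(alphas$id, betas$id), id_b = c(alphas$id, betas$id))
  ov <- overlay(net1, net1, idmap)
  expect_true(all(ov$conserved))
  # map a001 to an unconnected node: its edge is no longer conserved
  map2 <- idmap
  map2$id_b[map2$id_a == "a001"] <- "a002"
  ov2 <- overlay(net1, net1, map2)
  expect_false(ov2$conserved[ov2$a == "a001"])
})

test_that("triangle evidence equals cubic enumeration on random tripartite graphs", {
  set.seed(47)
  for (i in 1:25) {
    na <- sample(2:10, 1); nb <- sample(2:10, 1); ng <- sample(2:10, 1)
    alphas <- random_protein_set(na, len = 4, prefix = "a")
    betas <- random_protein_set(nb, len = 4, prefix = "b")
    gammas <- random_protein_set(ng, len = 4, prefix = "g")
    net <- screen(alphas, betas, gammas, function(a, b) runif(1))
    expect_equal(triangle_evidence(net), oracle_triangles(net))
  }
  # hand case: a full triangle, then remove one edge
  alphas <- random_protein_set(1, prefix = "a")
  betas <- random_protein_set(1, prefix = "b")
  gammas <- random_protein_set(1, prefix = "g")
  full <- screen(alphas, betas, gammas, function(a, b) 1)
  expect_equal(nrow(triangle_evidence(full)), 1L)
  noag <- screen(alphas, betas, gammas,
                 lookup_scorer(list("a001|b001" = 1, "b001|g001" = 1)))
  expect_equal(nrow(triangle_evidence(noag)), 0L)
})

test_that("perturbation test contracts: no-op, determinism, constant scorer", {
  ic <- make_interface_complex(synthetic_config(seed = 3, sequence_length = 100),
                               n_interface = 30)
  a <- ic$pair[1, ]; b <- ic$pair[2, ]
  # k = 0 is a no-op in both arms
  r0 <- perturbation_test(a, b, ic$scorer, ic$interface, k = 0, n_trials = 5,
                          seed = 9)
  expect_equal(r0$permuted_mean, r0$original)
  expect_equal(r0$random_mean, r0$original)
  # same seed, bit-identical result
  r1 <- perturbation_test(a, b, ic$scorer, ic$interface, k = 10, n_trials = 10,
                          seed = 99)
  r2 <- perturbation_test(a, b, ic$scorer, ic$interface, k = 10, n_trials = 10,
                          seed = 99)
  expect_identical(unclass(r1), unclass(r2))
  # a constant scorer gives exactly zero drop
  rc <- perturbation_test(a, b, function(x, y) 0.42, ic$interface, k = 10,
                          n_trials = 10, seed = 1)
  expect_identical(rc$original, 0.42)
  expect_identical(rc$permuted_mean, 0.42)
  expect_identical(rc$random_mean, 0.42)
  expect_identical(rc$permuted_sd, 0)
  # k above the site count errors in fixed-site mode, warns when sampling
  expect_error(perturbation_test(a, b, ic$scorer, 1:5, k = 10, n_trials = 2,
                                 seed = 1, sample_sites = FALSE), "k exceeds")
  expect_warning(perturbation_test(a, b, ic$scorer, 1:5, k = 10, n_trials = 2,
                                   seed = 1), "lowering k")
})

test_that("site-arm perturbation is selectively deleterious on a planted interface", {
  ic <- make_interface_complex(synthetic_config(seed = 21, sequence_length = 150),
                               n_interface = 30)
  r <- perturbation_test(ic$pair[1, ], ic$pair[2, ], ic$scorer, ic$interface,
                         k = 25, n_trials = 30, seed = 5)
  expect_lt(r$permuted_mean, r$original - 0.5)
  # random arm stays within 3 standard errors of the original
  se <- r$random_sd / sqrt(r$n_trials)
  expect_lt(abs(r$random_mean - r$original), max(3 * se, 0.2))
})

test_that("binding-site positions transfer through alignments", {
  expect_equal(site_positions_from_alignment("MKVLIV", "MKVLIV", c(2, 5)),
               c(2L, 5L))
  # 3-residue N-terminal extension in the candidate shifts positions by 3
  expect_equal(site_positions_from_alignment("---MKVLIV", "AAAMKVLIV", c(2, 5)),
               c(5L, 8L))
  # reference site aligned to a candidate gap is dropped with a warning
  expect_warning(
    got <- site_positions_from_alignment("MKVLIV", "MK-LIV", c(2, 3, 5)),
    "not alignable")
  expect_equal(got, c(2L, 4L))
})
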