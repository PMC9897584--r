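---
title: "Remote-homology annotation transfer: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote-homology annotation transfer: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homolot)
```

## The problem and the model

Annotating a proteome that is hundreds of millions of years from the
nearest well-studied organism faces two separate failures. First, pairwise
search misses homologues below roughly 30% identity; profile-HMM search
(HHblits-style) recovers them, and this package consumes those results
rather than re-running the search. Second — and less obvious — detection
does not identify function: receptor superfamilies expanded within the
model organism after the split, so its members are more similar to each
other than any is to the non-model protein, and no single alignment
statistic picks "the" homologue. `homolot`'s answer is a two-stage
procedure: symmetric evidence at the sequence level (best-bidirectional
hits, multi-organism consensus), then class-specific structural and
functional plausibility checks at positions known to determine
specificity.

## Stage 1: hit processing

A hit table is one query's ranked hit list with the statistics the search
tool prints: probability (0–100 scale, one decimal), E-value, P-value,
score, matched columns, alignment spans. Three parameter choices matter:

* `evalue_max = 1e-3`, `probability_min = 20`, `max_hits = 250` — the
  standard remote-homology search settings; they define "a hit" for every
  downstream count.
* **"Top ranked" means the tool's own rank-1 hit** after filtering, not a
  re-sort by any one statistic. The tool's ranking integrates several
  signals, and re-sorting silently changes non-redundant counts. A
  `rerank = TRUE` switch (probability desc, E-value asc, score desc, id)
  exists for tabular inputs lacking a meaningful rank.
* **"100% probability" means printed `100.0`**, i.e. ≥ 99.95: result files
  carry one decimal, so an exact `== 100` test would be sensitive to
  formatting, not biology. The consensus tally counts each (query, target)
  incidence once even when several alignment blocks hit the same target,
  because the unit of evidence is the query, not the alignment.

Best-bidirectional pairs are exactly the mutual rank-1 pairs; with BLAST
tabular input the best hit is max bitscore, ties broken by min E-value,
then lexicographic target id (ties are real in BLAST output, and an
undocumented tie-break would make runs irreproducible). Obsolete or
unmapped queries are reported, never dropped silently.

## Stage 2a: GPCR pockets

Ballesteros–Weinstein numbering makes pocket positions comparable across
receptors: position `h.nn` is offset `nn − 50` from the most conserved
residue of helix `h`. The anchors (rod opsin N55, D83, R135, W161, P215,
P267, P303), the helix spans, and the 30-position cavity-facing list ship
as editable YAML in `inst/extdata/` — they are inputs to the method, not
constants of it, and users studying another receptor family are expected
to replace them. The shipped 348-aa rod-opsin reference was verified at
every anchor position before release.

Profile identity counts positions where both profiles have a residue; the
default excludes gap positions from the denominator (a missing helix says
"no evidence", not "mismatch"), and a `strict = TRUE` mode counts them as
mismatches — both are provided because published identity counts rarely
state which convention they used.

The retinal rule is deliberately asymmetric: loss of the Schiff-base
lysine (BW 7.43) is a hard fail — without covalent retinal attachment
there is no light sensitivity — while counter-ion substitutions (BW 3.28,
E→Y common in invertebrate opsins, E→S observed) shift the absorbance
maximum but preserve function, so they are *recorded* (`tyrosine`,
`serine`, `acidic`, `other`) and never auto-rejected. The 4-residue
minimal-pocket check runs only when the user supplies the four positions;
no default is invented for them.

## Stage 2b: domain architectures

The PROSITE PA-syntax engine supports literals, `x`, allowed `[..]` and
forbidden `{..}` sets, fixed and ranged repeats, and `<`/`>` anchors.
Variable repeats are greedy with backtracking, so each start position
yields at most one hit; all-matches mode reports every matching start,
scan mode reports non-overlapping hits left to right. Weight-matrix
(profile) entries are out of scope; domains detectable only by profiles
can be supplied as precomputed hit tables. The engine is tested against an
oracle that expands patterns to every concrete string and substring
searches.

Placement assumes the type-I receptor convention: one TM helix,
N-terminus extracellular (`n_term_out`, overridable). Classification is a
pure function of the placed domain sets: canonical TLR requires ≥ 1
extracellular LRR *and* a cytoplasmic TIR *and* no unexpected
extracellular domain classes. The LRR threshold is 1 rather than
"multiple" because LRR counts depend entirely on pattern granularity; the
count is reported so users can cut stricter. The recognised
extra-ectodomain classes (cadherin, calcium-binding EGF, thrombospondin
repeats) are configuration.

## Stage 2c: PPI evidence

The interaction predictor is an external adapter: anything satisfying
`scorer(record_a, record_b) → [0, 1]`, deterministic for fixed inputs.
Role order (α first) is part of the contract because learned scorers need
not be symmetric. The default edge threshold is 0.5 on the scorer's
probability scale — the natural decision boundary for a calibrated
classifier — and is configurable. Interface residues use the any-atom
rule at 5 Å, the convention used when reading binding sites off
co-crystal structures.

The perturbation test interprets "randomly perturbed" as: sample `k = 25`
site positions without replacement per trial, substitute each uniformly
over the 19 non-identical standard residues, re-score; 50 trials per arm;
the control arm samples from the whole sequence. The substitution
distribution is a design choice (no substitution matrix), made for
symmetry between the two arms: any difference between arms is then
attributable to *position*, not substitution chemistry. Each arm runs in
a private seeded RNG stream, so results are bit-reproducible and the
caller's RNG state is untouched. When the known site set is smaller than
25, `k` is lowered with a warning rather than silently resampling.

## The synthetic corpus: what it emulates, and what it does not

The generators produce the study conditions the pipeline targets:
families diverged to ~25% identity (`mutation_rate = 0.75`, uniform
substitutions — matching the twilight-zone regime), planted top hits with
search probability in [95, 100] of which half print as 100.0 (so the
consensus path is exercised), decoy hits below the planted hit with one
decoy failing the E-value cutoff, TLR-style architectures whose motif
instances cannot arise by chance (the background alphabet excludes a
residue required by each motif), and toy complexes where geometry,
sequence and mock scorer agree on one planted interface.

They deliberately do **not** emulate: indel evolution (alignments are
substitution-only), paralog trees, realistic HMM score distributions, or
a trained interaction predictor (the mock scorer is a logistic function
of preserved interface residues). Passing tests therefore demonstrate
that the *logic* of every stage is exact on known truth — filtering,
inversion, symmetry, counting, placement, classification, perturbation
accounting — not that the upstream search or PPI tools are accurate.

## Numerical and degenerate-input choices

* Probability thresholds use half-ULP slack (`≥ threshold − 0.05`) only
  where "printed 100.0" is meant; the stage-1 filter applies its
  thresholds exactly as given.
* Interface distances compare squared distances with a 10⁻¹² tolerance so
  rigid-motion invariance holds to floating-point noise.
* Empty inputs are legal everywhere they can arise: empty FASTA → empty
  set, "No hits found" → empty table, empty hit directory → summary of
  zeros; zero TM segments → domains unplaced with a warning (not an
  error, since secreted proteins legitimately occur in candidate lists).
* Ambiguity codes B/Z/U map to X with a warning; any other letter is an
  error naming the record.
* Ties: consensus columns order by total count then id; BBH ties as
  above; all outputs are deterministically sorted so reruns are
  byte-identical.

## Problem sizes

The shipped tests run the full pipeline at 200 queries / 60 families /
120-residue sequences, oracle comparisons at 1000 random pattern cases,
networks ≤ 30 nodes and 50-atom toys, and the perturbation study at 20
pairs × 2 arms × 50 trials — sizes chosen so the complete suite exercises
every code path in well under a minute on one core while keeping every
combinatorial check exhaustive at its scale.

## Known limitations

Stage-1 counts at publication scale require the original hit tables;
the package reproduces the *logic* on planted corpora and on the shipped
cross-organism tally. TM-helix prediction, homology modelling, docking
and the PPI predictor itself are consumed as inputs by design. The final
call on a candidate list (e.g. which pocket mismatches are tolerable) is
expert judgement; the package reports evidence and flags rather than
automating that step.
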