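# homolot

Transfer of membrane-receptor annotations from a model organism to a
distant non-model organism, for genomes where ordinary BLAST-level search
breaks down. The motivating system is the stony coral *Pocillopora
damicornis*: the cnidarian host diverged from vertebrates roughly 700
million years ago, so most human receptor homologues sit in the "twilight
zone" of 10–30% sequence identity and are only reachable with
profile-HMM remote-homology search. Detection alone is not enough,
though — receptor superfamilies have diverged *within* the model organism,
so many human queries collapse onto few coral genes and no alignment
statistic picks the functional counterpart. `homolot` therefore implements
a two-stage pipeline:

**Stage 1 — hit-table processing.** HHblits-style result files (HHR text)
are parsed and filtered (E-value ≤ 10⁻³, probability ≥ 20 on the printed
0–100 scale, hit lists up to 250 entries). Per query the rank-1 surviving
hit is retrieved; inverting the map gives the non-redundant target list. A
coral protein is a *candidate* only if it is a best-bidirectional match:
its human partner is the top hit in both search directions. For
multi-organism analyses, a consensus matrix counts how often each organism
hits each target with printed probability 100.0, and candidates are
required to be represented in every organism.

**Stage 2 — structure/function plausibility filters**, branching by
receptor class:

* *GPCRs / opsins*: candidate pockets are read off at 30 cavity-facing
  positions in Ballesteros–Weinstein numbering (helix.offset, with each
  helix's most conserved residue fixed at x.50). A retinal-binding rule
  checks the Schiff-base lysine (rhodopsin K296, BW 7.43) and the
  counter-ion position (E113, BW 3.28), where E→Y or E→S substitutions
  shift absorbance but keep function, and loss of the lysine is fatal.
* *Toll-like receptors*: sequences are scanned with PROSITE PA-syntax
  patterns, hits are placed extracellular/cytoplasmic relative to the
  single transmembrane helix, and the composition is classified as
  `canonical_TLR`, `TIR_only`, `LRR_only`, `TLR_with_extra_domains` or
  `not_TLR`.
* *G proteins*: a pluggable pair scorer (any function `(a, b) →
  probability`, e.g. a deep-learning PPI predictor run externally) drives
  all-vs-all α/β/γ screens; α–β–γ triangles in the resulting network are
  functional evidence, cross-checked by overlaying a second species'
  network through a BLAST best-bidirectional map. An in-silico mutagenesis
  test perturbs 25 putative binding-site residues (50 trials, against a
  random-site control) and asks whether the interaction probability drops
  specifically at the binding site.

A deterministic synthetic-data generator (`make_homolog_corpus()`,
`make_hhr_files()`, `make_domain_proteins()`, `make_interface_complex()`)
builds planted-truth corpora for every stage, so the whole pipeline is
testable offline.

## Worked example

```r
library(homolot)

# planted corpus: 10 homolog families, 30 model-organism queries
cfg    <- synthetic_config(seed = 7, n_families = 10, n_queries = 30,
                           sequence_length = 80)
corpus <- make_homolog_corpus(cfg)
dirs   <- make_hhr_files(corpus, cfg, tempdir())
res    <- run_pipeline(pipeline_config(dirs$forward, dirs$reverse, tempfile()))
res$summary
#>       queries_in   queries_mapped queries_unmapped   unique_targets
#>               30               30                0               10
#>        bbh_pairs
#>               10
```

All 30 queries map, they collapse onto the 10 planted families
(`unique_targets`), and each family yields one best-bidirectional pair.
The consensus step on the shipped cross-organism TLR tally:

```r
counts <- tlr_hit_counts()
select_consensus_targets(counts,
  c("Human", "Zebrafish", "Frog", "Chicken", "Drosophila"))
#> [1] "11599" "9200"  "22934" "22930" "17966" "14109" "13021"
```

Seven coral proteins are homologous to at least one TLR in every one of
the five organisms (ordered by total hit count). And the retinal rule on
the shipped rod-opsin reference:

```r
bw  <- read_bw_config()
ref <- opsd_reference()
map <- assign_bw(ref$sequence, ref$sequence, bw$anchors, bw$helix_bounds)
check_retinal(extract_profile(ref, map, read_pocket_config()), retinal_rule())
#> $has_schiff_lysine
#> [1] TRUE
#> $counterion_residue
#> [1] "E"
#> $counterion_class
#> [1] "acidic"
```

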