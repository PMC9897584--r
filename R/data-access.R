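#' Published TLR consensus tally
#'
#' Loads the shipped organisms-by-targets count matrix of printed-100.0
#' remote-homology hits for the coral TLR candidate set (six model
#' organisms, thirteen candidate proteins). Feeding it to
#' [select_consensus_targets()] with the five model organisms other than
#' the nematode reproduces the published candidate shortlist.
#'
#' @param path TSV file; defaults to the copy shipped with the package.
#' @return integer matrix with organism rownames and target-id colnames.
#' @examples
#' counts <- tlr_hit_counts()
#' select_consensus_targets(counts,
#'   c("Human", "Zebrafish", "Frog", "Chicken", "Drosophila"))
#' @export
tlr_hit_counts <- function(path = system.file("extdata", "tlr_hit_counts.tsv",
                                              package = "homolot")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Shipped rod-opsin reference sequence
#'
#' @return a one-row `protein_set` with the 348-aa rod opsin reference used
#'   by the default BW numbering configuration.
#' @export
opsd_reference <- function() {
  parse_fasta(system.file("extdata", "opsd_human.fasta", package = "homolot"))
}
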