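#' Parse ATOM records from a PDB file
#'
#' Extracts chain, residue number/name, atom name and coordinates from
#' fixed-column `ATOM`/`HETATM` records (all other record types are ignored).
#' The heavy lifting is done by [bio3d::read.pdb()]; a pre-validation pass
#' reports truncated ATOM lines with their line number, which the underlying
#' reader would silently mangle.
#'
#' @param x path to a PDB file, or its text.
#' @return data frame with columns `chain`, `residue_number`, `residue_name`,
#'   `atom_name`, `x`, `y`, `z` (coordinates in Angstrom).
#' @export
parse_pdb_atoms <- function(x) {
  inp <- .as_input_file(x)
  on.exit(if (inp$temp) unlink(inp$path))
  lines <- readLines(inp$path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  short <- is_atom & nchar(lines) < 54L
  if (any(short)) {
    stop("truncated ATOM/HETATM record at line ", which(short)[1])
  }
  if (!any(is_atom)) {
    return(data.frame(chain = character(), residue_number = integer(),
                      residue_name = character(), atom_name = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  pdb <- bio3d::read.pdb(inp$path, verbose = FALSE)
  at <- pdb$atom
  out <- data.frame(chain = as.character(at$chain),
                    residue_number = as.integer(at$resno),
                    residue_name = as.character(at$resid),
                    atom_name = as.character(at$elety),
                    x = as.numeric(at$x), y = as.numeric(at$y),
                    z = as.numeric(at$z), stringsAsFactors = FALSE)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("non-finite coordinates in PDB input")
  }
  out
}

#' Write minimal PDB ATOM records
#'
#' Formats an atom table (as returned by [parse_pdb_atoms()]) as fixed-column
#' ATOM records; used by the synthetic-complex generator.
#'
#' @param atoms atom data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %-4.4s %-3.3s %1.1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(atoms)), atoms$atom_name, atoms$residue_name,
    atoms$chain, atoms$residue_number, atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
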