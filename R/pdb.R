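#' Read C-alpha coordinates from a PDB file
#'
#' Minimal fixed-column parser for ATOM records: first model only, one chain,
#' alternate locations resolved by highest occupancy then first-seen. Residues
#' present in the chain but lacking a C-alpha atom yield a row of `NA`.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier (single character).
#' @param n Optional residue count. When given, residue sequence numbers index
#'   directly into rows `1..n` and absent residues are `NA` rows; when `NULL`,
#'   rows follow the sorted residue sequence numbers actually observed.
#' @return Numeric matrix with columns `x`, `y`, `z` (Angstrom).
#' @export
read_pdb_ca <- function(path, chain = "A", n = NULL) {
  if (!file.exists(path)) fr_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  atoms <- lines[startsWith(lines, "ATOM  ")]
  if (!length(atoms)) fr_stop("PDB file '", path, "' contains no ATOM records")
  chains <- substr(atoms, 22, 22)
  if (!any(chains == chain))
    fr_stop(sprintf("chain '%s' not found in '%s' (chains present: %s)",
                    chain, path, paste(sort(unique(chains)), collapse = ", ")))
  atoms <- atoms[chains == chain]
  name <- trimws(substr(atoms, 13, 16))
  ca <- atoms[name == "CA"]
  if (!length(ca))
    fr_stop(sprintf("chain '%s' in '%s' has no C-alpha atoms", chain, path))
  resseq <- as.integer(substr(ca, 23, 26))
  occ <- suppressWarnings(as.numeric(substr(ca, 55, 60)))
  occ[is.na(occ)] <- 1
  xyz <- cbind(x = as.numeric(substr(ca, 31, 38)),
               y = as.numeric(substr(ca, 39, 46)),
               z = as.numeric(substr(ca, 47, 54)))
  # altloc resolution: keep, per residue number, the highest-occupancy CA
  # (ties and equal occupancies fall back to first-seen via stable ordering)
  keep <- order(resseq, -occ)
  keep <- keep[!duplicated(resseq[keep])]
  keep <- keep[order(resseq[keep])]
  resseq <- resseq[keep]
  xyz <- xyz[keep, , drop = FALSE]
  if (is.null(n)) {
    rownames(xyz) <- resseq
    return(xyz)
  }
  n <- as.integer(n)
  if (any(resseq < 1L | resseq > n))
    fr_stop(sprintf("PDB '%s': residue number %d outside 1..%d",
                    path, resseq[which(resseq < 1L | resseq > n)[1]], n))
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  out[resseq, ] <- xyz
  out
}

#' Write C-alpha-only coordinates as a PDB file
#'
#' Counterpart of [read_pdb_ca] used by the synthetic benchmark generator:
#' one CA ATOM record per residue (rows of `NA` are skipped, modelling
#' unresolved residues), chain A, occupancy 1, coordinates at 3 decimals.
#'
#' @param coords Numeric matrix with 3 columns, one row per residue.
#' @param sequence Amino-acid sequence (for residue names; one-letter codes are
#'   mapped to their three-letter equivalents).
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(coords, sequence, path, chain = "A") {
  coords <- as.matrix(coords)
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) != nrow(coords))
    fr_stop("sequence length does not match coordinate rows")
  res <- unname(aa3[chars])
  res[is.na(res)] <- "UNK"
  keep <- which(stats::complete.cases(coords))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(keep), res[keep], chain, keep,
    coords[keep, 1], coords[keep, 2], coords[keep, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
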