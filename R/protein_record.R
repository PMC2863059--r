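#' Protein record
#'
#' The per-protein container carried through the pipeline: amino-acid sequence,
#' optional 3-state secondary-structure string, optional contact probability
#' map, optional C-alpha coordinates, and optional experimental annotations
#' (log10 folding rate, kinetic label, precomputed geometric-contact scalar).
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (upper-cased on input).
#' @param ss_string Optional secondary-structure string over `{H, E, C}`, same
#'   length as `sequence`.
#' @param map Optional [contact_map] of dimension `nchar(sequence)`.
#' @param ca_coords Optional numeric matrix with 3 columns (x, y, z in
#'   Angstrom), one row per residue; rows of `NA` mark residues whose C-alpha
#'   is missing from the structure.
#' @param log_rate Optional experimental folding rate as log10(k_f / sec^-1).
#' @param kinetic_label Optional kinetic type, normalized to `"two_state"` or
#'   `"multi_state"` (case/punctuation-insensitive on input).
#' @param gc_value Optional precomputed geometric-contact scalar (a
#'   structure-derived packing feature consumed as-is, never computed here).
#' @param strict If `TRUE` (default) reject residues outside the 20-letter
#'   alphabet; if `FALSE` non-canonical residues are kept in the sequence but
#'   ignored by composition features.
#' @return An object of class `"protein_record"`.
#' @export
protein_record <- function(id, sequence, ss_string = NULL, map = NULL,
                           ca_coords = NULL, log_rate = NULL,
                           kinetic_label = NULL, gc_value = NULL,
                           strict = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) < 1L)
    fr_stop(sprintf("record '%s': sequence must be a non-empty string", id))
  validate_sequence(sequence, id = id, strict = strict)
  L <- nchar(sequence)
  if (!is.null(ss_string)) {
    ss_string <- toupper(as.character(ss_string))
    validate_ss(ss_string, id = id)
    if (nchar(ss_string) != L)
      fr_stop(sprintf("record '%s': ss_string length %d != sequence length %d",
                      id, nchar(ss_string), L))
  }
  if (!is.null(map)) {
    if (!is_contact_map(map)) map <- contact_map(map)
    if (nrow(map) != L)
      fr_stop(sprintf("record '%s': contact map dimension %d != sequence length %d",
                      id, nrow(map), L))
  }
  if (!is.null(ca_coords)) {
    ca_coords <- as.matrix(ca_coords)
    if (ncol(ca_coords) != 3L)
      fr_stop(sprintf("record '%s': ca_coords must have 3 columns", id))
    if (nrow(ca_coords) != L)
      fr_stop(sprintf("record '%s': ca_coords rows %d != sequence length %d",
                      id, nrow(ca_coords), L))
  }
  if (!is.null(log_rate)) {
    if (!is.numeric(log_rate) || length(log_rate) != 1L || !is.finite(log_rate))
      fr_stop(sprintf("record '%s': log_rate must be a finite number", id))
  }
  if (!is.null(kinetic_label))
    kinetic_label <- normalize_kinetic_label(kinetic_label, context = id)
  if (!is.null(gc_value))
    stopifnot_scalar_number(gc_value, "gc_value")
  structure(list(id = as.character(id), sequence = sequence,
                 ss_string = ss_string, map = map, ca_coords = ca_coords,
                 log_rate = log_rate, kinetic_label = kinetic_label,
                 gc_value = gc_value),
            class = "protein_record")
}

validate_sequence <- function(sequence, id = "?", strict = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% aa_alphabet()))
  if (strict && length(bad))
    fr_stop(sprintf("record '%s': illegal residue '%s' at position %d",
                    id, chars[bad[1]], bad[1]))
  # lenient mode still rejects characters that cannot be residues at all
  if (!strict) {
    nonletter <- which(!grepl("[A-Z]", chars))
    if (length(nonletter))
      fr_stop(sprintf("record '%s': non-letter character '%s' at position %d",
                      id, chars[nonletter[1]], nonletter[1]))
  }
  invisible(TRUE)
}

validate_ss <- function(ss_string, id = "?") {
  chars <- strsplit(ss_string, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% c("H", "E", "C")))
  if (length(bad))
    fr_stop(sprintf("record '%s': illegal secondary-structure character '%s' at position %d",
                    id, chars[bad[1]], bad[1]))
  invisible(TRUE)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record '%s': %d residues", x$id, nchar(x$sequence)))
  parts <- c(
    if (!is.null(x$ss_string)) "SS",
    if (!is.null(x$map)) "contact map",
    if (!is.null(x$ca_coords)) "CA coords",
    if (!is.null(x$log_rate)) sprintf("log10 rate %.2f", x$log_rate),
    if (!is.null(x$kinetic_label)) x$kinetic_label
  )
  if (length(parts)) cat(" [", paste(parts, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}
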