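#' Sequence length
#'
#' The number of residues in the chain.
#'
#' @param sequence Amino-acid string.
#' @return Integer residue count.
#' @export
sequence_length <- function(sequence) nchar(as.character(sequence))

#' Amino-acid composition
#'
#' Occurrence frequency of each of the 20 canonical residues, in the fixed
#' alphabetical order of [aa_alphabet()]. In strict mode (default) the vector
#' sums to exactly 1; in lenient mode non-canonical residues are dropped from
#' both numerator and denominator.
#'
#' @param sequence Non-empty amino-acid string.
#' @param strict Reject non-canonical residues (`TRUE`, default) or ignore them.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_composition <- function(sequence, strict = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) == 0L)
    fr_stop("sequence must be a single non-empty string")
  validate_sequence(sequence, strict = strict)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% aa_alphabet()]
  if (!length(chars))
    fr_stop("sequence contains no canonical residues")
  counts <- table(factor(chars, levels = aa_alphabet()))
  freq <- as.numeric(counts) / length(chars)
  names(freq) <- aa_alphabet()
  freq
}

#' Secondary-structure composition
#'
#' Fractions of residues in helix (H), strand (E) and coil (C) states; the
#' three fractions sum to 1.
#'
#' @param ss_string Non-empty string over `{H, E, C}`.
#' @return Named numeric vector `c(helix, sheet, coil)`.
#' @export
ss_composition <- function(ss_string) {
  ss_string <- toupper(as.character(ss_string))
  if (length(ss_string) != 1L || nchar(ss_string) == 0L)
    fr_stop("ss_string must be a single non-empty string")
  validate_ss(ss_string)
  chars <- strsplit(ss_string, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = c("H", "E", "C")))
  out <- as.numeric(counts) / length(chars)
  names(out) <- c("helix", "sheet", "coil")
  out
}
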