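# Internal validation helpers. All user-facing errors go through these so the
# message always names the offending record/position.

fr_stop <- function(..., call. = FALSE) stop(..., call. = call.)

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fr_stop(sprintf("'%s' must be a single finite number", name))
  if (strict_lower && x <= lower)
    fr_stop(sprintf("'%s' must be > %g", name, lower))
  if (!strict_lower && x < lower)
    fr_stop(sprintf("'%s' must be >= %g", name, lower))
  if (x > upper)
    fr_stop(sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter codes in the fixed (alphabetical) order used for every
#' amino-acid composition vector and feature matrix column block.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Kinetic type labels
#'
#' @return The two canonical kinetic labels, `"two_state"` and `"multi_state"`.
#' @export
kinetic_labels <- function() c("two_state", "multi_state")

# Normalize a user-supplied kinetic label ("Two-State", "MULTI_STATE", ...) to
# the canonical lower-case form, or error.
normalize_kinetic_label <- function(x, context = NULL) {
  key <- gsub("[^a-z]", "_", tolower(trimws(as.character(x))))
  key <- gsub("_+", "_", key)
  key <- sub("^_", "", sub("_$", "", key))
  if (key %in% c("two_state", "2_state", "twostate")) return("two_state")
  if (key %in% c("multi_state", "multistate", "three_state", "3_state"))
    return("multi_state")
  where <- if (is.null(context)) "" else paste0(" (", context, ")")
  fr_stop(sprintf("unrecognized kinetic label '%s'%s; expected two_state or multi_state",
                  x, where))
}

#' Convert natural-log rates to base-10 log
#'
#' Experimental folding rates are stored as log10(k_f / sec^-1) throughout.
#' Some literature values are quoted as ln(k_f); this converts them.
#'
#' @param x Numeric vector of natural-log rates.
#' @return `x / log(10)`.
#' @export
ln_to_log10 <- function(x) x / log(10)
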