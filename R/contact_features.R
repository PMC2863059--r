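#' Contact descriptor parameters
#'
#' Conventions for the long-range contact descriptors. Defaults follow the
#' standard probability-weighted long-range definitions: two residues are in
#' contact when their C-alpha atoms are within 8 Angstrom (closed comparison,
#' `d <= threshold`), a pair is "long-range" when at least 12 residues apart in
#' sequence, and the sums are normalized by sequence length to the power 1
#' (contact number) or 2 (contact order).
#'
#' @param distance_threshold Contact distance cut in Angstrom (> 0).
#' @param min_separation Minimum sequence separation `|i - j|` (>= 1).
#' @param c_lrcn Length-normalization exponent for the contact number.
#' @param c_lrco Length-normalization exponent for the contact order.
#' @return An object of class `"contact_params"`.
#' @export
contact_params <- function(distance_threshold = 8, min_separation = 12,
                           c_lrcn = 1, c_lrco = 2) {
  stopifnot_scalar_number(distance_threshold, "distance_threshold", 0,
                          strict_lower = TRUE)
  stopifnot_scalar_number(min_separation, "min_separation", 1)
  stopifnot_scalar_number(c_lrcn, "c_lrcn", 0)
  stopifnot_scalar_number(c_lrco, "c_lrco", 0)
  structure(list(distance_threshold = distance_threshold,
                 min_separation = as.integer(min_separation),
                 c_lrcn = c_lrcn, c_lrco = c_lrco),
            class = "contact_params")
}

check_map_dim <- function(map, L) {
  stopifnot(is_contact_map(map))
  if (nrow(map) != L)
    fr_stop(sprintf("contact map dimension %d does not match sequence length %d",
                    nrow(map), L))
  invisible(TRUE)
}

# Upper-triangle mask of pairs at sequence separation >= sep.
long_range_mask <- function(L, sep) {
  d <- abs(outer(seq_len(L), seq_len(L), "-"))
  upper.tri(d) & d >= sep
}

#' Long-range contact number (probability-weighted)
#'
#' The expected number of long-range contacts: the sum of contact probabilities
#' over unordered residue pairs at sequence separation `>= min_separation`,
#' normalized by `L^c_lrcn`. Each unordered pair contributes once.
#'
#' @param map A [contact_map].
#' @param L Sequence length; must equal the map dimension.
#' @param params A [contact_params].
#' @return Non-negative scalar.
#' @export
lrcn <- function(map, L = nrow(map), params = contact_params()) {
  check_map_dim(map, L)
  mask <- long_range_mask(L, params$min_separation)
  sum(unclass(map)[mask]) / L^params$c_lrcn
}

#' Long-range contact order (probability-weighted)
#'
#' The separation-weighted analogue of [lrcn]: the sum of
#' `P_ij * |i - j|` over unordered pairs at separation `>= min_separation`,
#' normalized by `L^c_lrco`.
#'
#' @inheritParams lrcn
#' @return Non-negative scalar.
#' @export
lrco <- function(map, L = nrow(map), params = contact_params()) {
  check_map_dim(map, L)
  sepm <- abs(outer(seq_len(L), seq_len(L), "-"))
  mask <- upper.tri(sepm) & sepm >= params$min_separation
  sum((unclass(map) * sepm)[mask]) / L^params$c_lrco
}

#' Relative contact order over all separations
#'
#' The classic relative contact order generalized to probability weights:
#' `sum(P_ij * |i - j|) / (L * sum(P_ij))` over all unordered pairs with
#' separation `>= 1` (the `min_separation` of `params` is not applied).
#' Defined as 0 for an all-zero map.
#'
#' @inheritParams lrcn
#' @return Scalar in `[0, 1)`.
#' @export
contact_order <- function(map, L = nrow(map), params = contact_params()) {
  check_map_dim(map, L)
  sepm <- abs(outer(seq_len(L), seq_len(L), "-"))
  mask <- upper.tri(sepm)
  total_p <- sum(unclass(map)[mask])
  if (total_p == 0) return(0)
  sum((unclass(map) * sepm)[mask]) / (L * total_p)
}

#' Binary contact map from C-alpha coordinates
#'
#' Builds the structure-derived ("real") contact map: `p(i, j) = 1` when the
#' Euclidean distance between the two C-alpha atoms is `<=` the distance
#' threshold, else 0. Pairs involving a missing coordinate contribute no
#' contact. Feeding the result to [lrcn] / [lrco] yields the structure-derived
#' descriptors rLRCN / rLRCO.
#'
#' @param ca_coords Numeric matrix with 3 columns; `NA` rows mark missing
#'   residues.
#' @param params A [contact_params] (only `distance_threshold` is used).
#' @return A binary [contact_map] of dimension `nrow(ca_coords)`.
#' @export
real_contact_map <- function(ca_coords, params = contact_params()) {
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3L) fr_stop("ca_coords must have 3 columns")
  ok <- stats::complete.cases(ca_coords)
  if (sum(ok) < 2L)
    fr_stop("need at least 2 non-missing C-alpha coordinates")
  n <- nrow(ca_coords)
  m <- matrix(0, n, n)
  d <- as.matrix(stats::dist(ca_coords[ok, , drop = FALSE]))
  idx <- which(ok)
  m[idx, idx] <- ifelse(d <= params$distance_threshold, 1, 0)
  diag(m) <- 0
  contact_map(m)
}

#' All contact descriptors for one record
#'
#' @param record A [protein_record] with a contact map; structure-derived
#'   descriptors are included when C-alpha coordinates are present.
#' @param params A [contact_params].
#' @return Named list with `lrcn`, `lrco`, `co` and, when a structure is
#'   available, `r_lrcn` and `r_lrco`.
#' @export
contact_descriptors <- function(record, params = contact_params()) {
  stopifnot(inherits(record, "protein_record"))
  if (is.null(record$map))
    fr_stop("record '", record$id, "' has no contact map")
  L <- nchar(record$sequence)
  out <- list(lrcn = lrcn(record$map, L, params),
              lrco = lrco(record$map, L, params),
              co = contact_order(record$map, L, params),
              r_lrcn = NA_real_, r_lrco = NA_real_)
  if (!is.null(record$ca_coords) &&
      sum(stats::complete.cases(record$ca_coords)) >= 2L) {
    rmap <- real_contact_map(record$ca_coords, params)
    out$r_lrcn <- lrcn(rmap, L, params)
    out$r_lrco <- lrco(rmap, L, params)
  }
  out
}
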