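#' Contact probability map
#'
#' A symmetric \eqn{L \times L} matrix of residue-residue contact probabilities
#' \eqn{P_{ij}}: the predicted probability that residues \eqn{i} and \eqn{j} lie
#' within the contact distance threshold (8 Angstrom by convention) in the
#' native structure. Indices are 1-based over residues; the diagonal is zero.
#'
#' @param p Either a square numeric matrix of probabilities, or a 3-column
#'   matrix/data.frame of triplets `(i, j, p)` with 1-based indices `i < j`.
#' @param n Residue count. Required when `p` is given as triplets; when `p` is a
#'   square matrix, `n` defaults to its dimension.
#' @return An object of class `"contact_map"`: a numeric matrix with symmetry
#'   enforced, zero diagonal, and all entries in `[0, 1]`.
#' @examples
#' m <- contact_map(cbind(1, 13, 0.9), n = 20)
#' m[1, 13] == m[13, 1]
#' @export
contact_map <- function(p, n = NULL) {
  if (is.data.frame(p)) p <- as.matrix(p)
  square <- is.matrix(p) && nrow(p) == ncol(p) && ncol(p) != 3L
  # a 3x3 matrix is ambiguous; resolve by whether n matches its dimension
  if (is.matrix(p) && ncol(p) == 3L && nrow(p) == 3L && (is.null(n) || n == 3L))
    square <- TRUE
  if (square && (is.null(n) || n == nrow(p))) {
    m <- p
    n <- nrow(p)
    storage.mode(m) <- "double"
    if (any(!is.finite(m))) fr_stop("contact map contains non-finite entries")
    if (any(m < 0 | m > 1))
      fr_stop("contact probabilities must lie in [0, 1]")
    if (any(abs(m - t(m)) > 1e-9))
      fr_stop("contact map matrix is not symmetric")
    m <- (m + t(m)) / 2
    diag(m) <- 0
  } else {
    if (is.null(n)) fr_stop("'n' is required when building a contact_map from triplets")
    n <- as.integer(n)
    if (n < 1L) fr_stop("contact map dimension must be >= 1")
    m <- matrix(0, n, n)
    if (length(p)) {
      trip <- matrix(as.numeric(p), ncol = 3L)
      i <- trip[, 1L]; j <- trip[, 2L]; pr <- trip[, 3L]
      if (any(i != round(i) | j != round(j)))
        fr_stop("contact pair indices must be integers")
      if (any(i < 1 | j < 1 | j > n | i > n))
        fr_stop(sprintf("contact pair index outside 1..%d", n))
      if (any(i >= j))
        fr_stop("contact pairs must satisfy i < j")
      if (any(pr < 0 | pr > 1))
        fr_stop("contact probabilities must lie in [0, 1]")
      key <- paste(i, j)
      if (anyDuplicated(key)) {
        dup <- key[duplicated(key)]
        agree <- vapply(unique(dup), function(k) {
          length(unique(pr[key == k])) == 1L
        }, logical(1))
        if (!all(agree))
          fr_stop("duplicate contact pair with conflicting probabilities: ",
                  unique(dup)[!agree][1])
      }
      m[cbind(i, j)] <- pr
      m[cbind(j, i)] <- pr
    }
  }
  structure(m, class = c("contact_map", "matrix", "array"))
}

#' @export
print.contact_map <- function(x, ...) {
  nz <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("contact_map: %d residues, %d non-zero pairs, max p = %.3f\n",
              nrow(x), nz, if (nz) max(x) else 0))
  invisible(x)
}

#' @rdname contact_map
#' @param x An object to test.
#' @export
is_contact_map <- function(x) inherits(x, "contact_map")

#' Threshold a probability map to a binary contact map
#'
#' Classic binary-contact methods first cut the probability map at a threshold
#' and then count contacts; this provides that baseline. An entry becomes 1 when
#' `p >= threshold` (closed at the boundary), else 0.
#'
#' @param map A [contact_map].
#' @param threshold Probability cut in `[0, 1]`.
#' @return A `contact_map` with entries in `{0, 1}`.
#' @export
binarize_map <- function(map, threshold) {
  stopifnot(is_contact_map(map))
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  m <- ifelse(unclass(map) >= threshold, 1, 0)
  diag(m) <- 0
  contact_map(m)
}
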