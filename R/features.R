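#' Feature configuration
#'
#' Controls which descriptors enter each model's feature vector.
#'
#' Under the defaults the three model roles use:
#' \describe{
#'   \item{`classifier`}{length, LRCO, LRCN, helix content, sheet content,
#'     and the 20 amino-acid frequencies (25 features).}
#'   \item{`two_state`}{LRCO, LRCN, helix content, sheet content (4 features);
#'     amino-acid composition is deliberately excluded from the regressors to
#'     avoid over-fitting, and coil content is excluded from every role.}
#'   \item{`multi_state`}{length plus the two-state set (5 features), or, with
#'     `multistate_features = "length_contacts_only"`, length, LRCO and LRCN
#'     only — the SS-content fractions are dropped, reflecting their weak
#'     correlation with multi-state rates.}
#' }
#'
#' @param multistate_features Which reading of the multi-state predictor set to
#'   use: `"with_ss"` (default) or `"length_contacts_only"`.
#' @param use_gc Append the precomputed geometric-contact scalar as an extra
#'   feature column to every role.
#' @param params A [contact_params] used when descriptors are computed.
#' @return An object of class `"feature_config"`.
#' @export
feature_config <- function(multistate_features = c("with_ss",
                                                   "length_contacts_only"),
                           use_gc = FALSE, params = contact_params()) {
  multistate_features <- match.arg(multistate_features)
  stopifnot(inherits(params, "contact_params"), is.logical(use_gc))
  structure(list(multistate_features = multistate_features,
                 use_gc = isTRUE(use_gc), params = params),
            class = "feature_config")
}

model_roles <- function() c("classifier", "two_state", "multi_state")

#' Feature names for a model role
#'
#' @param role One of `"classifier"`, `"two_state"`, `"multi_state"`.
#' @param config A [feature_config].
#' @return Character vector of feature names in assembly order.
#' @export
feature_names <- function(role = model_roles(), config = feature_config()) {
  role <- match.arg(role)
  # composition columns are prefixed so leucine cannot collide with length "L"
  base <- switch(role,
    classifier = c("L", "LRCO", "LRCN", "helix", "sheet",
                   paste0("aa_", aa_alphabet())),
    two_state = c("LRCO", "LRCN", "helix", "sheet"),
    multi_state = if (config$multistate_features == "with_ss")
      c("L", "LRCO", "LRCN", "helix", "sheet")
    else
      c("L", "LRCO", "LRCN")
  )
  if (config$use_gc) base <- c(base, "GC")
  base
}

#' Assemble the feature vector for one record and model role
#'
#' @param record A [protein_record] carrying the inputs the role requires (a
#'   contact map always; an SS string for roles that use SS content; a
#'   `gc_value` when the GC extension is enabled).
#' @param role One of `"classifier"`, `"two_state"`, `"multi_state"`.
#' @param config A [feature_config].
#' @return Named numeric vector ordered as [feature_names()].
#' @export
assemble <- function(record, role = model_roles(), config = feature_config()) {
  role <- match.arg(role)
  stopifnot(inherits(record, "protein_record"))
  nm <- feature_names(role, config)
  if (is.null(record$map))
    fr_stop("record '", record$id, "': contact map required for feature 'LRCO'")
  L <- nchar(record$sequence)
  vals <- c(L = as.numeric(L),
            LRCO = lrco(record$map, L, config$params),
            LRCN = lrcn(record$map, L, config$params))
  if (any(c("helix", "sheet") %in% nm)) {
    if (is.null(record$ss_string))
      fr_stop("record '", record$id,
              "': secondary-structure string required for features helix/sheet")
    ss <- ss_composition(record$ss_string)
    vals <- c(vals, helix = unname(ss["helix"]), sheet = unname(ss["sheet"]))
  }
  if (any(startsWith(nm, "aa_"))) {
    comp <- aa_composition(record$sequence, strict = FALSE)
    names(comp) <- paste0("aa_", names(comp))
    vals <- c(vals, comp)
  }
  if ("GC" %in% nm) {
    if (is.null(record$gc_value))
      fr_stop("record '", record$id,
              "': gc_value required when the GC feature is enabled")
    vals <- c(vals, GC = record$gc_value)
  }
  vals[nm]
}

#' Assemble a feature matrix for a list of records
#'
#' @param records List of [protein_record]s.
#' @param role,config As in [assemble].
#' @return Numeric matrix, one row per record (rownames are record ids),
#'   columns ordered as [feature_names()].
#' @export
assemble_matrix <- function(records, role = model_roles(),
                            config = feature_config()) {
  role <- match.arg(role)
  rows <- lapply(records, assemble, role = role, config = config)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(records, `[[`, character(1), "id")
  m
}

#' Fit per-feature scaling parameters
#'
#' Learned from the supplied (training) rows only; apply to held-out rows with
#' [apply_scaling]. Constant columns map to 0 without division errors.
#'
#' @param x Numeric feature matrix (training rows only).
#' @param method `"minmax"` (to `[0, 1]`; default), `"zscore"`, or `"none"`.
#' @return An object of class `"feature_scaling"`.
#' @export
fit_scaling <- function(x, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) fr_stop("empty feature matrix")
  if (method == "minmax") {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    span <- hi - lo
    span[span == 0] <- 1   # constant column guard -> scales to 0
    par <- list(center = lo, scale = span)
  } else if (method == "zscore") {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    par <- list(center = mu, scale = sd)
  } else {
    par <- list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  }
  structure(c(par, list(method = method, names = colnames(x))),
            class = "feature_scaling")
}

#' Apply fitted scaling to a feature matrix or vector
#'
#' @param scaling A `"feature_scaling"` from [fit_scaling].
#' @param x Numeric matrix (or single vector) with the same columns.
#' @return Scaled matrix.
#' @export
apply_scaling <- function(scaling, x) {
  stopifnot(inherits(scaling, "feature_scaling"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (ncol(x) != length(scaling$center))
    fr_stop(sprintf("feature count %d does not match scaling (%d features)",
                    ncol(x), length(scaling$center)))
  sweep(sweep(x, 2, scaling$center, "-"), 2, scaling$scale, "/")
}
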