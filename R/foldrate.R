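#' Fit the two-stage folding kinetics model
#'
#' Trains the full sequence-based predictor on a set of annotated protein
#' records: an RBF-kernel support vector classifier that assigns the folding
#' kinetic type (two-state vs multi-state) from length, probability-weighted
#' long-range contact order (LRCO) and contact number (LRCN), helix and sheet
#' content and the 20 amino-acid frequencies; and two kinetic-type-specific
#' epsilon-SVR models that predict the folding rate (log10 of k_f in 1/sec)
#' from the contact and secondary-structure descriptors.
#'
#' With `tune = TRUE` the classifier hyperparameters are selected by a
#' LOOCV-scored grid search and each regressor by the two-phase heuristic of
#' [tune_regressor]; the search surfaces are kept in `$tuning` for [plot()].
#'
#' @param records List of [protein_record]s with `kinetic_label` and
#'   `log_rate` set, each carrying a contact map and SS string.
#' @param hp_classifier,hp_two_state,hp_multi_state [hyper_params] per model.
#'   The defaults (`C = 1, gamma = 0.25` for the classifier;
#'   `C = 8, gamma = 0.125, epsilon = 0.1` for both regressors) are sensible
#'   RBF operating points for min-max-scaled features; tuning is recommended
#'   for new datasets.
#' @param config A [feature_config].
#' @param scaling Feature scaling method (see [fit_scaling]).
#' @param tune Run hyperparameter search instead of using the supplied values.
#' @param grids Grids for tuning (see [default_grids()]).
#' @return An object of class `"foldrate"` with `predict`, `print`, `summary`,
#'   `fitted`, `residuals` and `plot` methods.
#' @examples
#' recs <- synth_records(synth_config(n_proteins = 20, seed = 3))
#' fit <- foldrate(recs)
#' predict(fit, recs[[1]])
#' @export
foldrate <- function(records,
                     hp_classifier = hyper_params(C = 1, gamma = 0.25),
                     hp_two_state = hyper_params(C = 8, gamma = 0.125,
                                                 epsilon = 0.1),
                     hp_multi_state = hyper_params(C = 8, gamma = 0.125,
                                                   epsilon = 0.1),
                     config = feature_config(), scaling = "minmax",
                     tune = FALSE, grids = default_grids()) {
  lab <- check_records_annotated(records)
  if (min(table(factor(lab, levels = kinetic_labels()))) < 3L)
    fr_stop("need at least 3 records of each kinetic class")
  tuning <- NULL
  if (isTRUE(tune)) {
    gs <- grid_search_classifier(records, grids$C, grids$gamma,
                                 config = config, scaling = scaling)
    t2 <- tune_regressor(records, "two_state", grids$C, grids$gamma,
                         grids$epsilon, config = config, scaling = scaling)
    t3 <- tune_regressor(records, "multi_state", grids$C, grids$gamma,
                         grids$epsilon, config = config, scaling = scaling)
    hp_classifier <- gs$best
    hp_two_state <- t2$best
    hp_multi_state <- t3$best
    tuning <- list(classifier = gs, two_state = t2, multi_state = t3)
  }
  xc <- assemble_matrix(records, "classifier", config)
  sc_c <- fit_scaling(xc, method = scaling)
  classifier <- ksvm(apply_scaling(sc_c, xc), lab, "C-svc", hp_classifier)

  train_reg <- function(cls, hp) {
    sub <- records[lab == cls]
    x <- assemble_matrix(sub, cls, config)
    sc <- fit_scaling(x, method = scaling)
    list(model = ksvm(apply_scaling(sc, x), record_rates(sub), "eps-svr", hp),
         scaling = sc, x = x)
  }
  r2 <- train_reg("two_state", hp_two_state)
  r3 <- train_reg("multi_state", hp_multi_state)

  structure(list(classifier = classifier, scaling_classifier = sc_c,
                 reg_two_state = r2$model, scaling_two_state = r2$scaling,
                 reg_multi_state = r3$model, scaling_multi_state = r3$scaling,
                 train_features = list(two_state = r2$x, multi_state = r3$x),
                 config = config, scaling_method = scaling,
                 hp = list(classifier = hp_classifier,
                           two_state = hp_two_state,
                           multi_state = hp_multi_state),
                 tuning = tuning,
                 train_ids = record_ids(records),
                 train_labels = lab, train_rates = record_rates(records),
                 n = length(records), call = match.call()),
            class = "foldrate")
}

#' Predict kinetic type and folding rate for new proteins
#'
#' Step one classifies the record as a two-state or multi-state folder; step
#' two routes it to the matching kinetic-type-specific regressor for the rate.
#' Supplying `force_label` bypasses the classifier (the "what if this protein
#' were the other kinetic type" analysis).
#'
#' @param object A fitted [foldrate] model.
#' @param newdata A [protein_record] or list of them (contact map and SS
#'   string required).
#' @param force_label `NULL` (use the classifier) or a kinetic label to force.
#' @param ... Unused.
#' @return data.frame with columns `id`, `kinetic_label`, `log_rate`,
#'   `decision` (classifier decision value; `NA` when the label was forced).
#' @export
predict.foldrate <- function(object, newdata, force_label = NULL, ...) {
  if (inherits(newdata, "protein_record")) newdata <- list(newdata)
  if (!is.null(force_label))
    force_label <- normalize_kinetic_label(force_label)
  out <- lapply(newdata, function(rec) {
    stopifnot(inherits(rec, "protein_record"))
    if (is.null(force_label)) {
      xc <- assemble(rec, "classifier", object$config)
      dv <- predict(object$classifier,
                    apply_scaling(object$scaling_classifier, xc),
                    decision = TRUE)
      label <- decode_labels(dv)
    } else {
      dv <- NA_real_
      label <- force_label
    }
    reg <- object[[paste0("reg_", label)]]
    sc <- object[[paste0("scaling_", label)]]
    x <- assemble(rec, label, object$config)
    rate <- predict(reg, apply_scaling(sc, x))
    data.frame(id = rec$id, kinetic_label = label, log_rate = rate,
               decision = as.numeric(dv), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.foldrate <- function(x, ...) {
  cat("Two-stage folding kinetics model\n")
  cat(sprintf("  trained on %d proteins (%d two-state, %d multi-state)\n",
              x$n, sum(x$train_labels == "two_state"),
              sum(x$train_labels == "multi_state")))
  cat(sprintf("  classifier : kernel=%s C=%g gamma=%g (%d SVs)\n",
              x$hp$classifier$kernel, x$hp$classifier$C, x$hp$classifier$gamma,
              nrow(x$classifier$sv)))
  cat(sprintf("  two-state  : C=%g gamma=%g epsilon=%g (%d SVs, %d features)\n",
              x$hp$two_state$C, x$hp$two_state$gamma, x$hp$two_state$epsilon,
              nrow(x$reg_two_state$sv), ncol(x$reg_two_state$sv)))
  cat(sprintf("  multi-state: C=%g gamma=%g epsilon=%g (%d SVs, %d features)\n",
              x$hp$multi_state$C, x$hp$multi_state$gamma,
              x$hp$multi_state$epsilon,
              nrow(x$reg_multi_state$sv), ncol(x$reg_multi_state$sv)))
  invisible(x)
}

#' @export
summary.foldrate <- function(object, ...) {
  # in-sample fit of each regressor on its own class (training diagnostics,
  # not a validation estimate -- use loocv_pipeline for that)
  res <- stats::residuals(object)
  out <- list(model = object,
              in_sample_mad = tapply(abs(res), object$train_labels, mean))
  class(out) <- "summary.foldrate"
  out
}

#' @export
print.summary.foldrate <- function(x, ...) {
  print(x$model)
  cat("in-sample MAD by class (training diagnostic):\n")
  print(round(x$in_sample_mad, 3))
  cat("note: use loocv_pipeline() for an honest generalization estimate\n")
  invisible(x)
}

#' @export
fitted.foldrate <- function(object, ...) {
  # in-sample rate from the regressor of the *true* training label
  out <- numeric(object$n)
  for (cls in kinetic_labels()) {
    idx <- which(object$train_labels == cls)
    reg <- object[[paste0("reg_", cls)]]
    sc <- object[[paste0("scaling_", cls)]]
    out[idx] <- predict(reg, apply_scaling(sc, object$train_features[[cls]]))
  }
  names(out) <- object$train_ids
  out
}

#' @export
residuals.foldrate <- function(object, ...) {
  object$train_rates - fitted(object)
}

#' Plot a fitted folding kinetics model
#'
#' With stored tuning surfaces, draws the classifier LOOCV accuracy surface
#' over `(log2 C, log2 gamma)`; otherwise plots the training-rate distribution
#' by kinetic class.
#'
#' @param x A [foldrate] fit.
#' @param which `"surface"` or `"rates"`.
#' @param ... Passed on to the underlying plot.
#' @export
plot.foldrate <- function(x, which = c("surface", "rates"), ...) {
  which <- match.arg(which)
  if (which == "surface" && !is.null(x$tuning)) {
    plot(x$tuning$classifier, ...)
    return(invisible(x))
  }
  graphics::boxplot(split(x$train_rates, x$train_labels),
                    ylab = "log10 folding rate (1/sec)", ...)
  invisible(x)
}
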