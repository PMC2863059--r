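#' Pearson correlation between predicted and experimental rates
#'
#' Standard sample Pearson correlation, with explicit errors for the degenerate
#' inputs (constant vectors) for which the coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) fr_stop("vectors have different lengths")
  if (length(x) < 3L) fr_stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    fr_stop("correlation undefined: constant vector")
  stats::cor(x, y)
}

#' Mean absolute difference
#'
#' Mean of `|true - pred|`; the deviation measure reported alongside the
#' correlation for rate predictions (log10 units).
#'
#' @param true,pred Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
mad_error <- function(true, pred) {
  if (length(true) != length(pred)) fr_stop("vectors have different lengths")
  if (length(true) < 1L) fr_stop("need at least 1 observation")
  mean(abs(true - pred))
}

# Leave-one-out CV over a raw feature matrix. Scaling is re-fit inside every
# fold on the n-1 training rows only, so the held-out row never leaks into
# the scaling parameters or the model.
loocv_matrix <- function(x, y, type, hp, scaling = "minmax", tol = 1e-3) {
  x <- as.matrix(x)
  n <- nrow(x)
  pred <- if (type == "C-svc") character(n) else numeric(n)
  for (i in seq_len(n)) {
    sc <- fit_scaling(x[-i, , drop = FALSE], method = scaling)
    fit <- ksvm(apply_scaling(sc, x[-i, , drop = FALSE]), y[-i],
                type = type, hp = hp, tol = tol)
    pred[i] <- predict(fit, apply_scaling(sc, x[i, , drop = FALSE]))
  }
  pred
}

new_eval_report <- function(predictions, protocol, n_repeats = 1L,
                            seed = NA_integer_, per_repeat = NULL) {
  is_cls <- "pred_label" %in% names(predictions)
  rep <- list(predictions = predictions, protocol = protocol,
              n_repeats = n_repeats, seed = seed, per_repeat = per_repeat)
  if (is_cls) {
    rep$accuracy <- mean(predictions$pred_label == predictions$true_label)
  }
  if ("pred" %in% names(predictions)) {
    rep$pearson_r <- pearson_r(predictions$true, predictions$pred)
    rep$mad <- mad_error(predictions$true, predictions$pred)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s, %d prediction(s)]\n", x$protocol,
              nrow(x$predictions)))
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy   %.3f\n", x$accuracy))
  if (!is.null(x$pearson_r))
    cat(sprintf("  pearson r  %.3f\n  MAD        %.3f\n", x$pearson_r, x$mad))
  invisible(x)
}

check_records_annotated <- function(records, need_rate = TRUE) {
  lab <- vapply(records, function(r) {
    if (is.null(r$kinetic_label)) NA_character_ else r$kinetic_label
  }, character(1))
  if (anyNA(lab)) fr_stop("every record needs a kinetic_label")
  if (need_rate) {
    rate <- vapply(records, function(r) {
      if (is.null(r$log_rate)) NA_real_ else r$log_rate
    }, numeric(1))
    if (anyNA(rate)) fr_stop("every record needs a log_rate")
  }
  invisible(unname(lab))
}

record_ids <- function(records)
  unname(vapply(records, `[[`, character(1), "id"))
record_rates <- function(records)
  unname(vapply(records, `[[`, numeric(1), "log_rate"))
record_labels <- function(records)
  unname(vapply(records, `[[`, character(1), "kinetic_label"))

#' Strict leave-one-out cross-validation for one model role
#'
#' For each protein, feature scaling and the model are fitted on the other
#' n - 1 proteins and the held-out protein is predicted. For the regression
#' roles, only records of the matching kinetic class are used.
#'
#' @param records List of annotated [protein_record]s (labels for the
#'   classifier role, labels and rates for the regression roles).
#' @param role `"classifier"`, `"two_state"` or `"multi_state"`.
#' @param hp A [hyper_params].
#' @param config A [feature_config].
#' @param scaling Scaling method (see [fit_scaling]).
#' @return An `"eval_report"` with per-protein predictions and, per role,
#'   accuracy or Pearson r and MAD.
#' @export
loocv_eval <- function(records, role = model_roles(), hp = hyper_params(),
                       config = feature_config(), scaling = "minmax") {
  role <- match.arg(role)
  if (role == "classifier") {
    lab <- check_records_annotated(records, need_rate = FALSE)
    if (min(table(lab)) < 2L)
      fr_stop("classification LOOCV needs at least 2 records per class")
    x <- assemble_matrix(records, "classifier", config)
    pred <- loocv_matrix(x, lab, "C-svc", hp, scaling)
    return(new_eval_report(
      data.frame(id = record_ids(records), true_label = lab,
                 pred_label = pred, stringsAsFactors = FALSE),
      protocol = "LOOCV"))
  }
  check_records_annotated(records)
  records <- records[record_labels(records) == role]
  if (length(records) < 3L)
    fr_stop("regression LOOCV needs at least 3 records of class ", role)
  x <- assemble_matrix(records, role, config)
  z <- record_rates(records)
  pred <- loocv_matrix(x, z, "eps-svr", hp, scaling)
  new_eval_report(
    data.frame(id = record_ids(records), true = z, pred = pred,
               stringsAsFactors = FALSE),
    protocol = "LOOCV")
}

#' Strict LOOCV of the full two-stage pipeline
#'
#' Each protein is held out; the classifier and both class-specific regressors
#' are trained on the remaining proteins; the held-out protein is classified
#' and its rate predicted by the regressor matching the *predicted* class.
#'
#' @inheritParams loocv_eval
#' @param hp_classifier,hp_two_state,hp_multi_state Hyperparameters per model.
#' @return An `"eval_report"` whose predictions carry both the label and rate
#'   columns; `accuracy` is the classification accuracy, `pearson_r`/`mad`
#'   pool both classes (compute within-class metrics from `$predictions`).
#' @export
loocv_pipeline <- function(records, hp_classifier = hyper_params(),
                           hp_two_state = hyper_params(C = 8, gamma = 0.125),
                           hp_multi_state = hyper_params(C = 8, gamma = 0.125),
                           config = feature_config(), scaling = "minmax") {
  check_records_annotated(records)
  n <- length(records)
  if (n < 8L) fr_stop("pipeline LOOCV needs a reasonable dataset (n >= 8)")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- foldrate(records[-i], hp_classifier = hp_classifier,
                    hp_two_state = hp_two_state,
                    hp_multi_state = hp_multi_state,
                    config = config, scaling = scaling)
    out[[i]] <- predict(fit, records[[i]])
  }
  pred <- do.call(rbind, out)
  res <- data.frame(id = record_ids(records),
                    true_label = record_labels(records),
                    pred_label = pred$kinetic_label,
                    true = record_rates(records),
                    pred = pred$log_rate,
                    stringsAsFactors = FALSE)
  new_eval_report(res, protocol = "LOOCV")
}

#' Repeated random 90/10 split evaluation
#'
#' Repeats `n_repeats` times: hold out a random `test_fraction` of the records
#' (size `max(2, floor(n * test_fraction))`), fit on the rest, predict the test
#' set; reports per-repeat and pooled Pearson r and MAD (regression roles) or
#' accuracy (classifier role). Splits are drawn from `seed` and the whole
#' procedure is bit-reproducible.
#'
#' @inheritParams loocv_eval
#' @param n_repeats Number of random splits (default 5).
#' @param test_fraction Held-out fraction (default 0.10).
#' @param seed Integer seed for the split sampling.
#' @param stratify Draw the test set separately within each kinetic class.
#' @return An `"eval_report"`; `$per_repeat` holds the per-split metrics and
#'   the headline `pearson_r`/`mad`/`accuracy` are averages over repeats.
#' @export
repeated_split_eval <- function(records, role = model_roles(),
                                hp = hyper_params(), n_repeats = 5,
                                test_fraction = 0.10, seed = 1,
                                stratify = FALSE, config = feature_config(),
                                scaling = "minmax") {
  role <- match.arg(role)
  if (role == "classifier") {
    lab_all <- check_records_annotated(records, need_rate = FALSE)
  } else {
    check_records_annotated(records)
    records <- records[record_labels(records) == role]
    lab_all <- record_labels(records)
  }
  n <- length(records)
  n_test <- max(2L, floor(n * test_fraction))
  if (n - n_test < 3L) fr_stop("dataset too small for a ",
                               test_fraction * 100, "% split")
  x <- assemble_matrix(records, role, config)
  yv <- if (role == "classifier") lab_all else record_rates(records)
  type <- if (role == "classifier") "C-svc" else "eps-svr"
  set.seed(as.integer(seed))
  per <- vector("list", n_repeats)
  preds <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    test <- if (stratify) {
      unlist(lapply(split(seq_len(n), lab_all), function(ix) {
        k <- max(1L, floor(length(ix) * test_fraction))
        sample(ix, k)
      }), use.names = FALSE)
    } else sample(seq_len(n), n_test)
    train <- setdiff(seq_len(n), test)
    sc <- fit_scaling(x[train, , drop = FALSE], method = scaling)
    fit <- ksvm(apply_scaling(sc, x[train, , drop = FALSE]), yv[train],
                type = type, hp = hp)
    p <- predict(fit, apply_scaling(sc, x[test, , drop = FALSE]))
    if (role == "classifier") {
      per[[r]] <- data.frame(repeat_ = r, accuracy = mean(p == yv[test]))
      preds[[r]] <- data.frame(id = record_ids(records)[test], repeat_ = r,
                               true_label = yv[test], pred_label = p,
                               stringsAsFactors = FALSE)
    } else {
      per[[r]] <- data.frame(repeat_ = r,
                             pearson_r = tryCatch(pearson_r(yv[test], p),
                                                  error = function(e) NA_real_),
                             mad = mad_error(yv[test], p))
      preds[[r]] <- data.frame(id = record_ids(records)[test], repeat_ = r,
                               true = yv[test], pred = p,
                               stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  rep <- structure(list(predictions = do.call(rbind, preds),
                        protocol = "SPLIT_90_10", n_repeats = n_repeats,
                        seed = seed, per_repeat = per),
                   class = "eval_report")
  if (role == "classifier") {
    rep$accuracy <- mean(per$accuracy)
  } else {
    rep$pearson_r <- mean(per$pearson_r, na.rm = TRUE)
    rep$mad <- mean(per$mad)
  }
  rep
}

screen_feature_value <- function(record, feature, config) {
  L <- nchar(record$sequence)
  switch(feature,
    L = as.numeric(L),
    LRCO = lrco(record$map, L, config$params),
    LRCN = lrcn(record$map, L, config$params),
    CO = contact_order(record$map, L, config$params),
    helix = unname(ss_composition(record$ss_string)["helix"]),
    sheet = unname(ss_composition(record$ss_string)["sheet"]),
    coil = unname(ss_composition(record$ss_string)["coil"]),
    fr_stop("unknown screening feature '", feature, "'")
  )
}

#' Single-feature effectiveness screen
#'
#' For each feature and each kinetic class separately, a one-feature SVM
#' regressor is evaluated under strict LOOCV and the signed Pearson correlation
#' between predicted and experimental rates is reported (one row per
#' feature-class pair). A feature that is constant within a class yields `NA`
#' with the reason recorded, not an error.
#'
#' @inheritParams loocv_eval
#' @param features Feature names to screen (any of `"L"`, `"LRCO"`, `"CO"`,
#'   `"LRCN"`, `"helix"`, `"sheet"`, `"coil"`).
#' @return data.frame with columns `feature`, `kinetic_class`, `pearson_r`
#'   (predicted vs experimental rates, the performance of the one-feature
#'   model), `direction_r` (raw feature-vs-rate correlation, giving the sign
#'   of the relationship, e.g. negative for length), `mad`, `note`.
#' @export
single_feature_screen <- function(records,
                                  features = c("L", "LRCO", "CO", "LRCN",
                                               "helix", "sheet", "coil"),
                                  hp = hyper_params(C = 8, gamma = 0.125),
                                  config = feature_config(),
                                  scaling = "minmax") {
  check_records_annotated(records)
  lab <- record_labels(records)
  rows <- list()
  for (cls in kinetic_labels()) {
    sub <- records[lab == cls]
    if (length(sub) < 3L)
      fr_stop("screening needs at least 3 records per class (", cls, ")")
    z <- record_rates(sub)
    for (f in features) {
      x <- matrix(vapply(sub, screen_feature_value, numeric(1),
                         feature = f, config = config), ncol = 1,
                  dimnames = list(NULL, f))
      row <- data.frame(feature = f, kinetic_class = cls,
                        pearson_r = NA_real_, direction_r = NA_real_,
                        mad = NA_real_, note = "", stringsAsFactors = FALSE)
      if (stats::sd(x[, 1]) == 0) {
        # a constant feature cannot carry a defined correlation; surface the
        # condition per feature rather than fitting noise
        row$note <- "undefined correlation: feature constant across proteins"
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- tryCatch({
        pred <- loocv_matrix(x, z, "eps-svr", hp, scaling)
        row$pearson_r <- pearson_r(z, pred)
        row$direction_r <- pearson_r(x[, 1], z)
        row$mad <- mad_error(z, pred)
        row
      }, error = function(e) {
        row$note <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Multi-predictor linear regression baseline
#'
#' Ordinary least squares of the log10 folding rate on a chosen predictor
#' subset, with the overall ANOVA statistics: correlation between fitted and
#' observed rates, residual RMSE, F statistic and its p-value.
#'
#' @inheritParams loocv_eval
#' @param predictors Predictor names (any screening feature name of
#'   [single_feature_screen], e.g. `c("LRCO", "LRCN", "helix", "sheet")`).
#' @param class Restrict to one kinetic class (`"two_state"`/`"multi_state"`)
#'   or `NULL` for all records.
#' @return An object of class `"linear_baseline"`: coefficients, `r`, `rmse`,
#'   `f_value`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
linear_baseline <- function(records, predictors = c("LRCO", "LRCN",
                                                    "helix", "sheet"),
                            class = NULL, config = feature_config()) {
  check_records_annotated(records)
  if (!is.null(class))
    records <- records[record_labels(records) == normalize_kinetic_label(class)]
  n <- length(records)
  if (n <= length(predictors) + 1L)
    fr_stop("need more records than predictors + 1")
  x <- vapply(records, function(r) {
    vapply(predictors, screen_feature_value, numeric(1), record = r,
           config = config)
  }, numeric(length(predictors)))
  x <- if (length(predictors) == 1L) matrix(x, ncol = 1) else t(x)
  colnames(x) <- predictors
  df <- data.frame(log_rate = record_rates(records), x, check.names = FALSE)
  if (qr(cbind(1, x))$rank < ncol(x) + 1L)
    fr_stop("rank-deficient design: predictors are collinear (",
            paste(predictors, collapse = ", "), ")")
  fit <- stats::lm(log_rate ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = stats::coef(fit),
    r = pearson_r(df$log_rate, stats::fitted(fit)),
    rmse = sm$sigma,
    f_value = unname(fstat["value"]),
    p_value = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                               lower.tail = FALSE)),
    n = n, predictors = predictors, fit = fit
  ), class = "linear_baseline")
}

#' @export
print.linear_baseline <- function(x, ...) {
  cat(sprintf("linear baseline on %s (n = %d)\n",
              paste(x$predictors, collapse = " + "), x$n))
  cat(sprintf("  r = %.3f, RMSE = %.3f, F = %.2f, p = %.2g\n",
              x$r, x$rmse, x$f_value, x$p_value))
  invisible(x)
}
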