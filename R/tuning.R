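#' Default hyperparameter grids
#'
#' Powers-of-two grids spanning the usual operating range for RBF SVMs on
#' features scaled to `[0, 1]`; the epsilon sweep brackets the common default
#' tube width 0.1.
#'
#' @return Named list of numeric vectors.
#' @export
default_grids <- function() {
  list(C = 2^(-5:5), gamma = 2^(-7:3),
       epsilon = c(0.01, 0.05, 0.1, 0.2, 0.5))
}

# Deterministic tie-breaking: highest score, then smaller C, gamma, epsilon.
pick_best <- function(grid) {
  score <- grid$score
  score[is.na(score)] <- -Inf
  ord <- order(-score, grid$C, grid$gamma,
               if (!is.null(grid$epsilon)) grid$epsilon else rep(0, nrow(grid)))
  grid[ord[1], , drop = FALSE]
}

#' Grid search for the kinetic-type classifier
#'
#' Scores every `(C, gamma)` pair by full leave-one-out cross-validated
#' accuracy and keeps the whole surface (the accuracy-vs-`(C, gamma)` profile)
#' for inspection and plotting. Ties are broken toward smaller `C`, then
#' smaller `gamma`.
#'
#' @param records Annotated [protein_record]s (kinetic labels required).
#' @param C_grid,gamma_grid Numeric grids (defaults: [default_grids()]).
#' @param kernel Kernel name (see [hyper_params]).
#' @param config A [feature_config].
#' @param scaling Scaling method.
#' @return Object of class `"grid_search"`: `$grid` (C, gamma, score),
#'   `$best` ([hyper_params]), `$score_name = "accuracy"`.
#' @export
grid_search_classifier <- function(records, C_grid = default_grids()$C,
                                   gamma_grid = default_grids()$gamma,
                                   kernel = "rbf", config = feature_config(),
                                   scaling = "minmax") {
  if (!length(C_grid) || !length(gamma_grid)) fr_stop("empty grid")
  lab <- check_records_annotated(records, need_rate = FALSE)
  if (length(unique(lab)) < 2L)
    fr_stop("grid search needs both kinetic classes present")
  x <- assemble_matrix(records, "classifier", config)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$score <- vapply(seq_len(nrow(grid)), function(k) {
    hp <- hyper_params(C = grid$C[k], gamma = grid$gamma[k], kernel = kernel)
    mean(loocv_matrix(x, lab, "C-svc", hp, scaling) == lab)
  }, numeric(1))
  best <- pick_best(grid)
  structure(list(grid = grid,
                 best = hyper_params(C = best$C, gamma = best$gamma,
                                     kernel = kernel),
                 score_name = "accuracy", kernel = kernel),
            class = "grid_search")
}

#' Two-phase heuristic tuning for a rate regressor
#'
#' Phase 1 grids over `(C, gamma)` with the tube width held at
#' `epsilon_fixed = 0.1` (the common SVR default), scoring each point by
#' leave-one-out cross-validated Pearson correlation. Phase 2 sweeps `epsilon`
#' at the phase-1 optimum. Because the sweep includes the incumbent 0.1, the
#' final score can never fall below the phase-1 score.
#'
#' @param records Annotated [protein_record]s of one kinetic class, or a mixed
#'   list plus `class` to subset.
#' @param class Kinetic class to tune for (`"two_state"`/`"multi_state"`).
#' @param C_grid,gamma_grid,epsilon_grid Numeric grids.
#' @param epsilon_fixed Tube width held fixed during phase 1.
#' @param kernel,config,scaling As in [grid_search_classifier].
#' @return Object of class `"grid_search"` with `$grid` (both phases,
#'   `phase` column), `$best` (combined `(C, gamma, epsilon)`),
#'   `$score_name = "pearson_r"`, and `$phase1_score` / `$final_score`.
#' @export
tune_regressor <- function(records, class = "two_state",
                           C_grid = default_grids()$C,
                           gamma_grid = default_grids()$gamma,
                           epsilon_grid = default_grids()$epsilon,
                           epsilon_fixed = 0.1, kernel = "rbf",
                           config = feature_config(), scaling = "minmax") {
  if (!length(C_grid) || !length(gamma_grid) || !length(epsilon_grid))
    fr_stop("empty grid")
  class <- normalize_kinetic_label(class)
  check_records_annotated(records)
  records <- records[record_labels(records) == class]
  if (length(records) < 3L) fr_stop("need at least 3 records of class ", class)
  x <- assemble_matrix(records, class, config)
  z <- record_rates(records)
  if (stats::sd(z) == 0) fr_stop("degenerate targets: rates are constant")
  score_point <- function(C, gamma, epsilon) {
    hp <- hyper_params(C = C, gamma = gamma, epsilon = epsilon,
                       kernel = kernel)
    pred <- loocv_matrix(x, z, "eps-svr", hp, scaling)
    tryCatch(pearson_r(z, pred), error = function(e) NA_real_)
  }
  g1 <- expand.grid(C = C_grid, gamma = gamma_grid, KEEP.OUT.ATTRS = FALSE)
  g1$epsilon <- epsilon_fixed
  g1$score <- vapply(seq_len(nrow(g1)), function(k) {
    score_point(g1$C[k], g1$gamma[k], epsilon_fixed)
  }, numeric(1))
  b1 <- pick_best(g1)
  g2 <- data.frame(C = b1$C, gamma = b1$gamma, epsilon = epsilon_grid)
  g2$score <- vapply(seq_len(nrow(g2)), function(k) {
    if (g2$epsilon[k] == epsilon_fixed) return(b1$score)  # already scored
    score_point(g2$C[k], g2$gamma[k], g2$epsilon[k])
  }, numeric(1))
  b2 <- pick_best(g2)
  g1$phase <- 1L; g2$phase <- 2L
  structure(list(grid = rbind(g1, g2),
                 best = hyper_params(C = b2$C, gamma = b2$gamma,
                                     epsilon = b2$epsilon, kernel = kernel),
                 score_name = "pearson_r", kernel = kernel,
                 phase1_score = b1$score, final_score = b2$score),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("grid_search over %d point(s), score = %s\n",
              nrow(x$grid), x$score_name))
  cat("best: "); print(x$best)
  best_score <- if (!is.null(x$final_score)) x$final_score else
    max(x$grid$score, na.rm = TRUE)
  cat(sprintf("best %s = %.4f\n", x$score_name, best_score))
  invisible(x)
}

#' Plot a grid-search accuracy/correlation surface
#'
#' Filled-contour view of the score over `log2(C)` and `log2(gamma)` (the
#' phase-1 surface for regressor tunings).
#'
#' @param x A `"grid_search"`.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.grid_search <- function(x, ...) {
  g <- x$grid
  if (!is.null(g$phase)) g <- g[g$phase == 1L, ]
  Cs <- sort(unique(g$C)); gs <- sort(unique(g$gamma))
  if (length(Cs) < 2L || length(gs) < 2L) {
    graphics::plot(g$C, g$score, xlab = "C", ylab = x$score_name, log = "x")
    return(invisible(x))
  }
  z <- matrix(NA_real_, length(Cs), length(gs))
  z[cbind(match(g$C, Cs), match(g$gamma, gs))] <- g$score
  graphics::filled.contour(log2(Cs), log2(gs), z, xlab = "log2(C)",
                           ylab = "log2(gamma)",
                           main = paste("LOOCV", x$score_name), ...)
  invisible(x)
}
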