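#' SVM hyperparameters
#'
#' @param C Soft-margin cost (> 0): trade-off between training error and
#'   margin size.
#' @param gamma RBF kernel inverse-width (> 0); also scales the polynomial and
#'   sigmoid kernels.
#' @param epsilon Regression tube width (> 0); ignored by the classifier.
#' @param kernel One of `"rbf"` (Gaussian, `exp(-gamma * ||u - v||^2)`),
#'   `"linear"`, `"poly"` (`(gamma * u.v + coef0)^degree`), `"sigmoid"`
#'   (`tanh(gamma * u.v + coef0)`).
#' @param degree,coef0 Polynomial / sigmoid kernel constants.
#' @return An object of class `"hyper_params"`.
#' @export
hyper_params <- function(C = 1, gamma = 0.25, epsilon = 0.1,
                         kernel = c("rbf", "linear", "poly", "sigmoid"),
                         degree = 3, coef0 = 0) {
  kernel <- match.arg(kernel)
  stopifnot_scalar_number(C, "C", 0, strict_lower = TRUE)
  stopifnot_scalar_number(gamma, "gamma", 0, strict_lower = TRUE)
  stopifnot_scalar_number(epsilon, "epsilon", 0, strict_lower = TRUE)
  structure(list(C = C, gamma = gamma, epsilon = epsilon, kernel = kernel,
                 degree = degree, coef0 = coef0),
            class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  cat(sprintf("hyper_params: kernel=%s C=%g gamma=%g epsilon=%g\n",
              x$kernel, x$C, x$gamma, x$epsilon))
  invisible(x)
}

# Kernel Gram matrix between row sets X (m x d) and Y (k x d).
kernel_matrix <- function(X, Y, hp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  switch(hp$kernel,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      d2[d2 < 0] <- 0
      exp(-hp$gamma * d2)
    },
    linear = tcrossprod(X, Y),
    poly = (hp$gamma * tcrossprod(X, Y) + hp$coef0)^hp$degree,
    sigmoid = tanh(hp$gamma * tcrossprod(X, Y) + hp$coef0)
  )
}

#' Train a kernel support vector machine
#'
#' Fits either a soft-margin C-SVM classifier or an epsilon-tube support vector
#' regressor by sequential minimal optimization (maximal-violating-pair working
#' set selection). The fit is deterministic: identical inputs and
#' hyperparameters always give identical models.
#'
#' @param x Numeric feature matrix, one row per example.
#' @param y For `type = "C-svc"`: kinetic labels (`"two_state"` /
#'   `"multi_state"`, a factor, or `+1`/`-1`); two-state is encoded `+1`.
#'   For `type = "eps-svr"`: numeric targets (log10 rates).
#' @param type `"C-svc"` or `"eps-svr"`.
#' @param hp A [hyper_params].
#' @param tol SMO stopping tolerance on the KKT violation.
#' @return An object of class `"ksvm"` with the support-vector coefficients,
#'   offset and training metadata.
#' @export
ksvm <- function(x, y, type = c("C-svc", "eps-svr"), hp = hyper_params(),
                 tol = 1e-3) {
  type <- match.arg(type)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (type == "C-svc") {
    yv <- encode_labels(y)
    if (n < 2L || length(unique(yv)) < 2L)
      fr_stop("classification training needs at least 2 rows and both classes")
    K <- kernel_matrix(x, x, hp)
    Q <- (yv %o% yv) * K
    sol <- .smo_solve(Q, rep(-1, n), yv, rep(hp$C, n), tol = tol)
    coefs <- sol$alpha * yv
  } else {
    if (!is.numeric(y)) fr_stop("regression targets must be numeric")
    if (n < 3L) fr_stop("regression training needs at least 3 rows")
    z <- as.numeric(y)
    K <- kernel_matrix(x, x, hp)
    idx <- c(seq_len(n), seq_len(n))
    yext <- c(rep(1, n), rep(-1, n))
    Q <- (yext %o% yext) * K[idx, idx]
    p <- c(hp$epsilon - z, hp$epsilon + z)
    sol <- .smo_solve(Q, p, yext, rep(hp$C, 2L * n), tol = tol)
    coefs <- sol$alpha[seq_len(n)] - sol$alpha[n + seq_len(n)]
  }
  sv <- which(abs(coefs) > 1e-12)
  structure(list(type = type, hp = hp, coefs = coefs[sv],
                 sv = x[sv, , drop = FALSE], rho = sol$rho,
                 feature_names = colnames(x), n_train = n,
                 iter = sol$iter, converged = sol$converged),
            class = "ksvm")
}

encode_labels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) fr_stop("numeric labels must be +1/-1")
    return(as.numeric(y))
  }
  lab <- vapply(as.character(y), normalize_kinetic_label, character(1))
  ifelse(lab == "two_state", 1, -1)
}

decode_labels <- function(yv) ifelse(yv > 0, "two_state", "multi_state")

#' Decision values / predictions from a fitted ksvm
#'
#' @param object A fitted [ksvm] model.
#' @param newdata Numeric matrix (or single feature vector) with the same
#'   columns as the training matrix.
#' @param decision For classifiers, return the raw decision value instead of
#'   the label.
#' @param ... Unused.
#' @return For regressors, numeric predictions. For classifiers, kinetic labels
#'   (or decision values when `decision = TRUE`).
#' @export
predict.ksvm <- function(object, newdata, decision = FALSE, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sv))
    fr_stop(sprintf("newdata has %d features; model was trained with %d",
                    ncol(newdata), ncol(object$sv)))
  f <- as.numeric(kernel_matrix(newdata, object$sv, object$hp) %*%
                    object$coefs) - object$rho
  if (object$type == "eps-svr") return(f)
  if (decision) f else decode_labels(f)
}

#' @export
print.ksvm <- function(x, ...) {
  cat(sprintf("ksvm %s: kernel=%s C=%g gamma=%g%s, %d SVs of %d examples\n",
              x$type, x$hp$kernel, x$hp$C, x$hp$gamma,
              if (x$type == "eps-svr") sprintf(" epsilon=%g", x$hp$epsilon)
              else "",
              nrow(x$sv), x$n_train))
  invisible(x)
}
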