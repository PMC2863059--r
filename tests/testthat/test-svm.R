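test_that("separable clouds are classified perfectly by RBF and linear kernels", {
  d <- gaussian_clouds(n = 40, sep = 4, seed = 1)
  for (kern in c("rbf", "linear")) {
    m <- ksvm(d$x, d$y, "C-svc", hyper_params(C = 1, gamma = 0.25,
                                              kernel = kern))
    expect_equal(mean(predict(m, d$x) == d$y), 1)
  }
  expect_error(ksvm(d$x, rep("two_state", 40), "C-svc"), "both classes")
})

test_that("RBF solves XOR-patterned data where the linear kernel cannot", {
  d <- xor_data(n_per = 10, seed = 5)
  rbf <- ksvm(d$x, d$y, "C-svc", hyper_params(C = 10, gamma = 0.5))
  expect_equal(mean(predict(rbf, d$x) == d$y), 1)
  lin <- ksvm(d$x, d$y, "C-svc", hyper_params(C = 10, kernel = "linear"))
  expect_lt(mean(predict(lin, d$x) == d$y), 1)
})

test_that("epsilon-SVR fits realizable and degenerate targets", {
  x <- matrix(seq(0, 1, length.out = 20), ncol = 1)
  z <- 2 * x[, 1]
  m <- ksvm(x, z, "eps-svr", hyper_params(C = 100, gamma = 1, epsilon = 0.01))
  expect_lt(max(abs(predict(m, x) - z)), 0.01 + 0.01)

  zc <- rep(3, 20)
  mc <- ksvm(x, zc, "eps-svr", hyper_params(C = 10, gamma = 1, epsilon = 0.1))
  expect_lt(max(abs(predict(mc, x) - 3)), 0.1 + 1e-6)

  set.seed(8)
  xs <- matrix(runif(60, 0, 2 * pi), ncol = 1)
  zs <- sin(xs[, 1]) + rnorm(60, 0, 0.05)
  ms <- ksvm(xs, zs, "eps-svr", hyper_params(C = 10, gamma = 1, epsilon = 0.05))
  expect_gt(pearson_r(zs, predict(ms, xs)), 0.95)

  expect_error(ksvm(x[1:2, , drop = FALSE], z[1:2], "eps-svr"), "at least 3")
})

test_that("training is deterministic", {
  d <- gaussian_clouds(n = 30, sep = 2.5, seed = 6)
  probe <- matrix(rnorm(20), ncol = 2)
  m1 <- ksvm(d$x, d$y, "C-svc", hyper_params(C = 2, gamma = 0.5))
  m2 <- ksvm(d$x, d$y, "C-svc", hyper_params(C = 2, gamma = 0.5))
  expect_equal(predict(m1, probe, decision = TRUE),
               predict(m2, probe, decision = TRUE), tolerance = 1e-10)

  set.seed(9)
  xr <- matrix(runif(40), ncol = 2)
  zr <- xr[, 1] - xr[, 2]
  r1 <- ksvm(xr, zr, "eps-svr", hyper_params(C = 5, gamma = 1, epsilon = 0.05))
  r2 <- ksvm(xr, zr, "eps-svr", hyper_params(C = 5, gamma = 1, epsilon = 0.05))
  expect_equal(predict(r1, xr), predict(r2, xr), tolerance = 1e-10)
})

test_that("predict refuses feature-count mismatches", {
  d <- gaussian_clouds(seed = 2)
  m <- ksvm(d$x, d$y, "C-svc")
  expect_error(predict(m, matrix(0, 1, 3)), "features")
})

test_that("solver agrees with an independent SVM implementation", {
  # cross-check against scikit-learn (libsvm) on the same data and
  # hyperparameters; agreement is bounded by the two solvers' tolerances
  d <- gaussian_clouds(n = 30, sep = 2, seed = 13)
  m <- ksvm(d$x, d$y, "C-svc", hyper_params(C = 2, gamma = 0.5), tol = 1e-4)
  dv <- predict(m, d$x, decision = TRUE)

  set.seed(14)
  xr <- matrix(runif(50, 0, 1), ncol = 1)
  zr <- sin(3 * xr[, 1])
  mr <- ksvm(xr, zr, "eps-svr",
             hyper_params(C = 10, gamma = 2, epsilon = 0.05), tol = 1e-4)
  pr <- predict(mr, xr)

  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(x1 = d$x[, 1], x2 = d$x[, 2],
                              y = ifelse(d$y == "two_state", 1, -1), dv = dv),
                   file.path(dir, "svc.csv"), row.names = FALSE)
  utils::write.csv(data.frame(x = xr[, 1], z = zr, pred = pr),
                   file.path(dir, "svr.csv"), row.names = FALSE)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, pandas as pd, numpy as np",
    "from sklearn.svm import SVC, SVR",
    sprintf("d = pd.read_csv('%s')", file.path(dir, "svc.csv")),
    "m = SVC(C=2, gamma=0.5, tol=1e-4).fit(d[['x1','x2']].values, d['y'].values)",
    "e1 = np.max(np.abs(m.decision_function(d[['x1','x2']].values) - d['dv'].values))",
    sprintf("r = pd.read_csv('%s')", file.path(dir, "svr.csv")),
    "mr = SVR(C=10, gamma=2, epsilon=0.05, tol=1e-4).fit(r[['x']].values, r['z'].values)",
    "e2 = np.max(np.abs(mr.predict(r[['x']].values) - r['pred'].values))",
    "print(e1, e2)",
    "sys.exit(0 if (e1 < 5e-3 and e2 < 5e-3) else 1)"), script)
  out <- system2("python", script, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0,
              info = paste(out, collapse = "\n"))
})
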