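test_that("pearson and mad match textbook-formula oracles", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:3, 1:4), "lengths")

  expect_equal(mad_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mad_error(c(0, 0), c(1, -1)), 1)

  set.seed(31)
  for (rep in 1:50) {
    x <- rnorm(100); y <- rnorm(100)
    # from-scratch covariance / variance computation
    cv <- sum((x - mean(x)) * (y - mean(y))) / 99
    r_oracle <- cv / (sqrt(sum((x - mean(x))^2) / 99) *
                        sqrt(sum((y - mean(y))^2) / 99))
    expect_equal(pearson_r(x, y), r_oracle, tolerance = 1e-12)
    m_oracle <- 0
    for (i in 1:100) m_oracle <- m_oracle + abs(x[i] - y[i])
    expect_equal(mad_error(x, y), m_oracle / 100, tolerance = 1e-12)
  }
})

test_that("LOOCV: separable classification, planted regression, preconditions", {
  recs <- bench_records(n = 40, seed = 23)
  rep <- loocv_eval(recs, "classifier")
  expect_equal(nrow(rep$predictions), 40)
  expect_gte(rep$accuracy, 0.9)

  # planted y = 3x with negligible noise recovers almost perfectly
  set.seed(24)
  x <- matrix(runif(30), ncol = 1, dimnames = list(NULL, "x"))
  z <- 3 * x[, 1] + rnorm(30, 0, 0.005)
  pred <- foldrate:::loocv_matrix(x, z, "eps-svr",
                                  hyper_params(C = 100, gamma = 1,
                                               epsilon = 0.01))
  expect_gte(pearson_r(z, pred), 0.999)
  expect_lte(mad_error(z, pred), 0.05)

  two <- recs[vapply(recs, `[[`, character(1), "kinetic_label") == "two_state"]
  expect_error(loocv_eval(two[1:2], "two_state"), "at least 3")
})

test_that("LOOCV report is invariant to dataset row order", {
  recs <- bench_records(n = 24, seed = 25)
  r1 <- loocv_eval(recs, "classifier")
  set.seed(1)
  perm <- sample(length(recs))
  r2 <- loocv_eval(recs[perm], "classifier")
  expect_equal(r2$accuracy, r1$accuracy)
  expect_equal(r2$predictions[order(r2$predictions$id), "pred_label"],
               r1$predictions[order(r1$predictions$id), "pred_label"])
})

test_that("repeated 90/10 splits: size rule, determinism, recovery", {
  recs <- bench_records(n = 61, seed = 26)
  cls <- "two_state"
  sub_n <- sum(vapply(recs, `[[`, character(1), "kinetic_label") == cls)
  rep1 <- repeated_split_eval(recs, cls, n_repeats = 3, seed = 7)
  # test sets have floor(n * 0.10) rows (minimum 2)
  sizes <- table(rep1$predictions$repeat_)
  expect_true(all(sizes == max(2, floor(sub_n * 0.10))))
  rep2 <- repeated_split_eval(recs, cls, n_repeats = 3, seed = 7)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_identical(rep1$per_repeat, rep2$per_repeat)
  rep3 <- repeated_split_eval(recs, cls, n_repeats = 3, seed = 8)
  expect_false(identical(rep1$predictions$id, rep3$predictions$id))

  # planted-function recovery on the regression benchmark
  big <- bench_records(n = 100, seed = 27, noise_sd = 0.2)
  r <- repeated_split_eval(big, "two_state", n_repeats = 5, seed = 1)
  expect_gte(r$pearson_r, 0.9)

  # stratified classifier splits keep both classes in the test set
  rs <- repeated_split_eval(recs, "classifier", n_repeats = 3, seed = 7,
                            stratify = TRUE)
  byrep <- split(rs$predictions$true_label, rs$predictions$repeat_)
  expect_true(all(vapply(byrep, function(l) length(unique(l)) == 2, logical(1))))
})

test_that("single-feature screen: schema, planted signal, degenerate guard", {
  recs <- bench_records(n = 60, seed = 28)
  tab <- single_feature_screen(recs)
  # one row per feature x kinetic class
  expect_equal(nrow(tab), 14)
  expect_setequal(unique(tab$kinetic_class), kinetic_labels())

  # planted structure: LRCO informative for two-state rates; length
  # strongly (and negatively) related to multi-state rates
  two <- tab[tab$kinetic_class == "two_state", ]
  multi <- tab[tab$kinetic_class == "multi_state", ]
  expect_gt(two$pearson_r[two$feature == "LRCO"], 0.5)
  expect_gt(multi$pearson_r[multi$feature == "L"], 0.5)
  expect_lt(multi$direction_r[multi$feature == "L"], 0)

  # an informative feature beats an irrelevant one
  expect_gt(abs(two$pearson_r[two$feature == "LRCO"]),
            abs(two$pearson_r[two$feature == "coil"]))

  # constant feature yields NA + note, not an error
  lab <- vapply(recs, `[[`, character(1), "kinetic_label")
  mix <- c(which(lab == "two_state")[1:6], which(lab == "multi_state")[1:6])
  const <- lapply(recs[mix], function(r) {
    r$ss_string <- strrep("H", nchar(r$sequence)); r
  })
  tab2 <- single_feature_screen(const, features = "helix")
  expect_true(all(is.na(tab2$pearson_r)))
  expect_true(all(nzchar(tab2$note)))
})

test_that("linear baseline: noiseless recovery, F/p behaviour, rank guard", {
  set.seed(30)
  n <- 40
  recs <- bench_records(n = 40, seed = 31)
  # noiseless linear data through the record pathway: overwrite rates with an
  # exact linear function of two screened features
  recs2 <- lapply(recs, function(r) {
    L <- nchar(r$sequence)
    a <- lrco(r$map, L)
    b <- unname(ss_composition(r$ss_string)["helix"])
    r$log_rate <- 1 + 2 * a - b
    r
  })
  fit <- suppressWarnings(  # summary.lm warns on an essentially perfect fit
    linear_baseline(recs2, predictors = c("LRCO", "helix")))
  expect_equal(fit$r, 1, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(unname(fit$coefficients),
               c(1, 2, -1), tolerance = 1e-6)
  expect_lt(fit$p_value, 1e-12)

  # y independent of predictors: p-value > 0.05 in >= 90% of seeded trials
  hits <- 0
  for (t in 1:100) {
    set.seed(1000 + t)
    recs3 <- lapply(recs[1:30], function(r) { r$log_rate <- rnorm(1); r })
    f <- linear_baseline(recs3, predictors = c("LRCO", "LRCN"))
    if (f$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)

  # duplicated predictor -> rank-deficient design error
  expect_error(linear_baseline(recs2, predictors = c("LRCO", "LRCO")),
               "collinear|rank")
  expect_error(linear_baseline(recs2[1:3], predictors = c("LRCO", "helix")),
               "more records")
})

test_that("fold models are untouched by later mutation of held-out data", {
  recs <- bench_records(n = 20, seed = 33)
  x <- assemble_matrix(recs, "classifier")
  lab <- vapply(recs, `[[`, character(1), "kinetic_label")
  i <- 1
  sc <- fit_scaling(x[-i, , drop = FALSE], "minmax")
  fit <- ksvm(apply_scaling(sc, x[-i, , drop = FALSE]), lab[-i], "C-svc",
              hyper_params())
  snapshot <- list(coefs = fit$coefs, rho = fit$rho, sv = fit$sv,
                   scaling = sc)
  x[i, ] <- NaN   # corrupt the held-out row *after* the fold fit
  expect_identical(snapshot$coefs, fit$coefs)
  expect_identical(snapshot$rho, fit$rho)
  expect_identical(snapshot$sv, fit$sv)
  expect_identical(snapshot$scaling, sc)
})
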