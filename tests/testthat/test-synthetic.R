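test_that("identical config and seed give byte-identical benchmark directories", {
  cfg <- synth_config(n_proteins = 10, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_benchmark(cfg, d1)
  generate_benchmark(cfg, d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # a different seed changes the output
  d3 <- withr::local_tempdir()
  generate_benchmark(synth_config(n_proteins = 10, seed = 8), d3)
  expect_false(identical(readLines(file.path(d1, "rates.tsv")),
                         readLines(file.path(d3, "rates.tsv"))))
})

test_that("every emitted file parses cleanly and round-trips the records", {
  cfg <- synth_config(n_proteins = 10, seed = 19)
  dir <- withr::local_tempdir()
  tab <- generate_benchmark(cfg, dir)
  recs <- attr(tab, "records")
  expect_no_warning(loaded <- read_benchmark(dir))
  expect_identical(names(loaded), names(recs))
  for (id in names(recs)) {
    expect_identical(loaded[[id]]$sequence, recs[[id]]$sequence)
    expect_identical(loaded[[id]]$ss_string, recs[[id]]$ss_string)
    expect_equal(unclass(loaded[[id]]$map), unclass(recs[[id]]$map),
                 tolerance = 1e-12)
    expect_equal(unname(loaded[[id]]$ca_coords), unname(recs[[id]]$ca_coords))
    expect_equal(loaded[[id]]$log_rate, recs[[id]]$log_rate, tolerance = 1e-10)
    expect_identical(loaded[[id]]$kinetic_label, recs[[id]]$kinetic_label)
  }
})

test_that("with zero noise the planted rate model closes the loop exactly", {
  recs <- bench_records(n = 16, seed = 20, noise_sd = 0)
  pl <- attr(recs, "planted")
  params <- contact_params()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    L <- nchar(r$sequence)
    ss <- ss_composition(r$ss_string)
    mu <- foldrate:::planted_rate(r$kinetic_label, L,
                                  lrco(r$map, L, params),
                                  lrcn(r$map, L, params),
                                  ss[["helix"]], ss[["sheet"]])
    expect_identical(r$log_rate, mu)
    expect_identical(pl$rate_noiseless[i], mu)
  }
})

test_that("standalone map generator honours density and long-range bias", {
  m0 <- synth_contact_map(30, density = 0, seed = 1)
  expect_true(all(unclass(m0) == 0))

  mb <- synth_contact_map(40, density = 0.3, long_range_bias = 0, seed = 2)
  expect_identical(lrcn(mb), 0)   # no qualifying long-range mass at all
  expect_identical(lrco(mb), 0)
  expect_gt(sum(unclass(mb)), 0)  # but short-range mass exists

  # different seeds differ (in at least one entry, over several pairs)
  diffs <- vapply(1:10, function(k) {
    a <- synth_contact_map(25, 0.2, seed = 100 + k)
    b <- synth_contact_map(25, 0.2, seed = 200 + k)
    any(unclass(a) != unclass(b))
  }, logical(1))
  expect_true(all(diffs))

  expect_error(synth_contact_map(10, 0.2), ">= 15")
})

test_that("estimated and structure-derived descriptors correlate across the benchmark", {
  recs <- bench_records(n = 40, seed = 21)
  est <- t(vapply(recs, function(r) {
    d <- contact_descriptors(r)
    c(d$lrco, d$lrcn, d$r_lrco, d$r_lrcn)
  }, numeric(4)))
  expect_gt(pearson_r(est[, 1], est[, 3]), 0.5)  # LRCO vs rLRCO
  expect_gt(pearson_r(est[, 2], est[, 4]), 0.5)  # LRCN vs rLRCN
})

test_that("class-conditional length distributions overlap", {
  recs <- bench_records(n = 80, seed = 42)
  L <- vapply(recs, function(r) nchar(r$sequence), numeric(1))
  lab <- vapply(recs, `[[`, character(1), "kinetic_label")
  expect_gt(max(L[lab == "two_state"]), min(L[lab == "multi_state"]))
})

test_that("generated chains are physically sane walks", {
  recs <- bench_records(n = 10, seed = 22)
  for (r in recs[1:3]) {
    d <- sqrt(rowSums(diff(r$ca_coords)^2))
    expect_true(all(abs(d - 3.8) < 0.01))  # virtual bond length (3dp rounding)
    dm <- as.matrix(dist(r$ca_coords))
    nonadj <- abs(row(dm) - col(dm)) > 1
    expect_gte(min(dm[nonadj]), 3.4)       # self-avoidance
  }
})
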