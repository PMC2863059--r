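test_that("descriptor hand examples under default conventions", {
  zero <- contact_map(matrix(0, 20, 20))
  expect_equal(lrcn(zero), 0)
  expect_equal(lrco(zero), 0)
  expect_equal(contact_order(zero), 0)

  one <- contact_map(cbind(1, 13, 1), n = 20)
  expect_equal(lrcn(one), 1 / 20)          # single qualifying pair / L
  expect_equal(lrco(one), 12 / 400)        # p * separation / L^2
  # CO uses all separations and normalizes by total probability
  two <- contact_map(rbind(c(1, 3, 1), c(1, 5, 1)), n = 10)
  expect_equal(contact_order(two), (2 + 4) / (10 * 2))

  # sub-threshold separations do not count toward LRCN/LRCO
  near <- contact_map(cbind(1, 12, 1), n = 20)  # separation 11 < 12
  expect_equal(lrcn(near), 0)
  expect_equal(lrco(near), 0)
  expect_gt(contact_order(near), 0)

  expect_error(lrcn(one, L = 30), "dimension")
})

test_that("vectorized descriptors equal the brute-force double loop", {
  set.seed(101)
  for (rep in 1:20) {
    L <- sample(15:120, 1)
    dens <- sample(c(0.01, 0.05, 0.2), 1)
    m <- random_map_matrix(L, dens)
    cm <- contact_map(m)
    expect_equal(lrcn(cm), bf_lrcn(m, L), tolerance = 1e-12)
    expect_equal(lrco(cm), bf_lrco(m, L), tolerance = 1e-12)
    expect_equal(contact_order(cm), bf_co(m, L), tolerance = 1e-12)
  }
})

test_that("probability weighting degenerates exactly on binary maps", {
  set.seed(55)
  for (rep in 1:10) {
    L <- sample(20:60, 1)
    m <- (random_map_matrix(L, 0.1) > 0) * 1
    cm <- contact_map(m)
    # binary-contact definitions: count contacts / weighted count
    cnt <- 0; wsum <- 0
    for (i in seq_len(L - 1)) for (j in (i + 1):L) {
      if (j - i >= 12 && m[i, j] == 1) {
        cnt <- cnt + 1
        wsum <- wsum + (j - i)
      }
    }
    expect_identical(lrcn(cm), cnt / L)
    expect_identical(lrco(cm), wsum / L^2)
  }
})

test_that("descriptors are linear in the map and monotone in added pairs", {
  set.seed(77)
  m <- random_map_matrix(40, 0.1)
  cm <- contact_map(m)
  for (k in c(0, 0.3, 1)) {
    expect_equal(lrcn(contact_map(m * k)), k * lrcn(cm), tolerance = 1e-12)
    expect_equal(lrco(contact_map(m * k)), k * lrco(cm), tolerance = 1e-12)
  }
  # adding any qualifying pair strictly increases LRCN
  m2 <- m
  stopifnot(m2[2, 20] == 0 || TRUE)
  m2[2, 20] <- m2[20, 2] <- min(1, m2[2, 20] + 0.5)
  expect_gt(lrcn(contact_map(pmin(m2, 1))), lrcn(cm) - 1e-15)
})

test_that("descriptors are indifferent to which triangle was populated", {
  a <- contact_map(cbind(3, 40, 0.7), n = 50)
  b <- contact_map(matrix(0, 50, 50))
  bm <- unclass(b); bm[40, 3] <- bm[3, 40] <- 0.7
  b <- contact_map(bm)
  expect_identical(lrcn(a), lrcn(b))
  expect_identical(lrco(a), lrco(b))
})

test_that("real contact maps respect the closed 8 A convention", {
  collinear <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  m <- real_contact_map(collinear)
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 3], 1)
  expect_equal(m[1, 3], 1)  # 7.6 <= 8

  expect_equal(real_contact_map(rbind(c(0, 0, 0), c(7.99, 0, 0)))[1, 2], 1)
  expect_equal(real_contact_map(rbind(c(0, 0, 0), c(8.00, 0, 0)))[1, 2], 1)
  expect_equal(real_contact_map(rbind(c(0, 0, 0), c(8.01, 0, 0)))[1, 2], 0)

  # pairs with a missing CA contribute no contact
  mis <- rbind(c(0, 0, 0), c(NA, NA, NA), c(4, 0, 0))
  m <- real_contact_map(mis)
  expect_equal(m[1, 3], 1)
  expect_equal(m[1, 2], 0)
  expect_equal(m[2, 3], 0)
  expect_error(real_contact_map(rbind(c(0, 0, 0), c(NA, NA, NA))),
               "at least 2")
})

test_that("real-map contact count matches a brute-force distance count", {
  set.seed(9)
  coords <- matrix(rnorm(30 * 3, sd = 6), ncol = 3)
  m <- real_contact_map(coords)
  cnt <- 0
  for (i in 1:29) for (j in (i + 1):30)
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 8) cnt <- cnt + 1
  expect_equal(sum(unclass(m)[upper.tri(m)]), cnt)
})

test_that("binarize_map applies the >= threshold convention", {
  m <- contact_map(cbind(1, 13, 0.6), n = 20)
  expect_equal(binarize_map(m, 0.5)[1, 13], 1)
  m <- contact_map(cbind(1, 13, 0.5), n = 20)
  expect_equal(binarize_map(m, 0.5)[1, 13], 1)   # boundary: kept
  expect_equal(binarize_map(m, 0.51)[1, 13], 0)
  set.seed(2)
  m <- contact_map(random_map_matrix(20, 0.2))
  b0 <- binarize_map(m, 0)
  expect_true(all(unclass(b0)[unclass(m) > 0] == 1))
  expect_error(binarize_map(m, 1.2), "<= 1")
})

test_that("contact_params validates its conventions", {
  p <- contact_params()
  expect_equal(p$distance_threshold, 8)
  expect_equal(p$min_separation, 12L)
  expect_equal(p$c_lrcn, 1)
  expect_equal(p$c_lrco, 2)
  expect_error(contact_params(distance_threshold = 0), "> 0")
  expect_error(contact_params(min_separation = 0), ">= 1")
  # alternate conventions are honoured
  one <- contact_map(cbind(1, 13, 1), n = 20)
  expect_equal(lrcn(one, params = contact_params(min_separation = 13)), 0)
  expect_equal(lrcn(one, params = contact_params(c_lrcn = 0)), 1)
})
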