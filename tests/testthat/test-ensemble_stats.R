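test_that("site frequencies are exact counts with unit column sums", {
  one <- msa_from_codes(matrix(c(3L, 21L, 1L), 1, 3))
  f1 <- site_frequencies(one)
  expect_equal(f1[cbind(c(3, 21, 1), 1:3)], c(1, 1, 1))
  expect_equal(sum(f1), 3)

  msa <- msa_from_codes(random_codes(40L, 12L, seed = 2L))
  f <- site_frequencies(msa)
  expect_equal(colSums(f), rep(1, 12))
  # counting oracle via table()
  for (l in c(1L, 7L, 12L)) {
    tab <- table(factor(msa$codes[, l], levels = 1:21))
    expect_equal(unname(f[, l]), as.vector(tab) / 40)
  }
  gaps <- edge_case_alignments()$all_gap
  expect_equal(unname(site_frequencies(gaps)[21, ]), rep(1, gaps$length))
})

test_that("order-2 central moment equals the covariance identity f_ab - f_a f_b", {
  msa <- small_planted_msa(n = 200L, l = 15L)
  for (seed in 1:5) {
    pick <- with_seed(seed, list(pos = sample.int(15L, 2L),
                                 sym = sample.int(21L, 2L, replace = TRUE)))
    sites <- cbind(pick$pos, pick$sym)
    got <- central_moment(msa, sites, order = 2L)
    xa <- msa$codes[, pick$pos[1]] == pick$sym[1]
    xb <- msa$codes[, pick$pos[2]] == pick$sym[2]
    expect_equal(got, mean(xa & xb) - mean(xa) * mean(xb), tolerance = 1e-12)
  }
  expect_error(central_moment(msa, cbind(c(3L, 3L), c(1L, 2L)), 2L), "distinct")
})

test_that("independent uniform columns have near-zero covariance", {
  msa <- msa_from_codes(random_codes(4000L, 2L, seed = 6L))
  se <- sqrt(1 / 21 * (1 - 1 / 21) / 4000) # upper bound on the moment's s.e.
  got <- central_moment(msa, cbind(c(1L, 2L), c(4L, 9L)), 2L)
  expect_lt(abs(got), 3 * se)
})

test_that("self-comparison gives r = 1 and slope = 1 at every order", {
  msa <- small_planted_msa(n = 200L, l = 15L)
  for (m in 1:4) {
    mc <- moment_comparison(msa, msa, m, n_samples = 300L, seed = 4L)
    expect_equal(mc$pearson_r, 1, tolerance = 1e-12)
    expect_equal(mc$best_fit_slope, 1, tolerance = 1e-12)
  }
})

test_that("column shuffling preserves frequencies but destroys covariation", {
  msa <- small_planted_msa(n = 400L, l = 20L)
  shuf <- msa_from_codes(with_seed(8L, apply(msa$codes, 2L, sample)))
  m1 <- moment_comparison(msa, shuf, 1L)
  expect_equal(m1$pearson_r, 1, tolerance = 1e-12) # permutations keep counts
  m2 <- moment_comparison(msa, shuf, 2L, n_samples = 2000L, seed = 4L)
  expect_lt(abs(m2$pearson_r), 0.3)
})

test_that("best-fit slope matches an independent regression oracle", {
  msa <- small_planted_msa(n = 400L, l = 20L)
  gen <- small_planted_msa(n = 400L, l = 20L, seed = 91L)
  mc <- moment_comparison(msa, gen, 2L, n_samples = 500L, seed = 10L)
  fit <- stats::lm(generated ~ natural, data = mc$pairs)
  expect_equal(mc$best_fit_slope, unname(stats::coef(fit)[2]), tolerance = 1e-10)
  expect_equal(mc$pearson_r, stats::cor(mc$pairs$natural, mc$pairs$generated),
               tolerance = 1e-12)
})

test_that("degenerate natural values make the comparison an explicit error", {
  flat <- msa_from_codes(matrix(5L, 30L, 8L))
  expect_error(moment_comparison(flat, flat, 2L, n_samples = 50L), "undefined")
})

test_that("r20 self-comparison is exactly 1 at every order", {
  msa <- small_planted_msa(n = 400L, l = 20L)
  cur <- r20_curve(msa, msa, orders = 2:6, n_sets = 40L, seed = 3L)
  expect_equal(cur$mean_r, rep(1, 5), tolerance = 1e-12)
})

test_that("uniform-random sequences lose the high-order string frequencies", {
  msa <- small_planted_msa(n = 400L, l = 20L)
  rand <- msa_from_codes(random_codes(400L, 20L, seed = 55L))
  cur <- r20_curve(msa, rand, orders = c(2L, 5L, 8L), n_sets = 40L, seed = 3L)
  expect_lt(cur$mean_r[3], 0.3) # order 8: top natural strings essentially absent
})

test_that("the curve is robust to the top-n cutoff on a structured fixture", {
  msa <- small_planted_msa(n = 400L, l = 20L)
  # a second sample of the same planted truth plays the generated ensemble
  p <- make_planted_model(length = 20L, k_true = 3L, seed = 31L)
  gen <- sample_msa(p, 400L, seed = 77L)$msa
  curves <- lapply(c(10L, 20L, 50L), function(tn) {
    r20_curve(msa, gen, orders = 2:4, top_n = tn, n_sets = 40L, seed = 3L)$mean_r
  })
  for (i in 2:3) expect_lt(max(abs(curves[[i]] - curves[[1]])), 0.1)
})
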