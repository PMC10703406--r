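A <- length(msa_alphabet())

test_that("probability field: zero latents give the uniform model", {
  theta <- with_seed(1L, array(rnorm(A * 3 * 6), c(A, 3L, 6L)))
  pf <- probability_field(theta, matrix(0, 4, 3))
  expect_equal(pf$pi, array(1 / A, c(4, A, 6)), tolerance = 1e-12)
  expect_equal(pf$log_omega, matrix(log(A), 4, 6), tolerance = 1e-12)
})

test_that("probability field reduces to the Boltzmann weights at K=1, z=1", {
  w <- with_seed(2L, runif(A, 0.1, 5))
  theta <- array(-log(w), c(A, 1L, 1L))
  pf <- probability_field(theta, matrix(1, 1, 1))
  expect_equal(as.vector(pf$pi[1, , 1]), w / sum(w), tolerance = 1e-12)
})

test_that("probability field matches the naive double-loop evaluation", {
  for (seed in 1:3) {
    theta <- with_seed(seed, array(runif(A * 2 * 5, -2, 2), c(A, 2L, 5L)))
    z <- with_seed(seed + 10L, matrix(runif(4 * 2, -2, 2), 4, 2))
    pf <- probability_field(theta, z)
    for (n in 1:4) for (l in 1:5) {
      e <- vapply(1:A, function(a) exp(-sum(z[n, ] * theta[a, , l])), numeric(1))
      expect_equal(as.vector(pf$pi[n, , l]), e / sum(e), tolerance = 1e-12)
    }
  }
})

test_that("normalization survives large-magnitude energies via the log-space path", {
  for (seed in 1:5) {
    theta <- with_seed(seed, array(runif(A * 2 * 4, -250, 250), c(A, 2L, 4L)))
    z <- with_seed(seed + 50L, matrix(runif(3 * 2, -2, 2), 3, 2))
    pf <- probability_field(theta, z) # |z . theta| up to ~500
    expect_true(all(is.finite(pf$log_omega)))
    expect_lt(max(abs(apply(pf$pi, c(1, 3), sum) - 1)), 1e-10)
  }
  expect_error(probability_field(array(NaN, c(A, 1, 1)), matrix(1, 1, 1)), "non-finite")
})

test_that("log-likelihood: uniform closed form, concentration limit, and oracle", {
  msa <- msa_from_codes(random_codes(7L, 9L, seed = 4L))
  theta <- with_seed(5L, array(rnorm(A * 2 * 9), c(A, 2L, 9L)))
  expect_equal(
    log_likelihood(msa, probability_field(theta, matrix(0, 7, 2))),
    -7 * 9 * log(A)
  )
  # a field concentrating on the observed symbols drives the likelihood to 0-
  conc <- array(0, c(A, 1L, 9L))
  one <- msa_from_codes(msa$codes[1, , drop = FALSE])
  conc[cbind(one$codes[1, ], 1L, 1:9)] <- -30
  ll <- log_likelihood(one, probability_field(conc, matrix(1, 1, 1)))
  expect_lt(ll, 0)
  expect_gt(ll, -1e-9)
  # direct-summation oracle on the one-hot tensor
  z <- with_seed(6L, matrix(rnorm(7 * 2), 7, 2))
  pf <- probability_field(theta, z)
  oh <- one_hot(msa)
  expect_equal(log_likelihood(msa, pf), sum(oh * log(pf$pi)), tolerance = 1e-10)
  expect_error(log_likelihood(msa_from_codes(matrix(1L, 2, 2)), pf), "dimensions")
})

test_that("analytical gradients match central finite differences", {
  h <- 1e-5
  for (seed in 1:3) {
    planted <- make_planted_model(length = 5L, k_true = 2L, seed = seed)
    msa <- sample_msa(planted, 4L, seed = seed + 20L)$msa
    theta <- with_seed(seed, array(runif(A * 2 * 5, -1, 1), c(A, 2L, 5L)))
    z <- with_seed(seed + 30L, matrix(runif(4 * 2, -1, 1), 4, 2))
    g <- gradients(msa, theta, z)
    llf <- function(th, zz) log_likelihood(msa, probability_field(th, zz))
    for (i in with_seed(seed, sample(length(theta), 12L))) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      fd <- (llf(tp, z) - llf(tm, z)) / (2 * h)
      expect_lt(abs(fd - g$grad_theta[i]) / max(abs(fd), 1e-8), 1e-5)
    }
    for (i in with_seed(seed + 1L, sample(length(z), 4L))) {
      zp <- z; zp[i] <- zp[i] + h
      zm <- z; zm[i] <- zm[i] - h
      fd <- (llf(theta, zp) - llf(theta, zm)) / (2 * h)
      expect_lt(abs(fd - g$grad_z[i]) / max(abs(fd), 1e-8), 1e-5)
    }
  }
})

test_that("at z = 0 the latent gradient takes its uniform-field closed form", {
  msa <- msa_from_codes(random_codes(3L, 6L, seed = 7L))
  theta <- with_seed(8L, array(rnorm(A * 2 * 6), c(A, 2L, 6L)))
  g <- gradients(msa, theta, matrix(0, 3, 2))
  oh <- one_hot(msa)
  for (n in 1:3) for (k in 1:2) {
    expected <- sum(theta[, k, ] * (1 / A - oh[n, , ]))
    expect_equal(g$grad_z[n, k], expected, tolerance = 1e-10)
  }
})

test_that("fitting identical sequences concentrates probability on them", {
  codes <- matrix(rep(c(3L, 8L, 15L, 21L, 1L, 9L), each = 12L), nrow = 12L)
  msa <- msa_from_codes(codes)
  m <- fit_generalist(msa, fit_config(k_dim = 1L, max_iters = 1500L, seed = 2L))
  pf <- probability_field(m$theta, m$z)
  idx <- cbind(rep(1:12, 6), as.vector(codes), rep(1:6, each = 12))
  expect_gte(mean(pf$pi[idx]), 0.99)
})

test_that("fit trace is non-decreasing, improves on the start, and is reproducible", {
  msa <- small_planted_msa(n = 60L, l = 12L)
  cfg <- fit_config(k_dim = 2L, max_iters = 200L, seed = 5L)
  m1 <- fit_generalist(msa, cfg)
  expect_true(all(diff(m1$fit_meta$ll_trace) >= 0))
  expect_gte(m1$fit_meta$final_ll, m1$fit_meta$initial_ll)
  m2 <- fit_generalist(msa, cfg)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$z, m2$z)
  expect_error(fit_generalist(msa_from_codes(matrix(1L, 1, 3)), cfg), "at least 2")
})

test_that("overparameterized configurations are flagged", {
  msa <- msa_from_codes(random_codes(4L, 3L, seed = 9L))
  expect_warning(fit_generalist(msa, fit_config(k_dim = 5L, max_iters = 5L, seed = 1L)),
                 "overfitting")
})

test_that("restart protocol returns every run and the delta-sq minimizer", {
  msa <- small_planted_msa(n = 60L, l = 12L)
  cfg <- fit_config(k_dim = 2L, max_iters = 120L, n_restarts = 3L, seed = 40L)
  res <- fit_restarts(msa, cfg)
  expect_length(res$runs, 3L)
  expect_equal(min(res$delta_sq), res$delta_sq[which.min(res$delta_sq)])
  expect_identical(res$best, res$runs[[which.min(res$delta_sq)]])
  one <- fit_restarts(msa, fit_config(k_dim = 2L, max_iters = 120L, n_restarts = 1L, seed = 40L))
  expect_identical(one$best, one$runs[[1L]])
})

test_that("generation from the uniform model yields uniform symbol frequencies", {
  theta <- array(0, c(A, 1L, 8L))
  model <- manual_model(theta, matrix(0, 5, 1))
  gen <- generate_sequences(model, 5000L, seed = 3L)
  expect_equal(gen$n_sequences, 5000L)
  expect_equal(gen$length, 8L)
  f <- site_frequencies(gen)
  se <- sqrt((1 / A) * (1 - 1 / A) / 5000)
  expect_lt(max(abs(f - 1 / A)), 3.5 * se)
  expect_error(generate_sequences(model, 0L, seed = 1L), "at least 1")
})

test_that("a near-deterministic model generates its consensus exactly", {
  l <- 10L
  consensus <- with_seed(11L, sample.int(A, l, replace = TRUE))
  theta <- array(20, c(A, 1L, l))
  theta[cbind(consensus, 1L, seq_len(l))] <- -20
  model <- manual_model(theta, matrix(1, 4, 1))
  gen <- generate_sequences(model, 50L, seed = 5L)
  expect_true(all(gen$codes == matrix(consensus, 50L, l, byrow = TRUE)))
})

test_that("generation is deterministic given the seed", {
  m <- recovery_fit_small()
  g1 <- generate_sequences(m, 40L, seed = 8L)
  g2 <- generate_sequences(m, 40L, seed = 8L)
  expect_identical(g1$codes, g2$codes)
})

test_that("optimal_sequence: tie-break, argmax oracle, and dominance", {
  m <- recovery_fit_small()
  # all-ties at z = 0 resolve to the first alphabet symbol
  expect_equal(optimal_sequence(m, rep(0, m$k_dim)), rep(1L, dim(m$theta)[3]))
  # per-position exhaustive maximization oracle
  z1 <- m$z[3, ]
  opt <- optimal_sequence(m, z1)
  pf <- probability_field(m$theta, matrix(z1, 1))
  for (l in seq_len(dim(m$theta)[3])) {
    expect_equal(pf$pi[1, opt[l], l], max(pf$pi[1, , l]))
  }
  # the optimum dominates the natural sequence at the same latent point
  msa <- small_planted_msa(n = 60L, l = 12L)
  for (n in c(1L, 25L, 60L)) {
    expect_gte(
      sequence_log_prob(m, optimal_sequence(m, m$z[n, ]), m$z[n, ]),
      sequence_log_prob(m, msa$codes[n, ], m$z[n, ])
    )
  }
})

test_that("greedy hill climb solves separable landscapes and records ascent", {
  # separable score with a unique per-position optimum: global optimum reached
  target <- c(2L, 1L, 3L, 2L)
  score <- function(codes) -sum(codes != target)
  res <- greedy_hill_climb(score, start = c(1L, 1L, 1L, 1L), seed = 2L, n_symbols = 3L)
  expect_equal(res$codes, target)
  expect_true(all(diff(res$trace) > 0))
  expect_gte(res$trace[length(res$trace)], res$trace[1])
})

test_that("hill-climb terminals are single-substitution local optima (enumeration)", {
  l <- 4L; a <- 3L
  landscape <- with_seed(13L, array(rnorm(a^l), dim = rep(a, l)))
  score <- function(codes) landscape[matrix(codes, 1)]
  for (seed in 1:5) {
    start <- with_seed(seed + 100L, sample.int(a, l, replace = TRUE))
    res <- greedy_hill_climb(score, start, seed = seed, n_symbols = a)
    s_end <- score(res$codes)
    for (pos in 1:l) for (sym in 1:a) {
      if (sym == res$codes[pos]) next
      cand <- res$codes; cand[pos] <- sym
      expect_lte(score(cand), s_end)
    }
  }
})

test_that("per-position log-fold improvement has its closed-form special cases", {
  score10 <- function(codes) if (codes[1] == 2L) log(10) else 0
  expect_equal(per_position_log_fold_improvement(score10, 1L, 1L), 0)
  expect_equal(per_position_log_fold_improvement(score10, 1L, 2L), 1.0)
  # consistency with the model's own sequence log-probability
  m <- recovery_fit_small()
  z1 <- m$z[1, ]
  sc <- function(codes) sequence_log_prob(m, codes, z1)
  msa <- small_planted_msa(n = 60L, l = 12L)
  opt <- optimal_sequence(m, z1)
  imp <- per_position_log_fold_improvement(sc, msa$codes[1, ], opt)
  expect_equal(imp, (sc(opt) - sc(msa$codes[1, ])) / (12 * log(10)))
  expect_gte(imp, 0)
})

test_that("model serialization round-trips losslessly and rejects garbage", {
  m <- recovery_fit_small()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(unclass(back), unclass(m))
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "cannot read|not a saved model")
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "not a saved model")
})
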