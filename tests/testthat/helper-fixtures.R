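# Shared fixtures. Heavy objects (the planted recovery fixture and its fitted
# model) are built once per test run and memoized, since several test files
# probe different properties of the same fit.

# internal helpers used across test files
with_seed <- generalist:::with_seed
msa_from_codes <- generalist:::msa_from_codes
hmin_means <- generalist:::hmin_means
cross_hamming <- generalist:::cross_hamming

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Planted recovery fixture: K_true = 4, N = 2000, L = 30, default theta scale.
recovery_planted <- function() {
  memo("recovery_planted", function() {
    make_planted_model(length = 30L, k_true = 4L, seed = 11L)
  })
}

recovery_sample <- function() {
  memo("recovery_sample", function() sample_msa(recovery_planted(), 2000L, seed = 12L))
}

recovery_msa <- function() recovery_sample()$msa

# The fit used by the parameter-recovery and optimum-dominance checks. Run
# deep enough that the order-1 statistics saturate.
recovery_fit <- function() {
  memo("recovery_fit", function() {
    fit_generalist(
      recovery_msa(),
      fit_config(k_dim = 4L, max_iters = 4000L, tolerance = 1e-7, seed = 7L)
    )
  })
}

recovery_generated <- function() {
  memo("recovery_generated", function() {
    generate_sequences(recovery_fit(), 2000L, seed = 99L)
  })
}

# A small covariation-rich alignment for the cheaper statistic tests.
small_planted_msa <- function(n = 400L, l = 20L, seed = 31L) {
  key <- sprintf("small_%d_%d_%d", n, l, seed)
  memo(key, function() {
    p <- make_planted_model(length = l, k_true = 3L, seed = seed)
    sample_msa(p, n, seed = seed + 1L)$msa
  })
}

# A cheap fitted model shared by serialization / optimum / generation tests.
recovery_fit_small <- function() {
  memo("recovery_fit_small", function() {
    fit_generalist(
      small_planted_msa(n = 60L, l = 12L),
      fit_config(k_dim = 2L, max_iters = 400L, seed = 17L)
    )
  })
}

# Construct a generalist_model directly from arbitrary parameters (for tests
# that need exact control over theta and z without fitting).
manual_model <- function(theta, z) {
  structure(
    list(
      theta = theta, z = z, k_dim = ncol(z), alphabet = msa_alphabet(),
      fit_meta = list(seed = 0L, iterations = 0L, initial_ll = NA_real_,
                      final_ll = NA_real_, ll_trace = numeric(0), converged = TRUE)
    ),
    class = "generalist_model"
  )
}

random_codes <- function(n, l, seed) {
  with_seed(seed, matrix(sample.int(21L, n * l, replace = TRUE), n, l))
}
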