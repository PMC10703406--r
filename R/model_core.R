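# Core probability model, maximum-likelihood fitting, generation and local
# optimum search.
#
# The model assigns sequence n a latent vector z_n (length K) and the family a
# shared energy tensor theta (A x K x L). Position l of sequence n is an
# independent categorical over the A = 21 symbols with
#
#   pi[a, n, l] = exp(-sum_k z[n,k] theta[a,k,l]) / Omega[n,l],
#
# where Omega[n,l] is the explicit 21-term partition sum. Internally theta is
# flattened to a K x (A*L) matrix so that the per-sequence logits are a single
# matrix product; column c = a + (l-1)*A holds symbol a at position l.

theta_to_mat <- function(theta) {
  d <- dim(theta)
  matrix(aperm(theta, c(2L, 1L, 3L)), nrow = d[2L], ncol = d[1L] * d[3L])
}

mat_to_theta <- function(thmat, n_symbols, n_positions) {
  k <- nrow(thmat)
  aperm(array(thmat, dim = c(k, n_symbols, n_positions)), c(2L, 1L, 3L))
}

# logits, log-partition and (optionally) normalized probabilities for latent
# matrix z (M x K) against flattened theta (K x A*L). All log-sum-exp in
# max-subtracted form so arbitrarily large |z . theta| stays finite. With
# want_pi the per-symbol exponentials computed for the partition sum are
# reused for pi itself, saving a full second exp pass in the fit loop.
field_matrices <- function(thmat, z, n_symbols, want_pi = FALSE) {
  logits <- -(z %*% thmat)
  n_positions <- ncol(logits) / n_symbols
  cols <- function(a) seq.int(a, by = n_symbols, length.out = n_positions)
  mx <- logits[, cols(1L), drop = FALSE]
  for (a in 2:n_symbols) mx <- pmax(mx, logits[, cols(a), drop = FALSE])
  s <- matrix(0, nrow(logits), n_positions)
  pi_mat <- if (want_pi) matrix(0, nrow(logits), ncol(logits)) else NULL
  for (a in seq_len(n_symbols)) {
    ea <- exp(logits[, cols(a), drop = FALSE] - mx)
    if (want_pi) pi_mat[, cols(a)] <- ea
    s <- s + ea
  }
  if (want_pi) {
    for (a in seq_len(n_symbols)) {
      pi_mat[, cols(a)] <- pi_mat[, cols(a), drop = FALSE] / s
    }
  }
  log_z <- mx + log(s)
  list(logits = logits, log_z = log_z, n_positions = n_positions, pi = pi_mat)
}

# column index into the flattened symbol-by-position axis for observed codes
obs_columns <- function(codes, n_symbols) {
  codes + n_symbols * (col(codes) - 1L)
}

#' Per-sequence, per-position categorical probabilities
#'
#' Evaluates the model's probability field for an arbitrary latent matrix:
#' `pi[n, a, l] = exp(-sum_k z[n,k] * theta[a,k,l]) / Omega[n,l]`, with the
#' partition value `Omega[n,l]` computed by a max-subtracted log-sum-exp so
#' that large-magnitude energies do not overflow. The latent matrix need not
#' be the training one; any M x K matrix is accepted.
#'
#' @param theta Energy tensor, A x K x L (A = 21 symbols).
#' @param z Latent matrix, M x K.
#' @return An object of class `probability_field`: list with `pi`
#'   (M x A x L array, each (n,l) fibre summing to 1) and `log_omega`
#'   (M x L matrix of log partition values).
#' @export
probability_field <- function(theta, z) {
  z <- rbind(z) # promote a bare K-vector to a 1 x K matrix
  stopifnot(length(dim(theta)) == 3L, ncol(z) == dim(theta)[2L])
  if (!all(is.finite(theta)) || !all(is.finite(z))) {
    stop("non-finite entries in theta or z")
  }
  a <- dim(theta)[1L]
  fm <- field_matrices(theta_to_mat(theta), z, a)
  log_pi <- fm$logits - fm$log_z[, rep(seq_len(fm$n_positions), each = a), drop = FALSE]
  pi_arr <- aperm(array(exp(log_pi), dim = c(nrow(z), a, fm$n_positions)), c(1L, 2L, 3L))
  structure(list(pi = pi_arr, log_omega = fm$log_z), class = "probability_field")
}

#' Total log-likelihood of an alignment under a probability field
#'
#' Returns `sum over (n,l) of log pi[n, codes[n,l], l]`, the categorical
#' log-likelihood of the observed symbols. Always non-positive. Accepts either
#' an `encoded_msa` or a one-hot array as the data argument.
#'
#' @param data An `encoded_msa` or an N x A x L one-hot array.
#' @param field A `probability_field` whose `pi` has matching N and L.
#' @return Scalar log-likelihood (natural log).
#' @export
log_likelihood <- function(data, field) {
  stopifnot(inherits(field, "probability_field"))
  p <- field$pi
  if (inherits(data, "encoded_msa")) {
    codes <- data$codes
  } else {
    stopifnot(length(dim(data)) == 3L, all(dim(data) == dim(p)))
    codes <- apply(data, c(1L, 3L), which.max)
  }
  if (nrow(codes) != dim(p)[1L] || ncol(codes) != dim(p)[3L]) {
    stop("data dimensions do not match the probability field")
  }
  idx <- cbind(
    rep.int(seq_len(nrow(codes)), ncol(codes)),
    as.vector(codes),
    rep(seq_len(ncol(codes)), each = nrow(codes))
  )
  sum(log(pmax(p[idx], 1e-300)))
}

#' Analytical gradients of the log-likelihood
#'
#' Gradients of the total log-likelihood with respect to the energies and the
#' latent embeddings, oriented so that gradient *ascent* increases the
#' likelihood: `dL/dtheta[a,k,l] = sum_n z[n,k] (pi - sigma)[n,a,l]` and
#' `dL/dz[n,k] = sum_{a,l} theta[a,k,l] (pi - sigma)[n,a,l]`.
#'
#' @param msa An `encoded_msa` (the observed symbols sigma).
#' @param theta Energy tensor A x K x L.
#' @param z Latent matrix N x K.
#' @return List with `grad_theta` (A x K x L) and `grad_z` (N x K).
#' @export
gradients <- function(msa, theta, z) {
  stopifnot(inherits(msa, "encoded_msa"))
  a <- dim(theta)[1L]
  stopifnot(a == length(msa$alphabet), dim(theta)[3L] == msa$length,
            nrow(z) == msa$n_sequences, ncol(z) == dim(theta)[2L])
  thmat <- theta_to_mat(theta)
  fm <- field_matrices(thmat, z, a)
  resid <- exp(fm$logits - fm$log_z[, rep(seq_len(fm$n_positions), each = a), drop = FALSE])
  oc <- obs_columns(msa$codes, a)
  flat <- cbind(rep.int(seq_len(nrow(resid)), ncol(oc)), as.vector(oc))
  resid[flat] <- resid[flat] - 1 # pi - sigma
  gt <- crossprod(z, resid)      # K x (A*L); note logits = -(z theta)
  gz <- resid %*% t(thmat)
  if (!all(is.finite(gt)) || !all(is.finite(gz))) {
    stop("non-finite gradient encountered")
  }
  list(
    grad_theta = mat_to_theta(gt, a, fm$n_positions),
    grad_z = gz
  )
}

#' Training configuration
#'
#' Bundles the optimizer and initialization settings for [fit_generalist()].
#' Defaults: adaptive per-parameter steps (Adam-style first/second moment
#' estimates) at base step 1e-2, at most 2000 iterations, convergence when the
#' relative log-likelihood change over a 10-iteration window drops below
#' `tolerance`, 10 restarts, uniform(-0.1, 0.1) initialization.
#'
#' @param k_dim Latent dimension K (positive integer).
#' @param max_iters Maximum optimizer iterations.
#' @param step_size Base step size for the adaptive optimizer.
#' @param tolerance Relative log-likelihood change declaring convergence.
#' @param n_restarts Number of independent restarts for [fit_restarts()].
#' @param init_scale Half-width of the uniform initialization for theta and z.
#' @param seed Integer seed; every random draw in fitting flows from it.
#' @return A `fit_config` list.
#' @export
fit_config <- function(k_dim, max_iters = 2000L, step_size = 1e-2,
                       tolerance = 1e-6, n_restarts = 10L,
                       init_scale = 0.1, seed = 1L) {
  stopifnot(k_dim >= 1L, max_iters >= 1L, step_size > 0, tolerance >= 0,
            n_restarts >= 1L, init_scale > 0)
  structure(
    list(
      k_dim = as.integer(k_dim), max_iters = as.integer(max_iters),
      step_size = step_size, tolerance = tolerance,
      n_restarts = as.integer(n_restarts), init_scale = init_scale,
      seed = as.integer(seed)
    ),
    class = "fit_config"
  )
}

# Run a computation with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Fit the model to an alignment by maximum likelihood
#'
#' Joint full-batch gradient ascent on the log-likelihood in (theta, z) from a
#' uniform(-init_scale, init_scale) start. Steps use Adam-style adaptive
#' scaling with a safeguard: a proposed step is accepted only if it does not
#' decrease the log-likelihood; otherwise the step size is halved and the step
#' retried, so the recorded trace is non-decreasing. Stops at `max_iters`,
#' when the relative improvement over a 10-iteration window falls below
#' `tolerance`, or when the safeguarded step size underflows. Deterministic
#' given `config$seed`.
#'
#' @param msa An `encoded_msa` with at least 2 sequences.
#' @param config A [fit_config()].
#' @return An object of class `generalist_model`: list with `theta`
#'   (A x K x L), `z` (N x K), `k_dim`, `alphabet`, and `fit_meta` (seed,
#'   iterations, final and initial log-likelihood, the accepted-step
#'   log-likelihood trace, convergence flag).
#' @export
fit_generalist <- function(msa, config) {
  stopifnot(inherits(msa, "encoded_msa"), inherits(config, "fit_config"))
  if (msa$n_sequences < 2L) stop("fitting requires at least 2 sequences")
  n <- msa$n_sequences
  l <- msa$length
  a <- length(msa$alphabet)
  k <- config$k_dim
  n_par <- k * (a * l + n)
  if (n_par >= n * l * (a - 1L)) {
    warning(sprintf(
      "model has %d free parameters for %d observed symbols: expect overfitting",
      n_par, n * l
    ))
  }

  init <- with_seed(config$seed, list(
    thmat = matrix(stats::runif(k * a * l, -config$init_scale, config$init_scale), k, a * l),
    z = matrix(stats::runif(n * k, -config$init_scale, config$init_scale), n, k)
  ))
  thmat <- init$thmat
  z <- init$z
  oc_flat <- cbind(
    rep.int(seq_len(n), l),
    as.vector(obs_columns(msa$codes, a))
  )

  eval_state <- function(thmat, z) {
    fm <- field_matrices(thmat, z, a, want_pi = TRUE)
    ll <- sum(fm$logits[oc_flat]) - sum(fm$log_z)
    list(fm = fm, ll = ll)
  }
  grad_from_fm <- function(fm, thmat, z) {
    resid <- fm$pi
    resid[oc_flat] <- resid[oc_flat] - 1
    list(gt = crossprod(z, resid), gz = resid %*% t(thmat))
  }

  st <- eval_state(thmat, z)
  if (!is.finite(st$ll)) stop("non-finite log-likelihood at initialization")
  ll_init <- st$ll
  trace <- numeric(config$max_iters + 1L)
  trace[1L] <- st$ll

  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m_t <- matrix(0, k, a * l); v_t <- m_t
  m_z <- matrix(0, n, k); v_z <- m_z
  lr <- config$step_size
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iters) {
    iter <- iter + 1L
    g <- grad_from_fm(st$fm, thmat, z)
    # ascent: parameters move along +gradient of the log-likelihood
    m_t <- b1 * m_t + (1 - b1) * g$gt; v_t <- b2 * v_t + (1 - b2) * g$gt^2
    m_z <- b1 * m_z + (1 - b1) * g$gz; v_z <- b2 * v_z + (1 - b2) * g$gz^2
    c1 <- 1 - b1^iter; c2 <- 1 - b2^iter
    step_t <- (m_t / c1) / (sqrt(v_t / c2) + eps)
    step_z <- (m_z / c1) / (sqrt(v_z / c2) + eps)
    # accept the proposed step only if it does not decrease the likelihood;
    # halve the step otherwise. If the adaptive direction fails outright,
    # retry along the raw gradient (always an ascent direction), so step-size
    # underflow certifies a stationary point rather than a bad direction.
    fallback <- FALSE
    stalled <- FALSE
    repeat {
      cand_t <- thmat + lr * step_t
      cand_z <- z + lr * step_z
      cand <- eval_state(cand_t, cand_z)
      if (is.nan(cand$ll)) stop(sprintf("fit diverged (NaN log-likelihood) at iteration %d", iter))
      if (cand$ll >= st$ll) {
        thmat <- cand_t; z <- cand_z; st <- cand
        lr <- min(lr * 1.1, config$step_size)
        break
      }
      lr <- lr / 2
      if (lr < config$step_size * 1e-10) {
        if (!fallback) {
          fallback <- TRUE
          gscale <- max(abs(g$gt), abs(g$gz), eps)
          step_t <- g$gt / gscale
          step_z <- g$gz / gscale
          lr <- config$step_size
        } else {
          stalled <- TRUE
          break
        }
      }
    }
    trace[iter + 1L] <- st$ll
    if (stalled) { converged <- TRUE; break }
    if (fallback) lr <- config$step_size
    if (iter >= 10L) {
      prev <- trace[iter - 9L]
      if (abs(st$ll - prev) < config$tolerance * abs(prev)) {
        converged <- TRUE
        break
      }
    }
  }
  trace <- trace[seq_len(iter + 1L)]

  structure(
    list(
      theta = mat_to_theta(thmat, a, l),
      z = z,
      k_dim = k,
      alphabet = msa$alphabet,
      fit_meta = list(
        seed = config$seed, iterations = iter,
        initial_ll = ll_init, final_ll = st$ll,
        ll_trace = trace, converged = converged,
        n_train = n, length = l,
        config = unclass(config)
      )
    ),
    class = "generalist_model"
  )
}

#' @export
print.generalist_model <- function(x, ...) {
  cat(sprintf(
    "generalist_model: K = %d, trained on %d sequences x %d positions\n  final log-likelihood %.2f after %d iterations (%s)\n",
    x$k_dim, nrow(x$z), dim(x$theta)[3L], x$fit_meta$final_ll,
    x$fit_meta$iterations,
    if (isTRUE(x$fit_meta$converged)) "converged" else "iteration cap reached"
  ))
  invisible(x)
}

#' Fit with multiple restarts and keep the best by the Delta-squared criterion
#'
#' Runs [fit_generalist()] `config$n_restarts` times from independent
#' initializations (seeds `config$seed + 1, ..., config$seed + n_restarts`),
#' scores each fitted model by the squared difference between mean
#' nearest-natural-neighbour distances of a generated ensemble and of the
#' training alignment ([delta_sq()]), and returns all runs plus the run with
#' the smallest score.
#'
#' @param msa An `encoded_msa`.
#' @param config A [fit_config()].
#' @param n_generated Size of the generated ensemble used for scoring;
#'   defaults to `min(N, 2000)`.
#' @return List with `runs` (list of `generalist_model`), `delta_sq` (numeric
#'   per run), and `best` (the model minimizing `delta_sq`).
#' @export
fit_restarts <- function(msa, config, n_generated = NULL) {
  stopifnot(inherits(config, "fit_config"))
  if (is.null(n_generated)) n_generated <- min(msa$n_sequences, 2000L)
  runs <- vector("list", config$n_restarts)
  d2 <- numeric(config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    runs[[r]] <- fit_generalist(msa, cfg_r)
    d2[r] <- delta_sq(runs[[r]], msa, n_generated = n_generated, seed = cfg_r$seed)
  }
  list(runs = runs, delta_sq = d2, best = runs[[which.min(d2)]])
}

#' Generate de novo sequences from a fitted model
#'
#' Draws `n_out` latent vectors by bootstrap (rows of the learned Z, sampled
#' with replacement), forms each draw's per-position categorical
#' probabilities, and samples every position independently. Sampling uses the
#' Gumbel-max construction on the logits, which is exact for categorical draws
#' and never forms normalized probabilities explicitly.
#'
#' @param model A fitted `generalist_model`.
#' @param n_out Number of sequences to generate (>= 1).
#' @param seed Integer seed.
#' @return An `encoded_msa` of `n_out` sequences of the training length, with
#'   ids `gen_0, gen_1, ...`.
#' @export
generate_sequences <- function(model, n_out, seed) {
  stopifnot(inherits(model, "generalist_model"))
  if (n_out < 1L) stop("n_out must be at least 1")
  a <- dim(model$theta)[1L]
  l <- dim(model$theta)[3L]
  thmat <- theta_to_mat(model$theta)
  with_seed(seed, {
    rows <- sample.int(nrow(model$z), n_out, replace = TRUE)
    zb <- model$z[rows, , drop = FALSE]
    logits <- -(zb %*% thmat)
    gumbel <- -log(-log(stats::runif(length(logits))))
    y <- logits + gumbel
    cols <- function(s) seq.int(s, by = a, length.out = l)
    best <- y[, cols(1L), drop = FALSE]
    codes <- matrix(1L, n_out, l)
    for (s in 2:a) {
      ys <- y[, cols(s), drop = FALSE]
      upd <- ys > best
      best[upd] <- ys[upd]
      codes[upd] <- s
    }
    msa_from_codes(codes, id_prefix = "gen")
  })
}

#' Highest-probability sequence at a latent point
#'
#' Positions are conditionally independent given the latent location, so the
#' model's most probable sequence at `z_point` is the per-position argmax of
#' the categorical probabilities — no search is needed. Ties are broken by the
#' lowest alphabet index, deterministically.
#'
#' @param model A fitted `generalist_model`.
#' @param z_point Latent vector of length K.
#' @return Integer codes of length L (1-based alphabet indices).
#' @export
optimal_sequence <- function(model, z_point) {
  stopifnot(inherits(model, "generalist_model"), length(z_point) == model$k_dim)
  a <- dim(model$theta)[1L]
  l <- dim(model$theta)[3L]
  logits <- -(matrix(z_point, 1L) %*% theta_to_mat(model$theta))
  lm <- matrix(logits, nrow = a, ncol = l) # column l = logits of position l
  apply(lm, 2L, which.max)                 # which.max takes the first maximum
}

#' Log-probability of a single sequence at a latent point
#'
#' @param model A fitted `generalist_model`.
#' @param codes Integer codes of length L.
#' @param z_point Latent vector of length K.
#' @return Scalar natural-log probability of the sequence given `z_point`.
#' @export
sequence_log_prob <- function(model, codes, z_point) {
  stopifnot(inherits(model, "generalist_model"),
            length(codes) == dim(model$theta)[3L])
  a <- dim(model$theta)[1L]
  fm <- field_matrices(theta_to_mat(model$theta), matrix(z_point, 1L), a)
  oc <- codes + a * (seq_along(codes) - 1L)
  sum(fm$logits[1L, oc]) - sum(fm$log_z)
}

#' Greedy single-substitution hill climb on a sequence score
#'
#' Generic local search over sequences for any black-box log-probability:
#' proposes single-position substitutions in random order and accepts a
#' proposal only if the score strictly increases. A sweep evaluates all
#' L x (A-1) substitutions of the current sequence; the climb stops when a
#' full sweep accepts nothing or after `max_sweeps` sweeps. The returned score
#' never falls below the starting score.
#'
#' @param score Function mapping integer codes (length L) to a finite
#'   log-probability.
#' @param start Integer codes of the starting sequence.
#' @param max_sweeps Maximum number of full proposal sweeps.
#' @param seed Integer seed for the proposal order.
#' @param n_symbols Alphabet size (default 21).
#' @return List with `codes` (the local optimum), `trace` (scores after the
#'   start and each accepted move, strictly increasing), and `n_accepted`.
#' @export
greedy_hill_climb <- function(score, start, max_sweeps = 50L, seed = 1L,
                              n_symbols = length(msa_alphabet())) {
  cur <- as.integer(start)
  s_cur <- score(cur)
  if (!is.finite(s_cur)) stop("score is not finite at the starting sequence")
  trace <- s_cur
  with_seed(seed, {
    for (sweep in seq_len(max_sweeps)) {
      accepted <- FALSE
      props <- expand.grid(pos = seq_along(cur), sym = seq_len(n_symbols))
      props <- props[sample.int(nrow(props)), , drop = FALSE]
      for (i in seq_len(nrow(props))) {
        pos <- props$pos[i]; sym <- props$sym[i]
        if (sym == cur[pos]) next
        cand <- cur
        cand[pos] <- sym
        s_cand <- score(cand)
        if (!is.finite(s_cand)) stop("score returned a non-finite value")
        if (s_cand > s_cur) {
          cur <- cand; s_cur <- s_cand
          trace <- c(trace, s_cur)
          accepted <- TRUE
        }
      }
      if (!accepted) break
    }
  })
  list(codes = cur, trace = trace, n_accepted = length(trace) - 1L)
}

#' Per-position log10 fold improvement between two sequences
#'
#' `(log10 P(end) - log10 P(start)) / L` under a log-probability score: the
#' average order-of-magnitude gain in probability per aligned position, the
#' natural scale for comparing a local optimum with the natural sequence it
#' started from.
#'
#' @param score Function mapping integer codes to natural-log probability.
#' @param start,end Integer code vectors of equal length L.
#' @return Scalar, in log10 units per position.
#' @export
per_position_log_fold_improvement <- function(score, start, end) {
  if (length(start) != length(end)) stop("sequences differ in length")
  (score(end) - score(start)) / (length(start) * log(10))
}

#' Embed new sequences into a trained model's latent space
#'
#' Fits latent vectors for sequences not seen in training, holding theta
#' frozen and ascending the likelihood in z alone with the same safeguarded
#' adaptive optimizer used by [fit_generalist()]. This is a convenience
#' extension beyond the core training/generation pipeline.
#'
#' @param model A fitted `generalist_model`.
#' @param msa An `encoded_msa` of the training length.
#' @param max_iters,step_size,tolerance,seed Optimizer settings as in
#'   [fit_config()].
#' @return M x K latent matrix for the new sequences.
#' @export
embed_sequences <- function(model, msa, max_iters = 500L, step_size = 1e-2,
                            tolerance = 1e-6, seed = 1L) {
  stopifnot(inherits(model, "generalist_model"), inherits(msa, "encoded_msa"),
            msa$length == dim(model$theta)[3L])
  a <- dim(model$theta)[1L]
  k <- model$k_dim
  m <- msa$n_sequences
  l <- msa$length
  thmat <- theta_to_mat(model$theta)
  oc_flat <- cbind(rep.int(seq_len(m), l), as.vector(obs_columns(msa$codes, a)))
  z <- with_seed(seed, matrix(stats::runif(m * k, -0.1, 0.1), m, k))
  ll_of <- function(z) {
    fm <- field_matrices(thmat, z, a)
    list(fm = fm, ll = sum(fm$logits[oc_flat]) - sum(fm$log_z))
  }
  st <- ll_of(z)
  mz <- matrix(0, m, k); vz <- mz
  lr <- step_size
  prev_win <- st$ll
  for (iter in seq_len(max_iters)) {
    resid <- exp(st$fm$logits - st$fm$log_z[, rep(seq_len(l), each = a), drop = FALSE])
    resid[oc_flat] <- resid[oc_flat] - 1
    gz <- resid %*% t(thmat)
    mz <- 0.9 * mz + 0.1 * gz; vz <- 0.999 * vz + 0.001 * gz^2
    step <- (mz / (1 - 0.9^iter)) / (sqrt(vz / (1 - 0.999^iter)) + 1e-8)
    repeat {
      cand_z <- z + lr * step
      cand <- ll_of(cand_z)
      if (cand$ll >= st$ll) { z <- cand_z; st <- cand; lr <- min(lr * 1.1, step_size); break }
      lr <- lr / 2
      if (lr < step_size * 1e-10) break
    }
    if (lr < step_size * 1e-10) break
    if (iter %% 10L == 0L) {
      if (abs(st$ll - prev_win) < tolerance * abs(prev_win)) break
      prev_win <- st$ll
    }
  }
  z
}

#' Save a fitted model to disk
#'
#' Serializes theta, Z, the alphabet, the fit configuration and metadata in a
#' versioned, platform-portable container (R's XDR serialization, so files
#' move safely across architectures).
#'
#' @param model A `generalist_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "generalist_model"))
  payload <- list(format = "generalist_model", format_version = 1L,
                  model = unclass(model))
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to a saved model file.
#' @return The `generalist_model`, identical to the object saved.
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("cannot read model file '%s': %s", path, conditionMessage(e)))
  })
  if (!is.list(payload) || !identical(payload$format, "generalist_model")) {
    stop(sprintf("'%s' is not a saved model file", path))
  }
  if (!identical(payload$format_version, 1L)) {
    stop(sprintf("unsupported model file version %s", payload$format_version))
  }
  structure(payload$model, class = "generalist_model")
}
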