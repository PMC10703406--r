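# Deterministic synthetic-alignment generators. These provide planted ground
# truth for every test surface: a known energy tensor and latent distribution
# from which alignments are sampled, so that recovery of frequencies,
# covariation, latent clusters and the under/overfit signature can be checked
# against a model whose truth is known exactly.

#' Create a planted generative model
#'
#' Draws a ground-truth energy tensor theta i.i.d. uniform(-theta_scale,
#' theta_scale) and fixes a latent distribution from which [sample_msa()]
#' draws embeddings: either a unit-variance normal centred at `z_center`
#' (`z_spec = "normal"`) or a 2-component spherical Gaussian mixture with
#' stated means, common standard deviation and weights. Deterministic given
#' `seed`.
#'
#' The defaults (`theta_scale = 2`, `z_center = 1`) emulate a protein-family
#' alignment with genuine site conservation: a nonzero latent mean gives every
#' energy entry a consistent sign across sequences, so each position acquires
#' preferred residues (typical consensus-residue frequency near 0.3 and
#' within-family nearest-neighbour distances near 0.45 at these settings),
#' while the unit latent spread produces higher-order covariation. A latent
#' distribution centred at zero would instead average every residue's energy
#' to zero and yield alignments with no conserved positions.
#'
#' @param length Alignment width L (>= 2).
#' @param k_true Latent dimension of the planted model (>= 1).
#' @param theta_scale Half-width of the uniform energy draw (> 0); 0 < scale
#'   << 1 approaches the uniform model.
#' @param z_spec Either the string `"normal"` or a list with `means`
#'   (2 x k_true matrix of component means), `sd` (scalar component standard
#'   deviation), `weights` (length 2, summing to 1).
#' @param z_center Mean of each latent coordinate under the `"normal"` spec.
#' @param seed Integer seed.
#' @return An object of class `planted_model`: list with `theta_true`,
#'   `k_true`, `z_spec`, `z_center`, `seed`, `alphabet`.
#' @export
make_planted_model <- function(length, k_true, theta_scale = 2.0,
                               z_spec = "normal", z_center = 1.0, seed = 1L) {
  stopifnot(length >= 2L, k_true >= 1L, theta_scale > 0)
  a <- base::length(msa_alphabet())
  if (is.list(z_spec)) {
    stopifnot(nrow(z_spec$means) == 2L, ncol(z_spec$means) == k_true,
              z_spec$sd > 0, base::length(z_spec$weights) == 2L,
              abs(sum(z_spec$weights) - 1) < 1e-12)
  } else {
    stopifnot(identical(z_spec, "normal"))
  }
  theta <- with_seed(seed, array(
    stats::runif(a * k_true * length, -theta_scale, theta_scale),
    dim = c(a, k_true, length)
  ))
  structure(
    list(theta_true = theta, k_true = as.integer(k_true), z_spec = z_spec,
         z_center = z_center, seed = as.integer(seed), alphabet = msa_alphabet()),
    class = "planted_model"
  )
}

#' Sample a synthetic alignment from a planted model
#'
#' Draws `n` latent vectors from the planted latent distribution, forms each
#' draw's per-position categorical probabilities under the planted energies,
#' and samples every position independently. The true latents (and, for a
#' mixture, the component labels) are returned so recovery can be scored.
#'
#' @param planted A `planted_model`.
#' @param n Number of sequences (>= 1).
#' @param seed Integer seed.
#' @return List with `msa` (an `encoded_msa`), `z` (n x k_true matrix of the
#'   latents actually used), and `labels` (component labels, all 1 for the
#'   normal spec).
#' @export
sample_msa <- function(planted, n, seed = 1L) {
  stopifnot(inherits(planted, "planted_model"), n >= 1L)
  k <- planted$k_true
  with_seed(seed, {
    if (is.list(planted$z_spec)) {
      labels <- sample.int(2L, n, replace = TRUE, prob = planted$z_spec$weights)
      z <- planted$z_spec$means[labels, , drop = FALSE] +
        matrix(stats::rnorm(n * k, sd = planted$z_spec$sd), n, k)
    } else {
      labels <- rep(1L, n)
      z <- matrix(stats::rnorm(n * k, mean = planted$z_center), n, k)
    }
    a <- dim(planted$theta_true)[1L]
    l <- dim(planted$theta_true)[3L]
    logits <- -(z %*% theta_to_mat(planted$theta_true))
    gumbel <- -log(-log(stats::runif(base::length(logits))))
    y <- logits + gumbel
    cols <- function(s) seq.int(s, by = a, length.out = l)
    best <- y[, cols(1L), drop = FALSE]
    codes <- matrix(1L, n, l)
    for (s in 2:a) {
      ys <- y[, cols(s), drop = FALSE]
      upd <- ys > best
      best[upd] <- ys[upd]
      codes[upd] <- s
    }
    list(msa = msa_from_codes(codes, id_prefix = "synth"), z = z, labels = labels)
  })
}

#' Degenerate and edge-case alignments for tests
#'
#' A named set of small alignments exercising boundary behaviour: all
#' sequences identical, all-gap, an alignment containing a duplicated
#' sequence, a single-column alignment, a two-sequence alignment, and a fully
#' random alignment (uniform over the 21 symbols).
#'
#' @param seed Integer seed for the random member.
#' @return Named list of `encoded_msa` objects.
#' @export
edge_case_alignments <- function(seed = 1L) {
  a <- length(msa_alphabet())
  rand <- with_seed(seed, matrix(sample.int(a, 500L * 30L, replace = TRUE), 500L, 30L))
  list(
    all_identical = msa_from_codes(matrix(rep(c(1L, 5L, 9L, 21L, 2L), each = 10L),
                                          nrow = 10L, ncol = 5L, byrow = FALSE)),
    all_gap = msa_from_codes(matrix(a, 8L, 6L)),
    duplicated_pair = msa_from_codes(rbind(
      c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L),
      c(5L, 6L, 7L, 8L), c(9L, 10L, 11L, 12L)
    )),
    single_column = msa_from_codes(matrix(c(1L, 2L, 3L, 1L, 2L), ncol = 1L)),
    two_sequences = msa_from_codes(rbind(c(1L, 1L, 1L), c(21L, 21L, 21L))),
    fully_random = msa_from_codes(rand)
  )
}
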