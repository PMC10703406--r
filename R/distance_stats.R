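# Ensemble distance-distribution diagnostics, reported as survival curves:
# for a set of fractional Hamming distances, the fraction that are >= h on
# the native grid h in {0, 1/L, ..., 1}. Three kinds are compared between a
# generated and a natural ensemble: distances between random pairs within an
# ensemble, within-ensemble nearest-neighbour distances, and distances to the
# nearest natural sequence.

distance_profile <- function(kind, distances, width) {
  grid <- seq(0, 1, by = 1 / width)
  surv <- vapply(grid, function(h) mean(distances >= h - 1e-12), numeric(1L))
  structure(
    list(kind = kind, distances = distances,
         survival = data.frame(h = grid, fraction = surv)),
    class = "distance_profile"
  )
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf(
    "distance_profile (%s): %d distances, mean %.4f, median %.4f\n",
    x$kind, length(x$distances), mean(x$distances), stats::median(x$distances)
  ))
  invisible(x)
}

#' Distances between random sequence pairs within an ensemble
#'
#' Samples unordered pairs of distinct sequences uniformly and records their
#' fractional Hamming distances. When the ensemble has at most `n_pairs`
#' distinct pairs, all of them are enumerated exactly instead.
#'
#' @param msa An `encoded_msa` with at least 2 sequences.
#' @param n_pairs Pair budget (default 100000).
#' @param seed Integer seed (unused in the exhaustive case).
#' @return A `distance_profile` of kind `"random_pair"`.
#' @export
random_pair_distances <- function(msa, n_pairs = 100000L, seed = 1L) {
  stopifnot(inherits(msa, "encoded_msa"), msa$n_sequences >= 2L)
  n <- msa$n_sequences
  total <- n * (n - 1) / 2
  if (total <= n_pairs) {
    d <- cross_hamming(msa$codes, msa$codes)
    dist <- d[upper.tri(d)]
  } else {
    dist <- with_seed(seed, {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      while (any(i == j)) {
        eq <- which(i == j)
        j[eq] <- sample.int(n, length(eq), replace = TRUE)
      }
      rowMeans(msa$codes[i, , drop = FALSE] != msa$codes[j, , drop = FALSE])
    })
  }
  distance_profile("random_pair", dist, msa$length)
}

#' Within-ensemble nearest-neighbour distance distribution
#'
#' Each sequence's fractional Hamming distance to its closest neighbour in
#' the same ensemble (itself excluded). Shares the exact all-pairs kernel of
#' [hmin_to_reference()].
#'
#' @param msa An `encoded_msa` with at least 2 sequences.
#' @return A `distance_profile` of kind `"nn_within"`.
#' @export
nn_within <- function(msa) {
  h <- hmin_to_reference(msa, msa, exclude_self = TRUE)
  distance_profile("nn_within", h$values, msa$length)
}

#' Nearest-natural-neighbour distance distribution
#'
#' Each query sequence's fractional Hamming distance to the closest sequence
#' of the natural ensemble.
#'
#' @param query,natural `encoded_msa` objects of equal width.
#' @return A `distance_profile` of kind `"nn_to_natural"`.
#' @export
nn_to_natural <- function(query, natural) {
  if (query$length != natural$length) stop("alignment widths differ")
  h <- hmin_to_reference(query, natural, exclude_self = FALSE)
  distance_profile("nn_to_natural", h$values, query$length)
}

#' Kolmogorov-Smirnov distance between two survival curves
#'
#' The maximum absolute difference between the two survival curves on their
#' shared grid; 0 for identical profiles, 1 for profiles concentrated at
#' opposite ends.
#'
#' @param a,b `distance_profile` objects of the same kind and grid.
#' @return Scalar in [0, 1].
#' @export
profile_distance <- function(a, b) {
  stopifnot(inherits(a, "distance_profile"), inherits(b, "distance_profile"))
  if (!identical(a$kind, b$kind)) stop("profiles are of different kinds")
  if (!isTRUE(all.equal(a$survival$h, b$survival$h))) {
    stop("profiles are on different grids")
  }
  max(abs(a$survival$fraction - b$survival$fraction))
}
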