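# Summary-statistic comparisons between two aligned ensembles: positional
# frequencies, central moments (cumulants) of orders 2-4 over one-hot
# indicators, and the r20 higher-order co-occurrence metric.
#
# The gap participates as an ordinary 21st symbol throughout, mirroring its
# role in the model.

#' Per-site symbol frequencies
#'
#' @param msa An `encoded_msa`.
#' @return A x L matrix with entry (a, l) the fraction of sequences carrying
#'   symbol a at position l; columns sum to 1 exactly. Rows are named by the
#'   alphabet. No pseudocounts.
#' @export
site_frequencies <- function(msa) {
  stopifnot(inherits(msa, "encoded_msa"))
  a <- length(msa$alphabet)
  counts <- apply(msa$codes, 2L, tabulate, nbins = a)
  f <- counts / msa$n_sequences
  rownames(f) <- msa$alphabet
  f
}

#' Central moment of one-hot indicators at chosen (position, symbol) sites
#'
#' For sites `(l_1, a_1), ..., (l_m, a_m)` with distinct positions, returns
#' `E[ prod_i (x_i - E[x_i]) ]` over sequences, where `x_i` is the indicator
#' of symbol `a_i` at position `l_i`. Order 2 is the covariance
#' `f_ab - f_a f_b`; orders 3 and 4 are the corresponding higher central
#' moments.
#'
#' @param msa An `encoded_msa`.
#' @param sites Two-column matrix (or list of length-2 vectors) of
#'   (position, symbol) pairs; exactly `order` rows, positions all distinct.
#' @param order Moment order, 2, 3 or 4.
#' @return Scalar central moment.
#' @export
central_moment <- function(msa, sites, order) {
  stopifnot(inherits(msa, "encoded_msa"), order %in% 2:4)
  if (is.list(sites)) sites <- do.call(rbind, sites)
  sites <- matrix(as.integer(sites), ncol = 2L)
  if (nrow(sites) != order) stop("sites must have exactly `order` rows")
  if (anyDuplicated(sites[, 1L])) stop("positions in a moment must be distinct")
  x <- rep(1, msa$n_sequences)
  for (i in seq_len(order)) {
    ind <- as.numeric(msa$codes[, sites[i, 1L]] == sites[i, 2L])
    x <- x * (ind - mean(ind))
  }
  mean(x)
}

# Batch central moments. pos/sym are n_combos x m matrices; returns one
# moment per combo. Works on raw codes, centering indicators within `rows`
# (all rows by default), chunked so no N x n_combos matrix is materialized.
moments_batch <- function(codes, pos, sym, rows = seq_len(nrow(codes)),
                          chunk = 2000L) {
  n_comb <- nrow(pos)
  m <- ncol(pos)
  sub <- codes[rows, , drop = FALSE]
  out <- numeric(n_comb)
  for (s in seq.int(1L, n_comb, by = chunk)) {
    e <- min(s + chunk - 1L, n_comb)
    idx <- s:e
    acc <- matrix(1, nrow(sub), length(idx))
    for (i in seq_len(m)) {
      ind <- sub[, pos[idx, i], drop = FALSE] ==
        matrix(sym[idx, i], nrow(sub), length(idx), byrow = TRUE)
      storage.mode(ind) <- "double"
      acc <- acc * scale(ind, center = TRUE, scale = FALSE)
    }
    out[idx] <- colMeans(acc)
  }
  out
}

# Draw n_samples (position-set, symbol-set) combinations of a given order.
# Positions are distinct within a combination; each position's symbol is
# drawn uniformly among symbols with nonzero frequency in `freq_ref`.
sample_combos <- function(freq_ref, order, n_samples) {
  l <- ncol(freq_ref)
  if (l < order) stop("alignment has fewer positions than the moment order")
  pos <- t(replicate(n_samples, sample.int(l, order)))
  if (order == 1L) pos <- matrix(pos, ncol = 1L)
  sym <- matrix(0L, n_samples, order)
  present <- apply(freq_ref > 0, 2L, which) # list per position
  if (is.matrix(present)) present <- asplit(present, 2L)
  for (i in seq_len(order)) {
    sym[, i] <- vapply(
      pos[, i],
      function(p) {
        cand <- present[[p]]
        cand[sample.int(length(cand), 1L)]
      },
      integer(1L)
    )
  }
  list(pos = pos, sym = sym)
}

#' Compare moment spectra of two ensembles at one order
#'
#' Order 1 compares all A x L positional frequencies. For orders 2-4,
#' `n_samples` random (position-set, symbol-set) combinations are drawn once —
#' positions distinct, symbols restricted to those actually observed at that
#' position in the natural ensemble — and the central moment of each
#' combination is computed in both ensembles. Reports the Pearson correlation
#' and the least-squares slope of generated-vs-natural values; a slope below 1
#' means the generated ensemble under-predicts the statistic.
#'
#' @param natural,generated `encoded_msa` objects of equal width.
#' @param order Moment order 1-4.
#' @param n_samples Number of sampled combinations for orders >= 2
#'   (default 50000).
#' @param seed Integer seed for combination sampling.
#' @return An object of class `moment_comparison`: list with `order`, `pairs`
#'   (data.frame of natural/generated values), `pearson_r`, `best_fit_slope`.
#' @export
moment_comparison <- function(natural, generated, order, n_samples = 50000L,
                              seed = 1L) {
  stopifnot(inherits(natural, "encoded_msa"), inherits(generated, "encoded_msa"),
            order %in% 1:4)
  if (natural$length != generated$length) stop("alignment widths differ")
  if (order == 1L) {
    x <- as.vector(site_frequencies(natural))
    y <- as.vector(site_frequencies(generated))
  } else {
    freq_nat <- site_frequencies(natural)
    cmb <- with_seed(seed, sample_combos(freq_nat, order, n_samples))
    x <- moments_batch(natural$codes, cmb$pos, cmb$sym)
    y <- moments_batch(generated$codes, cmb$pos, cmb$sym)
  }
  if (stats::sd(x) == 0) {
    stop("all natural values are equal: correlation and slope are undefined")
  }
  slope <- stats::cov(x, y) / stats::var(x)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  structure(
    list(
      order = order,
      pairs = data.frame(natural = x, generated = y),
      pearson_r = r,
      best_fit_slope = slope
    ),
    class = "moment_comparison"
  )
}

#' @export
print.moment_comparison <- function(x, ...) {
  cat(sprintf(
    "moment comparison (order %d, %d combinations): Pearson r = %.4f, slope = %.4f\n",
    x$order, nrow(x$pairs), x$pearson_r, x$best_fit_slope
  ))
  invisible(x)
}

# numeric key encoding the symbols of `codes` at `pos` with the first
# position most significant; ascending key order is lexicographic in the
# alphabet encoding. Exact for order <= 11 (21^11 < 2^53).
combo_keys <- function(codes, pos) {
  m <- length(pos)
  base <- 21
  key <- numeric(nrow(codes))
  for (i in seq_len(m)) key <- key + codes[, pos[i]] * base^(m - i)
  key
}

#' The r20 higher-order co-occurrence curve
#'
#' For each order n, repeatedly draws n distinct positions, ranks the joint
#' symbol strings observed there by natural-ensemble frequency (ties broken
#' deterministically by the encoded string), keeps the `top_n` most frequent,
#' and Pearson-correlates their frequencies between the two ensembles. The
#' per-order mean over `n_sets` position sets is reported. Restricting to the
#' most frequent strings keeps the statistic robust to sampling noise at high
#' orders, where almost all strings are rare. Sets with fewer than 2 distinct
#' string frequencies in the natural ensemble are skipped (logged); a set
#' whose generated frequencies are all equal scores r = 0 (no linear
#' association).
#'
#' @param natural,generated `encoded_msa` objects of equal width.
#' @param orders Integer vector of string orders (default 2:10).
#' @param top_n Number of top strings per position set (default 20).
#' @param n_sets Position sets per order (default 500).
#' @param seed Integer seed.
#' @return An object of class `r20_curve`: list with `orders`, `mean_r`,
#'   `top_n`, `n_sets`, `n_skipped` (per order).
#' @export
r20_curve <- function(natural, generated, orders = 2:10, top_n = 20L,
                      n_sets = 500L, seed = 1L) {
  stopifnot(inherits(natural, "encoded_msa"), inherits(generated, "encoded_msa"))
  if (natural$length != generated$length) stop("alignment widths differ")
  l <- natural$length
  mean_r <- rep(NA_real_, length(orders))
  skipped <- integer(length(orders))
  with_seed(seed, {
    for (oi in seq_along(orders)) {
      m <- orders[oi]
      if (l < m) stop(sprintf("order %d exceeds alignment width %d", m, l))
      rs <- numeric(0L)
      for (set in seq_len(n_sets)) {
        pos <- sample.int(l, m)
        key_nat <- combo_keys(natural$codes, pos)
        tab <- sort(table(key_nat), decreasing = TRUE)
        # stable ordering: frequency desc, then encoded string asc
        keys <- as.numeric(names(tab))
        ord <- order(-as.integer(tab), keys)
        keep <- keys[ord][seq_len(min(top_n, length(keys)))]
        f_nat <- as.integer(tab)[ord][seq_along(keep)] / natural$n_sequences
        if (length(unique(f_nat)) < 2L) {
          skipped[oi] <- skipped[oi] + 1L
          next
        }
        key_gen <- combo_keys(generated$codes, pos)
        f_gen <- vapply(keep, function(k) sum(key_gen == k), numeric(1L)) /
          generated$n_sequences
        rs <- c(rs, if (stats::sd(f_gen) == 0) 0 else stats::cor(f_nat, f_gen))
      }
      if (skipped[oi] > 0L) {
        message(sprintf("order %d: %d position set(s) skipped (degenerate natural frequencies)",
                        m, skipped[oi]))
      }
      if (length(rs)) mean_r[oi] <- mean(rs)
    }
  })
  structure(
    list(orders = orders, mean_r = mean_r, top_n = top_n,
         n_sets = n_sets, n_skipped = skipped),
    class = "r20_curve"
  )
}

#' @export
print.r20_curve <- function(x, ...) {
  cat(sprintf("r20 curve (top %d strings, %d sets per order)\n", x$top_n, x$n_sets))
  print(data.frame(order = x$orders, mean_r = x$mean_r))
  invisible(x)
}
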