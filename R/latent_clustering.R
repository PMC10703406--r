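# Clustering of the latent embeddings: full-covariance Gaussian mixtures
# fitted by EM (engine: mclust), stability-based choice of the number of
# components via a pair-counting Jaccard index over repeated fits, and a
# contrast of higher-order sequence statistics between two latent clusters
# against size-matched random partitions.

# Random hard-assignment initialization: n_components distinct data rows act
# as centers, points join their nearest center. Guarantees every component
# starts non-empty.
random_init_labels <- function(z, n_components) {
  centers <- z[sample.int(nrow(z), n_components), , drop = FALSE]
  d2 <- outer(rowSums(z^2), rep(1, n_components)) -
    2 * z %*% t(centers) +
    outer(rep(1, nrow(z)), rowSums(centers^2))
  cl <- max.col(-d2, ties.method = "first")
  for (g in seq_len(n_components)) {
    if (!any(cl == g)) cl[which.max(d2[, cl[1L]])] <- g
  }
  cl
}

#' Fit a Gaussian mixture to latent embeddings
#'
#' Full-covariance Gaussian mixture fitted by expectation-maximization, with
#' 5 random restarts (random nearest-center hard assignments seed the first
#' M-step); the restart with the highest log-likelihood is kept and each
#' sequence is labelled with its maximum-posterior component. Deterministic
#' given `seed`.
#'
#' @param z N x K latent matrix.
#' @param n_components Number of mixture components (1 <= G < N).
#' @param seed Integer seed.
#' @param n_restarts EM restarts (default 5).
#' @param max_iter,tol EM iteration cap and relative tolerance.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (1-based component per row), `n_components`, `sizes`, and `gmm_meta`
#'   (seed, converged flag, log-likelihood).
#' @export
fit_gmm <- function(z, n_components, seed = 1L, n_restarts = 5L,
                    max_iter = 500L, tol = 1e-4) {
  z <- as.matrix(z)
  stopifnot(nrow(z) > n_components, n_components >= 1L)
  if (n_components == 1L) {
    return(structure(
      list(labels = rep(1L, nrow(z)), n_components = 1L, sizes = nrow(z),
           gmm_meta = list(seed = seed, converged = TRUE, loglik = NA_real_)),
      class = "cluster_assignment"
    ))
  }
  ctrl <- mclust::emControl(itmax = max_iter, tol = tol)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- mclust::unmap(random_init_labels(z, n_components))
      fit <- tryCatch(
        suppressWarnings(
          if (ncol(z) == 1L) {
            mclust::meV(data = as.vector(z), z = init, control = ctrl)
          } else {
            mclust::meVVV(data = z, z = init, control = ctrl)
          }
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best)) {
    stop("EM failed in every restart (degenerate covariance?)")
  }
  labels <- max.col(best$z, ties.method = "first")
  structure(
    list(
      labels = labels,
      n_components = as.integer(n_components),
      sizes = tabulate(labels, nbins = n_components),
      gmm_meta = list(
        seed = seed,
        converged = !is.null(attr(best, "returnCode")) &&
          attr(best, "returnCode") >= 0 || is.finite(best$loglik),
        loglik = best$loglik
      )
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: %d components, sizes %s\n",
    x$n_components, paste(x$sizes, collapse = ", ")
  ))
  invisible(x)
}

#' Pair-counting Jaccard similarity of two cluster assignments
#'
#' Over all unordered pairs of sequences, the number co-clustered in both
#' assignments divided by the number co-clustered in at least one. Invariant
#' to label permutation; 1 iff the partitions coincide. Two all-singleton
#' partitions (no co-clustered pairs anywhere) coincide and score 1.
#'
#' @param a,b `cluster_assignment` objects (or bare label vectors) over the
#'   same N sequences.
#' @return Scalar in [0, 1].
#' @export
assignment_jaccard <- function(a, b) {
  la <- if (inherits(a, "cluster_assignment")) a$labels else as.integer(a)
  lb <- if (inherits(b, "cluster_assignment")) b$labels else as.integer(b)
  if (length(la) != length(lb)) stop("assignments cover different numbers of sequences")
  ct <- table(la, lb)
  pairs <- function(x) sum(x * (x - 1) / 2)
  both <- pairs(ct)
  in_a <- pairs(rowSums(ct))
  in_b <- pairs(colSums(ct))
  union <- in_a + in_b - both
  if (union == 0) 1 else both / union
}

#' Choose the number of mixture components by Jaccard stability
#'
#' For each candidate count, fits `n_iterations` pairs of mixtures with
#' independent seeds and records the pair-counting Jaccard similarity of
#' their assignments; a stable component count yields reproducible
#' partitions, hence Jaccard near 1. The chosen count has the highest median
#' Jaccard, ties going to the smaller count. The one-component partition is
#' trivially identical across fits, so a candidate of 1 is reported (Jaccard
#' identically 1) but never selected unless it is the only candidate:
#' stability carries no information about it.
#'
#' @param z N x K latent matrix.
#' @param candidate_ns Integer vector of candidate component counts.
#' @param n_iterations Fit pairs per candidate (default 20).
#' @param seed Integer seed.
#' @return An object of class `stability_report`: list with `candidate_ns`,
#'   `jaccard_samples` (list of numeric vectors per candidate), `chosen_n`.
#' @export
select_n_components <- function(z, candidate_ns, n_iterations = 20L, seed = 1L) {
  stopifnot(length(candidate_ns) >= 1L, all(candidate_ns >= 1L))
  samples <- vector("list", length(candidate_ns))
  names(samples) <- as.character(candidate_ns)
  for (i in seq_along(candidate_ns)) {
    g <- candidate_ns[i]
    js <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      s1 <- seed + 1000L * i + 2L * it
      s2 <- s1 + 1L
      js[it] <- assignment_jaccard(
        fit_gmm(z, g, seed = s1),
        fit_gmm(z, g, seed = s2)
      )
    }
    samples[[i]] <- js
  }
  med <- vapply(samples, stats::median, numeric(1L))
  eligible <- candidate_ns > 1L
  if (!any(eligible)) eligible <- rep(TRUE, length(candidate_ns))
  med_sel <- replace(med, !eligible, -Inf)
  ord <- order(-med_sel, candidate_ns)
  chosen <- candidate_ns[ord[1L]]
  structure(
    list(candidate_ns = candidate_ns, jaccard_samples = samples,
         median_jaccard = med, chosen_n = as.integer(chosen)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("component-count stability (pair-counting Jaccard over repeated EM fits)\n")
  print(data.frame(n_components = x$candidate_ns, median_jaccard = x$median_jaccard))
  cat(sprintf("chosen: %d components\n", x$chosen_n))
  invisible(x)
}

#' Contrast higher-order statistics between two latent clusters
#'
#' Splits the alignment by a 2-cluster assignment and, for each moment order,
#' computes the same sampled moment vector (order 1: all positional
#' frequencies) separately within each cluster, then Pearson-correlates the
#' two clusters' vectors. The observed correlations are compared with a null
#' ensemble of `n_null` random partitions with identical cluster sizes: if
#' the latent clusters carry distinct covariation structure, the observed
#' cross-cluster correlation falls below the null at orders >= 2.
#'
#' @param msa An `encoded_msa`.
#' @param labels A 2-component `cluster_assignment` (or label vector), each
#'   cluster of size >= 2.
#' @param orders Moment orders to contrast (subset of 1:4).
#' @param n_samples Sampled combinations per order >= 2 (default 1000).
#' @param n_null Random partitions in the null (default 100).
#' @param seed Integer seed.
#' @return An object of class `cluster_contrast`: list with `orders`,
#'   `observed_r`, `null_r` (n_null x length(orders) matrix), `null_mean`,
#'   `null_sd`.
#' @export
cluster_statistic_contrast <- function(msa, labels, orders = 1:4,
                                       n_samples = 1000L, n_null = 100L,
                                       seed = 1L) {
  stopifnot(inherits(msa, "encoded_msa"), all(orders %in% 1:4))
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else as.integer(labels)
  if (length(lab) != msa$n_sequences) stop("labels do not match the alignment")
  groups <- sort(unique(lab))
  if (length(groups) != 2L) stop("exactly 2 clusters are required")
  if (any(tabulate(match(lab, groups)) < 2L)) stop("each cluster needs at least 2 sequences")

  a <- length(msa$alphabet)
  freq_all <- site_frequencies(msa)
  combos <- with_seed(seed, lapply(orders, function(m) {
    if (m == 1L) NULL else sample_combos(freq_all, m, n_samples)
  }))

  r_of_partition <- function(lab_vec) {
    r1 <- lab_vec == groups[1L]
    vapply(seq_along(orders), function(oi) {
      m <- orders[oi]
      if (m == 1L) {
        x <- as.vector(apply(msa$codes[r1, , drop = FALSE], 2L, tabulate, nbins = a) / sum(r1))
        y <- as.vector(apply(msa$codes[!r1, , drop = FALSE], 2L, tabulate, nbins = a) / sum(!r1))
      } else {
        cmb <- combos[[oi]]
        x <- moments_batch(msa$codes, cmb$pos, cmb$sym, rows = which(r1))
        y <- moments_batch(msa$codes, cmb$pos, cmb$sym, rows = which(!r1))
      }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
    }, numeric(1L))
  }

  observed <- r_of_partition(lab)
  null_r <- with_seed(seed + 1L, {
    t(vapply(seq_len(n_null), function(i) r_of_partition(sample(lab)),
             numeric(length(orders))))
  })
  structure(
    list(
      orders = orders, observed_r = observed, null_r = null_r,
      null_mean = colMeans(null_r, na.rm = TRUE),
      null_sd = apply(null_r, 2L, stats::sd, na.rm = TRUE)
    ),
    class = "cluster_contrast"
  )
}

#' @export
print.cluster_contrast <- function(x, ...) {
  cat("cluster-vs-null contrast of moment correlations\n")
  print(data.frame(order = x$orders, observed_r = x$observed_r,
                   null_mean = x$null_mean, null_sd = x$null_sd))
  invisible(x)
}
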