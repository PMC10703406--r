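# Latent-dimension selection by matching nearest-neighbour distance
# statistics between generated and natural ensembles.
#
# The single distance kernel below (cross_hamming / hmin_to_reference) also
# backs the ensemble distance-distribution diagnostics, so every module
# measures sequence similarity identically: fractional Hamming distance with
# the gap counted as an ordinary 21st symbol.

#' Fractional Hamming distance between two sequences
#'
#' Fraction of aligned positions at which the integer codes differ; the gap
#' is an ordinary symbol, so gap-vs-residue counts as a mismatch.
#'
#' @param seq_a,seq_b Integer code vectors of equal length.
#' @return Scalar in [0, 1].
#' @export
fractional_hamming <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b)) stop("sequences differ in length")
  mean(seq_a != seq_b)
}

# Full Nq x Nr fractional Hamming matrix via per-symbol match counting:
# matches(i,j) = sum_a <1[q_i == a], 1[r_j == a]>, one BLAS product per
# symbol. Queries are processed in row blocks to bound memory.
cross_hamming <- function(qcodes, rcodes, block = 1024L) {
  l <- ncol(qcodes)
  stopifnot(ncol(rcodes) == l)
  a_max <- max(max(qcodes), max(rcodes))
  out <- matrix(0, nrow(qcodes), nrow(rcodes))
  starts <- seq.int(1L, nrow(qcodes), by = block)
  for (s in starts) {
    e <- min(s + block - 1L, nrow(qcodes))
    qb <- qcodes[s:e, , drop = FALSE]
    matches <- matrix(0, nrow(qb), nrow(rcodes))
    for (a in seq_len(a_max)) {
      qa <- qb == a
      if (!any(qa)) next
      storage.mode(qa) <- "double"
      ra <- rcodes == a
      storage.mode(ra) <- "double"
      matches <- matches + tcrossprod(qa, ra)
    }
    out[s:e, ] <- 1 - matches / l
  }
  out
}

#' Nearest-neighbour distances from queries to a reference ensemble
#'
#' For each query sequence, the minimum fractional Hamming distance to any
#' reference sequence (H_min). With `exclude_self = TRUE` the two ensembles
#' must be the same object and each sequence's own row is skipped, giving the
#' within-ensemble nearest-neighbour distribution.
#'
#' @param queries,reference `encoded_msa` objects of equal width.
#' @param exclude_self Skip same-index pairs (queries and reference must then
#'   be the same ensemble, of size >= 2).
#' @return An object of class `hmin_sample`: list with `values` (one H_min
#'   per query), `reference_set` label, and `mean`.
#' @export
hmin_to_reference <- function(queries, reference, exclude_self = FALSE) {
  stopifnot(inherits(queries, "encoded_msa"), inherits(reference, "encoded_msa"))
  if (queries$length != reference$length) stop("alignment widths differ")
  if (exclude_self) {
    if (!identical(queries$codes, reference$codes)) {
      stop("exclude_self requires queries and reference to be the same ensemble")
    }
    if (reference$n_sequences < 2L) {
      stop("exclude_self needs at least 2 sequences (no neighbour exists)")
    }
  }
  d <- cross_hamming(queries$codes, reference$codes)
  if (exclude_self) diag(d) <- Inf
  vals <- apply(d, 1L, min)
  structure(
    list(
      values = vals,
      reference_set = if (exclude_self) "natural" else "generated",
      mean = mean(vals)
    ),
    class = "hmin_sample"
  )
}

#' The Delta-squared fit/novelty criterion
#'
#' Generates `n_generated` sequences from the model and returns
#' `(<H_min>_generated - <H_min>_natural)^2`: the squared gap between the mean
#' nearest-natural-neighbour distance of the generated ensemble and the mean
#' nearest-neighbour distance within the natural alignment itself. Small
#' values mean generated sequences sit at natural-like distances from the
#' alignment — neither trivial copies (overfit) nor outliers (underfit).
#'
#' @param model A fitted `generalist_model`.
#' @param natural The training `encoded_msa`.
#' @param n_generated Generated ensemble size (default `min(N, 2000)`).
#' @param seed Integer seed for generation.
#' @return Non-negative scalar.
#' @export
delta_sq <- function(model, natural, n_generated = NULL, seed = 1L) {
  if (is.null(n_generated)) n_generated <- min(natural$n_sequences, 2000L)
  gen <- generate_sequences(model, n_generated, seed = seed)
  h_gen <- hmin_to_reference(gen, natural, exclude_self = FALSE)
  h_nat <- hmin_to_reference(natural, natural, exclude_self = TRUE)
  (h_gen$mean - h_nat$mean)^2
}

# as delta_sq but returning both means, for diagnostics of under/overfitting
hmin_means <- function(model, natural, n_generated = NULL, seed = 1L) {
  if (is.null(n_generated)) n_generated <- min(natural$n_sequences, 2000L)
  gen <- generate_sequences(model, n_generated, seed = seed)
  c(
    generated = hmin_to_reference(gen, natural, exclude_self = FALSE)$mean,
    natural = hmin_to_reference(natural, natural, exclude_self = TRUE)$mean
  )
}

#' Scan the latent dimension and select the best K
#'
#' For each K in `k_grid`, fits the model `config$n_restarts` times from
#' independent initializations and records each run's Delta-squared score. The
#' selected K minimizes the per-K mean score; ties go to the smaller K. When
#' the latent dimension is below the optimum the model underfits
#' (`<H_min>_generated > <H_min>_natural`); above it, it overfits and the sign
#' flips. Runs whose fit diverges are recorded as failed and excluded from the
#' per-K mean; a K with no surviving run is dropped from the selection.
#'
#' @param natural An `encoded_msa`.
#' @param k_grid Integer vector of candidate latent dimensions.
#' @param config A [fit_config()]; its `k_dim` is overridden per grid point.
#' @param n_generated Generated ensemble size per run (default `min(N, 2000)`).
#' @return An object of class `scan_result`: list with `k_grid`, `per_k_runs`
#'   (per K, a data.frame of seed, delta_sq, hmin_generated, hmin_natural,
#'   failed), `delta_sq_mean`, and `k_optimal`.
#' @export
scan_k <- function(natural, k_grid, config, n_generated = NULL) {
  stopifnot(length(k_grid) >= 1L, all(k_grid >= 1L))
  per_k <- vector("list", length(k_grid))
  names(per_k) <- as.character(k_grid)
  means <- rep(NA_real_, length(k_grid))
  for (i in seq_along(k_grid)) {
    rows <- vector("list", config$n_restarts)
    for (r in seq_len(config$n_restarts)) {
      cfg <- config
      cfg$k_dim <- as.integer(k_grid[i])
      cfg$seed <- config$seed + (i - 1L) * config$n_restarts + r
      rows[[r]] <- tryCatch({
        model <- fit_generalist(natural, cfg)
        hm <- hmin_means(model, natural, n_generated = n_generated, seed = cfg$seed)
        data.frame(
          seed = cfg$seed, delta_sq = (hm[["generated"]] - hm[["natural"]])^2,
          hmin_generated = hm[["generated"]], hmin_natural = hm[["natural"]],
          failed = FALSE
        )
      }, error = function(e) {
        data.frame(
          seed = cfg$seed, delta_sq = NA_real_,
          hmin_generated = NA_real_, hmin_natural = NA_real_, failed = TRUE
        )
      })
    }
    per_k[[i]] <- do.call(rbind, rows)
    ok <- !per_k[[i]]$failed
    if (any(!ok)) {
      message(sprintf("K = %d: %d of %d runs failed and were excluded",
                      k_grid[i], sum(!ok), length(ok)))
    }
    if (any(ok)) means[i] <- mean(per_k[[i]]$delta_sq[ok])
  }
  if (all(is.na(means))) stop("every run failed at every K")
  k_opt <- k_grid[which.min(replace(means, is.na(means), Inf))]
  structure(
    list(k_grid = k_grid, per_k_runs = per_k,
         delta_sq_mean = means, k_optimal = k_opt),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat("latent-dimension scan (Delta-squared criterion)\n")
  print(data.frame(K = x$k_grid, mean_delta_sq = x$delta_sq_mean))
  cat(sprintf("selected K = %d\n", x$k_optimal))
  invisible(x)
}
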