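---
title: "Methods: the latent-space family model and its evaluation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the latent-space family model and its evaluation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(generalist)
```

## The model and its assumptions

An aligned family of `N` sequences of width `L` over `A = 21` symbols (20
amino acids and the gap, treated as an ordinary category everywhere) is
modeled by giving each sequence a latent vector `z_n` of dimension `K` and
the family a shared energy tensor `theta` (`A x K x L`). Conditional on
`z_n`, the symbol at position `l` follows a Gibbs–Boltzmann categorical
distribution with energies `sum_k z_nk * theta_akl`, normalized by an
explicit 21-term partition sum. Three modeling assumptions matter in
practice:

* **Conditional independence.** Given a latent location, positions are
  independent. All covariation in the marginal distribution comes from
  integrating over the spread of latent embeddings. A corollary the package
  exploits: the most probable sequence at a latent point is a per-position
  argmax (`optimal_sequence()`), with no search.
* **Per-sequence embeddings are parameters.** Every training sequence gets
  its own `z_n`, fitted jointly with `theta` by maximum likelihood. Nothing
  regularizes `z` or `theta`; overfitting is controlled only through the
  choice of `K`.
* **Non-identifiability.** The likelihood is invariant under `z -> z G`,
  `theta -> G^{-T} theta` for invertible `G`, and under per-position energy
  shifts absorbed by the partition sum. Models must therefore be compared
  through probabilities or generated statistics, never through raw
  parameters — the test suite follows this rule throughout.

## Fitting

`fit_generalist()` maximizes the exact log-likelihood with full-batch
adaptive gradient ascent (Adam-style first/second moment estimates, base
step `1e-2`), from uniform(-0.1, 0.1) initializations of both `theta` and
`z`. Two numerical safeguards shape the implementation:

* **Monotone acceptance.** A proposed step is accepted only if it does not
  decrease the log-likelihood; otherwise the step size is halved and the
  proposal retried. If the adaptive direction fails even at tiny steps, the
  raw gradient — always an ascent direction — is tried before declaring a
  stationary point. The recorded trace is therefore non-decreasing by
  construction, and "converged by step underflow" certifies stationarity
  rather than a badly scaled direction. The fallback matters in degenerate
  corners such as an alignment of identical sequences, where the uniform
  model is a saddle whose escape direction the moment estimates initially
  miss.
* **Log-space partitions.** All partition values are computed with
  max-subtracted log-sum-exp, and probabilities are floored at `1e-300`
  before logs, so energies up to several hundred in magnitude stay finite.
  The per-symbol exponentials computed for the partition sum are reused for
  the probabilities themselves, which roughly halves the per-iteration cost.

Iteration stops at `max_iters` (default 2000) or when the relative
log-likelihood change over a 10-iteration window falls below `tolerance`
(default `1e-6`). The 10-run restart protocol (`fit_restarts()`) derives
seeds `base + 1 .. base + n_restarts` and keeps the run with the smallest
`delta_sq()`.

## Choosing the latent dimension

`delta_sq()` generates `min(N, 2000)` sequences (bootstrap of the learned
embeddings, then per-position categorical sampling via the Gumbel-max
construction, which never forms normalized probabilities) and compares mean
nearest-neighbour fractional Hamming distances: generated-to-natural
versus natural-to-natural (self excluded). `scan_k()` fits a grid of `K`
values with restarts and selects the `K` minimizing the mean `Delta^2`,
ties to the smaller `K`. Duplicated natural sequences are kept (their
`H_min` is 0); nothing deduplicates the alignment. Distances are computed
exactly — per-symbol indicator matrix products, no approximate nearest
neighbours — which is the same kernel the distance-distribution module
uses, so the selection criterion and the diagnostics can never disagree
about what "distance" means.

## The synthetic-data generator

`make_planted_model()` draws ground-truth energies i.i.d.
uniform(-`theta_scale`, `theta_scale`) and samples latents from either a
normal distribution centred at `z_center` or a stated 2-component Gaussian
mixture. The defaults — `theta_scale = 2`, `z_center = 1`, unit latent
variance — were chosen so the planted family looks like a protein family
in the ways the evaluation battery measures:

* A **nonzero latent mean** gives every energy entry a consistent sign
  across sequences, which is what creates genuinely conserved positions.
  With zero-mean latents every residue's expected energy is zero and site
  frequencies are nearly flat (mean consensus-residue frequency ~0.07,
  barely above the uniform 1/21 = 0.048); two independent N = 2000 samples
  of such a truth correlate at only r ~0.83 in order-1 frequencies, i.e.
  the statistics one wants to recover would be dominated by sampling
  noise, a property no real alignment shares. At the chosen defaults the
  consensus frequency averages ~0.29, within-family nearest-neighbour
  distances average ~0.45, and two independent samples of one truth agree
  at r = 0.996 (order 1) and 0.95 (order 2) — those ceilings, measured
  truth-against-truth, bound what any fitted model can achieve.
* The **unit latent spread** produces higher-order covariation that decays
  with order, as in real families.

What the generator does *not* emulate: phylogenetic relatedness (sequences
are exchangeable draws, with no tree structure or sampling bias),
insert-state geometry, and length variation. Tests passing on these
fixtures therefore demonstrate correct recovery of planted probabilistic
structure, not performance on phylogenetically correlated data.

## Statistics: sampling policies and edge rules

* **Moments.** Order 1 compares all `A x L` frequencies. For orders 2–4,
  `moment_comparison()` samples combinations once (default 50,000; tests
  and the acceptance script use 2,000–5,000) and evaluates the identical
  combinations in both ensembles, removing between-ensemble sampling
  variance. Positions within a combination are distinct; symbols are drawn
  uniformly among those observed at that position in the natural ensemble,
  avoiding a point mass of structural zeros. A natural moment vector with
  zero variance is an explicit error; a zero-variance generated vector
  scores r = 0 (no linear association) rather than NA.
* **r20.** For each order, 500 position sets by default (tests use 40–200);
  per set, joint symbol strings are ranked by natural frequency with ties
  broken deterministically by the encoded string, the top 20 kept, and
  their frequencies Pearson-correlated between ensembles. Sets with fewer
  than two distinct natural frequencies are skipped and counted. String
  keys are exact base-21 integers in doubles up to order 11.
* **Distance profiles.** Survival curves live on the native grid
  `{0, 1/L, ..., 1}`, which is lossless for fractional Hamming values.
  Random-pair sampling switches to exhaustive enumeration whenever the
  ensemble has at most `n_pairs` pairs. Profiles are compared by the
  Kolmogorov–Smirnov statistic on the shared grid.

## Latent clustering

`fit_gmm()` fits full-covariance Gaussian mixtures by EM (engine: mclust's
`meVVV`, or `meV` for one-dimensional latents) behind the package's own
seeded initialization: five restarts, each started from a random
nearest-center hard assignment, best log-likelihood kept. The default
deterministic hierarchical initialization used by mclust would make
repeated fits identical, which matters because the number of components is
chosen by *stability*: `select_n_components()` fits 20 independent pairs
of mixtures per candidate and records the pair-counting Jaccard similarity
of their assignments (co-clustered pairs in both over co-clustered in at
least one — label-permutation invariant, no matching step needed). The
candidate with the highest median Jaccard wins, ties to the smaller count,
with one deliberate exception: a single component yields the trivial
partition, identical across fits by construction, so candidate 1 is
reported but never selected over informative candidates — stability
carries no information about it.

`cluster_statistic_contrast()` compares moment vectors computed separately
within two clusters (same sampled combinations, per-cluster centering)
against a null of 100 size-matched random partitions. On planted
two-component mixtures the observed order-2 cross-cluster correlation
falls far below the null's 1st percentile; on random labels it sits inside
the null band.

## Determinism and the CLI

Every random draw flows from an explicit integer seed through a
save/restore wrapper, so no call disturbs the session RNG; restart and
grid seeds are derived by fixed offsets. The CLI (`generalist_cli()`, with
a thin Rscript wrapper installed under `inst/cli/`) writes all
quantitative results as JSON plus a run manifest; rerunning an invocation
with identical arguments reproduces result files byte for byte (manifests
record wall time and are exempt).

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run the recovery fixture at
N = 2000, L = 30, K_true = 4 (fit capped at 1500–4000 iterations, which is
past the point where order-1/2 recovery statistics saturate), the
dimension scan over K in {1, 2, 4, 16, 64} at 400 iterations and one
restart per grid point, r20 at 40–200 position sets per order, and
clustering fixtures at N = 600 with mixture means separated by ~4.5
standard deviations. These sizes keep the full battery at a few minutes on
one CPU while leaving each criterion's signal far above its noise floor.

## Known limitations

* Full-batch fitting materializes the `N x (A*L)` probability matrix;
  memory grows linearly in all three and the method is practical to roughly
  `N * A * L ~ 10^8` on a desktop.
* No phylogenetic weighting is offered anywhere (deliberately: all
  sequences count equally), and nothing corrects for tree-induced
  correlation in the statistics.
* The greedy hill climb accepts only strict improvements and so cannot
  traverse plateaus; on scores with exact ties its terminal point depends
  on the proposal order (seeded).
* `embed_sequences()` (latents for unseen sequences with frozen energies)
  is a convenience extension; nothing in the evaluation battery depends on
  it.
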