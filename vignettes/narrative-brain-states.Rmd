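---
title: "Methods: linking movie narrative semantics to dynamic brain states"
author: "nbstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking movie narrative semantics to dynamic brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`nbstates` implements a pipeline for relating the semantic content of a
continuously presented narrative (a movie) to recurring whole-timeline
brain states estimated from naturalistic fMRI:

1. **Text semantics.** Timed subtitle text is tokenized, binned onto the
   scanner's repetition-time (TR) grid, smoothed with a centered sliding
   window, tf-idf weighted, and factored by nonnegative matrix
   factorization (NMF) into `s` *semantic contexts*: word-weight vectors
   (rows of `H`) paired with per-timepoint expression trajectories
   (columns of `W`).
2. **Brain states.** For each subject and each *region-network
   combination* (one neocortical network's parcels plus one limbic
   structure's principal-component embeddings), a hidden Markov model
   (HMM) with multivariate Gaussian emissions segments the timeline into
   `n = 4` recurring states, yielding posterior state-presence
   probabilities `gamma` (T x n).
3. **Linkage.** Pearson correlations between state presence and context
   expressions are summarized by the *top-10 link statistic* (per state,
   the mean of its ten largest signed correlations; the model index is
   the mean over states), with permutation nulls and network-level
   two-sample t-tests.
4. **Temporal structure.** Dwell times (maximal runs of the
   hard-assigned state sequence, in seconds) and their local volatility
   across movie segments.
5. **Group signatures.** After Hungarian alignment of state labels to a
   template subject, state-specific rows are concatenated across
   subjects and a one-component partial-least-squares (PLS) regression
   links the combined description matrix (contexts + annotations) to the
   brain columns, validated by blocked 20-fold cross-validation.

A synthetic-data generator with known ground truth stands in for real
fMRI recordings so that every stage is testable at desk scale.

# The text model

Tokens are lowercased, punctuation-stripped words; a SubRip cue
contributes its tokens to every TR bin its time span overlaps (bin `t`
covers `[t*TR, (t+1)*TR)` seconds). Stop-word removal takes a
configurable word list, since the appropriate list depends on the corpus
language.

**Smoothing.** Each row of the T x V count matrix is replaced by the
mean of the rows within half a window on each side (default window 4
minutes, i.e. 2 min before and 2 min after), truncated at the timeline
edges; the mean is always over the rows actually available. Speech is
sparse at the 2-s scale, so this is the step that turns word counts into
continuous semantic trajectories. A window shorter than one TR is the
identity.

**tf-idf.** Counts become
`tf * idf = (f[w,t] / sum_w' f[w',t]) * ln(T / (1 + n_w))`, with `n_w`
the number of timepoints whose (smoothed, possibly fractional) count for
word `w` is positive. Timepoints with no tokens map to zero rows rather
than dividing by zero. The formula permits a *negative* idf for words
present at nearly every timepoint (`n_w >= T/e`); these values are kept
as computed at this stage and clipped to zero only at the NMF input,
which requires nonnegativity. The number of clipped entries is reported.
Note that after 4-minute smoothing, "presence" is much broader than raw
occurrence, so ubiquitous-word clipping is common and intentional: it is
the mechanism by which idf suppresses words that carry no temporal
information.

**NMF-LSA.** `M ~ W H` with `W, H >= 0` is fitted by the classical
multiplicative updates for squared Frobenius error, which make the
objective nonincreasing at every step. Initialization is random uniform
scaled by `sqrt(mean(M)/s)` under a fixed seed; the iteration cap
defaults to 500 with a relative objective-change tolerance of `1e-6`.
NMF has no inherent component order, so contexts are sorted by total
expression; rows of `H` are scaled to unit Euclidean norm with the scale
absorbed into `W`, making word weights comparable across contexts.

**Choosing the window.** `gridSearchWindow()` re-runs
smooth-tfidf-NMF for each candidate window and scores the mean and
maximum of the top-10 link statistic against a supplied state-presence
matrix. In sparse, low signal-to-noise streams (about one token every
few bins, weak coupling), the 4-minute window is the stable optimum of
the mean metric over `{1, 4, 16}` minutes; with dense well-coupled
streams shorter windows already suffice, and the metric is nearly flat
in the window. The test suite exercises the former regime because it is
the one in which the window choice matters.

# Signal preparation

Subregion time series are detrended and z-scored independently within
each movie segment and column: the least-squares linear trend is
removed, then the residual is scaled to mean 0 and standard deviation 1
(population `1/N` convention, fixed for reproducibility). Columns that
are constant within a segment become zeros instead of NaN. The
standardization is idempotent.

Hippocampal and amygdalar subregions are embedded with one PCA per
structure whose components are *shared across hemispheres*: the two
hemispheres' (column-centered) T x m matrices are stacked along the time
axis into a 2T x m matrix, the components are taken from its singular
vectors, and each hemisphere is projected with the same components.
Sharing the basis keeps left/right loadings directly comparable, which
is what makes lateralization effects readable in downstream loadings.
Standardization precedes the PCA, so components capture signal shape
rather than amplitude offsets. Each component's largest-magnitude
element is made positive (a deterministic sign convention), and
`inverseProjectLoadings()` maps PC-space loadings back to the 2m
subregions through the transposed component matrix.

A combination's feature matrix is the column concatenation of the
network's parcels with the six limbic PCs
(`R = r_network + 2 * 3`).

# The hidden Markov model

Emissions are full-covariance multivariate Gaussians per state; the
chain is first-order with a time-invariant transition matrix `Theta`
(`Theta[l,k] = P(S_t = k | S_{t-1} = l)`). Inference uses the scaled
forward-backward recursions (compiled in C++), which are exact and
underflow-free at thousands of timepoints; `gamma` rows sum to one to
`1e-8`.

**EM details.** Means are seeded from randomly chosen timepoints with a
shared sample covariance (a k-means-style start); `pi` is uniform and
`Theta` starts with 0.8 self-transition mass. Every M-step covariance
gets a ridge of `1e-6` times the mean diagonal variance of the data, so
states that momentarily capture few timepoints cannot produce singular
covariances. EM stops when the relative log-likelihood change falls
below `1e-6` or at 500 iterations. A looser tolerance such as `1e-4`
sounds harmless but is *relative*: with data log-likelihoods of order
`1e4`-`1e5` it corresponds to several whole log-likelihood units per
iteration and can freeze the transition matrix short of convergence;
`1e-6` costs only a handful of extra iterations because convergence is
geometric once states separate.

**Restarts and selection.** The likelihood surface is multimodal, so
`multiRestartFit()` runs independent EM fits (the study-scale protocol
is 100; tests use 5-20) and keeps the solution with the strongest
semantic linkage - the model-level top-10 link index against the
context expressions. Selection uses signed correlations by default
(absolute values behind a flag). Note that the index is only
informative when the number of contexts comfortably exceeds the top-k:
with exactly `k` features it averages *all* signed correlations, which
is approximately zero for any solution.

**How many states.** `selectNStates()` sweeps candidate state counts
and tabulates the link index, the cross-subject state-presence
similarity (when several subjects are supplied), and the Bayesian
information criterion computed with and without the limbic columns,
with `p = (n-1) + n(n-1) + n(R + R(R+1)/2)` free parameters. Selection
is by minimum BIC with ties broken by the larger link index. On
synthetic data with four planted states the sweep over 2..8 recovers
four.

# External descriptions

Observer annotation intervals are rasterized into inter-observer
agreement (IOA) series: `IOA[t]` is the fraction of observers with an
interval overlapping bin `t` (positive-measure overlap). Bipolar
indicators (arousal, valence, direction) subtract the negative pole's
IOA from the positive pole's, spanning `[-1, 1]`. Episodes are maximal
runs where any attribute's `|IOA| >= 0.5`; the boundary value counts, so
an even observer split is included. Continuous attributes take the
per-timepoint maximum of episode medians across characters; all other
attributes become binary presence series. The default synthetic
attribute battery has 52 entries (44 character-emotion indicators, 3
bipolar dimensions, 4 location/time flags, 1 soundtrack flag), but the
attribute list is a configurable input.

# Linkage statistics

`correlationMatrix()` computes plain Pearson correlations; zero-variance
columns yield `r = 0` with a warning rather than NaN. The permutation
null applies one random row permutation *jointly* to all `gamma` columns
(preserving each row's simplex constraint) and recomputes the model
index `B` times; `p = (1 + #{null >= observed}) / (1 + B)` avoids
p = 0. A circular-shift variant that preserves autocorrelation is
available behind a flag; plain permutation is the default, which is why
even modest observed indices are typically "significant" against this
null - the null destroys the autocorrelation alignment entirely. The
network comparison is a pooled-variance two-sample t-test of per-subject
model indices (Welch behind a flag), with no multiplicity correction by
default and a Bonferroni flag.

# Temporal statistics

Dwell spells are maximal runs of the hard-assigned sequence times TR;
spells are pooled across a model's states for the headline mean/sd
(sample, n-1), with the per-state breakdown also available. For local
volatility, spells are computed within each movie segment independently
(runs truncate at segment boundaries, they are not bridged), and the
volatility is the sample sd of per-segment mean dwells. Under a planted
self-transition `a`, run lengths are geometric and the mean dwell is
`TR / (1 - a)`; the suite verifies this law within 15% at T = 10000 for
`a` in {0.8, 0.9, 0.95}.

# Group-level signatures

State labels are arbitrary per subject, so each subject's solution is
aligned to a template subject by minimum-cost bipartite assignment
(an O(n^3) Hungarian solver, exact against exhaustive search in tests)
with cost equal to the Euclidean distance between state mean vectors.
Means alone are used because, after z-scoring, they live on a common
scale; a flag adds a Frobenius covariance term.

Each timepoint's rows are routed to its hard-assigned (aligned) state;
state-specific blocks are concatenated across subjects in subject order.
One-component PLS then finds the weight pair maximizing the covariance
between the combined description matrix `E` (context expressions +
annotation series, columns standardized by default because the two live
on different scales) and the brain matrix `G` - computed as the dominant
singular pair of the centered cross-covariance via NIPALS power
iteration (tolerance `1e-10`), with the largest-magnitude description
weight made positive. Cross-validation splits each subject's
state-specific rows into contiguous blocks (respecting temporal
autocorrelation); fold f's test set concatenates block f across
subjects, and the held-out Pearson correlation between the two latent
scores is reported per fold.

`signatureReport()` names the top contexts (with their top words), the
top annotations per category, and maps the limbic PC loadings back to
subregions through the shared PCA basis.

# The synthetic study

The generator plants every ingredient the analysis assumes, at the
emulated study's layout: 15 subjects x 3543 timepoints at TR = 2 s in 8
near-equal segments; 7 neocortical networks with 5-24 parcels
(100 parcels total); 19 hippocampal and 9 amygdalar subregions per
hemisphere; 4 hidden states per region-network combination; 9 annotation
observers and 52 attributes.

- **Stimulus-locked chains.** Each network has one hidden state chain
  shared by all subjects; emissions are subject-specific. This models
  fully stimulus-driven dynamics - the idealization that makes a single
  text stream able to couple to every subject's states.
- **Dwell gradient.** Default self-transition probabilities rise from
  0.80 (visual analog, mean dwell 10 s) to 0.92 (default-network analog,
  25 s), planting the unimodal-to-associative timescale hierarchy the
  temporal analyses are designed to detect.
- **Emissions.** State means are drawn with a minimum pairwise distance
  of 4 (approximately Mahalanobis units; the well-separated regime);
  covariances are identity plus symmetric uniform off-diagonals
  projected to the nearest SPD matrix by eigenvalue clipping at 0.05.
  Limbic subregions follow a three-factor latent structure per
  hemisphere, independent of the chains, so the shared PCA embedding is
  well-defined but carries no state signal - network parcels carry it.
- **Token stream.** Per bin, a zero-inflated Poisson number of tokens
  (mean 4, 30% silent bins) is drawn from a mixture of a background
  distribution and 10 topics with disjoint 12-word signatures. Each
  topic's mixture weight is a base rate plus an idiosyncratic episodic
  activation (its own recurring bursts, smoothed at the analysis
  timescale - what makes topics temporally separable from one another)
  plus a coupled gain that follows the 4-minute-smoothed presence of its
  planted state. The gain is calibrated by bisection until the realized
  correlation between the smoothed topic expression and the smoothed
  state presence hits the target `rho` (default 0.4, matched at the
  smoothed timescale because a 2-s indicator and a 4-minute-smoothed
  expression can never correlate strongly in raw form). All topics
  couple to the default-network analog by default.
- **Annotations.** Episodes are planted per attribute; each observer
  marks each episode independently with the configured agreement
  probability (default 0.8), copying the planted boundaries.

**What the generator does not emulate** - and hence what passing tests
do *not* show about real data: hemodynamic convolution and autocorrelated
scanner noise (emissions are white given the state); per-subject state
idiosyncrasy (real subjects' dynamics are only partly stimulus-locked);
linguistic syntax and Zipfian vocabulary structure; drift or motion
artifacts beyond the linear per-segment trend. Recovery results on this
generator certify the *pipeline's statistical machinery*, not
field-strength effect sizes.

**Topic recovery and tf-idf.** The idf factor deliberately rescales
words by rarity, so factors recovered from the tf-idf matrix live in an
idf-scaled word space; their cosine against the *raw* planted
word-probability vectors is bounded well below 1 by that rescaling
alone. Topic-dictionary recovery is therefore evaluated on the NMF of
the smoothed count matrix, where the planted factorization is the
data's own low-rank structure; the tf-idf stage is validated separately
against the formula and through the end-to-end linkage results.

# Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which each property is stably measurable: single-
combination recovery and model selection at the full T = 3543 with
R = 12; the coupled-network comparison with 5 subjects and 4 networks
(s = 50 contexts, 5 restarts, 200 permutations); permutation
calibration with 200-400 replicate datasets at T = 300; the geometric
dwell law at T = 10000; the demo pipeline at 3 subjects, T = 400, 2
networks, s = 20.

Other fixed choices: all randomness flows from integer seeds through a
deterministic sub-seed derivation, and generator outputs are
bit-reproducible per seed; TSV writers format numbers with fixed
significant digits so identical runs are byte-identical; hard
assignment breaks ties toward the lowest state index; `topWords()`
breaks weight ties lexicographically; empty token bins, constant
columns, and zero-variance features all take defined values (zeros)
with warnings instead of propagating NaN.

# Known limitations

- NMF is non-convex; different seeds give different factorizations, and
  recovered dictionaries vary in quality across data realizations. The
  pipeline reports the reconstruction-error trace and seed so runs are
  auditable.
- The restart-selection index inherits selection bias: picking the
  restart with the strongest semantic link inflates that link slightly.
  The permutation test operates on the selected solution and therefore
  inherits the same optimism; the calibration checks use fixed (not
  selected) state-presence matrices.
- Cross-subject state-presence similarity is a diagnostic computed with
  a greedy matching, not the Hungarian solver; it is not used for any
  inferential claim.
- With a single subject per fit and stimulus-locked synthetic chains,
  between-subject variance in the synthetic cohort is emission noise
  only; real between-subject variability is larger and structured.
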