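# nbstates

Linking the semantic content of a movie narrative to dynamic brain
states in naturalistic fMRI.

When people watch a full-length film in the scanner, their brain
activity is driven by a continuously evolving story. `nbstates` is an R
package for researchers who want to quantify that relationship at the
single-subject level: it distills the movie's timed text into
data-driven *semantic contexts*, segments region-network fMRI time
series into recurring *brain states*, and measures how tightly each
brain system's state dynamics track the narrative — with permutation
nulls, dwell-time (temporal receptive window) statistics, and
group-level partial-least-squares signatures on top. A synthetic-data
generator with known ground truth makes the entire pipeline testable
without any imaging data.

## The model

**Semantic contexts.** Subtitle tokens are binned onto the TR grid,
smoothed with a 4-minute sliding window, and weighted by

> tfidf(w, t) = ( f<sub>w,t</sub> / Σ<sub>w′</sub> f<sub>w′,t</sub> ) · ln( T / (1 + n<sub>w</sub>) ),

timepoints acting as documents. Nonnegative matrix factorization then
yields `M ≈ W H` with `W, H ≥ 0`: each of the `s` contexts pairs a
word-weight vector (row of `H`, unit norm) with an expression
trajectory (column of `W`).

**Brain states.** For each subject and each region-network combination
(a network's parcels plus 3 shared-basis PCA components per limbic
hemisphere, `R = r_network + 6` features), a hidden Markov model with
multivariate Gaussian emissions

> x<sub>t</sub> | S<sub>t</sub> = k ~ N(μ<sub>k</sub>, Σ<sub>k</sub>),  P(S<sub>t</sub> = k) = Σ<sub>l</sub> Θ<sub>l,k</sub> P(S<sub>t−1</sub> = l)

is fitted by multi-restart Baum–Welch EM; the retained restart is the
one whose posterior state presence `γ` correlates most strongly with
the semantic contexts. The number of states is selected by BIC.

**Linkage.** Each state's link strength is the mean of its 10 largest
Pearson correlations with the `s` context expressions; the model index
averages the states. Significance comes from shuffling the rows of `γ`
(jointly across states); networks are compared by two-sample t-tests of
per-subject indices. Dwell times — maximal runs of the hard-assigned
sequence, in seconds — expose each system's processing timescale.
Group signatures are obtained by Hungarian-aligning state labels across
subjects, concatenating state-specific rows, and extracting the
dominant PLS component between descriptions (contexts + annotations)
and brain features, with blocked 20-fold cross-validation.

## Worked example

A compact synthetic study: 3 subjects, 2 networks, with the
default-network analog coupled to the planted semantic topics.

```r
library(nbstates)

cfg <- groundTruthConfig(n_subjects = 3, n_timepoints = 400, n_segments = 4L,
                         networks = c(VIS = 6L, DN = 8L),
                         limbic = c(HC = 8L, AM = 5L), seed = 5)
bundle <- runPipeline(pipelineConfig(out_dir = tempfile("demo"), seed = 9,
                                     gt_config = cfg, s = 20L,
                                     n_restarts = 3L, B = 100L, n_folds = 5L))

## which network tracks the narrative best?
with(bundle$link_table, tapply(link_index, network, median))
#>        DN       VIS
#> 0.0941786 0.0826472

aggregate(cbind(mean_dwell, volatility) ~ combination, bundle$dwell_table, mean)
#>   combination mean_dwell volatility
#> 1       DN&AM  11.306118   2.925856
#> 2       DN&HC  14.898511   6.301944
#> 3      VIS&AM   9.029437   2.258420
#> 4      VIS&HC   9.060953   1.178415

bundle$solutions[[1]][["DN&HC"]]
#> HMMSolution: 4 states, 400 timepoints x 14 features
#>   log-likelihood -6890.95 after 21 EM iterations (converged)
```

The coupled DN analog shows the higher median semantics–brain link
index (0.094 vs 0.083) and the longer, more volatile dwell times
(planted: DN-analog states dwell ~25 s, visual-analog ~10 s) — the
pattern the pipeline is designed to detect. The bundle also carries the
fitted contexts, the 52-attribute annotation matrix, per-model
permutation p-values, and per-state PLS signatures;
`writeReport(bundle, "report.md")` renders the summary tables.

A YAML-driven command-line wrapper over the same pipeline lives at
`inst/scripts/run-pipeline.R`.

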