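---
title: "Methods: joint-interval ERP analysis and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-interval ERP analysis and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jierp)
```

## The model

A train of tactile stimuli with inter-stimulus intervals spanning
100 ms to 10 s drives an evoked cortical response whose amplitude
depends on the recent stimulation history. The analysis treats each
stimulus from the third onward as the endpoint of a *triad*: its
previous interval $k$ and penultimate interval $k{-}1$ (both in
seconds). The pair $(k{-}1, k)$ indexes a 5 × 5 joint-interval grid
with upper bin edges 0.5, 1, 2, 4, 8 s; membership is half-open
$(\mathrm{lower}, \mathrm{upper}]$, and a triad is excluded when either
interval exceeds 8 s (beyond that, an hour-long session leaves too few
trials per bin to estimate a stable ERP). Single-trial epochs pooled
within a bin are averaged into the per-bin ERP; the stacked result is
the JIERP tensor, 5 × 5 bins × 500 latencies (−200..299 ms at 1 kHz).
A bin needs at least 10 trials to be considered estimated; below that
it is flagged invalid and excluded, never imputed.

Latency-wise z-scoring across the valid bins re-expresses each latency
as a relative modulation map: positive z means that context evokes a
larger response than the across-context mean at that moment. All
downstream statistics operate on these maps.

Three latency windows name the processing stages: early 1–75 ms,
intermediate 75–150 ms, late 150–300 ms. They are labels for reading
the results; every latency is analyzed.

## Preprocessing

The chain is: zero-phase FIR band-pass → epoching → ±80 µV amplitude
rejection → average reference → baseline correction (−200..−50 ms),
in that order, and the applied order is stamped into the output
metadata. Design notes:

- The FIR filter is a Hamming-window design (`signal::fir1`) applied as
  a single delay-compensated linear-phase pass via FFT convolution with
  reflection padding. The filter order follows the ~3.3 transition-width
  cycles heuristic with transition widths
  $\min(\max(0.25 f, 2), f)$ at the low edge and
  $\min(\max(0.25 f, 2), f_{N} - f)$ at the high edge. A one-pass
  compensated application (rather than forward–backward) keeps the
  passband gain at $|H(f)|$ rather than $|H(f)|^2$ and does not shift
  component latencies. Two-stage filtering (0.1–75 Hz then 1–45 Hz) is
  available; the default is the single 1–45 Hz pass, which is the
  spectrally binding constraint of the pair.
- "Beyond ±80 µV" is implemented as strict exceedance: an epoch peaking
  at exactly 80 µV is retained. The boundary is tested operationally by
  amplitude sweep.
- Electrode selection takes the ROI channel whose trial-averaged ERP has
  the largest **positive** peak in 25–75 ms (the P50 positivity);
  maximum absolute amplitude is available as an option, and ties break
  to the lowest channel index. For central electrodes the window
  150–300 ms is used instead.
- Eye-blink ICA, impedance-based channel exclusion and spherical
  interpolation are not implemented: the pipeline expects pre-cleaned
  (or synthetic) input and documents the omission.

## Statistics

**Mass-univariate t-tests.** At every bin × latency cell the
across-subject z-scores are tested against zero (two-sided one-sample
t, df = contributing subjects − 1). A subject contributes wherever its
bin is valid; cells with fewer than 3 contributors are flagged
untested, and zero-variance cells are flagged degenerate (t = 0,
p = 1). Correction is Benjamini–Hochberg applied **jointly across all
25 × T cells** at α = 0.05 (Benjamini–Yekutieli available). Under a
global null the joint BH procedure acts as a Simes global test, so the
expected false-discovery proportion equals α exactly; the test-suite
check of this property therefore allows the two-standard-error
Monte-Carlo band above α rather than asserting a sharp inequality that
a correct implementation would fail on half of all seeds.

**Latency cross-correlation.** The similarity of the modulation map at
latency $t_i$ to the map at $t_j$ is the Spearman correlation over the
jointly valid bins (minimum 5), with two-sided p from the
t-approximation on $n-2$ df. Each unordered pair is computed once, so
the FDR pool is not double-counted, and pairs within ±25 ms of the
diagonal are excluded from the pool entirely — near-diagonal
correlations are trivially high (ρ = 1 on the diagonal) and would
inflate the number of discoveries. The 25 ms figure is implemented as a
half-width with a configuration switch, since a full-width reading is
also defensible.

## Dimensionality reduction

The post-stimulus magnitude matrix is
$M = z(|\mathrm{JIERP}|) - \min z(|\mathrm{JIERP}|)$ over valid bins ×
299 latencies: magnitudes because the factorization should capture
modulation strength regardless of component polarity, and the common
shift because NNMF requires non-negative input while preserving every
pairwise difference. Invalid bins are excluded as rows and reported as
missing in $W$, not imputed — imputation would fabricate modulation
structure.

`M ≈ W H` is fitted by the classical multiplicative updates (Frobenius
objective, ε-floor $10^{-12}$, default max 500 iterations, relative
tolerance $10^{-5}$); the update rule guarantees a non-increasing error,
which is asserted on every run.

**Rank selection** is Wold-style matrix-completion cross-validation:
10% of entries are masked per fold (5 folds; draws that empty a row or
column are redrawn), the factorization is fitted on observed entries by
masked updates, and the held-out RMSE is averaged; the selected rank
minimizes it with a one-standard-error tie-break toward the smaller
rank. The per-fold fits use a stricter convergence setting (max 6000
iterations, tolerance $10^{-8}$) than ordinary fitting: an
under-converged low-rank fit inflates its held-out error, which
systematically biases selection toward larger ranks — with the default
fitting tolerance a planted rank-3 matrix was selected at rank 4–5 in
most runs, while at the stricter setting the held-out curve shows the
textbook minimum at the true rank.

**Stability selection (starNNMF).** The factorization is repeated 100
times from independent uniform initializations; similarity between two
runs is the mean cosine of best-matched $W$ columns under the optimal
one-to-one assignment (solved exactly by subset dynamic programming —
ranks never exceed 10, so at most $2^{10}$ states), which makes the
score invariant to column order and to the $cW, H/c$ rescaling. The
returned solution is the medoid — the run with the highest mean
similarity to all others — and that mean is its stability score. Note a
mathematical caveat used deliberately in the tests: a dense strictly
positive low-rank matrix has a *non-unique* NMF (rotational ambiguity),
so run-to-run similarity below 1 is expected there; near-perfect
stability is only demanded of inputs whose factors have distinct
support, where the factorization is essentially unique.

**Population clustering.** Meta-times are unit-normalized (the inverse
scale absorbed into $W$, leaving $WH$ unchanged) before pooling —
NNMF scale is arbitrary, and clustering raw rows would group subjects
by amplitude rather than by temporal shape. All factors of all subjects
are pooled as individual points; k-means (Lloyd, squared Euclidean)
runs 1000 seeded restarts per candidate k, each initialized from k
distinct points, and k ∈ 3..7 is chosen by the mean silhouette width
(Euclidean distance; the common default for this diagnostic). Cluster
representatives are elementwise means of member meta-times and of their
paired meta-JIERPs, averaging over non-missing bins.

## The synthetic generator

The generator defines the conditions under which the pipeline is
validated:

- **Trains**: intervals i.i.d. log-uniform on [100, 10000] ms (uniform
  offered). The log-uniform default mirrors the intended coverage of
  the quadratic bin edges: each of the 25 joint bins then receives
  roughly balanced counts, with the smallest expected share
  $(\ln 2/\ln 100)^2 \approx 2.3\%$. The true sampling law of the
  original stimulus programme is not published, so the distribution is
  an explicit parameter rather than an assertion. Onsets are rounded to
  the 1 kHz grid so noiseless identities are exact. A full session is
  ~1800 stimulations; a single fingertip receives ~600, and the
  per-finger analyses here use 600-event trains.
- **Template**: five Gaussian-windowed components at 50, 75, 100, 150,
  200 ms with alternating polarity and amplitudes 4, −3, 3.5, −4, 5 µV
  (half-widths 7–17 ms, broadening with latency as evoked components
  do), anchored to 0 µV at latency 0.
- **Modulation**: multiplicative gains per latency window.
  `early_late_suppression` plants the headline structure — in the early
  and late windows the gain is a logistic ramp in $\log k$ that is
  below 1 for $k < 0.5$ s and above 1 for $k > 2$ s; the intermediate
  window depends on both $k$ and $k{-}1$, with larger gain after short
  intervals. `diagonal` is monotone in $\min(k, k{-}1)$. Gains are
  piecewise constant across windows.
- **Noise**: i.i.d. Gaussian per sample and channel (default study runs
  use 3 µV). 1/f structure, blink and muscle artifacts, topographic
  realism and background-state fluctuations are *not* simulated, so
  passing tests demonstrate correctness of the computation under the
  stated statistical structure — not robustness to real-world EEG
  artifacts.
- Overlapping responses sum linearly; with intervals ≥ 100 ms and a
  300 ms template this affects at most the tail of the preceding
  epoch, and linear superposition is the simplest defensible model.

## Problem sizes and determinism

The bundled simulation studies use sizes chosen to exercise every
code path at desk scale: 12–20 subjects, 600-event trains, 200-replicate
null simulations, 50–100 stability repetitions, 200–1000 k-means
restarts. Every stochastic stage takes an explicit integer seed and is
bit-reproducible given it; derived seeds stay within 32-bit range.

## Known limitations

- No vendor EEG formats: the interchange container is plain TSV + JSON
  (lossless at `%.17g`), plus a TSV event list. BrainVision/EDF readers
  are refused with a pointer to the supported container.
- The grand-average validity rule (a bin must be valid in ≥ 80% of
  subjects, configurable) is an addition; with per-subject missingness
  the reference analysis did not specify pooling behavior.
- Spearman p-values use the t-approximation; with 25 bins this is
  adequate, but exact permutation p would be preferable below ~10
  jointly valid bins.
- The NNMF rank-selection CV and the stability score are both
  stochastic; their defaults trade runtime against selection stability
  and are documented above.
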