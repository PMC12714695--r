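---
title: "Joint deconvolution and de-biasing of multi-assay ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint deconvolution and de-biasing of multi-assay ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdeconv)
```

## The problem

ChIP-seq coverage of a histone modification is not the modification's
occupancy. Sonication and cross-linking favour accessible chromatin,
mappability varies along the genome, and unspecific fragments are pulled
down regardless of the antibody. All assays performed on the same cells
share these distortions, so treatment tracks correlate strongly with their
input controls even where nothing is enriched — and a sequenced input
control is usually far too shallow to estimate the distortion well
genome-wide on its own.

`chipdeconv` treats this as a joint estimation problem. When several
modifications have been assayed on the same sample, all tracks are analysed
together: the component shared by every sample is the chromatin bias, and
whatever a given assay adds on top of it is that mark's specific signal.

## The generative model

Coverage is averaged over fixed-width genomic bins (200 bp by default).
For bin $b$, let $a_b$ be cell-type-specific accessibility, $m_b$
sequence-driven mappability, and $n_b$ the remaining unspecific signal.
A control replicate $r$ has expectation

$$ c^{(r)}_b = D^{(r)} \, a_b \, m_b \, n_b, $$

and a treatment replicate of mark $h$, with true enrichment $s_{h,b}$ and
antibody specificity $k_h^{(r)}$,

$$ t^{(r)}_{h,b} = D^{(r)}_h \, a_b \, m_b \,
   \bigl( k^{(r)}_h s_{h,b} + n_b \bigr), $$

where $D$ absorbs sequencing depth. Two composite tracks matter downstream:
the chromatin bias $x = a \cdot m \cdot n$ and the biased mark signal
$y_h = a \cdot m \cdot s_h$. The method estimates both and then removes the
residual confounder from $y_h$.

## Step 1 — constrained KL-NMF

All binned samples form a matrix $V$ (bins $\times$ samples, controls
first). $V$ is factorized as $V \approx W K$ with $W \ge 0$ the signal
matrix (one column per treatment condition plus the bias column $x$, so
$l$ = number of conditions including control) and $K \ge 0$ the mixing
matrix. All stages minimize the generalized Kullback–Leibler divergence
plus L2 penalties ($\lambda_W = 0.01$ on $W$, $\lambda_K = 0.001$ on $K$).

An unconstrained factorization would happily mix enrichment into the
background component, so the mixing matrix is built in stages on a training
subset of bins:

1. **Controls only.** A rank-1 factorization of the control block yields
   $x$ and the control coefficients.
2. **Background coefficients.** With $x$ fixed, each treatment column gets
   the scalar $\beta_j \ge 0$ minimizing the 1-D regularized KL to
   $\beta_j x$ — as much of the treatment as possible is explained by
   background alone. With the L2 term the objective has an exact root
   ($2\lambda\beta^2 + \sum x\,\beta - \sum v = 0$), which we solve in
   closed form; tests verify it against a dense grid search.
3. **Specific signals.** Residuals $\max(V_j - \beta_j x, 0)$ are
   factorized rank-1 per condition, giving $y_h$ and per-replicate
   coefficients.
4. **Relaxation.** The block structure of $K$ is released and $W$ and $K$
   are optimized by alternating updates from the staged initialization.
   This keeps the staged solution's interpretation while letting off-block
   coefficients express imperfect antibody specificity.

The mixing matrix is then fixed and $W$ is re-solved over all genome bins
(the problem separates by bin). Finally each $W$ column is divided by its
98th percentile, the matching $K$ row multiplied by it — the
reconstruction is unchanged, depth factors concentrate in $K$, and signal
columns become comparable (the percentile rather than the maximum avoids
outlier leverage).

### Numerical choices

* **Update rule.** The updates are exact majorization-minimization steps:
  each element solves the quadratic from the standard KL auxiliary
  function augmented with the L2 term. At $\lambda = 0$ this is the
  classic multiplicative update; for $\lambda > 0$ it keeps the
  regularized loss monotonically non-increasing, which the tests assert at
  1e-10 slack. A loss increase aborts the run.
* **Stopping.** Relative loss improvement below 1e-6 or 500 iterations per
  stage by default.
* **Zero handling.** $0 \log 0 = 0$; ratios use a $10^{-12}$ guard.
  Multiplicative updates cannot leave an exact zero, so the relaxation
  unlocks zeros in the staged $W_0, K_0$ to $10^{-6} \times \max$ before
  alternating.
* **Genome-wide extension.** Deterministic per-row initialization and a
  fixed number (200) of updates make the result independent of chunking;
  the training-bin solution is finished with the same routine so training
  and genome-wide values agree where they overlap.
* **Degenerate inputs.** An all-zero control block or bias signal is an
  error; an all-zero residual for a condition yields a zero signal with a
  warning; an all-zero bin yields an all-zero signal row.
* **Training bins.** Uniform sample without replacement among bins whose
  cross-sample mean coverage exceeds a threshold (0 for simulated data,
  &gt;1 recommended for real data), sized 100,000 by default, 400,000 for
  deep real datasets, 5,000 for the simulated study where the genome has
  only 5,000 bins.

### Optimizer quality

On exact low-rank instances of the generative structure the staged-then-
relaxed procedure reaches the same regularized KL as the best of 100
random restarts of a plain multiplicative-update NMF (tests assert
agreement within 1e-4). On noisy matrices the two need not coincide: the
staged initialization is deliberately designed to keep the background
component control-like, and on data without that structure an
unconstrained optimizer can reach factorizations with lower loss but no
interpretation. We consider that behaviour the point of the design rather
than a defect, and test optimizer equivalence where the global optimum is
the structured one.

## Step 2 — half-sibling regression

The factorization removes *additive* unspecific signal, but $y_h$ is still
multiplied by $a \cdot m$. Assuming $s_h$ independent of $x$, the
confounder is removed by regressing the target on its "half-sibling":

$$ \log \hat s_h = \log y_h - \mathbb E[\log y_h \mid \log x], $$

with the conditional expectation estimated by ordinary least squares of
$\log y_h$ on $\log x$. Subtraction in log space is division in linear
space, so $\hat s_h$ is a fold-change track. The regression is fitted on
the factorization's training bins, restricted to bins where both signals
are positive (no pseudocount is added to the fit), and applied genome-wide.

Where the predicted divisor is essentially zero the ratio would explode, so
the divisor is floored at 0.1 — the signal is amplified at most 10-fold.
Bins with $x = 0$ use the floored divisor; the log base is immaterial since
the floor and cap are linear-scale quantities. A constant $x$ degenerates
to division by the geometric mean of $y_h$. One consequence of the
formula worth noting: rescaling $y_h$ by a constant leaves $\hat s_h$
unchanged after refitting (the intercept absorbs the constant), while with
frozen regression parameters the output scales proportionally; the tests
pin down both behaviours.

## Step 3 — enriched regions

Maximal runs of bins with $\hat s_h$ at or above a fold-change threshold
become regions; regions separated by at most `merge_gap` bins are merged
and regions narrower than `min_width` bins are dropped. No significance
test is performed, hence no multiple-testing correction is needed. The
defaults — threshold 2, merge gap 2 bins, minimum width 2 bins (5 for
broad marks) — are pragmatic choices exposed as arguments, since sensible
values depend on the mark's domain structure. Raising the threshold never
increases the total called bases.

## The simulator

`simulate_experiment()` generates a complete experiment with ground truth
so that the whole pipeline can be tested against known $a, m, n, s_h, D,
k$:

* **Layout.** A Markov chain on one synthetic chromosome: from background
  the chain stays in background with probability 1/2 or enters a narrow,
  broad, or randomly-placed peak state with probability 1/6 each; every
  peak returns to background. Runs have fixed lengths — background
  1000 bp, narrow 450 bp, broad 1200 bp, random 750 bp — and a final peak
  that would be truncated by the genome end is emitted as background, so
  every peak run is length-exact. These weights put 5–14% of the genome
  into each mark's peaks (28% in any peak), the enriched-minority regime
  in which explaining most bins by background is the right inductive bias.
* **Latents.** $\log a$ and $\log n$ are stationary AR(1) processes
  (sd 0.25, lag-1 autocorrelation 0.8): smooth, positive, unit-median.
  $m$ is i.i.d. Beta(2,2) rescaled into $(0.5, 1]$: rough, as mappability
  is. Setting the noise amplitudes to zero gives the exact pure-signal
  limit $a = m = n = 1$. Per-peak amplitudes are log-normal around the
  mark's mean enrichment (6 for narrow, 3 for broad, 4 for random — the
  narrow-high/broad-low pattern of real marks), laid out as a flat top
  with half-height single-bin shoulders so that shape preservation can be
  asserted.
* **Samples.** Three replicates per mark and two controls by default.
  Depth factors are log-normal around a mean control coverage of 20 per
  bin (a realistic post-normalization coverage for a deeply sequenced
  experiment); specificities $k$ are uniform on $[0.6, 0.95]$, wide enough
  that the mixing-matrix antibody diagnostic has signal to detect.
  Observed counts are Poisson around the model expectation
  (negative-binomial and noiseless modes are available).

What the simulator does **not** emulate: read-level artefacts (PCR
duplicates, mapping errors, blacklist-like pathological regions),
fragment-length variation within a library, correlated enrichment between
marks, copy-number variation, and broad-domain substructure. Passing tests
therefore demonstrate that the estimator recovers its own generative
model — a necessary check, not evidence about any particular real dataset.

## Preprocessing choices

* Fragment length per treatment condition by the maximum of the strand
  cross-correlation over shifts 50–500 bp (the standard estimator);
  control fragment length is the median of the treatment estimates.
* Treatment reads extend 5'→3' to the fragment length; control reads
  extend symmetrically about their midpoint; extension clips at chromosome
  ends.
* Libraries are normalized to a 25-million-read total by per-read
  weighting, not subsampling, so preprocessing is deterministic; the
  library size is the number of QC-retained alignments before extension.
* Coverage is averaged over contiguous bins (default 200 bp); the final
  partial bin of a chromosome is averaged over its true width.
* Any bin overlapping a blacklist interval by at least 1 bp is removed
  from all samples after binning; removed indices are retained for
  coordinate round-trips.

## Problem sizes in the test suite

The shipped tests and the acceptance script run the full study on a 1 Mb
genome (5,000 bins, 11 samples) with 5,000 training bins, five seeds for
the recovery properties, a 10 Mb genome for the rescaling check, and
20×4 / 50×2 matrices for optimizer-equivalence — sizes at which every
property is informative while a complete run stays interactive.

## Limitations

* The model is multiplicative-bias times additive-signal; assays whose
  bias is not shared with the input (e.g. strong antibody-specific
  off-target pulldown) violate it and surface as off-block mixing weight.
* The HSR step assumes $s_h \perp x$; marks genuinely concentrated in
  accessible chromatin (H3K4me3-like) retain true correlation with $x$,
  and de-biasing preserves — but cannot prove — that residual signal.
* Fold-change peak calls carry no error control; where calibrated FDR is
  needed, a dedicated peak caller should be run on the de-biased tracks.
* With a single control replicate the control stage cannot average
  replicate noise, and with no control at all the background is fitted to
  all samples jointly, which weakens the bias/enrichment separation.
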