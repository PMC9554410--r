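---
title: "Latent-space reverse correlation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space reverse correlation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentrc)
```

## The problem

Classical reverse correlation estimates an observer's internal template for a
face attribute by adding random pixel noise to one base photograph and
correlating the noise with the observer's two-alternative choices. Working in
the latent space of a pre-trained face generator changes the substrate: each
face is a point in a smooth, semantically organized coordinate system — an
`L x D` real matrix, one `D`-vector per style layer (18 x 512 by default) —
and arithmetic on latent codes corresponds to meaningful changes in rendered
faces. `latentrc` implements the full analysis pipeline on that substrate:
stimulus construction, a three-alternative categorization data model, a
per-participant directional-vector estimator with intensity extrapolation,
inter-participant agreement statistics, and a variance decomposition that
separates shared from idiosyncratic judgment structure. Generator inversion
and photorealistic rendering are deliberately out of scope; a pluggable
renderer interface with a deterministic mock backend exercises the rendering
contract without trained weights.

## Stimulus construction

Each stimulus is built in two steps from a pool of base latents: average the
latents of `k_average` faces sampled without replacement (default 10), then
perturb every matrix entry with i.i.d. Gaussian noise, `N(mu, sigma^2)` with
`mu = 0`, `sigma = 0.4` by default, and 300 stimuli per experiment. The
averaging step produces a plausible novel neutral face (a convex combination
of real ones); the noise step decorrelates stimuli from the pool and provides
the random variation that the reverse-correlation estimator needs.

Two readings of the noise step were possible and we fixed one: noise is
i.i.d. per matrix entry with a single `sigma` for all layers, in raw latent
units. Subsets may overlap across stimuli (sampling is without replacement
only within a stimulus), since no exclusion rule is part of the procedure.
All randomness flows through explicit integer seeds — a pool is a pure
function of (base latents, config) — which is what makes the bit-identical
regeneration tests possible.

## The directional-vector model

For one participant, let \(\bar A\) and \(\bar B\) be the elementwise mean
latents of the stimuli they categorized as the target and the opposite
attribute, and \(N\) the mean latent of their "neither" selections. The
fitted model is

\[
A = \bar A - \bar B, \qquad M_C = N + C\,A .
\]

`direction_model()` computes exactly this (means over the *noised* stimuli
actually shown, because those are what the participant judged), and
`extrapolate()` / `predict()` evaluate \(M_C\). The anchor \(N\) is the
participant's own neutral point; when a participant never answers "neither",
the anchor falls back to the mean of 20 stimuli drawn uniformly without
replacement from the pool. The fallback perturbs only the starting point —
the direction is bit-identical across fallback draws, and the tests assert
this. Sessions with zero target or zero opposite selections leave the
direction undefined and are rejected, the same way a participant who put
every face in one category would be excluded from analysis.

Extrapolation is exact linear algebra; the only numerical subtlety is none at
all, and the tests hold it to machine precision
(\(M_{2C}-N = 2(M_C-N)\) entrywise). Constants beyond \(\pm 8\) warn rather
than fail: the \(\pm 8\) bound is a rendering-quality heuristic (images
degrade), not a mathematical one, and \(\pm 4\) is the point from which
differences between representations tend to become visually apparent —
`representation_series()` carries that threshold as metadata.

## Agreement between participants

Agreement in a condition is the mean Pearson correlation over all unordered
pairs of participants' extrapolated representations \(M_C\), compared at the
extremes \(C = \pm 8\). The representation matrices are flattened row-major
(layer-major) to 9,216-vectors before correlating; this whole-matrix reading
is the default because it uses every coordinate symmetrically. Two variants
are exposed rather than silently chosen: `method = "per_layer"` averages the
18 per-layer correlations instead, and `include_anchor = FALSE` correlates
\(C\,A\) without the anchor, isolating directional agreement from shared
starting points. High agreement is the signature of a first-order,
physically grounded attribute (masculinity/femininity); low agreement is the
signature of a second-order, idiosyncratic one (trustworthiness).

## Simulated observers

The synthetic-data layer exists so that every estimator in the package can be
tested against a known ground truth. A synthetic latent pool plants
`n_factors` orthonormal attribute axes: face \(f = \sum_j s_{fj} u_j +
\varepsilon_f\) with factor scores \(s_{fj}\sim N(0, 1)\) and isotropic
residual sd 0.25 by default — a few dominant axes of variation over a small
unstructured remainder, which is the qualitative geometry attribute-editing
methods rely on. The pool generator's defaults (2,484 faces of 18 x 512)
match the scale of the inverted-photograph pool the method was developed on.

An observer is a unit preference direction
\(d_i = \mathrm{normalize}(w\,d_{\text{shared}} + (1-w)\,e_i)\) with
\(e_i\) isotropic on the unit sphere, plus a symmetric decision rule: project
the stimulus (relative to the pool grand mean) onto \(d_i\) and answer
target / opposite / neither as the score is above \(\tau\), below \(-\tau\),
or in between (exact ties fall to neither); with probability `lapse` the
answer is replaced uniformly at random. This linear-projection observer is
deliberately minimal: it is the simplest model under which the
subtraction-of-means estimator is consistent, so recovery tests probe the
pipeline rather than a richer theory of categorization. The shared weight
`w` operationalizes the first-order/second-order contrast — `w = 0.9` vs
`w = 0.3` populations reproduce the ordering of agreement between the
masculine/feminine and trustworthy/untrustworthy conditions.

What the simulation does *not* emulate: real inverted-face pools have
correlated, non-Gaussian structure; human observers drift, anticipate and
disagree with themselves; rendering quality interacts with latent magnitude.
Passing recovery tests therefore demonstrates correctness of the estimators
under the stated generative model, not validity of the psychology.

## Variance partitioning

For rating data in which `p` participants rate `s` stimuli `r` times each,
the additive crossed random-effects model

\[
y_{ijk} = \mu + a_i + b_j + (ab)_{ij} + e_{ijk}
\]

separates shared variance (the stimulus component \(\sigma^2_s\): structure
every rater responds to) from idiosyncratic variance (the participant main
effect \(\sigma^2_p\), which may be mere scale use, and the
participant-by-stimulus interaction \(\sigma^2_{ps}\), which is genuine
preference structure). `vpc()` estimates the components by the
expected-mean-squares method of moments on the balanced layout:
\(\hat\sigma^2_e = MS_E\), \(\hat\sigma^2_{ps} = (MS_{PS}-MS_E)/r\),
\(\hat\sigma^2_s = (MS_S-MS_{PS})/(pr)\),
\(\hat\sigma^2_p = (MS_P-MS_{PS})/(sr)\), negative estimates truncated to
zero before normalization. The source literature for this decomposition uses
cross-classified mixed models; we chose the closed-form estimator because it
is fully specifiable, dependency-free, exactly testable against brute-force
summation, and identical to REML on balanced data in practice. Both
normalizations are always reported — shares of total variance, and shares of
"reliable" (non-residual) variance — because published figures differ in
whether they fold the residual in.

Two policy choices: full decomposition requires `r >= 2` (with `r = 1` the
interaction and residual are confounded; `vpc()` then returns a reduced,
clearly labelled decomposition), and unbalanced tables are not silently
re-weighted — `balanced_subset()` applies a stated greedy completion (drop
participants that miss stimuli, then uncovered stimuli, then truncate
repetitions to the common minimum) and reports what it dropped.

A caution that the package's own simulations quantify: at a 99 x 120 x 2
design the stimulus-share estimate carries sampling noise of about
\(\pm 0.03\) (one sd) even for a perfectly specified model, because
\(\sigma^2_s\) rests on 119 stimulus degrees of freedom. Single-study
variance shares should be read at that resolution.

## Numerical and interface choices

* **Flattening convention.** Row-major (layer 1 first). Fixed once and used
  everywhere: correlations, serialization, observer projections.
* **Serialization.** Latent pools, stimulus pools, model matrices and series
  are CSV with ids plus `v0..v{LD-1}` columns, written via `%.17g` so the
  write-read round trip is bit-exact; YAML sidecars carry shape and
  provenance, JSON sidecars carry model metadata. Sessions and ratings are
  long-format CSV.
* **Mock renderer.** A fixed, internally seeded linear projection of the
  latent onto a 64 x 64 grayscale grid (`U %*% values %*% V` with seeded
  Gaussian factors), min–max scaled to 0–255. Deterministic by construction;
  it exercises the render-and-write-PNG path end to end and nothing more.
* **Degenerate inputs.** Zero-variance latents make Pearson correlation
  undefined and raise; empty constant lists, empty pools, shape mismatches
  and non-finite constants raise with specific messages; validation of
  sessions *returns* violations rather than raising, because partial and
  pilot sessions are legitimate data.

## Problem sizes in the test suite

The suite runs the full study geometry where it matters — 18 x 512 latents,
300-stimulus pools, 99 x 120 x 2 rating designs — but sizes replicate counts
for a laptop-class run: 20 seeds for recovery and agreement orderings, 20
replicate pairs for the regime contrasts, and a 300-face synthetic pool
standing in for the 2,484-face inverted pool (one fixed pool, as in the
original design). Unit tests use small toys (2 x 2 to 4 x 32 latents) where
exactness against brute-force oracles is the point.

## Known limitations

* No generator inversion or photorealistic rendering; conclusions about
  rendered imagery require a real backend implementing the renderer
  contract.
* The agreement statistic is descriptive; no inferential machinery
  (confidence intervals, permutation tests) is attached to it.
* The variance decomposition assumes a balanced crossed design; REML-style
  unbalanced estimation is out of scope by design.
* An optional HDF5 pool container is not provided; large pools are
  regenerated from seeds rather than stored.
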