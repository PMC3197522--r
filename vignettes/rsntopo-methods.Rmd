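---
title: "Methods: voxel-level small-world analysis of resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-level small-world analysis of resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rsntopo)
```

## The analysis

`rsntopo` characterizes the internal topology of individual resting-state
networks (RSNs) at the voxel level. Six networks are analyzed — three
higher-cognitive (CEN, DAN, DMN) and three perceptual (SMN, AN, VN) — and
the question asked is twofold: does each network on its own show
small-world organization, and do the two groups of networks differ
topologically and spectrally?

For each subject and network the pipeline:

1. drops voxels claimed by more than one network, so every analyzed voxel
   belongs to exactly one RSN;
2. regresses nuisance variance out of every voxel time-course: six motion
   parameters, white-matter, ventricular and global signals, and the
   temporal derivative of each (19 design columns including an intercept);
3. band-pass filters the residuals to 0.01–0.08 Hz (zero-phase Butterworth
   of order 2);
4. computes the voxel-by-voxel Pearson correlation matrix and thresholds it
   into undirected binary graphs over the grid T = 0.125, 0.150, …, 0.550;
5. measures the mean clustering coefficient C (per node, the fraction of
   neighbor pairs that are themselves connected; degree-below-2 nodes
   contribute 0 and all nodes enter the average) and the characteristic
   path length L (mean BFS distance over connected pairs within the
   largest connected component);
6. compares C and L at a conservative analysis threshold against 30
   degree-matched random graphs obtained by Maslov–Sneppen double-edge
   swaps, yielding γ = C/C_rand, λ = L/L_rand and the small-world index
   σ = γ/λ;
7. tests γ, λ, σ against 1 (one-sample t, Bonferroni over 6 networks × 3
   indices), compares each metric across networks (one-way ANOVA) and
   between groups (two-way ANOVA, group + network-within-group).

Spectral summaries are computed on regressed but *unfiltered* series,
because they span the full detectable range (0–Nyquist = 0.25 Hz at
TR = 2 s): the relative power of the network-averaged time-course
(periodogram divided by its maximum), the fraction of non-DC energy in
0.01–0.08 Hz ("band contribution"), and the per-voxel variant of that
fraction averaged over the network (fALFF). A 6×6 cross-network
correlation matrix of the cleaned network-average time-courses is also
produced.

## Thresholds

The grid minimum 0.125 is the smallest grid value at or above the critical
Pearson r for two-sided p = 0.05 at df = 248 (r = 0.124), i.e. it excludes
connections that would not reach uncorrected significance with 250
volumes. The grid maximum 0.55 is where the largest connected component
still holds at least 90% of every network's voxels. The single-threshold
statistics are computed at a data-driven conservative threshold: the
smallest grid value at or above the critical r for
α = 0.05 / (number of voxel pairs in the largest network) at df = t − 2
(Bonferroni over pairs). With the default synthetic cohort this lands at
T\* = 0.30.

## The synthetic cohort

No public voxel-level resting-state dataset accompanies this analysis, so
the package ships a seeded generator whose output has the statistical
structure the analysis assumes; every stage is exercised end-to-end
without any download.

Per network, a ring of K communities is built. Each community has a latent
time-course; community latents share a network latent with weight
`between_community_r / within_community_r`, so the clean correlation
between voxels of different communities equals `between_community_r`. A
voxel's signal is `alpha × latent + noise_sd × white noise`, with
`alpha = sqrt(r / (1 − r))` solved from the target within-community
correlation `r` for unit-variance noise. This calibration is anchored at
the default `noise_sd = 1`: realized correlations then match the targets;
raising `noise_sd` lowers them monotonically, and `noise_sd = 0` gives
perfectly correlated communities (the clean path used by several tests).

A fraction (default 0.15) of each community's voxels are *bridges* that mix
the latents of two ring-adjacent communities. Real voxel data is spatially
autocorrelated, which keeps thresholded voxel graphs connected even at
conservative thresholds; the bridges emulate exactly that property, and
they are why the largest component retains ≥ 90% of voxels at T = 0.55.

Latents are synthesized in the frequency domain with fixed per-bin
amplitudes and uniformly random phases: the fraction of (non-DC) power in
0.01–0.08 Hz equals `low_freq_fraction` *by construction*, which makes the
spectral-recovery tests sharp rather than statistical.

Nuisance sources — six motion-like random walks and band-limited
white-matter, ventricular and global signals — are injected into every
painted voxel with independent Gaussian per-voxel loadings at configurable
amplitudes (zero amplitudes are supported), and are recorded as the
regressor channels the preprocessing consumes. A cohort-level latent is
coupled to network latents with weight `group_coupling`, positive for
cognitive and negative for perceptual networks, reproducing the
cognitive-versus-perceptual anti-correlation structure seen in the
cross-network matrix of real data.

### Default study conditions

Twelve subjects, 250 volumes at TR = 2 s, grid 24×24×12, six networks of
160–260 voxels with 10% pairwise overlap between ring-adjacent networks.
Cognitive networks: 6–7 communities, within/between community r =
0.85/0.15, low-frequency fraction 0.75–0.78. Perceptual networks: 3
communities, 0.85/0.20, low-frequency fraction 0.55–0.62. These sizes are
a desk-scale stand-in for real voxel counts (thousands per network); they
were chosen once so that the default cohort reproduces the qualitative
group dichotomy — higher σ, γ, λ and band power and lower C for the
cognitive group — and they are configuration, not claims about effect
sizes in real data, for which no quantitative connectivity difference is
available to calibrate against.

### What the generator does not emulate

No hemodynamic response or neural-mass dynamics, no scanner artifacts, no
spatial normalization errors, and only stylized spatial autocorrelation
(bridges instead of smooth spatial kernels). Passing tests therefore show
that the *analysis machinery* behaves as specified under the assumed
statistical structure — not that real data would produce any particular
effect size.

## Numerical choices

- **Filter realization.** Zero-phase forward-backward Butterworth of order
  2 (`signal::butter` + `filtfilt`), the standard resting-state choice.
  Measured gains: 0.996 at band center (0.04 Hz), 7×10⁻⁴ at 0.2 Hz, 0.043
  at 0.005 Hz — within the contract (passband ≥ 0.9; one octave outside
  either edge ≤ 0.1). Rows are demeaned before filtering: DC lies outside
  any passband analytically, and removing it first avoids edge-transient
  leakage of the mean.
- **Temporal derivatives.** Backward differences with first entry 0; the
  discretization is not dictated by the analysis description, and this is
  the simplest causal choice.
- **Intercept.** Included in the nuisance design so residuals are
  mean-free before correlation; non-intercept columns are mean-centered.
- **Rank deficiency.** The regression falls back to the Moore–Penrose
  pseudoinverse with a warning instead of failing.
- **Signed thresholding.** Edges require r > T (not |r| > T): all grid
  thresholds are positive, and the grid-minimum rationale concerns weak
  positive coupling. An `absolute = TRUE` switch exists.
- **Disconnected pairs.** L is restricted to the largest connected
  component (reported alongside as `lcc_fraction`); the ≥ 90% coverage at
  the grid maximum keeps this close to the all-pairs value. The
  harmonic-mean alternative was rejected to stay close to the plain
  definition.
- **Spectra.** Raw periodogram of the mean time-course, no taper, no
  Welch averaging; "energy" is summed periodogram power over discrete
  non-DC frequencies. Power is normalized so that the non-DC ordinates sum
  to t × population variance (discrete Parseval, asserted in tests to
  1e-8). fALFF uses the power-ratio convention by default; the
  square-root-amplitude convention is available via `mode = "amplitude"`.
- **Rewiring.** Each null draw performs 10 × E successful double-edge
  swaps. For graphs denser than half of all pairs the chain runs on the
  graph *complement* (a swap there preserves the complement's degrees,
  hence the original degree sequence exactly, and mixes far faster when
  few non-edges remain); the budget is then 10 × E_complement. A complete
  graph admits no swap and is returned unchanged with a warning.
- **Theoretical baselines.** C_rand = k/N and L_rand = ln N / ln k are
  exposed only as a sanity cross-check; γ, λ, σ always use the empirical
  rewired ensemble, whose degree sequence matches the data.
- **Node equalization.** Uniform subsampling without replacement to the
  smallest network's size, 10 seeded draws by default, metrics averaged
  over draws.
- **Randomness.** All stages draw from named substreams derived from one
  root seed, so the generator, equalization and rewiring are
  independently reproducible.
- **Two-way ANOVA.** The second factor is network nested within group,
  subjects as replicates; `subject_block = TRUE` adds subject as an
  additive block (changing the error degrees of freedom). The Bonferroni
  family sizes are explicit arguments, logged in the output rather than
  hidden.

## Design choices that were genuinely open

- **Spectra pre- or post-regression?** Computed on regressed series:
  nuisance variance is not signal, but the full frequency range must
  remain, so filtering is not applied. A `filter = FALSE` path through
  `preprocess_subject()` makes the choice explicit and switchable.
- **Nulls per graph instance.** The 30-network ensemble is generated per
  (subject × network × threshold) graph, each with its own derived seed.
- **No on-disk stage cache.** At the problem sizes used here (see below)
  every stage re-runs in seconds, so result tables carry full provenance
  instead of a content-addressed cache.
- **Smoothing off by default.** Voxel-graph analyses on smoothed data
  inflate local correlations; `smooth_fwhm_mm = 8` reproduces the
  with-smoothing arm of the sensitivity comparison.

## Problem sizes and what to expect

The test-suite and acceptance runs use the 12-subject default cohort with
~150–240 exclusive voxels per network; a full run (threshold sweep, 30
nulls per graph at T\*, statistics) completes in about a minute on one
core. At this scale the cognitive/perceptual ordering of every metric is
stable across seeds, but the magnitudes are not those of real data:
cognitive σ runs ~2–3 (real voxel networks: ~1.3–1.5) and λ runs ~1.0–1.15
rather than pinning to 1. In particular "λ ≈ 1" should be read as λ small
relative to γ — with modular synthetic graphs at a few hundred nodes a
one-sample test can still distinguish λ from 1, which is expected and not
a failure of the machinery.

## Known limitations

- The generator's group differences are qualitative by design; no
  published quantitative connectivity difference exists to calibrate
  against.
- Degree-below-2 nodes contribute C_i = 0 to the network average, which
  biases C downward in very sparse graphs (highest thresholds).
- `filtfilt` edge transients make the first/last few samples of filtered
  series less reliable; gain contracts are asserted on the series
  interior.
- The ln N / ln k path-length baseline is accurate only when k ≈ √N; it is
  a cross-check, never part of σ.
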