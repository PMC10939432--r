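---
title: "Posture dynamics of developing C. elegans locomotion: methods and design"
author: "wormPosture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormPosture)
```

# The model

A tracked worm is summarised per video frame by ten inter-segment bending
angles $\theta(s)$, $s = 1,\dots,10$ (the body is divided into eleven
segments along the anterior–posterior axis; angles are in radians, signed by
the dorsal–ventral convention of the tracker, sampled at 14 Hz). The posture
repertoire of a gait is characterised by the population covariance over all
pooled frames,

$$C(s, s') = \big\langle (\theta(s) - \langle\theta\rangle)\,
             (\theta(s') - \langle\theta\rangle) \big\rangle ,$$

whose eigenvectors $\mu_i(s)$ — *eigenworms* — are canonical body shapes and
whose eigenvalues $\lambda_i$ measure the posture variance each shape
captures. Any posture is a linear combination of eigenworms; the projection
coefficients $a_i(t) = \langle \theta_t - \langle\theta\rangle, \mu_i\rangle$
are the *eigenworm amplitudes*. Coordinated undulation confines $(a_1, a_2)$
to a ring whose angular position encodes the phase of the locomotor cycle.

Three derived quantities carry the analysis:

* **Cumulative variance** $\sigma_k^2 = \sum_{i \le k}\lambda_i / \sum_i
  \lambda_i$, the fraction of posture variance captured by the first $k$
  eigenworms.
* **Participation ratio** $\mathrm{PR} = (\sum_i \lambda_i)^2 / \sum_i
  \lambda_i^2$, a continuous dimensionality between 1 (one mode) and $S$
  (evenly spread variance). It is computed per recording from that
  recording's own covariance, so each tracked session contributes one
  dimensionality estimate to its developmental-stage group.
* **Phase-resolved speed**: the Euclidean step length between consecutive
  points in amplitude space times the sampling frequency, binned by the
  instantaneous phase of $a_1$ (the angle of its analytic signal, computed
  by FFT). A wave propagating at uniform angular speed gives a flat
  profile; within-cycle modulation (the swimming "dwell in the C-shape")
  gives a bimodal one.

Amplitude distributions are visualised with a 2D Gaussian kernel density
estimate whose kernel covariance is the data covariance scaled by Scott's
rule, $n^{-2/(d+4)}$ with $d = 2$ — the covariance-scaled convention, not
the product of per-axis bandwidths.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `samplingRate` | 14 | Hz | tracker frame rate of the recording format |
| `nAngles` / `nSegments` | 10 | — | eleven body segments give ten angles |
| `kEigenworms` | 4 | — | four eigenworms suffice for both gaits' variance curves |
| `nPhaseBins` | 24 | — | 15° bins balance angular resolution against per-bin counts |
| `edgeTrim` | 0.5 | s | the analytic signal is unreliable near record edges |
| `minFrames` | 28 | frames | ≈2 s at 14 Hz; PR and phase on fewer frames are noise |
| `alpha` | 0.05 | — | family-wise error rate before Bonferroni division |
| `coreFraction` | 0.5 | — | ring-center radius threshold, relative to the median radius |
| KDE grid | 128×128, ±3 bandwidths | — | presentational; stated for reproducibility |

`minFrames`, `edgeTrim`, `coreFraction` and the KDE grid are package
decisions; sampling rate and segment count follow the tracking convention
of the recording format.

# Statistical testing

Stage groups of per-recording PRs are compared with all $G(G-1)/2$
two-sided two-sample t-tests; with the six developmental groups (young L1,
late L1, L2–L4, adult) that is 15 comparisons and a Bonferroni-adjusted
threshold of $0.05/15 = 0.0033$. Both the equal-variance and the Welch
variant are exposed; Welch is the default because group variances differ
markedly across stages (young L1 cohorts are far more dispersed), while the
equal-variance variant is retained for exact reproduction of published
swimming comparisons. Sidedness is always two-sided. Pairs with a group
smaller than two recordings are skipped with a warning but still counted in
the correction denominator, keeping the threshold conservative.

# The synthetic undulation generator

`generateUndulation()` emulates exactly the statistical structure the
analysis assumes, so the full pipeline is testable without any download:

$$\theta(s, t) = A\, e(t) \sin\!\Big(\frac{2\pi s}{S\,\lambda} - \phi(t)\Big)
 + \varepsilon_{s,t}, \qquad
 \dot\phi = 2\pi f\,(1 + m\cos 2\phi),$$

with amplitude $A$ (0.6 rad), spatial wavelength $\lambda$ in body lengths
(swimming-like 2.0 — the long C/S shapes; crawling-like 1.0 — a full
sinusoid along the body), frequency $f$ (2.0 vs 0.5 Hz) and within-cycle
speed-modulation depth $m$ (0.4 vs 0). These swim/crawl contrasts are chosen
to make the two gaits' eigenworms visibly distinct and to reproduce the
bimodal-versus-flat phase-speed contrast by construction; they are not
calibrated worm kinematics. Measurement noise $\varepsilon$ is i.i.d.
Gaussian per segment and frame (0.05 rad).

Coordination lapses — the young-L1 phenotype of intermittent uncoordinated
movement — are modelled minimally: Poisson onsets at `lapseRate` per second,
exponential durations (mean 0.5 s), during which the wave envelope $e(t)$
relaxes to 0 with a 0.2 s time constant and the noise is replaced by
independent segment noise of three times the baseline sd. Any mechanism
that collapses the ring and spreads variance across segments would raise PR
and center occupancy; this one is simple and seedable. Identical parameter
sets (including the seed) give bit-identical recordings, and the global RNG
stream is untouched.

What the generator does **not** emulate: head/tail asymmetries and
non-sinusoidal waveform harmonics, slow frequency drift, postural bias
(nonzero mean posture), tracking gaps and outliers, and the young-L1
crawling phenotype of *altered eigenworm shapes* (it only degrades
coordination, not the shapes themselves). Passing tests therefore
demonstrate the correctness of the estimators on data satisfying the
model's assumptions, not robustness to every artefact of real tracking
data.

# Numerical choices

* **Population normalisation.** The covariance divides by the total frame
  count $T$, matching the bracket-average definition. This differs from the
  sample ($T-1$) convention by a factor irrelevant to everything
  scale-invariant here (PR, variance fractions, eigenvectors), but is
  documented so reimplementations can reconcile eigenvalues exactly.
* **Pooled mean.** The mean subtracted before pooling covariances is the
  grand mean over all pooled frames (not per-recording means). For
  mean-centred undulations the two choices agree; with postural bias they
  differ, and the grand mean keeps the covariance a true second moment of
  the pooled cloud.
* **Eigenvector conventions.** The eigendecomposition is sign-ambiguous, so
  each eigenworm is flipped to make its largest-magnitude loading positive;
  numerically tied eigenvalues are ordered by the ascending index of the
  dominant loading and flagged as degenerate. This makes golden-file tests
  and CSV exports stable across platforms.
* **Phase conventions.** Phase increases in the direction of temporal
  progression (the analytic phase of $\cos \omega t$ advances at $+\omega$);
  the signal is mean-subtracted first; the first and last 0.5 s of each
  recording are excluded from pooled phase statistics; phase is computed per
  recording before pooling across animals; and the speed over the step
  $t \to t+1$ is assigned the phase at frame $t$. At 7 samples per cycle
  (2 Hz at 14 Hz) the frame-$t$ assignment lags the midpoint by up to half
  a frame of phase — about 0.45 rad — which shifts, but does not blur, the
  profile extremes.
* **Ring separation.** Two coordinated gaits in one mean-subtracted
  embedding trace rings that are both centred near the origin, so a
  centroid-distance criterion cannot distinguish them. `ringSeparation()`
  therefore reports, alongside the centroid/spread ratio, the largest
  principal angle between the two epochs' best-fit ring planes; rings are
  called separated when that angle exceeds 45° (more than halfway to
  orthogonal). On the synthetic swim/crawl concatenation the measured angle
  is about 65° with a centroid ratio near zero.
* **Degenerate inputs.** Constant recordings, all-zero spectra, collinear
  KDE inputs and constant phase signals raise typed errors rather than
  returning NaN; rows with non-finite angles are dropped at read time with
  a count.

# Problem sizes in the test suite

The suite runs entirely on synthetic data: covariance oracles on up to
200×10 matrices, wave recordings of 10–120 s at 14 Hz, the lapse-rate
monotonicity check on 20 recordings of 30 s per rate, the independent-noise
limit at 2000 frames, and the end-to-end cohort of 6 stages × 2 gaits × 10
recordings of 10 s. These sizes give stable statistics (e.g. PR sampling
error well under the asserted 0.05 at 2000 frames) while keeping the whole
suite under a minute of compute on one core. One acceptance check — the
reproduction of published variance fractions and stage-mean PRs from the
deposited tracking dataset — requires that dataset to be downloaded and
unpacked locally (see the README) and fails with an explanatory message
when it is absent.

# Known limitations

* Eigenworm bases are linear; strongly curled postures (omega turns) are
  not compactly represented and will inflate PR.
* The phase estimate assumes a narrowband $a_1$; recordings mixing two
  gaits should be split (or embedded with `transitionEmbedding()`) before
  phase statistics are pooled.
* The reader tolerates irregular timestamps (gaps are kept, flagged by the
  frame-interval warning), but all spectral quantities assume the nominal
  sampling rate; heavily gapped recordings should be excluded upstream.
* Group tests assume independent recordings; repeated tracking of one
  animal violates this and is not modelled.

# A worked example

```{r example, eval = FALSE}
root <- tempfile("cohort"); out <- tempfile("results")
profiles <- list(
  youngL1 = undulationParams(durationS = 30, lapseRate = 0.5),
  adult   = undulationParams(durationS = 30))
generateStageCohort(profiles, nPerStage = 10, baseSeed = 1, root = root)
cfg <- analysisConfig(root, out, gait = "swimming",
                      stages = c("youngL1", "adult"))
res <- runFullAnalysis(cfg)
res$swimming$stageSummary
```
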