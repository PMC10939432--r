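# wormPosture

Quantitative analysis of undulatory locomotion in developing
*Caenorhabditis elegans*, for researchers studying how coordinated
movement emerges across larval stages. The package consumes tracked
segment-angle time series (the 11-column text format: timestamps plus ten
inter-segment angles in radians at 14 Hz) and answers three questions about
a locomotor repertoire:

* **How low-dimensional is it?** Postures are decomposed into *eigenworms*
  — eigenvectors of the posture covariance
  `C(s,s') = ⟨(θ(s)−⟨θ⟩)(θ(s')−⟨θ⟩)⟩` — and summarized by cumulative
  variance fractions `σ²_k = Σ_{i≤k} λ_i / Σ λ_i` and the per-recording
  participation ratio `PR = (Σλ)² / Σλ²`, a continuous dimensionality
  between 1 and the number of segments.
* **How is the locomotor cycle organized?** The first two eigenworm
  amplitudes trace a ring whose angle is the cycle phase; the package
  computes trajectory speed in amplitude space, the analytic-signal
  (Hilbert) phase of the first amplitude, phase-binned speed profiles
  (bimodal in swimming, flat in crawling), covariance-scaled Gaussian
  kernel densities of the amplitude distribution (Scott's rule), and a
  ring-center occupancy statistic for coordination lapses.
* **Do stages differ?** Per-recording PRs are grouped by developmental
  stage and compared with all pairwise two-sample t-tests (equal-variance
  or Welch) under Bonferroni correction (six stages → 15 pairs → adjusted
  alpha 0.05/15 ≈ 0.0033).

A seedable synthetic undulation generator (traveling bending waves with
gait-specific wavelength and frequency, within-cycle speed modulation,
measurement noise, and Poisson coordination lapses) emits the same
11-column format, so every stage of the pipeline runs and is tested without
any external data.

## Worked example

Generate a two-stage synthetic swimming cohort — young L1 worms lapse into
uncoordinated movement at 0.5 episodes/s, adults do not — and run the full
pipeline:

```r
library(wormPosture)

root <- tempfile("cohort"); out <- tempfile("results")
profiles <- list(
  youngL1 = undulationParams(durationS = 30, lapseRate = 0.5),
  adult   = undulationParams(durationS = 30))
generateStageCohort(profiles, nPerStage = 10, baseSeed = 1, root = root)

cfg <- analysisConfig(root, out, gait = "swimming",
                      stages = c("youngL1", "adult"))
res <- runFullAnalysis(cfg)

res$swimming$stageSummary
#>     stage  n   meanPR      q25      q75         iqr
#> 1   adult 10 1.957879 1.956768 1.958413 0.001644157
#> 2 youngL1 10 2.093580 2.065124 2.083131 0.018007481

res$swimming$pairwiseTests
#>   stageA  stageB tStatistic       pValue testVariant significant
#> 1  adult youngL1  -6.788264 7.923313e-05       welch        TRUE
```

The adult cohort sits at the two-mode dimensionality of a clean traveling
wave (PR ≈ 2, the sine/cosine pair of the ring), while lapsing young-L1
recordings spread variance across additional modes and come out
significantly higher — the developmental contrast the statistics are built
to detect. `out/swimming/` now holds the CSV tables: `eigenworms.csv`,
`variance.csv` (eigenvalues and cumulative variance), `pr.csv`,
`pr_summary.csv`, `pairwise_tests.csv`, `phase_speed.csv`, per-stage
`density_<stage>.csv` grids, `basis_similarity.csv`, and a `run.log`
recording every exclusion and threshold.

A thin command-line front end over the same functions ships in
`inst/scripts/wormposture` (subcommands `simulate`, `eigen`, `pr`, `speed`,
`density`, `transition`, `analyze`).

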