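# ecocycle

Seasonality and environmental coupling of marine microbial time series, with
the SAR11 (Pelagibacterales) ecotypes as the model system.

Surface-ocean bacterioplankton communities cycle with the seasons: at a
temperate coastal station, "warm" ecotypes such as SAR11 Ia.3 peak in
summer while Ia.1 and IIa.B peak in winter, and the community as a whole
swings between two states each year. ecocycle packages the analyses needed
to establish and dissect that behaviour from amplicon sequence variant
(ASV) count tables with sample dates and an environmental metadata table —
the post-processing products of a 16S rRNA survey — for people who study
multiannual marine (or any dated) microbial time series.

## What it computes

* **Community preparation** — dated count matrices (`count_matrix`),
  TSV/CSV/BIOM-JSON I/O, rarefaction without replacement, relative
  abundance, ecotype-level aggregation, SAR11 fraction per sample.
* **Time decay** — mean Bray–Curtis dissimilarity as a function of
  calendar-day lag, fitted with an exactly periodic cubic B-spline basis
  (df = 4, period = 366 days). An annually cycling community peaks near the
  half period:

  `mean_d(ℓ) = Σ_k β_k B_k(ℓ mod 366)`, with `B_k(t) = B_k(t + 366)`.

* **Seasonality screening** — per ASV, Fisher's exact g-test on the
  periodogram (`g = max_k I(f_k) / Σ_k I(f_k)` with the exact null tail),
  BH adjustment across ASVs, and a harmonic regression
  `y ~ 1 + cos 2πd_c/365 + sin 2πd_s/365` (midwinter- and New-Year-anchored
  days) whose fitted peak day classifies significant ASVs as
  summer-peaking (2 May – 21 September) or winter-peaking.
* **Ordination** — PCoA, distance-based RDA on environmental variables
  (constrained proportion and permutation-adjusted R²), one-way PERMANOVA
  with seeded or exhaustive permutations, warm/cold hierarchical
  clustering.
* **Environmental coupling** — Monday-grid alignment, min–max
  standardization, consecutive-week Bray–Curtis vs Euclidean distance
  series, Morlet wavelet coherence with white-noise Monte-Carlo
  significance, coupled/uncoupled segmentation, and per-variable
  Mann–Whitney comparison between phases.
* **Synthetic data** — a generator (`simulate_dataset()`, `presets()`)
  producing monthly open-ocean and weekly coastal designs with antagonistic
  summer/winter ASV guilds, a 17-variable environment driven by a shared
  weather/mixing state, Dirichlet-multinomial counts, and a per-year
  environment→community coupling switch, plus the ground truth to score
  every stage.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data: `01_simulate.R` writes four datasets under `results/data/`, and
`02`–`06` analyse them. A condensed session:

```r
library(ecocycle)

ds <- simulate_dataset("wec_like", seed = 1)   # 7 y weekly coastal design
sar11 <- subset_count_matrix(ds$counts,
                             asvs = ds$taxonomy[ds$counts$asv_ids] != "other")
rar <- rarefy(sar11, seed = 1)
bc <- pairwise_distance(rar$counts, "bray_curtis")
curve <- fit_periodic_spline(time_decay(bc, rar$dates))
first_peak_lag(curve)
#> [1] 172

tab <- seasonality_screen(relative_abundance(ds$counts), "weekly")
table(tab$class)
#>      nonseasonal summer winter
#>               14      8      8
```

Running the scripts prints, among other things:

```
community turnover is maximized at a lag of 172 days (first interior peak of the fitted curve)
detected 16 / 16 truly seasonal ASVs (100%)
correct summer/winter class in 100% of detections
false positive rate among aperiodic ASVs: 0%
environmental variables explain 63% (adjusted 61%) of SAR11 community variance
PERMANOVA: pseudo-F = 478.669 (df 1,327), R2 = 0.594, Pr(>F) = 0.001 [999 permutations]
coupled_year     68% of weeks coupled (1 interval(s))
decoupled_year    0% of weeks coupled (0 interval(s))
```

Read: the community repeats annually (turnover maximal ~half a year apart);
every planted seasonal ASV is recovered with the right guild and no false
positives among the aperiodic ones; the environment explains most
community variance and the warm/cold split is as strong as a permutation
test can report (p = 0.001, the floor at 999 permutations); and the
year in which the community tracks the same-week environment shows
sustained significant in-phase wavelet coherence, while the decoupled
(stormy, homogenized) year shows none.

The methods vignette (`vignettes/seasonal-dynamics.Rmd`) documents the
models, parameter choices, the generator's assumptions and the estimators'
known limitations.

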