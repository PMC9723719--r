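---
title: "Seasonality and environmental coupling of marine microbial time series"
author: "ecocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonality and environmental coupling of marine microbial time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

ecocycle analyses multiannual 16S rRNA amplicon time series of marine
bacterioplankton, with the SAR11 (Pelagibacterales) ecotypes as the model
system. Two sampling designs are targeted: a monthly open-ocean series
(BATS-style, oligotrophic gyre) and a weekly coastal series (Western English
Channel L4-style, temperate shelf). The pipeline asks three questions:

1. **Does the community cycle annually?** Pairwise Bray–Curtis
   dissimilarities of rarefied SAR11 ASV counts are averaged over all sample
   pairs sharing the same calendar-day lag (the time-decay curve) and fitted
   with a periodic spline. An annually cycling community produces a curve
   whose first interior maximum sits near the half period, ~180 days:
   communities half a year apart are maximally different.
2. **Which ASVs drive the cycle, and when do they peak?** Each ASV's
   relative-abundance series is screened with Fisher's exact g-test on the
   periodogram, and classified by a harmonic regression whose peak day
   assigns it to the summer or winter guild.
3. **Does week-scale community change track week-scale environmental
   change?** On the weekly design, consecutive-week Bray–Curtis distances
   (community) and Euclidean distances over min–max-standardized
   environmental variables are compared by Morlet wavelet coherence;
   coherent, in-phase, significant regions mark weeks where the community is
   coupled to its environment.

Constrained ordination (db-RDA) on the environmental table, PERMANOVA of the
warm/cold split, and hierarchical clustering complete the picture of a
two-state annual community.

## Models and conventions

### Time-decay and the periodic spline

For samples $i, j$ with dates $t_i, t_j$, all pairs with identical lag
$\ell = |t_i - t_j|$ (whole days; no binning beyond identical-lag grouping)
are averaged. The fitted curve uses a cyclic cubic B-spline basis with
`df = 4` basis functions wrapped on $[0, 366)$ days, so every basis function
satisfies $B(t) = B(t + 366)$ exactly; coefficients come from ordinary least
squares on the per-lag means. The basis is built with `mgcv::cSplineDes`,
whose wrapped knot vector gives exact periodicity; because cyclic B-splines
sum to one, the basis spans constants and no intercept is added. The peak is
read off the fitted curve on a 1-day grid rather than off the noisy means —
the means' maximum wanders by weeks, the smooth fit's does not.

### Harmonic design and the warm window

The annual harmonic uses two predictors:
$X_c = \cos 2\pi d_c / 365$ with $d_c$ the days since the most recent
21 December (midwinter anchor), and $X_s = \sin 2\pi d_s / 365$ with $d_s$
the days since 1 January. Both terms are fitted jointly by OLS; the model
F-test and the (BH-adjusted) Fisher g-test must both pass at
$\alpha = 0.05$ for an ASV to be called seasonal. The peak day is the argmax
of the fitted harmonic on a 1-day grid; peaks inside the warm window
(2 May – 21 September, the cold/warm split used for sample clustering) are
"summer", the rest "winter". The two-test rule matters in practice: a purely
semiannual artefact (see *Compositional closure* below) passes the g-test
but not the annual F-test.

Fisher's test needs even spacing, so each ASV series is first linearly
interpolated onto a regular grid (7 days for weekly designs, 365/12 days for
monthly ones). Relative abundances enter the regression untransformed.

### Ordination, PERMANOVA, clustering

PCoA discards negative-eigenvalue axes (no Lingoes/Cailliez correction), so
the constrained proportion of the db-RDA stays interpretable as a fraction
of representable inertia. The db-RDA regresses the retained PCoA axes on the
column-standardized environmental table; its adjusted $R^2$ is
permutation-based — the mean $R^2$ of row-permuted environment tables is
subtracted and the remainder rescaled — because Ezekiel's formula is not
defined for non-Euclidean dissimilarities. PERMANOVA uses the standard
pseudo-F on squared dissimilarities with
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$; for two-group designs
with few samples, complete enumeration of splits is available and exact.
Hierarchical clustering uses average linkage (UPGMA); the two clusters are
annotated warm/cold by the majority of their sample dates falling in the
warm window.

### Weekly grid and wavelet coherence

Sampling dates snap to the closest Monday (offsets of 0–3 days backwards,
4–6 forwards — never more than 3 days of movement); collisions keep the
sample whose original date is nearer; remaining gaps are filled by linear
interpolation of the per-ASV abundances and per-variable environmental
values (interpolate-then-distance). Environmental variables are min–max
standardized to $[0,1]$ before Euclidean distances; constant variables are
degenerate under this map and dropped with a warning.

The Morlet CWT ($\omega_0 = 6$) uses the standard FFT formulation with
zero-padding to the next power of two, a dyadic scale grid at 1/20-octave
steps covering periods from 2 weeks to half the record, and a
$\sqrt{2}\,s$ e-folding cone of influence. Coherence smoothing follows the
Torrence–Webster pattern — a Gaussian in time whose width is proportional to
scale and a 0.6-octave boxcar across scales — with one deliberate choice:
the Gaussian's standard deviation defaults to **two** e-folding scales
rather than one (`time_smooth = 2`). At record lengths around a hundred
weeks, single-width smoothing leaves so few degrees of freedom that the 95%
white-noise coherence threshold sits near 0.85–0.9 and essentially no
realistic signal can reach significance; doubling the width lowers the
threshold to ~0.75 while keeping null calibration (verified by simulation:
the fraction of significant cells for independent noise pairs stays at the
nominal 5–6%). The cost is time resolution: a regime boundary is recovered
only to within a few driver periods, which the two-regime tests assert
explicitly. Significance is cell-wise Monte-Carlo against white-noise
surrogate pairs (the package default; an AR(1) null would be stricter for
strongly autocorrelated series and is a known limitation of the white-noise
choice). A week counts as coupled when the 12-week rolling mean of the
coupling score — the fraction of in-COI scales that are significant and in
phase ($|\Delta\phi| < \pi/4$) — reaches 0.2. Weeks whose cone of influence
excludes every scale (the outermost few weeks of the record) score zero: the
segmentation is conservative there by construction.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, so
every stage is testable without sequence downloads. Its defaults describe
the weekly coastal design: 7 years, 10% of interior weeks missed, 30 ASVs.

* **Environment.** 17 variables on the sampling grid: temperature is an
  annual sinusoid (mean 13.4 °C, amplitude 5.8 °C, trough mid-February,
  matching a temperate shelf's 7.6–19.2 °C span); nitrate, nitrite, silicate
  and phosphate peak midwinter and are floored at zero; chlorophyll has a
  spring-bloom Gaussian bump; wind and river flow are log-normal AR(1)
  series whose level scales with a per-year storminess setting; oxygen, air
  temperature, PAR, net heat flux, salinity, turbidity, ammonium and
  humidity fill out the table as correlated nuisance variables.
* **The mixing state.** Week-scale change in coastal surface water is
  weather-coherent: one latent "mixing state" $\delta(w)$ — an AR(1) core
  under a slowly varying storm-regime envelope with a quasi-periodic
  ~8-week storm-cycle component — loads onto most variables at once
  (cooling, nutrient injection, turbidity, river input, deoxygenation of
  stratification). The log-envelope is centred per realization: the year's
  storm load is a configured condition, while regimes redistribute it within
  the year.
* **Community.** Each seasonal ASV $i$ has log-affinity
  $A\cos 2\pi(d - \mathrm{peak}_i)/365$ with $A = 1.2$ (an ~11-fold
  summer:winter swing). The winter guild mirrors the summer guild exactly —
  peaks offset by half a year, base shares paired — so the guilds' combined
  seasonal mass is semiannual, not annual, and compositional closure leaks
  no annual signal into the aperiodic ASVs. Seasonal ASVs additionally
  respond to the same-week mixing state with weight 0.5 (positive for
  summer, negative for winter ecotypes), through a saturating (tanh) and
  mean-neutral response: the expected multiplicative response under the
  week's anomaly distribution is divided out, so stormy regimes do not
  rectify the softmax denominator. Expected proportions are drawn
  Dirichlet with concentration 200 (realistic amplicon overdispersion) and
  counts multinomial at log-normal library sizes (~20,000 reads). Guild base
  shares are fixed (summer 22%, winter 22%, aperiodic SAR11 11%, non-SAR11
  45%), so the SAR11 fraction and ecotype tiers resemble a coastal series.
* **Coupling.** Per year, the effective seasonal log-affinity is
  $c \cdot \mathrm{signal} + (1 - c) \cdot \mathrm{MA}_8(\mathrm{signal})$:
  at $c = 1$ expected proportions respond to the same-week environment; at
  $c = 0$ the 8-week moving average removes the week-scale response —
  including the ~8-week storm cycle, which the moving average nulls exactly
  — while preserving the annual cycle. This implements decoupling as
  temporal homogenization: a permanently mixed surface layer blurs sharp
  transitions without erasing seasonality.

What the generator does **not** emulate: primer and sequencing-platform
biases, chimeras, taxonomic misassignment, long-term warming trends,
horizontal advection events, and any feedback from the community onto the
environment. Passing tests therefore demonstrate that the estimators recover
the structure they target under realistic sampling noise — not that real
SAR11 data are this clean.

## Numerical choices and degenerate inputs

* Rarefaction subsamples without replacement (multivariate hypergeometric);
  the default depth is the minimum total among samples with at least 1000
  reads, lower samples are dropped and reported. A single seeded draw is
  used, not repeated averaging.
* Zero-total samples are flagged, their relative abundances left as zero
  rows, and the SAR11 fraction reported missing.
* Fisher's p uses the exact alternating series on the log scale; constant
  series return $p = 1$ by convention.
* Bray–Curtis of two all-zero profiles is an error (undefined), as is a
  constant variable under min–max standardization.
* Collinear environmental columns are dropped with a warning (QR pivoting);
  missing values are imputed by per-variable linear interpolation in time
  before ordination.
* Merge ties in clustering follow `stats::hclust`'s deterministic order;
  everything stochastic (rarefaction, permutations, surrogates, simulation)
  flows from explicit integer seeds.

## Design decisions that were genuinely open

* **Multiplicity.** BH across ASVs is the default (none/bonferroni
  available): with tens to hundreds of ASVs screened, unadjusted p < 0.05
  overstates seasonality.
* **Combined significance rule.** The g-test certifies periodicity, the
  harmonic F-test certifies *annual* phase structure; requiring both keeps
  semiannual and other non-annual periodicities out of the summer/winter
  classification.
* **Single joint harmonic fit.** The two harmonic terms are fitted jointly
  rather than as competing one-term models; the peak-day rule is identical
  either way and the joint fit needs no model selection.
* **Problem sizes.** The synthetic designs used throughout the tests and
  scripts — 7 weekly years for seasonality, 2-year pairs for coupling, 100
  wavelet surrogates, 999 permutations where a permutation floor matters,
  199 elsewhere — are the smallest sizes at which the analyses' behaviour is
  stable; they keep a full run in minutes on a laptop.

## Known limitations

* The wavelet segmentation's time resolution is coarse — a few analyzed
  periods — so it distinguishes coupled from decoupled *records* robustly,
  but locates a mid-record regime change only approximately, and the
  outermost weeks of a record can never be labeled coupled (empty cone of
  influence). Sharper localization would need longer records or narrower
  smoothing, which at these record lengths costs all statistical power.
* White-noise surrogates understate the null coherence of strongly
  autocorrelated series; the coupled/uncoupled contrast reported by the
  package rests on the *difference* between regimes under identical nulls.
* The g-test is applied to linearly interpolated series; interpolation
  slightly reddens the spectrum and makes the test conservative at high
  frequencies, which is acceptable for annual periodicity on weekly or
  monthly grids.
* Lomb–Scargle for irregular series and AR(1) coherence surrogates are
  deliberate non-goals of this version.
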