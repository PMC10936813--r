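---
title: "Models and methods: simulating and measuring meiotic DSB interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and measuring meiotic DSB interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(meiodsb)
```

This vignette documents the models implemented by `meiodsb`, the parameters
that matter, the numerical choices made where the design was genuinely open,
and what the synthetic-data generator does and does not emulate. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The primed-domain model of Spo11 DSB formation

A cell's genome is modelled as chromosomes carrying DSB hotspots, grouped
into contiguous *priming domains* — sub-chromosomal regions that must mature
to a DSB-competent state before any of their hotspots can fire. Per cell:

1. **Prophase window.** The cell draws an exit time
   $T \sim \mathcal N(\mu, \sigma_T)$, truncated to $[0, t_{\max}]$. With
   `ndt80 = FALSE` (prophase arrest) $T = t_{\max}$ exactly for every cell.
   Defaults encode the genotype dependence of prophase kinetics: cells
   lacking Tel1 exit earlier (`exit_mean` 6.5 h vs 8 h, SD 1 h,
   `t_max` 10 h). These are configurable model choices, not measurements.
2. **Domain priming.** Each domain has a mean priming time $\tau_d$ and the
   cell realises $t_d = \max(0, \tau_d + \mathcal N(0, \sigma_j))$. The
   *primed fraction* of a domain is $f_d = P(t_d < T)$, available in closed
   form via `primed_fraction()`
   ($\Phi((\mu - \tau_d)/\sqrt{\sigma_T^2 + \sigma_j^2})$, with the strict
   inequality as tie-break when both SDs are zero, and neglecting the
   truncation of $T$ and the floor on $t_d$ — accurate when both means sit
   well inside $[0, t_{\max}]$).
3. **Firing.** From $t_d$ to $T$, in discrete steps $\Delta t$, each
   still-uncut hotspot–chromatid fires with probability
   $w\,\Delta t\,\sigma$, where $w$ is the hotspot's intrinsic rate
   (per chromatid per hour) and $\sigma$ is the Tel1 suppression factor
   $\prod_{\text{prior cuts}} (1 - s\,e^{-d/\lambda})$, floored at 0, over
   cuts at distance $d$ on the same chromatid ($s = 0$ whenever `tel1`
   is off). Four chromatids are simulated independently — the assays count
   broken chromatids, and the model needs no sister/homologue coupling.
4. **Cut placement.** A firing hotspot cuts at its midpoint plus uniform
   jitter within the hotspot width; coordinates are 1-based throughout.

Under this model with $s = 0$, observed double cuts factorise within the
primed subpopulation, so the coefficient of coincidence
$\mathrm{CoC} = \mathrm{DC}_{\text{obs}} / (f_1 f_2)$ tends to $1/f_d$ and
the measured interference $-\log_2(\mathrm{CoC})$ tends to $\log_2 f_d$:
heterogeneous priming alone produces apparent clustering. Tel1 suppression
adds a positive component, and the two combine approximately additively —
measured interference ≈ within-domain interference + $\log_2 f$.

### Key parameters

| parameter | units | default | role |
|---|---|---|---|
| `rate` ($w$) | per chromatid per h | lognormal, mean 0.0012 | intrinsic hotspot strength; default calibrated so a default genome (~4000 hotspots, 16 chromosomes) expects 100–200 breaks per cell over a typical 8 h window (`expected_breaks_per_cell()`) |
| `max_domain_span` | bp | 15 000 | cap on a priming domain's end-to-end span — activation zones are short-range |
| `tau0`, `tau_per_mb` | h, h/Mb | 3, 10 | priming-time gradient with distance from the centromere; the same deterministic value is exposed as the domain's association time (`rec114_time`), emulating early pericentromeric loading of pro-DSB factors |
| `exit_mean`, `exit_sd`, `t_max` | h | 8 (Tel1+) / 6.5 (tel1), 1, 10 | prophase-exit window per genotype |
| `suppression` ($s$), `decay_bp` ($\lambda$) | –, bp | 0.8, 10 000 | Tel1 suppression strength and reach; the quantitative values are illustrative — the biology constrains neither precisely |
| `dt` | h | 0.1 | hazard discretisation step |
| `background_rate` ($\beta$) | HpM/bp | 0 | uniform non-specific reads added to simulated break maps |

### Numerical choices in the simulator

* **Discrete-time hazard, not exact event simulation.** Suppression changes
  only at cut events, so a step scheme is adequate; the per-step bias is
  $O(w\,\Delta t)$. `w * dt > 1` is rejected outright (probability
  overflow).
* **Two samplers, one law.** With $s = 0$ hotspot–chromatids are
  independent, and firing steps are drawn directly from the truncated
  geometric distribution (fast, used for genome-scale runs). With $s > 0$ a
  step-by-step loop applies $\sigma$ from the accumulated cuts.
  `method = "step"` forces the loop, which keeps common random numbers
  across suppression strengths for monotonicity comparisons.
* **Same-step collisions.** Candidates that fire in the same step are
  resolved sequentially in random order; each later candidate, drawn at rate
  $p\,\sigma_{\text{old}}$, is thinned to $p\,\sigma_{\text{new}}$ by
  accepting with probability $\sigma_{\text{new}}/\sigma_{\text{old}}$. With
  full, long-range suppression ($s = 1$, large $\lambda$) this makes a
  second same-chromatid cut impossible, as it should be.
* **Suppression distances** are measured between hotspot midpoints; the
  uniform cut-position jitter is applied after firing.
* **Cis by default.** Whether suppression acts only on the cut chromatid or
  across chromatids is biologically unresolved; `cis_only = FALSE` switches
  to trans action, and nothing in the package asserts either.
* **Reproducible substreams.** Each cell seeds its own RNG stream by a fixed
  counter scheme, `(seed + 48271 * cell) mod (2^31 - 1)`, so enlarging
  `n_cells` extends the population without reshuffling earlier cells.

### What the generator emulates — and what it does not

Emulated: per-cell stochastic domain priming with a centromere-anchored
timing gradient; genotype-dependent prophase windows (finite for `NDT80+`,
arrest otherwise); four chromatids per cell; distance-dependent suppression
of subsequent cuts; uniform background contamination of break maps; the
blot's bookkeeping artefacts (below). Timepoint censuses expose a cut at
census $t$ only if it formed before $\min(t, T)$.

Not emulated: resection and repair, homologue engagement, Mec1 signalling,
replication timing, chromatin feature covariates of hotspot strength,
sequencing artefacts other than uniform background, and any attempt to fit
the simulator's parameters to measured gel percentages. Passing tests
therefore show that the *statistics* behave as derived under the model's
assumptions — not that the model captures every feature of real libraries.

## The blot-style assay surface

`breaks_to_assay()` reports frequencies as fractions of chromatids (the
analogue of fraction-of-lane signal on a gel), in two modes:

* `ideal` — a chromatid counts for a single-cut assay if cut at the target
  hotspot; for a DC assay if cut at both hotspots, regardless of other cuts.
* `blot` — what a gel can see: a single counts only if the *nearest* cut on
  the probe side is the target (a closer cut occludes the fragment), and a
  DC counts only with no intervening cut. Gels count broken chromatids, not
  cuts.

This makes the classic correction an exact bookkeeping identity on a
two-hotspot molecule: blot-mode distal single + DC = ideal distal single,
which is the rationale for `correct_distal_single()` (adding the measured
DC frequency to an occluded distal measurement). `correct_multicopy()`
implements the complementary probe correction: when the DC probe hybridises
to `copies` loci, only `1/copies` of the parental signal derives from the
assayed locus, so the measured fraction is multiplied by `copies` (capped at
1 and flagged).

## The interference statistic

`dsb_interference()` averages each assay over the requested timepoints
(default 6 and 8 h, to damp technical variation; repeats missing a timepoint
are flagged, never dropped), corrects the DC frequency, forms
expected DCs as the product of the two singles, and reports per-repeat
$-\log_2(\text{obs}/\text{exp})$. Numerical rules:

* **Near-zero exclusion.** The ratio is unstable when both terms approach
  zero; entries with observed or expected at or below `epsilon` (default
  `1e-4` in fraction units — the qualitative exclusion practice made
  explicit) are flagged and excluded, never reported as ±Inf.
* **Average after the transform.** Per-repeat interference values are
  averaged on the $-\log_2$ scale, then compared between genotypes with a
  pooled-variance two-sample two-tailed t-test (`aggregate_and_compare()`).
  The comparison is made on per-repeat interference values; comparing raw
  frequencies instead is possible by passing them directly, and neither is
  asserted as the only valid choice.
* **Degenerate test.** With zero pooled variance the t statistic is
  undefined; the documented rule is $p = 1$ if the group means are equal,
  else $p = 0$, with a `degenerate` flag.
* Frequencies are fractions internally; percentages appear only in I/O or
  display.

## Hotspot calling and NormHpM

`call_hotspots()` implements: Hann-smooth the strand-combined HpM profile
(201 bp window, weights $0.5(1-\cos(2\pi k/(N-1)))$ normalised to sum 1;
raw window sum $(N-1)/2 = 100$, so an impulse of mass $m$ peaks at $m/100$);
threshold the smoothed profile at 0.193 HpM; merge intervals whose gap
(`next.start - prev.end - 1`) is under 200 bp; then apply the 25 bp minimum
length and 25-read minimum mass. Choices worth recording:

* **Order of rules** (threshold → merge → filters) is not forced by the
  recipe's wording; merging first lets a merged composite qualify as a
  single hotspot, matching the intent that close intervals are "considered
  as a single hotspot".
* **The cutoff applies to the smoothed profile** (the raw profile is used
  only for the read-mass filter); this is the natural reading of
  "smooth, then cut off" and is recorded here as an assumption.
* **"25 reads"** is interpreted as raw count mass within the interval; on a
  pooled map (where counts are HpM by construction, `pool_fullmaps()` sets
  the depth to $10^6$) it is HpM mass, and the interpretation used is
  recorded in the template's attributes.
* **Zero-padded ends.** Chromosome ends are zero-padded so total signal is
  conserved on the padded domain (`hann_smooth(pad = TRUE)` exposes it);
  mass smoothed past an end is truncated from the returned profile.
* Calling is per library, then `combine_templates()` merges overlapping or
  abutting intervals with per-source presence flags. Repetitive regions
  (e.g. an rDNA-like array) are removed afterwards with `exclude_region()`,
  which reports the count. The null-control convention is retained: for a
  catalytically dead control library where nothing calls at 0.193 HpM, the
  lowered 0.125 HpM cutoff is available (`default_config()$hotspots`).

`estimate_background()` takes the mean HpM per bp in the 47 longest ORFs
over 5.5 kb (presumed Spo11-inactive); `hotspot_strengths()` subtracts
`background * length` per hotspot, floors at zero (flagged), and normalises
the corrected signal to `sum(NormHpM) = 1e6` exactly.

## Genome-wide comparisons

* **Local regression.** `smooth_ratio()` and `prepare_timing_track()` use
  degree-1 local regression with tricube weights over the nearest
  span-fraction of points — written out as closed-form weighted least
  squares so its behaviour is pinned by an independent weighted-`lm` oracle
  in the tests (to 1e-8 on fixtures) rather than by any particular library's
  implementation details. Chromosomes with fewer than 5 usable points pass
  through unsmoothed, flagged. The timing track's span is `80 / n` points
  per chromosome (clamped to (0, 1]), normalising smoothing for chromosome
  size.
* **Bin anchoring.** Ratio heat maps bin at 50 kb anchored at the
  centromere (bin $k$ covers $[\mathrm{cen} + 50\,000k,\ \mathrm{cen} +
  50\,000(k+1))$, partial terminal bins retained, rows ranked by chromosome
  size); the timing track bins anchor at position 0, since nothing fixes its
  grid. For `correlate_fc_with_timing()` the timing bins are re-anchored
  onto the centromere grid by overlap-weighted averaging so pairs align.
* **No pseudocount.** Per-hotspot and per-bin log2 ratios with a zero on
  either side are flagged undefined and dropped with a count — a pseudocount
  would quietly shrink extreme ratios.
* **Correlation conventions.** Pearson or Spearman on NormHpM over shared
  hotspots, zero-strength pairs excluded and counted. Spearman p-values use
  the large-sample t approximation for $n \ge 10$ and exact permutation
  enumeration below that. The fold-change-versus-timing coefficient is
  reported with its raw sign and an explicit convention string (negative =
  early-associating regions enriched in the numerator library); published
  displays often reverse the time axis, so the sign convention must travel
  with the number.

## Problem sizes used by the tests

The test suite and acceptance script size their simulations to be decisive
yet quick, and these sizes are part of the package's stated study
conditions: 20 000 cells for the coefficient-of-coincidence law (interference
within ±0.10 of $\log_2 0.5$ at $f = 0.5$, ±0.05 of 0 at $f = 1$); 4 000
cells per genotype scenario for the sign/order panel; 100 random profiles for
caller–oracle identity; a 2.6 Mb four-chromosome genome with ~400 hotspots
and 5 000 cells per genotype for the priming-gradient correlation; 2 000
replicate pairs for the t-test's type-I error (0.05 ± 0.01).

## Known limitations

* The closed-form primed fraction ignores truncation; configurations with
  `exit_mean` near 0 or `t_max` will show small systematic deviations from
  the simulated fraction.
* The discrete hazard understates interference slightly when `w * dt` is
  not small (bias $O(w\,\Delta t)$); reduce `dt` for strongly saturating
  hotspots.
* The simulator's background is uniform; structured artefacts (mappability,
  repeats) are out of scope, so background calibration on real libraries
  should still be sanity-checked against known inactive regions.
* `NormHpM` is a *relative* measure: fold-change curves crossing zero need
  not mark absolute increases or decreases, only regions changing less or
  more than the rest of the genome.
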