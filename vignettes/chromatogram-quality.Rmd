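---
title: "Quality evaluation of EICs and chromatographic peaks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality evaluation of EICs and chromatographic peaks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromqc)
```

`chromqc` scores the quality of extracted ion chromatograms (EICs) and
of the chromatographic peaks detected inside them, for centroided
electrospray LC/MS metabolomics runs. This vignette explains the
underlying models and every design decision that was genuinely open,
so that the behavior of the pipeline can be predicted rather than
discovered.

## The data model

A centroided run is an ordered collection of scans; each scan holds
discrete (m/z, intensity) points. Retention time is kept in seconds
internally, whatever unit an mzML file declares, and every
scan-to-time conversion goes through the run's `rt` mapping rather
than an assumed scan rate. Scan indices are 1-based throughout.

An EIC is a *dense* intensity series $I_1 \dots I_N$ over a contiguous
scan range: scans in which the mass trace had no centroid are stored
as zeros, so all index arithmetic below treats the series as regularly
sampled. A detected peak is a slice of its EIC between a left and
right boundary, with an apex index $p$ inside the slice.

## EIC extraction

Extraction uses region-of-interest mass tracing: an open trace is
extended by the centroid of the next scan whose m/z lies within
`ppm_tolerance` (default 40 ppm) of the trace's running
intensity-weighted mean m/z. The weighted mean follows slow m/z drift
without the signal splitting that fixed-width binning suffers when a
drifting analyte straddles a bin edge. When one scan offers several
candidate points, pairs are resolved globally by smallest ppm
deviation, one point per trace; losers seed new traces. A trace not
extended for more than `max_gap` scans (default 2) is closed, and
closed traces with fewer than `min_trace_points` nonzero points
(default 5) are discarded — together these defaults tolerate one or
two missing centroids without splitting a trace, while refusing to
promote isolated spikes into EICs.

## EIC quality: the MCQ family and the global zigzag index

The **spike detection index** is the cosine similarity between the
series and its moving-average smoothed version (window
`smooth_window`, default 5 scans, truncated at the edges). The
**background detection index** is the cosine between the series and
its mean-subtracted self, which reduces in closed form to
$\sigma/\sqrt{\sigma^2 + \mu^2}$ (population standard deviation): a
high flat background drives it toward zero. The **MCQ index** combines
the two as the inner product of the unit-norm smoothed series with the
unit-norm mean-subtracted original, clamped to $[0, 1]$; it is bounded
above by roughly the smaller of its two components.

The **global zigzag index** is
$$Z \;=\; \frac{\sum_{n=2}^{N-1} (2 I_n - I_{n-1} - I_{n+1})^2}{N \cdot \mathrm{EPI}^2},$$
the second-difference energy of the series normalized by its length
and squared effective peak intensity. A linear ramp scores 0; an
alternating zero/c series scores $4(N-2)/N$, which approaches the
supremum 4 as $N$ grows.

**Baseline rule.** The effective peak intensity is
$\mathrm{EPI} = \max(I) - \mathrm{baseline}$, and the baseline
estimator is the series minimum. This choice is deliberate: it is
exact (zero) on zero-baseline series, shifts one-for-one under a
constant offset so that EPI — and hence the zigzag index — is exactly
shift- and scale-invariant, and it makes the $[0, 4)$ range *provable*
(each second difference is bounded by $2\,\mathrm{EPI}$ in magnitude
when the series lives in $[\min I, \max I]$). A smoothed-minimum
baseline was considered and rejected: under it the alternating
worst case evaluates above 4, destroying the range guarantee.

**Why two indices.** The MCQ index is a distributional (global)
score: an EIC consisting mostly of flat background scores badly even
when it contains one perfectly good peak, and a short single-peak EIC
never reaches high values because the peak itself dominates the mean.
The zigzag index is a *shape* score — it only asks whether neighboring
points transition smoothly — so it stays low for high-background or
single-peak EICs with clean local shape, and high for genuinely
noise-dominated traces. The EIC filter therefore defaults to the
zigzag criterion (`eic_zigzag_max = 0.9`, keep strictly below), with
MCQ (`eic_mcq_min = 0.6`) and an either/or mode available.

Degenerate inputs raise typed conditions rather than returning
sentinels: an all-zero series has no spike/MCQ index, a constant
series has no background/zigzag index (EPI = 0). `filter_eics()`
treats such EICs as rejected.

## Peak detection

Detection follows the continuous-wavelet-transform ridge-line
approach. Coefficients are computed with the Mexican-hat (Ricker)
wavelet on an integer scale grid (default 1–16 scans, covering peaks
5–50 scans wide) against reflectively padded data. Local coefficient
maxima are linked from the largest scale downward into ridges, with a
position tolerance equal to the current scale and up to 2 missing
scales bridged; ridges spanning fewer than 3 scales are dropped.

Three numerical choices matter here:

* **Best scale = strongest interior local maximum** of the
  coefficient-vs-scale profile along the ridge. A genuine peak's
  response peaks at its characteristic scale, whereas a 1–3-scan
  spike's response decays monotonically from scale 1; using the global
  maximum would let a spike riding on a peak flank hijack the ridge.
* **Despiked geometry.** Apex and boundary placement run on a despiked
  copy of the series: a centered binomial $(1,2,1)/4$ average — which
  cancels alternating-sign zigzag noise without phase shift — followed
  by a width-11 running median, which removes anything up to the
  5-scan footprint a 3-scan spike acquires after the binomial average,
  while every admissible peak (at least `min_width` = 5 scans) survives.
  A running median alone is not enough: applied directly to
  alternating noise it manufactures spurious square plateaus. All
  *quality metrics* and the SNR are always computed from the raw
  series; despiking only steers geometry. Because the median flattens
  a smooth apex into a plateau, the apex is taken at the plateau
  middle.
* **Boundaries** walk outward from the apex on the smoothed despiked
  series until the first local minimum, a zero-intensity gap (a gap is
  a natural boundary), a decay to 1% of the apex amplitude above
  baseline, or a cap of twice the best scale — additionally bounded so
  the slice never exceeds `max_width`: a broad peak gets a truncated
  slice rather than no detection. Overlapping slices of neighboring
  peaks are trimmed at the between-apex minimum, so boundary intervals
  never overlap.

A candidate is accepted if its width lies in
[`min_width`, `max_width`] scans (default 5–50), its CWT
signal-to-noise ratio — apex coefficient at the best scale over the
95% quantile of absolute scale-1 coefficients within ±50 scans —
reaches `snr_floor` (default 1, deliberately below the quality
filter's 1.3 so the filter, not the detector, draws the quality line),
and the smoothed slice itself rises by at least 15% at the apex
relative to its edges. The last gate exists because slices that owe
their prominence to a residual spike or to flat alternating noise have
no such rise and are not chromatographic peaks; it is a coherence
check, not a quality metric.

Apex ties (two adjacent equal samples) resolve to the earlier scan.

## Peak quality metrics

All six metrics operate on the raw slice $I_1 \dots I_N$ with apex
index $p$:

* **Sharpness**
  $\sum_{i=2}^{p} \frac{I_i - I_{i-1}}{I_{i-1}} + \sum_{i=p}^{N-1} \frac{I_i - I_{i+1}}{I_{i+1}}$.
  The sums run over the *slice* (boundary to apex to boundary), the
  only reading consistent with metrics defined between the peak
  boundaries. Zero denominators — common after local-minimum boundary
  placement — are handled by offsetting the slice by $\varepsilon = 1$
  intensity unit first (configurable).
* **Gaussian similarity**: nonlinear least-squares Gaussian fit
  (height, center, width; `minpack.lm::nlsLM`, initialized from the
  apex and the full width at half maximum) to the baseline-subtracted
  slice, then the cosine between slice and fit, clamped to $[0, 1]$.
  The slice minimum is subtracted before both fit and cosine —
  otherwise a high flat baseline makes every slice look Gaussian. Fit
  failures raise a typed condition; the filter treats them as rejects.
* **SNR**: as at detection time; the ±50-scan window bounds the noise
  estimate to the peak's neighborhood.
* **Peak significance**: mean intensity within ±1 point of the apex
  over the mean of the 2 points at each boundary (both windows
  configurable). A zero boundary mean yields `Inf`, which passes the
  filter — a peak rising from true zero background is maximally
  significant.
* **TPASR**: $|TPA - RPA|/TPA$ with $TPA = \tfrac12 (N-1) I_p$ and
  $RPA = \sum_i I_i$. The width factor is the scan-count difference
  between the boundaries, and the apex intensity is $I_p$ at the
  *detected* apex (not the slice maximum), so a residual spike inside
  the slice inflates RPA — and the metric — rather than silently
  inflating both areas.
* **Local zigzag**: the global zigzag formula applied to the slice,
  EPI from the slice itself.

The combined filter keeps a peak iff sharpness ≥ 2.0, Gaussian
similarity ≥ 0.6, SNR ≥ 1.3, significance ≥ 1.2, TPASR ≤ 0.8 and
zigzag ≤ 0.9; any clause can be disabled (`NA`) for single-metric
sweeps, and a missing metric value fails its clause.

## Benchmarking

Two peak lists are matched one-to-one: candidate pairs within 0.05 Da
and 5 s are accepted greedily in order of increasing combined
normalized distance $|\Delta m/z|/tol_{mz} + |\Delta rt|/tol_{rt}$.
Greedy matching was chosen over optimal assignment for determinism and
speed; on small instances the test suite verifies it leaves no
in-tolerance pair unmatched. Consensus ground truth merges the three
pairwise matchings into co-location groups; every group seen by at
least two tools contributes one truth peak, represented by its medoid.
The group count equals the inclusion–exclusion expression
$N_{12} + N_{13} + N_{23} - 2 N_{123}$ whenever matching is
unambiguous, and the suite asserts that identity on a thousand random
fixtures.

Recall is TP/NP. The source formulation of Precision repeats the
Recall formula (TP/NP), which cannot be a rate of the evaluated
program's output and is inconsistent with the benchmark numbers it
accompanies; `chromqc` uses Precision = TP/n_detected. One caveat on
sweep curves: Recall is *exactly* monotone along a loosening sweep
(keep-sets nest, so TP and FP both grow), but Precision is a ratio of
two growing counts and can tick upward by at most one-peak granularity
when a true positive joins a small keep-set; it is non-increasing only
up to that granularity, which is how the tests phrase it.

## The synthetic benchmark

The generator's defaults define the standing study conditions. A
600-scan run at 1.2 s/scan carries 20 planted peaks (heights
500–5000, Gaussian widths 3–8 scans, every fourth peak with an
exponential tail of 0.6 σ), a baseline of 20 counts, multiplicative
zigzag noise at 5% of the local level, 0.3 spikes per 100 scans per
channel at 5–20× the local level, and 10 ppm per-scan m/z jitter —
values a practitioner would call moderate for UPLC/Q-TOF centroid
data. Twelve background channels model chemical noise at 8–15× the
baseline: two thirds carry one to three shallow bumps (0.2–0.4× their
level) under 12% zigzag noise — features a ridge picker flags but
whose relative amplitude is too small for good sharpness or
significance — and every third channel is pure alternating noise with
no underlying feature, the regime whose global zigzag index exceeds
the EIC filter threshold.

Three modeling choices deserve justification:

* **Zigzag noise alternates in sign** (random phase, random per-scan
  magnitude). Alternation is what distinguishes zigzag from white
  noise — it injects second-difference energy coherently, the way
  detector oscillation does — and it is exactly the structure the
  zigzag index integrates.
* **The truth table records the realized apex.** For tailed peaks the
  profile maximum sits later than the nominal Gaussian center; truth
  must describe what was planted, or benchmarking would mismatch every
  tailed peak by the tail shift.
* **Simulated tool peak lists** place their false peaks on a jittered
  grid far from the truth and from each other, so consensus matching
  is unambiguous and the inclusion–exclusion identity holds exactly.
  Real tools' false positives can co-locate; the identity is then only
  approximate, which is why the paper-style consensus definition is
  itself a heuristic.

What the generator does **not** emulate: isotope patterns and adducts,
detector saturation, chromatographic drift between runs,
intensity-dependent (heteroscedastic shot) noise, and profile-mode
spectra. Passing tests therefore demonstrate the pipeline's internal
consistency and its behavior under the modeled failure modes — not
performance on any particular instrument's data.

Problem sizes throughout the suite — one 600-scan benchmark run,
10,000-series range checks, 1,000 consensus fixtures, 40–120 draws for
ordering and correlation properties — were chosen as the smallest
sizes at which the properties under test are stable across seeds.

## Known limitations

* A spike landing within a few scans of a genuine apex can still cost
  that peak: it inflates the scale-1 noise estimate (lowering SNR
  below 1.3) or the raw peak area (raising TPASR above 0.8). This is
  faithful metric behavior, not a pipeline bug; on the default
  benchmark it costs at most one of twenty peaks.
* The zigzag index is normalized by EPI = max − min, so a single
  large spike *inside* an otherwise noisy EIC deflates the index and
  can mask the noise; the spike detection index is the complementary
  guard.
* The sharpness sum rewards noise on *low* backgrounds (relative
  rises are large when the denominator is small), so it separates
  shallow high-background junk from real peaks much better than it
  separates low-baseline noise blobs — which the zigzag index
  handles.
* Exact reproduction of any published EIC or peak count requires the
  original raw data; the package reproduces formula identities, range
  bounds, orderings, curve shapes and filter behavior on synthetic
  data instead.
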