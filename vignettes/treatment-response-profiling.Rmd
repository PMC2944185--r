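---
title: "Profiling treatment response in glioblastoma: models and methods"
author: "GBMprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling treatment response in glioblastoma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Glioblastoma cohorts treated with radiotherapy alone or with first-line
alkylating chemotherapy contain both responders and non-responders, and the
molecular correlates of response differ between the two arms. GBMprofiler
implements the complete desk-side analysis for such a two-arm
responder/non-responder study: array-CGH copy-number calling on BAC-clone
log2 ratios with tumor-purity-aware thresholds for homozygous deletions and
amplicons, aggregation of per-sample calls into recurrent minimal common
regions (MCRs), Fisher-exact differential genomics with Benjamini–Hochberg
control, nearest-centroid transcriptomic subtyping, empirical-Bayes
moderated-t differential expression with hypergeometric gene-set
over-representation, and Kaplan–Meier / log-rank survival statistics.
Because deposited arrays are not required, a seeded synthetic-cohort
generator reproduces the statistical structure the analysis assumes, making
every stage testable end to end.

# The copy-number model

A tumor sample is a two-population mixture: a fraction $R$ of tumor cells
(the *tumor-cell rate*, i.e. purity) carrying copy number $c$ at a locus,
diluted by normal diploid cells. Against a diploid reference, the expected
log2 ratio at a clone is

$$\mu(c, R) = \log_2\frac{R\,c + 2(1 - R)}{2}.$$

Every quantity in the caller is an inversion of this formula:

* a single-copy loss sits at $\log_2(1 - R/2)$, a single-copy gain at
  $\log_2(1 + R/2)$;
* a homozygous deletion ($c = 0$) sits at $\log_2(1 - R)$, which is also
  the detection threshold;
* the amplicon threshold $\log_2(1 + 1.5R)$ is exactly the 5-copy boundary:
  $\mu(c, R) \ge \log_2(1 + 1.5R) \iff c \ge 5$, independent of purity.
  Because the equality is attained at $c = 5$, and the threshold
  comparisons are inclusive (within `tolerance`, default $10^{-9}$), a
  5-copy segment is called amplified; "amplicon" in this package therefore
  means *at or above* the 5-copy boundary.

The generator simulates from the same mixture, so generator and caller are
mutually consistent by construction and noiseless recovery is exact — a
property the test suite asserts rather than assumes.

# Segmentation

Per-clone ratios are smoothed per chromosome by exact least-squares
piecewise-constant segmentation: `segmentSignal()` minimizes
$\sum_k \mathrm{SSE}_k + \lambda\,(\#\text{segments})$ by dynamic
programming (optimal partitioning), so the returned fit is the global
optimum, verified in tests against exhaustive enumeration on short signals.
The penalty defaults to $\lambda = 2\hat\sigma^2\log n$ with the noise
scale estimated robustly from first differences,
$\hat\sigma = 1.4826\,\mathrm{median}\lvert\Delta x\rvert/\sqrt2$, and a
floor of $10^{-8}$ so that noiseless signals select the minimal number of
segments achieving zero residual. Ties in the DP are broken toward the
smaller segment start, making results deterministic. Missing clones are
dropped from the fit and stay missing in the output — never imputed.

# Profile statistics and calling

**Mode.** The center of a profile is the argmax of a Gaussian kernel
density of the smoothed values (Silverman bandwidth, 512-point grid),
*snapped to the nearest observed value*. Snapping matters: smoothed values
are quantized at segment means, and the raw grid argmax carries an
$O(\text{range}/512)$ error that would otherwise leak into the purity
estimate; with snapping, recentering is exact on piecewise-constant
profiles.

**Spread.** The threshold scale is $1.4826 \times$ the median absolute
deviation about the mode — robust, so chromosome-7 gains and chromosome-10
losses covering large genome fractions do not inflate the gain/loss bands.
On strongly segmented profiles this spread is small (segment means
concentrate tightly), which makes single-SD gain/loss calls sensitive;
whole-chromosome drift can then be flagged as gain or loss. This is the
intended behavior of a mode ± 1 SD rule and a known limitation (see
*Limitations*).

**Tumor-cell rate.** The rate is estimated by inverting aberrant segment
displacements as single-copy events: a loss segment at displacement $m$
implies $R = 2(1 - 2^{m})$, a gain implies $R = 2(2^{m} - 1)$. Three
safeguards make the inversion identifiable:

1. *Admissibility clamp.* Implied rates outside $[0.1, 0.95]$ are
   discarded. This automatically rejects homozygous-deletion segments
   misread as single-copy losses (they imply $2R > 0.95$ for any realistic
   purity).
2. *Minimum aberrant fraction.* A candidate class (losses, then gains) is
   trusted only if its admissible segments cover at least 2% of clones.
   Single-copy events in glioblastoma are chromosome-scale; without this
   gate, samples lacking a true het loss latch onto small spurious
   segments.
3. *Deep-loss fallback.* If neither losses nor gains qualify, segments
   displaced below the single-copy band are inverted at the
   homozygous-deletion level, $R = 1 - 2^{m}$; failing that, a default
   rate (0.7) is used with a warning.

The estimate is the segment-length-weighted median of admissible implied
rates. On noiseless profiles with one het-loss chromosome the recovery is
exact to $<10^{-9}$ across purities 0.5–0.9 (tested).

**Detection margin under noise.** The homozygous-deletion level *equals*
its threshold when the rate estimate is exact, so any symmetric noise on a
short homdel segment would be missed half the time. `callAberrations()`
therefore derives the homdel/amp thresholds from a noise-guarded effective
rate
$$R_\mathrm{eff} = 1 - (1 - \hat R)\,2^{\,g\,(\hat\sigma_\mathrm{res} + \mathrm{se})},$$
where $\hat\sigma_\mathrm{res}$ is the robust per-clone residual noise
($1.4826\,\mathrm{median}\lvert x - \text{smoothed}\rvert$), se is the
delta-method standard error of $\log_2(1-\hat R)$ propagated from the rate
estimate (important near $R \to 1$, where the threshold slope
$1/((1-R)\ln 2)$ amplifies small estimation errors), and $g$ is the
`noiseGuard` multiplier (default 1.5). Both uncertainty terms are exactly
zero on noiseless data, so the closed-form thresholds
($-2.321928$ and $1.137504$ at $\hat R = 0.8$) and all exact-boundary
behaviors are untouched; under noise the guard converts a knife-edge
comparison into a one-sided detection margin. The relaxation also lowers
the amplicon threshold slightly; with the default events (single-copy gains
at $\log_2(1+R/2)$ vs amp thresholds near $\log_2(1+1.5R)$) the gap
remains several noise SDs wide.

**States.** On the recentered value $v$: homdel if
$v \le \log_2(1-R_\mathrm{eff})$, else amp if
$v \ge \log_2(1+1.5R_\mathrm{eff})$, else loss/gain outside
$\pm\,\texttt{sdMultiplier}\times sd$, else neutral (homdel/amp take
priority; all five states are mutually exclusive). With $sd = 0$
(degenerate spread on noiseless data) gain/loss are uncallable and a
warning is raised.

# Minimal common regions

`deriveMCRs()` sweeps each chromosome's per-sample aberrant intervals
(clone-bounded runs of one event type): interval breakpoints cut the axis
into atomic intervals, each atom's supporting-sample set is computed, and
an MCR is a maximal run of atoms with identical support and recurrence at
or above `minRecurrence` (default 2; the threshold is configurable because
no canonical value exists). Atoms that fall entirely between clones carry
no measurement and are dropped (on sparsely tiled regions the gap support
is the intersection of the flanking clones' supports, which would otherwise
fabricate unmeasured regions); coordinates are clamped to the clones the
run covers. Adjacent MCRs with different supporting sets are *not* merged —
they are distinct events, which is why recurrent-gain tables in this kind
of study show many contiguous rows on 19p/20q. The construction is
invariant to sample order and every MCR is contained in each supporter's
aberrant interval (both property-tested).

# Differential genomics

For each region and event type, a sample is event-positive if any
non-missing clone in the region carries the event; the group × presence
2 × 2 table is tested with the two-sided Fisher exact test
(probability-mass criterion with a $10^{-7}$ relative tolerance on the
inclusion comparison) and BH q-values are computed across the regions of
one event type per contrast — scoping the correction within event type
keeps the tests of one biological question together. Two-sided tests are
used throughout; they reproduce the printed two-digit p-values of the
motivating study's contingency tables. A region with no events in either
group is reported at $p = 1$ by convention. The $r \times c$
generalization (Freeman–Halton) enumerates all margin-consistent tables
exhaustively; cohort-scale tables are tiny, and totals above 200 are
refused rather than approximated.

# Transcriptomics

**Clustering.** Samples are clustered on $1 - $ Pearson correlation with
Ward's linkage applied directly to the dissimilarity (the classical
`ward.D` Lance–Williams update, the convention of the microarray
toolchains this pipeline mirrors — deliberately not `ward.D2`).

**Centroid subtyping.** `buildCentroidClassifier()` z-scores each probe
across the reference cohort and averages per class;
`classifyByCentroid()` z-scores the cohort being classified across *its
own* samples and assigns the class with maximal Pearson correlation,
dropping missing probes pairwise and refusing less than 50% probe overlap.
Correlation ties go to the first class in model order, with a warning. The
probe list is the user's choice (any marker panel can be supplied); the
classifier machinery makes no claim about which probes are optimal.

**Moderated t.** Per-gene pooled variances $s_g^2$ (df $d_g$) are shrunk
by the standard empirical-Bayes construction: moment matching on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ gives the prior df $d_0$
(trigamma inversion by Newton iteration) and prior scale $s_0^2$; the
moderated variance is $(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the
statistic is referred to $t_{d_g + d_0}$. When the log-variances show no
excess spread the matching degenerates ($d_0 = \infty$); $s_0^2$ is then
defined as $\overline{s_g^2}$ so that the moderated t collapses *exactly*
to the ordinary pooled t. The implementation is cross-checked in the test
suite against the reference empirical-Bayes implementation (limma) to
$10^{-6}$ and its null size is calibrated by simulation.

**Top genes and filtering.** Ranked lists take the `nPerSide` smallest
p-values per direction (default 500 up in each group, i.e. a 1000-gene
list), ties broken lexicographically by probe id for determinism.
Count-style filtering keeps genes with raw $p < 0.05$ and
$\max(\mathrm{FC}, 1/\mathrm{FC}) > 1.5$ — raw p, because such gene counts
conventionally precede multiplicity adjustment. The fold change is
$2^{\bar A - \bar B}$ with A the first-named group of the contrast;
printed FC values below 1 for the same direction are handled by the
$\max(\mathrm{FC}, 1/\mathrm{FC})$ convention.

**Enrichment.** Over-representation uses the exact hypergeometric upper
tail $P(X \ge k)$ with BH across sets. Probes collapse to genes by the
highest-variance probe (`collapseToGenes()`), and the universe is the set
of collapsed genes on the array — chosen over a probe-level universe
because duplicated probes of one gene would otherwise count as independent
draws.

# Survival

Kaplan–Meier curves use the product-limit estimator (subjects censored at
an event time remain at risk at that time); the reported median is the
smallest observed event time with $S \le 0.5$, undefined if the curve
never reaches it. The log-rank test is the standard observed-minus-expected
statistic with hypergeometric variance at each distinct event time, ties
by the standard formula, no continuity correction, p from $\chi^2_1$. Both
wrap the survival package; the test suite validates them against hand
product-limit computations and a 20,000-permutation null.

# The synthetic cohort

`simulationConfig()` parameterizes the generator; the defaults *are* the
study conditions the pipeline targets:

* **Array geometry:** 4,434 clones (~150 kb wide) allocated to rounded
  human-like chromosome lengths proportionally (largest remainder) and
  placed evenly, giving an effective spacing of ~680 kb against the
  nominal 670 kb.
* **Cohort:** 21/18 radiotherapy responders/non-responders and 11/17
  chemotherapy responders/non-responders — one cohort of 67 samples with
  both modalities (the real study's expression subset overlaps but does
  not equal its CGH subset; generating both for everyone is a desk-scale
  simplification).
* **Events:** whole-chr7 gain and whole-chr10 loss at 80% everywhere
  (the canonical GBM backbone), a focal 2.8 Mb 9p21 homozygous deletion
  (p16/CDKN2A locus; ~4 clones) at 9/11 vs 0/17 in the chemotherapy arm,
  and a 7p11 EGFR amplicon (copy number 10) at 9/11 vs 6/17. Per-cell
  frequencies are planted as **exact counts** (`round(p × n)` carriers
  drawn at random): the planted contingency tables, and hence their Fisher
  p-values, are reproduced exactly rather than up to binomial noise.
* **Signal:** purity uniform on [0.5, 0.9] per sample (the study reports
  no purities; the range brackets realistic tumor content), per-clone
  Gaussian noise of 0.15 log2 units.
* **Expression:** 2,000 probes mapped 1:1 to genes; four subtype centroids
  (20 marker probes each, +1.5 log2 in the subtype's samples) with
  per-cell subtype mixtures shaped like the study's subtype-by-response
  table; disjoint 50-gene immune/hypoxia/stem-cell sets with +1 log2
  effects in RT responders, RT non-responders and CT non-responders
  respectively; baseline N(7, 1), noise SD 0.5; ten random background
  sets for the multiple-testing context.
* **Survival:** exponential PFS per cell (hazards 0.08/0.35/0.07/0.30
  per month), drawn consistently with the radiotherapy response rule —
  responders from the conditional distribution above 10 months
  (memorylessness: $10 + \mathrm{Exp}(h)$), non-responders by inverse-CDF
  truncation below 5 months — so re-deriving RT labels from simulated PFS
  reproduces the planted labels, which the generator verifies internally.
  OS adds an independent exponential excess; censoring (rate 0.15) is
  applied on the OS interval so PFS stays observed.

What the generator deliberately does **not** emulate: probe-level spatial
artifacts and dye bias (the pipeline starts from normalized ratios),
genotype-level structure, subclonal heterogeneity (one purity per sample),
correlated expression noise, and probe-to-gene multiplicity. Passing tests
therefore demonstrate correctness of the *analysis machinery* under the
stated model, not robustness to every artifact of real arrays.

# Problem sizes and determinism

The test suite and acceptance script run the full 4,434-clone, 67-sample
cohort (segmentation of the whole cohort takes seconds), 2,000-gene null
calibrations over three seeds, 2,000-replicate log-rank null uniformity,
and 20,000-permutation oracles — sizes chosen so the whole suite completes
in about two minutes while keeping Monte-Carlo error well below the
asserted tolerances. All randomness flows from a single seed fanned out
into fixed per-stage child seeds, so any stage is individually
reproducible and identical config + seed gives byte-identical outputs
(asserted in the pipeline test).

# Limitations

* Mode ± 1 robust-SD gain/loss bands are sensitive on strongly segmented
  profiles: chromosome-level drift of a few hundredths of a log2 unit can
  be called gained/lost. Recurrent spurious calls are diluted across
  samples and do not survive differential testing, but per-sample
  neutral specificity is modest by construction of the rule.
* The tumor-cell-rate estimator assumes at least one chromosome-scale
  single-copy event or a detectable deep loss; profiles with neither fall
  back to a default rate and a warning.
* Freeman–Halton is exhaustive by design and refuses totals above 200.
* The survival module covers KM and two-group log-rank only — no Cox
  regression or multivariable adjustment.
* Coordinates are handled in the Bioconductor 1-based closed convention
  inside GRanges containers; files (clone-map TSV, BED) are written
  0-based half-open, and conversion happens only at the I/O boundary.
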