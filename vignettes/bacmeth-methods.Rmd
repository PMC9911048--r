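---
title: "Methods: signal-difference methylation calling and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal-difference methylation calling and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacmeth)
```

# The measurement model

Nanopore sequencing reads the ionic current of DNA translocating a pore;
base modifications such as N6-methyl-adenine (6mA) and C5-methyl-cytosine
(5mC) perturb that current. Comparing a *native* sample against a
*whole-genome-amplified* (WGA) aliquot of the same DNA — amplification erases
all modifications — turns methylation detection into a two-sample problem at
every genomic position: do the native and WGA signal observations at this
position come from the same distribution?

`position_test()` answers with a two-sided Mann–Whitney *U* test and a Welch
*t* test, and `difference_table()` applies both to every position with at
least `min_cov` observations in each sample (default 5; positions below that
are unreliable and are dropped, as signal-comparison tools conventionally do).
The *U* statistic uses midranks for ties. Its p-value comes from exact
enumeration of all `choose(n1 + n2, n1)` label assignments whenever both
samples have ≤ 8 observations (the null is symmetric around `n1·n2/2` even
under ties, since swapping labels maps U to `n1·n2 − U`), and otherwise from
the tie-corrected normal approximation with a 0.5 continuity correction —
standard practice that noticeably improves calibration at moderate coverage.
Degenerate inputs are pinned down explicitly: if every pooled observation is
tied the *U* p-value is 1; if both groups are constant and equal the *t*
p-value is 1, and if constant but unequal it is machine epsilon (a guarded
"p → 0"). Strand is not a dimension anywhere: all reads contribute to one
test per genomic location, and one p-value is reported per position.

## From positions to motif sites

The pore senses roughly five bases at once, so the signal disturbance caused
by a methyl group is local but not single-base, and the smallest p-value near
a modified base is often one base off. A motif site's statistic is therefore
the **minimum U p-value over the focal base and its two neighbours**
(`site_pvalues()`). The focal base is the modified one: the A of GATC for
Dam, the second C of CCWGG for Dcm. Sites at which none of the three
positions is scorable get a missing sentinel and drop out of all counts
downstream.

Binary calls need a null for "what does p_site look like at an unmethylated
position?". `build_null()` computes the same min-over-±1 statistic at
`n_sites` random positions (default 1,000) drawn uniformly without
replacement from the first 1 Mbp — random positions are overwhelmingly
unmethylated, and restricting to the genome start only saves compute because
they are exchangeable along the genome. The classification threshold is the
**10th percentile** of these null p-values, and a site is methylated iff
`p_site < threshold` (strict, so at most 10% of the null's own values fall
below it). This builds in a designed ~10% false-positive rate; the test suite
and the acceptance script verify on fully unmethylated simulations that the
realized rate is 0.10 within binomial and threshold-sampling noise. Random
null positions are *not* excluded from motif neighbourhoods by default (they
are "likely unmethylated", not "guaranteed"); an `exclude =` argument
supports a purified null. One null is built per condition run and shared
across motifs.

## Quantile convention

Every quantile in the package — the null threshold and the coverage
percentile — uses a single declared rule, *nearest-rank-lower*:
`sorted(x)[max(1, floor(n·p/100))]` (`quantile_nearest_lower()`). A single
exact rule keeps thresholds reproducible and testable; interpolating rules
differ across software and would make the strict-inequality threshold
property above only approximate.

# Coverage standardization

Detection power rises with coverage, so uneven coverage masquerades as
methylation structure. `target_coverage()` takes the pooled per-window
coverage values of all samples and returns a low percentile (default the
5th), i.e. a depth essentially every window of every sample can reach;
systematically shallower samples (a late-stationary-phase time point, say)
can be pooled separately via `groups`. Whether that percentile should be over
per-window or per-base coverage is a free choice; per-window matches the
10-Kbp resolution of everything downstream and is the default here.

`subsample()` then draws, per 10-Kbp window,
`round(target · window / mean_read_length)` reads whose *start* lies in the
window (500 reads for a 100× target with 2-Kbp reads). Because coverage is
measured over full read extents, reads bleed into downstream windows by
design, and irregular read-length distributions can leave the realized
coverage off target; in that case the mean read length is re-estimated from
the mapped subsample and the draw repeated (up to `max_iter = 5` times,
acceptance at median relative error ≤ `tol = 0.1`), returning the best
iterate. Short final windows get proportionally fewer reads; windows with too
few originating reads contribute everything they have and are logged, not
fatal.

# The synthetic-data generator

The simulator exists so that every downstream statistic can be exercised, and
calibrated, with known ground truth.

* **Genome**: i.i.d. bases at a stated GC fraction. Real genomes have k-mer
  structure; for signal-difference testing only motif placement matters, and
  the i.i.d. model gives the analytically convenient GATC density of
  `length/256`.
* **Methylation landscape** (`build_landscape()`): per condition, each 10-Kbp
  window gets a base methylation level
  `rho · shared + (1 − rho) · condition-specific`, both profiles i.i.d.
  `Beta(2, 2)` per window (mean 0.5, full support, moderate spread — a
  reasonable stand-in for pervasive-but-incomplete Dam/Dcm methylation);
  each site's probability θ is its window's level plus clipped
  `Normal(0, 0.05)` site noise. `rho` directly controls the expected
  between-condition correlation of window profiles,
  `rho² / (rho² + (1 − rho)²)` under equal variances, which the tests verify
  by simulation. This emulates the premise that specific genome regions are
  consistently hyper-/hypo-methylated with condition dependence.
* **Reads**: uniform starts, `1 + Geometric` lengths (mean 5,000 bp default)
  truncated at the genome end, no circular wrap (window analyses ignore wrap
  anyway). Each native read is a molecule: at every overlapped site it
  carries a methyl mark with probability θ, independently across sites. No
  hemimethylation state and no strand-resolved dynamics are modelled — the
  classifier cannot distinguish hemi- from heterogeneous methylation, so the
  simpler molecule-level Bernoulli suffices.
* **Signals** (`simulate_signals()`): `baseline(pos) + delta ·
  1[within k of a marked focal base] + Normal(0, sigma)`. The baseline is a
  seeded `Normal(100, 10)` draw per position, *fixed across samples*, so
  native-vs-WGA differences come only from methylation and noise — a
  fixed-baseline Gaussian shift model, not pore k-mer physics, which is
  exactly enough to give every downstream statistic its intended sampling
  behaviour. Defaults `sigma = 1`, `delta_5mC = 1.2`, `delta_6mA = 0.5`,
  `halfwidth_k = 2` (the five-base sensing window) are calibration choices,
  not measured constants: no public estimate of the per-modification signal
  shift exists, and these values reproduce the observed qualitative
  asymmetry — near-complete Dcm detection and partial Dam detection at 50× —
  without saturating either test.
* **Titration** (`mix_reads()`): read-count mixtures of a native and a WGA
  pool at stated fractions and target depth, compared against an independent
  WGA control. Signals are simulated once per pool and each mixture selects
  its reads' events (`events_for_reads()`), mirroring how real reads would be
  re-pooled.

What passing tests on this generator do **not** show: robustness to pore
k-mer context effects, basecalling or alignment artefacts, strand asymmetries,
or non-Gaussian signal noise. They do show that the statistics, thresholds,
window arithmetic and correlation machinery behave exactly as designed on
data satisfying the model's assumptions.

## Targeted event emission

A full event table has `coverage × genome_length` rows, which at 1 Mbp × 50×
× 2 samples is ~10⁸ observations — pointless when the analysis only ever
scores motif sites ±1 and null positions ±1. `simulate_signals(positions =)`
emits events only at a stated position set; conditional on the read set,
events are independent across positions, so the per-position test at the
retained positions is distributionally identical to a full run. The pipeline
uses this targeted mode by default (`diff: targeted: true`), drawing the null
positions up front with the run seed.

# Window profiles and correlations

`window_fractions()` tiles the genome into 10-Kbp windows, counts motif sites
(the denominator of *potential* modifications, including unscorable sites)
and methylated calls per window, and discards zero-site windows. The weighted
identity `sum(n_methylated) / sum(n_sites) = genome-wide methylated fraction`
holds exactly and is asserted in tests. `normalize_profile()` divides by the
unweighted mean of included-window fractions (normalized mean exactly 1);
condition correlations run on raw fractions by default, with normalization an
explicit separate step.

Coverage affects the chance a site is *detected* as methylated, so
between-condition correlations are computed as **partial correlations**:
residualize both fraction vectors on an intercept plus per-window covariates
(each condition's native coverage and the shared WGA coverage — three
vectors, configurable) and correlate the residuals, with a t p-value on
`n − 2 − k` degrees of freedom. Per-window rather than genome-mean coverage
is used because the confounding acts window by window. Collinear covariates
are reported by name; pairs sharing fewer than three windows yield a missing
result with a warning rather than aborting the whole matrix. P-values are
reported unadjusted (an optional Benjamini–Hochberg column exists for the
pair matrix).

`long_range_scan()` generalizes this to an autocorrelation-style grid:
fractions on a tiling of step `w`, correlated against the same fractions a
lag away. The separation convention had to be chosen: here `d` is the **gap
in bp between the end of the first window and the start of the second**, so
`d = 0` means adjacent windows and the index lag is `1 + round(d/w)`;
`d = −w` is accepted as the degenerate self-correlation sanity lag (r = 1).
Cells with fewer than three complete pairs are missing, not errors.

With several i.i.d. conditions, *some* pair is always most correlated; under
exchangeability a designated condition tops another's correlation list with
probability exactly 1/(c − 1) (≈ 0.20 for six conditions), which the tests
confirm — the baseline against which "replicates match best" becomes
meaningful.

# Candidate-region export

For motif discovery, `extract_candidate_regions()` subsamples positions
uniformly from the scored genome (100,000 by default, ~2% of a 5 Mbp
genome — subsampling keeps the strongest motif from monopolizing the input),
ranks them by U p-value with ties broken by a seeded shuffle, and writes the
`top_n = 5,000` lowest as FASTA flanks. The flank default is 10 bp per side —
wide enough to contain any 4–6 bp motif around an off-by-one signal minimum,
small enough not to dilute the motif signal; no principled published value
exists. Running the motif finder itself is out of scope.

# The pipeline

`validate_config()` fills a YAML config with the defaults above and reports
*all* violations with field paths in one error. `run_pipeline()` executes the
stages in dependency order, writes every primary table as TSV/BED/FASTA under
`outdir`, logs per-stage progress to stderr, and records a manifest. Each
stage's parameter hash chains on its upstream hash, so an unchanged rerun
skips everything and a changed parameter re-runs its stage and all dependants.
All randomness derives from the single config seed via fixed offsets, making
primary outputs byte-identical across reruns.

# Problem sizes and numerical tolerances in the tests

The suite exercises the pipeline at deliberately modest scales chosen to make
every stochastic assertion sharp at roughly three standard deviations of its
sampling noise: null calibration on a 1 Mbp genome at 50× (≈ 3,850 GATC
sites, FPR asserted at 0.10 ± 0.03), titration on 150 Kbp with fractions
{0, 0.25, 0.5, 0.75, 1} at 25×, correlation recovery on 2 Mbp / 200 windows
at 50× with a strong shift (`delta = 2`, asserted within ±0.15 of the true
landscape correlation), uniformity of null p-values at 10,000 positions
(KS D < 0.02, which also bounds the discreteness of the rank statistic at
30× coverage), and the small-sample U oracle at `n, m ≤ 8` to 10⁻¹².

# Known limitations

* The signal model is a location shift with shared deterministic baseline;
  modification-type classification (6mA vs 5mC vs 4mC) is out of scope and
  the simulator's `delta` values are calibration choices.
* Pooled-strand testing: if a real dataset's signal differences are strongly
  strand-asymmetric, the pooled test dilutes them.
* The subsampler standardizes coverage by read starts; extreme read-length
  heterogeneity within a window still leaves residual coverage structure
  (hence partial correlations downstream).
* Non-palindromic motifs are scanned on both strands, but hemimethylation is
  neither simulated nor called.
* FASTA/event I/O assumes a single contig; multi-replicon genomes should be
  analysed per contig.
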