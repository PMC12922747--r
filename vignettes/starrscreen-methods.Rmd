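---
title: "Models and methods behind starrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind starrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starrscreen)
```

# The assay and the analysis problem

A self-transcribing reporter screen places a candidate regulatory fragment
downstream of a minimal promoter inside the transcription unit, so active
enhancers transcribe themselves. Sequencing the input plasmid pool (DNA) and
the output transcripts (RNA) gives, per fragment, a pair of counts whose
ratio measures enhancer activity. Two variant-centric designs are handled
here:

* **SNP screens**: each variant is represented by several 120-nt inserts
  identical except for the base at the variant position (reference plus the
  known alternative alleles, optionally all four bases). Comparing the arms
  of one variant isolates the allelic effect from everything else about the
  locus.
* **Methylation screens**: 120-nt CpG-containing windows (centered on
  H3K27ac peak summits, or selected differentially methylated probes) are
  assayed twice from the same plasmid pool — once enzymatically methylated,
  once mock-treated — and the two arms are compared per window.

Every insert is synthesized between constant adapters
(`ATGGCTACGATCCGACTT`, `AAGTCGGAGGCCAAGCGGTCTTAGGAAGACAA`), giving 170-nt
oligos; the adapters double as the anchor for read quantification.

# Library design rules

* **Common variants**: a SNP is retained when its minor allele frequency is
  at least the threshold (default 0.05, inclusive) in *every* requested
  population. The population list is a parameter (default EUR + EAS; the
  panel carries AMR/EUR/EAS/SAS columns) because design sources differ on
  which populations to require.
* **LD expansion**: lead SNPs are expanded to proxies with
  r² ≥ 0.5 within ±500 kb, with r² computed from phased haplotypes as
  \(r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))\), \(D = p_{AB} - p_A p_B\).
  A monomorphic SNP has no defined r² and is reported as an error, never as
  r² = 0. The window is anchored on each lead independently; a proxy
  qualifying for several leads is emitted once; leads are reported
  separately from proxies, and leads are retained in the library regardless
  of their own MAF.
* **Enhancer localization**: enhancers are the base-pair intersection of
  H3K27ac and ATAC peak sets; a SNP localizes to an enhancer when its
  0-based coordinate lies in an intersected interval. All intervals are
  BED-style 0-based half-open internally; SNP tables are 1-based at the I/O
  boundary only.
* **Window centering**: an even window width cannot center a single base.
  For width 120 the insert is the 0-based half-open interval
  \([pos-1-60,\; pos-1+60)\) with the variant at insert offset 60 — 60 bp
  of upstream and 59 bp of downstream context. The same convention is used
  for CpG windows at peak summits, and it is applied uniformly rather than
  inferred per site.
* **Differentially methylated probes** are selected by a strict
  \(|\Delta\beta| > \delta\) (library selection uses 0.3; biomarker
  selection 0.25) combined with a Welch two-sided t test, BH-adjusted,
  q ≤ 0.05. The test is Welch rather than pooled-variance because
  tumor/normal β variances routinely differ; the procedure behind "FDR" is
  BH, the field default, and both knobs are arguments.

# Quantification

Because the library is a closed set of known 120-mers, read alignment
reduces to insert matching: the first exact occurrence of the upstream
adapter is located, the following 120 bases are the insert, and the insert
is matched against the manifest by hash. With `max_mismatch = 1`, unmatched
inserts are assigned to a manifest insert at Hamming distance 1 only when
that neighbour is unique; reads equidistant from two oligos are discarded,
and the mode refuses manifests containing insert pairs within the mismatch
radius — which includes every SNP library, since allele arms differ at one
base, so SNP screens are always counted exactly. Per-sample tallies satisfy
matched + discarded = reads. No quality trimming is performed; a hook
accepts pre-trimmed FASTQ.

# Normalization and activity scoring

Size factors are plain median-of-ratios: the per-oligo reference is the
geometric mean of its counts across samples (over oligos positive in every
sample), and each sample's factor is the median ratio of its counts to the
reference. Factors are estimated jointly over all DNA and RNA libraries of
an experiment so both modalities share one scale — the analogue of fitting
one count model to the full table. The median is taken on the ratio scale
exactly as defined; log-scale medians (as some implementations use) agree
except at even usable-oligo counts, where the two middle ratios combine
geometrically instead of arithmetically (relative differences ~1e-3), and
that implementation is the cross-check oracle in the test suite.

One algebraic caveat is worth recording: rescaling one of \(m\) samples by
\(c\) moves the geometric-mean reference by \(c^{1/m}\), a global drift of
the normalized scale that no ratio-based estimator can detect. The drift
cancels in every EAS ratio except through the +1 pseudocount (relative
~1e-3 at depth 200). The exact invariance the normalization provides is
*absorption*: the scaled sample's factor absorbs \(c\), and with that factor
EAS is bit-identical; the test suite asserts both the exact absorption
identity and the near-exactness under re-estimation.

The enhancer activity score for oligo \(o\) in biological replicate \(r\) is

\[ EAS_{o,r} = \frac{\overline{RNA}_{o,r} + 1}{\overline{DNA}_{o,r}}, \]

with technical replicates averaged arithmetically on the normalized scale
within biological replicate and modality — technical replicates re-measure
the same transfection and contribute precision, not biology. The
pseudocount sits on RNA only, exactly as the score is defined; zero or low
DNA is handled by qualification, not by a denominator pseudocount: an oligo
whose tech-averaged DNA falls below 10 normalized counts in any biological
replicate is unqualified and excluded from calling (the "qualified
variants" notion is otherwise undefined; the coverage floor is an exposed
flag). When DNA was sequenced per biological replicate, RNA is paired with
its own replicate's DNA; otherwise each RNA replicate is divided by the
pooled DNA mean, matching designs that sequence the plasmid input once as a
shared control (note the shared-control layout correlates the replicate
log2FCs and is not used by the simulator's default, which sequences DNA per
replicate).

Per variant and biological replicate,
\(\mathrm{log2FC}_{v,r} = \log_2 EAS_{test,r} - \log_2 EAS_{ref,r}\), the
point estimate is the mean over replicates, and both arms must be qualified
in every replicate. Computing log2FC per replicate (rather than once on
replicate-averaged EAS) is what feeds the paired t test below; for
multi-allelic SNPs each alternative allele is scored against the single
reference arm.

# Thresholding and calling

Effect-size cutoffs are found geometrically on the curve of sorted log2FC
values placed at rank-normalized x positions \(x_i = (i-1)/(n-1)\). For the
right threshold, negative values are clamped to zero; the chord slope
\(s = \max(y') - \min(y')\) is computed on the clamped curve, and the
threshold is the y value at \(\arg\min_i (y'_i - s x_i)\) — the point where
a line of slope \(s\) slid up from below first touches the curve. The left
side mirrors the construction with clamping from above and an argmax. Two
ambiguities are resolved explicitly: (1) the slope is computed on the
*clamped* curve by default (the clamp precedes the slope in the procedure's
description; since the clamped minimum is zero this makes \(s = \max(y')\)),
with an `original`-extrema mode provided; (2) ties are broken toward the
conservative extreme — largest index on the right, smallest on the left —
so ties never enlarge the call set. Rank-normalizing x is what makes
"slope = max − min" the chord slope of the curve, the only reading under
which a tangent of that slope generically exists. The construction
guarantees left ≤ 0 ≤ right; degenerate inputs (fewer than three finite
values, or all equal) are errors because no threshold is defined. The
implementation is the closed form of an exhaustive intercept search and is
property-tested against an independently coded search on random vectors.

Significance is a one-sample two-sided t test of the per-replicate log2FC
against zero (df = replicates − 1), equivalent to a paired test of log2 EAS
between arms — pairing by replicate removes replicate-level effects shared
by both arms. A two-sample Welch mode exists behind a flag. Zero variance
across replicates leaves the statistic undefined and is reported as a
distinct degenerate flag, never as a p-value. A variant is called when its
mean log2FC lies strictly beyond a knee threshold *and* its test clears
α = 0.05 on the BH-adjusted q value (default) or on the raw p-value
(`adjust = "none"`, the literal reading of the screening procedure, which
names a two-sided t test at P < 0.05 while the hit definition names
adjusted P).

The two modes trade off sharply at the reference conditions (2000 variants,
5% planted effects of |log2FC| = 1.5, 200 reads/oligo, 3×3 replicates), and
the benchmark script measures this rather than asserting it away: with
df = 2 the smallest attainable p-values are of order \(1/t^2\), and the
counting-noise floor on the per-replicate log2FC (four count terms over
three technical replicates) is ≈ 0.12 log2 units at depth 200 even for
Poisson noise, so BH across 2000 variants leaves sensitivity near 0.05–0.35
(FDR ≈ 0.03); the raw-P rule recovers essentially all planted effects but
admits ≈ 20–33% false calls because the knee tangent lands inside the null
noise at this effect mixture. Estimation accuracy is unaffected (mean
absolute error ≈ 0.07–0.08 log2 units). Deeper screens close the gap — the
workflow's demonstration screens use 1000 reads/oligo, where the BH rule
calls most planted effects — but at the reference depth no rule in this
family is simultaneously sensitive (≥ 0.8) and strict (FDR ≤ 0.15), and we
report that honestly instead of tuning toward it.

# Integration and prioritization

Cross-line comparison partitions variants at the variant level; "specific
to B" always means *tested in A and not called there* — a variant
unqualified in A cannot be claimed B-specific and is reported separately.
Overlap enrichment is the upper-tail hypergeometric probability
\(P(X \ge k)\) (one-sided Fisher test); the universe size is an explicit
required argument because it is a modelling choice, not a constant the
data supply. Coverage reports use percentages rounded half away from zero
to one decimal. DEG filtering is strict on both thresholds
(log2FC > 0.75, adjusted P < 0.05); TSS linking treats "within ±1 Mb" as
inclusive, on the same chromosome, one-to-many.

Motif evidence is a PWM log-odds scan reimplemented from first principles:
per-position score \(\log_2((p_b + 0.1\,bg_b)/bg_b)\), summed over the
window, maximized over all windows covering the variant on both strands.
"Disruption" is qualitative: exactly one of the two alleles reaches 80% of
the motif's maximum achievable score (both knobs exposed). The signed score
change is recorded either way, so gain- and loss-of-site variants are both
visible; the relative-score rule replaces p-value calibration, which needs
a background model out of scope here. Metastasis-specific peaks are peaks
with zero base-pair overlap against the other condition's peak set — the
strictest reading of "condition-specific" absent a quantitative rule. A
variant is prioritized when all four criteria hold: condition-specific
call, condition-specific peak, an up-regulated DEG within the window, and
at least one disrupted motif. Removing any criterion can only enlarge the
set (tested as a monotonicity property).

# The synthetic data generator

The generator emulates the screen's replicate structure and noise, not its
sequences: three biological replicates, each sequenced as three technical
replicates, for DNA and RNA (and per methylation arm when CpG oligos are
present). Counts are negative binomial with variance \(\mu + \alpha\mu^2\).
Per-oligo expected DNA abundance is lognormal around the target depth
(sdlog 0.3, synthesis/cloning skew); per-(oligo, replicate) abundance
jitter (sdlog 0.2) is shared by the DNA and RNA libraries of a replicate,
so it cancels in EAS — technical replicates differ only in sampling.
Baseline activity is lognormal (sdlog 0.5) **per variant**, identical
across the arms of a variant, so null variants have exactly no allelic
difference; planted effects multiply the RNA mean of the alternative (or
methylated) arm by \(2^{\mathrm{effect}}\), with effects of fixed magnitude
and random sign in a configurable fraction of variants, recorded in a truth
table. A truth table can also be imposed, which is how two cell lines share
germline effects while one acquires more. The default dispersion
α = 0.002 reflects the near-Poisson reproducibility reporter screens show
between replicate libraries; per-sample depth factors (sdlog 0.15) exercise
normalization. Haplotype LD is planted in blocks copied from an anchor
column with 5% or 30% flip probability (r² ≈ 0.8 and ≈ 0.15), giving both
in- and out-of-LD pairs within the proxy window; population MAFs are drawn
independently per population from a scaled Beta(1, 3), putting mass on both
sides of the 0.05 filter.

What the generator does *not* emulate: real sequence composition and
mappability, PCR duplication structure, plasmid supercoiling or transfection
batch effects, allele-frequency correlation between populations, realistic
LD decay, bisulfite chemistry, or motif content of real enhancers (motif
tests plant their sites explicitly). Passing tests therefore demonstrate
correctness of the procedures and calibration under the stated noise model,
not performance on any real screen.

Every generator is a pure function of its configuration: the RNG state is
saved and restored around each call, and a fixed seed gives byte-identical
outputs.

# Numerical and scale choices

* Problem sizes: unit tests use a 50-kb genome with 60 SNPs; the benchmark
  and acceptance runs use a 1-Mb genome with 2000 SNPs (~4400 oligos ×
  18 samples per screen), 10 null seeds and 20 recovery seeds — large
  enough for stable rates, small enough to run in minutes on one CPU.
* Floating point: knee ties are compared exactly (the oracle shares the
  arithmetic); EAS invariance is asserted at 1e-12 (absorption) and 2e-3
  (re-estimated factors); r² against the correlation identity at 1e-12.
* Degenerate inputs are signalled, not coerced: monomorphic SNPs in r²,
  all-equal knee input, zero-variance t tests, constant DMR groups, zero
  denominators in percentages.
* `percent()` rounds half away from zero because banker's rounding would
  change printed one-decimal proportions.

# Known limitations

* The BH-adjusted calling rule is severely conservative for three
  biological replicates at moderate depth (see the measured operating
  characteristics above); analyses at that design should either sequence
  deeper or consciously choose the raw-P mode and report its FDR.
* Insert matching assumes intact adapters and exact 120-mers; indels or
  heavy 5' trimming defeat it (out of scope: alignment-based recovery).
* The shared-pooled-DNA pairing mode biases no estimates but correlates
  replicate log2FCs, mildly miscalibrating the t test; prefer per-replicate
  DNA when available (the simulator always provides it).
* Motif disruption uses a relative-score rule, not a calibrated p-value;
  thresholds are comparable within a PWM, not across PWMs of different
  information content.
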