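---
title: "Methods: from multiplexed small RNA reads to a placental miRNA biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multiplexed small RNA reads to a placental miRNA biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentamir)
library(dplyr)
```

This vignette explains the models and procedures the package implements, the
assumptions behind them, the parameters that matter and why their defaults
are what they are, and what the synthetic-data generators do and do not
emulate. Nothing here states a number the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Read-level processing

### Demultiplexing

Each read starts with a 4-nt sample barcode drawn from a sixteen-word code
with minimum pairwise Hamming distance two in which every word ends in a
cytosine (`default_barcode_set()`). Assignment is **exact-prefix only**: a
distance-two code detects any single barcode error (the prefix then matches
no code word) but cannot correct it — the erroneous word is equidistant from
at least two code words — so attempting correction would risk silent
mis-assignment. Reads whose prefix matches nothing are counted
`unassigned`; this is a deliberate conservative choice.

### Adapter trimming

The 3' adapter is removed by aligning its prefix at every read offset, left
to right. At offset $s$ the aligned length is
$L = \min(\text{adapter length}, \text{read length} - s)$, and an alignment
is accepted when $L \ge 7$ with at most one mismatch, or $L \ge 10$ with at
most two. Design choices where the rule leaves freedom:

* **Leftmost accepted offset wins** (maximal trimming). This is conservative
  against adapter read-through: a spurious early match costs insert bases,
  while a missed match leaves adapter sequence that simply fails to map.
* **Alignments shorter than 7 bases never trim.** Terminal 1–6-base matches
  are statistically indistinguishable from random sequence
  ($P(\text{exact 6-mer at a given offset}) = 4^{-6}$), so untrimmed tails
  shorter than 7 are tolerated and handled by the mapper's exactness instead.
* **`N` counts as a mismatch** — again conservative.

The implementation scans all reads offset-by-offset on an integer base
matrix; its correctness is established in the test suite against an
independent brute-force oracle that enumerates every offset and counts
mismatches by direct character comparison, on random reads with adapter
fragments planted across the 7/9/10 tier boundaries.

### Complexity and length filtering

Junk reads (ligation artefacts, primer concatemers) are flagged by the
Shannon entropy of their overlapping dinucleotide frequencies:
$H = -\sum_d f_d \log_2 f_d$ over the $L-1$ dinucleotides of an $L$-nt
insert, bounded by $\log_2 \min(16, L-1)$. A homopolymer scores 0, a pure
two-letter repeat 1, and typical miRNA inserts 3.5–4. The threshold is a
required configuration value with **default 1.5 bits**, placed to remove
both degenerate families with a wide margin while sitting far below the
miRNA range. Inserts shorter than **14 nt** are then removed (strictly
less-than, so a 14-nt insert is kept). The complexity filter runs first and
each removed read is counted in exactly one category, which keeps the
disposition accounting a partition: per library,
`unassigned + Σ assigned` equals the input read count and
`low_complexity + short + passed` equals each sample's assigned count.

## 2. Quantification and differential calls

Inserts are mapped to a mature-miRNA reference by **gapless containment**: a
hit is an end-to-end placement of the insert inside a mature sequence with at
most `max_mismatches` substitutions (default 0, configurable to 2). Mature
references are 19–24 nt, so gaps have no role; indel-bearing reads simply
fail to map, which at sequencing error rates of a fraction of a percent per
base is an acceptable loss paid equally by all conditions. The default
multi-mapper policy is `unique` (only single-hit reads counted); `all` and
`fractional` are provided for sensitivity analysis.

Counts are normalized to **reads per million of the library total**, where
"total" is the number of post-filter processed reads. The alternative —
normalizing to miRNA-assigned reads only — is available by constructing the
count table with those totals; both interpretations are defensible and the
package does not assert one as canonical. For logarithmic display and fold
changes a **pseudocount of 2 is added to the normalized value** (not the raw
count), so an absent miRNA has $\log_2(0 + 2) = 1$.

A miRNA is called **consistently deregulated** when its per-replicate-pair
log2 fold change (on pseudocounted values) reaches a threshold with the same
sign in every pair. The default threshold is $|\log_2 FC| \ge 1$ — at least
twofold in every replicate. No numeric rule is canonical here; twofold in
all replicates is a standard, deliberately strict convention, and with four
replicate pairs it keeps the null flag rate well below 1% at 50,000
reads/library (checked by simulation in the acceptance suite).

## 3. Placenta cohort statistics

The qPCR arm assumes the idealized efficiency-1 amplification model: one
cycle per twofold template difference. Relative expression is
$2^{-(Ct_\text{target} - Ct_\text{ref})}$ with U6 snRNA as the miRNA
reference (RPLP0 for mRNAs). The analysis chain is: RIN > 7.5 retention
(strict inequality), technical-replicate collapse by **median** (robust to
single-well dropout), per-piece relative expression, then per-placenta
averaging. The **placenta is the default unit of analysis** to avoid
pseudoreplication — pieces of one placenta share its biology and are not
independent; `unit = "piece"` reproduces per-piece plotting and testing for
comparison.

Group comparisons use the two-sided **Mann–Whitney** test: exact by full
enumeration when $n_1 + n_2 \le 12$ with tie-free data, otherwise the normal
approximation with midranks, tie correction and continuity correction. When
both groups are one constant value the p-value is 1 by convention. Box
summaries use linear interpolation between order statistics (R's type-7
quantile), the inclusive method, reported as median, quartiles, and 5th/95th
percentiles.

The **severe-PE rule** requires both a confirmed blood pressure — two
readings meeting the threshold at least 6 hours apart — and repeated
proteinuria — dipstick grade ≥ 2+ twice within 24 hours. The notation
"≥ 160/100 mmHg" is read as systolic ≥ 160 **or** diastolic ≥ 100, the
standard obstetric convention for threshold pairs; an `"and"` variant sits
behind a flag. The rule is monotone: raising any reading can never turn a
positive classification negative (property-tested).

The **ratio biomarker** exploits the opposite effect directions: with miR210
up and miR455 down in PE, the linear-space ratio
$2^{(Ct_{455} - Ct_{210})}$ accumulates both shifts. Its ΔCt form
($Ct_{455} - Ct_{210}$) is the log2 of the same score and yields an
identical ROC curve, since AUC is rank-based. AUC is computed by the
rank-statistic identity $AUC = U/(n_1 n_2)$ with midranks; the test suite
verifies it against trapezoidal integration of the curve and against pROC.

## 4. What the generators emulate — and what they do not

`simulate_library()` writes reads of the form *barcode (4 nt) + insert + 3'
adapter fill*, truncated to a fixed 36-cycle read length — the convention of
the sequencer generation this library structure belongs to, and fully
configurable. Inserts are drawn multinomially from the reference abundances;
substitution errors are independent per base (no indels, matching the
gapless mapper); junk is injected as homopolymer/dinucleotide-repeat inserts
and sub-14-nt inserts, with the per-category counts drawn once and recorded
as ground truth. Qualities are constant Phred+33 'I': the pipeline does no
quality-based processing, so modeling quality would only decorate the
fixture. There is **no PCR-duplication model, no isomiR end-variation, and
no quality-correlated error structure** — so a pass on synthetic data shows
the operators implement their definitions and recover planted signals, not
that real libraries are free of those artefacts.

Default study conditions: 4 replicate pairs, 50,000 reads per library
(sequencing depth is a free parameter of the design; 50,000 keeps binomial
counting error on a ~0.4%-abundance miRNA near 0.1 log2 units while the full
8-library run stays around ten seconds), fivefold miR455-3P/-5P induction,
50% of miRNA read mass on the 30 cluster-tagged reference entries, 0.5%
per-base error, 0.8% low-complexity and 2% short junk.

`simulate_cohort()` draws
$Ct = \text{reference mean} - \log_2(\text{abundance}) + \varepsilon$ with
independent Gaussian noise at three levels: between placentas (SD 0.8
cycles), between pieces (0.4), technical (0.15). Effect sizes are **−2 log2
units for both miR455 arms and +2 for miR210**, zero for the C19MC
representatives and U6. The directions are the study's finding; the
magnitudes are the package's choice, made once: because the ΔCt against U6
carries the reference gene's placenta-level noise as well (effective SD
$\sqrt{2}\times 0.8 \approx 1.1$ cycles), a fourfold shift corresponds to a
standardized effect near 1.8 — a separation that is *robustly* significant
at $n = 15$ vs $14$, which is what the underlying cohort finding was.
Clinical fields are constructed so PE records satisfy and controls fail the
severe-PE rule by design, which lets the classifier be tested end to end but
means classifier accuracy on synthetic cohorts says nothing about borderline
real patients.

`simulate_luciferase()` applies multiplicative log-normal noise
(mean-centered, CV `noise_cv`) independently to RL and FL per well; with
zero noise `percent_repression()` returns the configured truth exactly,
which the tests use as a round-trip check. Percent repression centers by
**mean** across biological replicates (median by flag); technical replicates
are averaged within biological replicate first, so the significance test's
$n$ is the number of biological experiments (three), honestly small. The
"non-parametric" two-condition test is Mann–Whitney — with 3 + 3 biological
replicates its smallest attainable two-sided p is 0.1, a floor the user
should know about.

## 5. Numerical and degenerate-input choices

* All generators run under `withr::with_seed`: bit-reproducible under a
  seed, non-disturbing to the caller's RNG, child streams derived
  deterministically and kept below $2^{31}$.
* Entropy of length-<2 sequences is 0 by definition; zero-count libraries
  make `cluster_fraction` `NA` with a warning rather than 0/0.
* A zero library total is an error naming the library, not a silent NaN.
* Barcode-matching reads shorter than 5 nt are assigned with an empty insert
  and fall to the length filter, keeping the disposition partition exact.
* p-values are clamped to $(0, 1]$; `direction` is the sign of the median
  difference, 0 when medians tie.

## 6. Problem sizes used by the checks

The test suite and acceptance script use: 10,000 random read/adapter pairs
for the trimmer oracle, 10,000 random reads for the entropy bound, 100
fuzzed libraries for disposition conservation, one 8 × 50,000-read
experiment for fold-change and cluster-fraction recovery, full enumeration
of all tie-free Mann–Whitney inputs to $n_1+n_2 = 10$ plus 2,000 null
simulations at 14 vs 15, 100 seeded default cohorts for direction recovery
and the biomarker comparison, and 500 reduced null cohorts for the type-I
check. These sizes are the package's own accuracy/runtime trade-off: each
Monte-Carlo tolerance in the tests is set to three standard errors at the
stated size.

## 7. Known limitations

* The mapper has no genome stage: reads not contained in a mature reference
  sequence are simply unmapped, so novel miRNAs and isomiRs are invisible.
* Exact barcode matching discards every read with a barcode error
  (≈ `4 × error_rate` of reads); this is by design, not a bug.
* The cohort model is Gaussian on the Ct scale with a shared noise SD across
  targets; real qPCR panels show target-dependent variance and occasional
  non-detects, neither of which is modeled.
* No multiple-testing layer is applied across the qPCR panel; the package
  reports per-target p-values as is.
* The luciferase test inherits the n = 3 granularity of the assay; it can
  rank conditions but not estimate effect uncertainty narrowly.
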