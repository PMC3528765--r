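---
title: "Methods: from expression signature to FISH deletion screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from expression signature to FISH deletion screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brca2del)
```

# The inference chain

`brca2del` models a specific multi-level consequence of hemizygous
deletion in tumors: when one copy of a contiguous chromosomal region is
lost in the tumor-cell population of a specimen, (i) genes in the region
are transcribed from a single allele and their measured log2 expression
drops; (ii) array-CGH probe log2 ratios in the region shift negative;
(iii) heterozygous SNPs split away from B-allele frequency 0.5; and (iv) a
FISH probe inside the region yields one spot instead of two in tumor
nuclei. Every one of these signals is attenuated by the tumor-cell
fraction $f \in (0,1]$ of the specimen, because the remaining $1-f$ normal
cells are diploid. The package implements the analysis stages that exploit
each signal and a generator that produces cohorts in which all four
signals share one ground truth.

# Synthetic cohorts

## Generative model

For gene $g$ and sample $j$, expression is

$$x_{gj} = \mu_g + \mathbb{1}\{g \text{ deleted in } j\}\, f_j\, \beta + \varepsilon_{gj},
\qquad \varepsilon_{gj} \sim N(0, \sigma_e^2),$$

with gene baselines $\mu_g \sim N(7, 1.5)$ on the log2 scale — the
magnitude range typical of RMA-normalized arrays, so scores and variances
have realistic units without requiring real chips. CGH probe ratios follow
the mixture-of-cells formula $\log_2\!\big((f c + 2(1-f))/2\big)$ with
tumor-cell copy number $c \in \{1, 2\}$, plus Gaussian noise. Heterozygous
SNPs in a deleted region sit at the allele ratios $1/(2-f)$ and
$(1-f)/(2-f)$ (B allele retained/lost), homozygous SNPs at 0/1, neutral
heterozygous SNPs at 0.5; noise is added and the result clipped to
$[0,1]$. FISH nuclei are tumor cells with probability $f$ (touch imprints
are contaminated by normal cells at rate $1-f$); green (pericentromeric)
spots are $\mathrm{Bin}(2, \eta)$ and red (deletion-probe) spots
$\mathrm{Bin}(c_\text{red}, \eta)$ with detection efficiency $\eta$ and
$c_\text{red} = 1$ in deleted tumor cells.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| `nCase`, `nControl` | 7, 24 | the discovery design: 7 mutant vs 24 control familial tumors |
| `tumorFractionRange` | [0.50, 0.95] | the spread of tumor-cell content reported for such specimens |
| `deletedRegions` | 13q13–13q14, 14q24–14q32 | the commonly deleted spans on 13q/14q |
| `penetrance` | 1 | deletions are modeled as the defining case lesion |
| `exprEffect` | −0.7 log2 | hemizygosity under partial dosage compensation; the true per-copy expression drop is not identifiable from published summaries, so this is an explicit package choice, not a measured value |
| `exprNoiseSd` | 0.3 log2 | residual biological+technical SD typical of array data |
| `cghNoiseSd` | 0.1 | residual SD of a well-behaved BAC array |
| `bafNoiseSd` | 0.04 | Illumina-class BAF scatter for good-quality DNA |
| `fishNucleiPerSample`, `fishDetectionEff` | 100, 0.95 | a realistic scoring session: ~100 intact nuclei, rare probe dropout |

The genome is a compact 26-band karyotype: 13q and 14q at band resolution
plus background bands from chromosomes 1, 4, 17 and 19, with 15–20 genes,
8 CGH probes and 40 SNPs per 10 Mb band. One RNG stream is split per
modality in a fixed order (truth, expression, CGH, BAF, FISH), so changing
a FISH parameter never perturbs the expression draws and a fixed seed
reproduces every byte.

## What the generator does not emulate

Amplifications, subclonal structure beyond a single tumor fraction,
probe-level GC or intensity bias, batch effects, and correlated
(co-regulated) gene noise. Passing tests therefore demonstrate that the
analysis recovers copy-number-driven structure under honest noise and
dilution — not that it is robust to batch confounding or to expression
heterogeneity unrelated to copy number, which are the main hazards in real
cohorts.

# Differential expression

The moderated t follows the standard empirical-Bayes treatment: gene-wise
pooled variances are modeled as scaled inverse-$\chi^2$ draws around a
prior $s_0^2$ with prior df $d_0$, estimated by moment matching of
$\log s_g^2$ using digamma/trigamma identities. The trigamma inverse is
solved by Newton iteration (tolerance $10^{-8}$, at most 50 iterations).
Two degenerate regimes are handled explicitly:

* **Underdispersed variances** (sample spread of $\log s_g^2$ below the
  theoretical sampling spread): $d_0 = \infty$ and the prior reduces to
  the geometric mean of the $s_g^2$, which makes identical gene variances
  an exact fixed point of the moderation (shrinkage changes nothing).
* **All-constant genes**: excluded from the prior fit; their t is
  $\pm\infty$ mapped to $p = 0$ when the group means differ (0 and 1
  otherwise) and flagged in `zeroVar`, so they cannot poison the moment
  matching.

P-values are two-sided, the default behavior of the reference
implementation being emulated; `t > 0` means higher in the case group, so
deletion-driven genes appear with negative t. Forcing `d0 = 0` recovers
the ordinary pooled t-test exactly, which the tests use as an oracle, and
the full fit is cross-checked against limma to machine precision.

Probeset collapse keeps, per gene symbol, the probeset with the largest SD
across the whole dataset. Heatmap ordering uses centroid linkage on the
centered-Pearson distance $1 - r$; centroid linkage on a non-Euclidean
distance is the classic microarray-viewer heuristic, not a geometrically
consistent method — inversions are possible — and orderings are
deterministic (tied distances resolve by `stats::hclust`'s fixed
agglomeration order).

# Signature scoring and ROC

The score $S_j = \sum_g w_g (x_{gj} - m_g)$ uses the moderated t as
weight. Since reduced-expression genes carry negative weights, deletion
pushes the score up: higher means more case-like. Centering means $m_g$
default to the scored cohort's own means (the natural within-set
analysis); `center = "reference"` freezes the training-cohort means, the
appropriate mode for external validation — published analyses do not
always state which was used, so both are provided. AUC is the rank-sum
(Mann–Whitney) probability with ties counted 1/2, provably equal to the
trapezoidal area under the empirical ROC; the tests assert that equality
to $10^{-12}$ on tied inputs.

# Positional enrichment

Band gene sets are built from a gene→band annotation, filtered to the
ranked universe before size filtering (defaults 5–500). The enrichment
score is the signed maximal deviation of the weighted running sum
($|t|^p$ at members, $p = 1$; unweighted fallback when all in-set weights
are zero). Ties in the ranking statistic keep input order, making the
score deterministic.

The null is gene-permutation (random same-size sets drawn from the ranked
list): once only a precomputed ranking is supplied, phenotype permutation
is no longer available, and the preranked convention is the appropriate
null. NES divides the observed ES by the mean magnitude of sign-matched
null scores; the nominal p is the sign-matched exceedance fraction floored
at $1/(n_\text{perm}+1)$ (never exactly zero); the FWER is the fraction of
permutations whose most extreme sign-matched normalized statistic across
all sets beats the observed NES, floored the same way for consistency.
Published per-band ES/NES values depend on the deposited expression data
and the reference implementation's internals, so they are reproduced
qualitatively (sign and extremity) on synthetic cohorts, not bit-exactly.

# Copy-number profiling

Gain/loss calls use symmetric ±0.25 log2 thresholds, the conventional
BAC-CGH practice (the thresholds used in the original analyses were
inherited from prior work and are not restated); they are configurable.
The common region of overlap is the set of maximal runs of consecutive
probes called loss in 100% of case samples, with interval bounds at the
outermost probe bounds of the run. A single neutral probe breaks a run by
default; `gapTolerance` can bridge short interior interruptions. Adding a
sample can only shrink the common region, which the tests assert as a
property. Whole-chromosome losses are reported like any other region.

BAF imbalance scans non-overlapping windows of 25 SNPs and flags windows
whose heterozygous SNPs deviate from 0.5 by more than 0.15 on average.
Heterozygous status comes from (in preference order) an explicit germline
flag, a paired-normal BAF inside (0.3, 0.7), or a density fallback
(tumor BAF in (0.1, 0.9)); the fallback cannot see pure LOH at tumor
fraction 1, where germline genotypes are required.

# FISH deletion test

The deletion percentage takes as denominator the nuclei with the modal
green (pericentromeric) count — the reading consistent with scoring
"nuclei with the modal number of green spots" — plus single-green/
single-red nuclei; the numerator is modal nuclei with fewer red spots plus
those same (1,1) nuclei, so monosomy of both probes counts as loss and
when the mode is 1 the (1,1) nuclei contribute to both counts. Nuclei
with more green spots than the mode (doublets, overlaps) are excluded.
Whether published percentages used modal-green or all nuclei as
denominator cannot be determined from the text; `allNuclei = TRUE`
provides the alternative, and the downstream 2×2 tables are invariant to
the choice at the calling threshold. Modal ties break toward the larger
count so centromeric dropout does not lower the inferred ploidy. Samples
are called loss at percentage ≥ 50 (boundary inclusive), combined calls
require loss on every scored chromosome, and the exact two-sided Fisher p
comes from the closed-form hypergeometric sum with probability ordering
(relative tolerance $1+10^{-7}$ against floating-point ties), verified
against full lattice enumeration for all margins ≤ 12.

# Validation design and problem sizes

The test suite separates oracle equivalence (closed forms, brute-force
enumerations, independent implementations) from statistical recovery and
calibration:

* **Recovery** uses 10 simulated cohorts of 10 + 20 samples with effect
  −0.7 and tumor fractions in [0.7, 0.95], checking that the most negative
  NES belongs to a truly deleted band, that common-region boundaries land
  within one probe spacing of truth, and that a signature trained on one
  cohort classifies an independent one (mean held-out AUC ≥ 0.9).
* **Calibration** uses 200 null replicates each for the enrichment nominal
  p (random rankings, random 20-gene sets, 199 permutations) and the FISH
  Fisher screen, requiring both rejection rates within 3 binomial SEs of
  0.05. Under the cohort-scale FISH defaults a penetrance-0 cohort yields
  all-"other" calls, a degenerate table and a rejection rate of exactly 0,
  so the calibration study deliberately uses a sparse-spot regime (9 + 9
  samples, 6 nuclei, detection efficiency 0.7) in which the binary loss
  call is maximally variable — the hardest case for test size. These
  conditions were fixed at design time.

These sizes keep the full suite under a minute of simulation time while
leaving the binomial bands meaningful; they are the package's chosen
validation scale, stated here so users can scale them up.

# Known limitations

* The expression model is gene-independent given the deletion mask; real
  co-expression inflates signature variance relative to the simulation.
* No segmentation is performed on CGH data (thresholding only); noisy
  single probes can split a common region, which `gapTolerance` mitigates
  but does not model.
* The enrichment FWER follows the permutation convention described above
  and is not an FDR; leading-edge extraction is out of scope.
* The FISH simulator draws green and red spots independently given the
  cell's copy numbers; optical colocalization artifacts are not modeled.
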