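---
title: "Somatic-germline-zygosity calling from tumor-only sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic-germline-zygosity calling from tumor-only sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgzr)
```

# The problem

Clinical tumor sequencing is usually performed without a patient-matched
normal sample. Every variant detected in the tumor is then of unknown
origin: it may be an inherited (germline) polymorphism present in every
cell, or a somatic mutation acquired by the tumor. The two cannot be told
apart by allele frequency alone, because tumor aneuploidy, loss of
heterozygosity (LOH), and admixed normal tissue all displace allele
frequencies away from the naive 50%/100% germline expectations.

`sgzr` resolves variant origin and tumor zygosity by first fitting a
genome-wide allele-specific copy-number model — tumor purity $p$, ploidy
$\Psi$, and per-segment copy number $C_i$ with minor-allele count $M_i$ —
and then testing each variant's observed allele fraction against the
germline and somatic expectations implied by that model.

# The copy-number model

A specimen is a mixture of tumor cells (fraction $p$) and diploid normal
cells (fraction $1-p$). For a genomic segment $S_i$ of length $l_i$ with
tumor copy number $C_i$, the median-normalized coverage log-ratio $r_i$ is
modeled as Gaussian with mean

$$E[r_i] = \log_2 \frac{p C_i + 2(1-p)}{p \Psi_0 + 2(1-p)},$$

and the minor allele fraction $f_i$ of germline-heterozygous SNPs in the
segment as Gaussian with mean

$$E[f_i] = \frac{p M_i + (1-p)}{p C_i + 2(1-p)}.$$

The tumor ploidy is the length-weighted mean copy number,
$\Psi = \sum_i l_i C_i / \sum_i l_i$.

Two ploidy-like quantities appear above deliberately. Observed log-ratio
profiles are *median*-normalized, and the median copy state generally
differs from the length-weighted mean $C$; the fitted normalization
coordinate $\Psi_0$ absorbs that offset inside the log-ratio expectation,
while the reported ploidy is always recomputed from the fitted $C_i$.
Re-assigning states against the recomputed ploidy would re-introduce the
median-vs-mean offset whenever the modal copy number differs from the
ploidy, so the package keeps $\Psi_0$ for expectations and reports $\Psi$
as the biological summary.

## Pipeline

1. **Preprocess** — per-bin tumor depth divided by a process-matched
   normal, log2, median-centered; GC bias removed by Lowess regression of
   log-ratio on GC fraction (span 0.3, one robustness iteration);
   heterozygous SNPs selected tumor-only by an allele-fraction window
   (default [0.10, 0.90] at depth ≥ 20) and folded to minor fraction.
2. **Segmentation** — recursive circular binary segmentation (CBS) on the
   bin-level log-ratios, per chromosome: the arc maximizing the
   two-sample $t$ statistic is split off when its permutation p-value
   falls below `cbs_alpha` (default 0.01, 1000 permutations, seeded);
   segments shorter than `min_bins` (default 10) are never created.
3. **Model fit** — a grid search over (purity, $\Psi_0$) and a
   Metropolis-within-Gibbs sampler (below), combined by a five-requirement
   selection heuristic.
4. **Variant classification** — exact two-tailed binomial tests of each
   variant's alt-read count against the germline and somatic expected
   allele frequencies of its segment.
5. **Cohort aggregation** — per-variant germline/somatic call counts
   across samples combined into a posterior somatic probability under
   binomial error models and a flat prior.

## Grid search in copy-number units

At each grid point the observed log-ratio is inverted into a *measured
continuous copy number*
$\hat c_i = [(p\Psi_0 + 2(1-p))\,2^{r_i} - 2(1-p)]/p$, and the segment
mean minor fraction into a measured minor-allele copy count; both are
snapped to the nearest valid integers and the grid point is scored by the
weighted mean squared copy-number residuals. Copy-number units matter: the
whole-genome doubling map ($p \to p/(2-p)$, $C \to 2C$, $M \to 2M$) and
the affine shift maps ($C \to C + b$ with purity raised accordingly)
reproduce the log-ratio *and* MAF expectations exactly, so observation-space
mean squared errors cannot distinguish these interpretations — but their
measured copy numbers carry proportionally more noise against the same
unit spacing, so they score strictly worse in copy-number units. All local
minima of the score surface are candidates; each is refined off-grid by
Nelder-Mead before comparison, and near-tied candidates (possible on
noise-free input) break toward the lower ploidy.

## Markov chain Monte Carlo fit

The sampler works on the segment summary statistics: the median log-ratio
with standard error $\sigma_{r_i}/\sqrt{n_i}$ and the mean folded minor
fraction with standard error $\sigma_{f_i}/\sqrt{m_i}$. Priors are uniform
on purity over [0.05, 1] and on $\Psi_0$ over [0.8, 8]; the joint
$(C_i, M_i)$ states are categorical over $0 \le C \le 10$,
$0 \le M \le \lfloor C/2 \rfloor$, with a weak parsimony prior
$\exp(-1.5\,|C_i - 2|)$. The parsimony prior is the tie-breaker for the
doubling degeneracy described above: without it the posterior splits
between a genome and its doubled image, while within one interpretation it
is far weaker than the data's preference between adjacent copy states.

Purity and $\Psi_0$ move by collapsed Metropolis steps — random walks plus
independence proposals drawn from the marginal posterior tabulated on a
grid before sampling — with the discrete states summed out, so chains can
hop between copy-number interpretations; states are then redrawn from
their exact conditional (a Gibbs step via the Gumbel-max trick). Defaults
are 500 burn-in sweeps, 500 retained samples, thinning 1, and 9 chains;
convergence is monitored by split-$\hat R$ of purity (flagging above 1.1,
in which case selection falls back to the grid candidates). The point
estimate combines the posterior-median purity and $\Psi_0$ with
per-segment posterior-mode states, then polishes that estimate to the
score optimum of its own mode so that goodness-of-fit comparisons against
grid candidates compare optima with optima.

## Model selection

The MCMC model is the default. A grid candidate (among the first three
local minima) replaces it only if **all** of: (1) it improves the fit —
the log-ratio MSE, the MAF MSE, and the measured-copy-number score are all
reduced (the copy-number score is the scale-aware tiebreaker; the
observation-space MSEs alone tie across doubled or shifted
interpretations); (2) its ploidy exceeds 1.2; (3) its genome fraction at
$C = 0$ is at most 10%; (4) it is not a more complex model, defined as
ploidy at least 1.1 higher together with purity at least 0.1 lower than
the default; (5) its purity does not exceed 0.99 unless an independent
high-purity screen agrees.

The high-purity screen inspects the raw genome-wide SNP table rather than
the het-selected profile — necessarily, because near purity 1 the het SNPs
in LOH segments are displaced outside any heterozygous selection window.
It reports a plausibly near-pure specimen when ≥ 30% of SNPs inside a wide
allele-fraction window ([0.01, 0.99]) have folded minor fraction below
0.10, or when the ordinary het window's occupancy collapses below 25%
(pure specimen with widespread LOH).

# Variant classification

For a variant with read depth $n$ and allele fraction $f$ in a segment
with state $(C, M)$ at purity $p$, the candidate tumor allele counts are
$V \in \{M, C-M\}$ — a variant rides one parental lineage — with $V = 0$
("not in tumor") additionally allowed under the germline hypothesis. The
expectations are

$$AF_{germline} = \frac{pV + (1-p)}{pC + 2(1-p)}, \qquad
  AF_{somatic} = \frac{pV}{pC + 2(1-p)},$$

and each hypothesis is scored by the exact minimum-likelihood two-tailed
binomial p-value of $k = \mathrm{round}(nf)$ (the exact alt count when
available) at its best candidate $V$ (ties toward the smaller $V$). With
$\alpha = 0.01$:

* **somatic** if $P(y|S) > \alpha$ and $P(y|G) \le \alpha$;
* **germline** if $P(y|G) > \alpha$ and $P(y|S) \le \alpha$;
* **subclonal somatic** if both $\le \alpha$, $f < AF_{somatic}/1.5$, and
  purity > 0.20;
* otherwise **ambiguous**, with the reason recorded (compatible with both,
  outside both, high purity, model misfit, or undefined expectations).

No-call gates: specimens with fitted purity above 0.95 are not called at
all; variants in segments whose observed median log-ratio deviates from
the model expectation by more than 3 segment SDs (or lying outside every
modeled segment) are no-calls for model misfit. Zygosity — homozygous
($V = C$), heterozygous ($0 < V < C$), not-in-tumor ($V = 0$) — is
reported only at purity ≥ 0.20.

Classification depends on the model *only* through the candidate
expected-AF sets: two models producing the same candidate sets at a
variant's segment yield identical calls, a property verified by a
randomized test over constructed model pairs.

An AF-only comparator (`basic_method_classify`) is included: germline if
$f$ is within 0.10 of 0.5 or at least 0.90, otherwise somatic. It always
calls, and its germline accuracy degrades on LOH/aneuploid genomes — the
contrast that motivates the model-based method.

# Cohort aggregation

For a variant observed across samples with $n_G$ germline and $n_S$
somatic calls (subclonal somatic counts as somatic; ambiguous calls carry
no weight), the posterior somatic probability under a flat prior is

$$P(S \mid n_G, n_S) =
  \frac{P(n_G, n_S \mid S)}{P(n_G, n_S \mid G) + P(n_G, n_S \mid S)},$$

with binomial error likelihoods at conservative single-sample error rates
$e_G = 0.05$ and $e_S = 0.10$. The computation runs in log space and also
reports $\log_{10} P(S)$, which stays exact when the posterior itself
underflows a double (hundreds of concordant calls).

# The synthetic-specimen generator

All validation runs on simulated specimens with known truth. The
generator emulates deep targeted sequencing of an admixed tumor:

* a default genome of 20 segments on 8 chromosomes (80 bins of 1 kb per
  segment) covering balanced diploid, copy-neutral LOH, single-copy loss,
  unbalanced gains, and a focal amplification, with consecutive segments
  always differing in total copy number;
* per-bin normal depth Poisson around `mean_depth` (default 800×, deep
  panel sequencing); tumor depth Poisson around
  `mean_depth`·2^(expected log-ratio) with log-normal bin noise of SD 0.1
  log2 units; optional polynomial GC bias;
* a genome-wide SNP panel (30 SNPs per segment, 60% heterozygous);
  het-SNP alt reads are binomial at the expected allele fraction with
  random parental orientation; homozygous SNPs are emitted at alt
  fraction 0.999 so het selection has realistic work to do;
* variants with binomial alt reads at the germline expectation, or at the
  somatic expectation thinned by the cancer-cell fraction for subclonal
  variants; tumor allele counts are drawn from the parental-lineage set
  $\{M, C-M\}$.

The defaults represent the operating regime of deep panel sequencing: a
mostly near-diploid genome at ≥ 500× with segment sizes large enough that
adjacent integer copy states separate clearly in the log-ratio. What the
simulations do **not** contain: mapping artifacts, FFPE damage,
sequencing-error profiles beyond binomial sampling, subclonal copy number,
and germline CNVs. Passing tests therefore demonstrate the statistical
machinery under its stated model, not robustness to violations of it.

# Numerical choices

* **Folded-MAF correction.** Observed minor fractions are folded to
  [0, 0.5], which biases segment means below 0.5 near balanced states by
  about $s\sqrt{2/\pi}$ (with $s$ the per-SNP binomial SD). Model-side
  expectations use the folded-normal mean; measured minor-copy inversions
  first unfold the observed mean by numerically inverting that map.
  Ignoring this tilts flat genomes toward spuriously high purity.
* **SD floors** of 0.05 (log-ratio) and 0.02 (MAF) prevent zero-variance
  likelihood collapse on tiny segments.
* **Segment assignment** of a variant outside every segment falls to the
  nearest segment midpoint on its chromosome.
* **Ties** between $V = M$ and $V = C-M$ break toward the larger p-value,
  then the smaller $V$; grid score ties break toward the lower ploidy.
* **Binomial test**: minimum-likelihood two-tailed with a $1+10^{-7}$
  relative slack on probability ties (the same convention as
  `stats::binom.test`, which serves as an independent cross-check in the
  test suite).
* The optional germline-homozygous hypothesis (normal carries two alt
  copies, $AF \to 1$) is **not** modeled: the germline expectation encodes
  a heterozygous normal. Variants near $f = 1$ in a diploid segment fall
  to "outside both" rather than being called germline-homozygous.

# Known limitations

* Near purity 0.5 the germline "not in tumor" and somatic heterozygous
  expectations in diploid segments converge ($AF = (1-p)/2$ versus $p/2$),
  and near purity 0.25 under CN-3 LOH the germline-absent and
  somatic-homozygous expectations cross at exactly 1/3 — genuinely
  undecidable cases that surface as "compatible with both" no-calls.
* Below roughly 22% purity the selection heuristic's complexity guard
  (rule 4) cannot flag a whole-genome-doubled alternative by its stated
  thresholds (the doubling map changes purity by less than 0.1 there);
  the copy-number-unit score carries the discrimination instead.
* Copy numbers above 10 are capped at `c_max`; subclonal copy number and
  allele-specific states beyond $(C, M)$ are out of scope.
* Purity estimates above 0.95 trigger a blanket no-call, and zygosity
  requires purity ≥ 0.20; both gates reflect the information actually
  available at those compositions, not implementation limits.

# Problem sizes in the test suite

The acceptance-level tests run 20 specimens across purity 0.2–0.8 for
parameter recovery (depth 800, noise SD 0.1, 20 true segments of 80 bins)
and a six-level titration cohort at purities 10–75% for end-to-end
classification; unit tests use an 8-segment genome at 30–60 bins per
segment. These sizes give each segment enough bins that the median's
standard error sits well below the half-spacing of adjacent copy states —
the same regime that hundreds of exons per segment provide in practice —
while keeping the full suite fast enough to run routinely.
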