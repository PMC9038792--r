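---
title: "lohscape: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lohscape: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`lohscape` scores percent genomic loss of heterozygosity (gLOH) — a genomic
scar used as a surrogate of homologous recombination deficiency (HRD) — from
targeted-panel SNP allele data, and provides the cohort-level statistics
used to study gLOH in leiomyosarcoma (LMS): distribution description with a
ranked-curve inflection cutoff, gene–alteration association screens,
differential prevalence between uterine (uLMS) and non-uterine disease, and
survival analysis of a clinical sub-cohort. Because the cohorts that
motivate these analyses are not publicly available, the package ships a
synthetic-data generator whose defaults emulate their published statistical
structure; every pipeline stage is exercised against planted ground truth.

# The scoring model

## Observation model

For a tumor of purity $p$ and mean ploidy $\psi$, a genomic segment with
integer total copy number $C_i$ and minor-allele copy count $M_i$
($0 \le M_i \le \lfloor C_i/2 \rfloor$) produces

* a log2 copy ratio $\mathrm{lr} = \log_2 \frac{pC_i + 2(1-p)}{p\psi + 2(1-p)}$
  relative to a process-matched normal reference, and
* a minor-allele ("folded") B-allele frequency at germline-heterozygous SNPs
  $b = \frac{pM_i + (1-p)}{pC_i + 2(1-p)}$, with the alternate allele playing
  the minor role at random per site.

The generator (`simulate_sample()`) draws per-site depth as Poisson around
the expected copy ratio with log-normal noise (default SD 0.15 on the log2
scale — the assay's real noise characteristics are unpublished, so this is a
configurable default chosen to make segmentation non-trivial but
recoverable) and binomial alternate-read counts. Only heterozygous sites are
generated: homozygous sites carry no LOH information.

## Segmentation

`segment_profile()` runs penalized multiple-changepoint detection (PELT
with an L2 cost) per chromosome on the joint signal of log-ratio and
per-site folded BAF $|{\rm baf} - 0.5|$, each standardized by a robust
noise estimate from successive differences. The penalty defaults to
$3\log n$ per chromosome (BIC-style: two segment means plus one
breakpoint). The published method says only that the profile "was
segmented"; any consistent changepoint method would do, and the test suite
pins this one to an exhaustive dynamic-programming oracle on the identical
cost. Segment boundaries sit at midpoints between flanking SNPs; segments
with fewer than `min_snps` (default 5) SNPs are merged into the neighbour
with the closest mean log-ratio.

A bias worth noting: the raw mean of $|{\rm baf}-0.5|$ over a segment
overestimates true allelic imbalance by the binomial sampling noise
($\approx 0.025$ at depth 250 for a balanced site). Segment summaries are
therefore debiased as
$\hat\Delta = \sqrt{\max(\overline{({\rm baf}-0.5)^2} -
\overline{{\rm baf}(1-{\rm baf})/{\rm depth}},\,0)}$; without this the
purity/ploidy fit systematically drifts to high-ploidy candidates whose
denser BAF state grid can interpolate the bias.

## Purity/ploidy fit and its identifiability

`fit_purity_ploidy()` scans purity $\in \{0.10, 0.12, \dots, 1.00\}$ and
$\psi \in \{1.0, 1.1, \dots, 6.0\}$; each candidate assigns every segment
its best integer state and is scored by the length-weighted mean squared
error in (log-ratio, folded BAF). Two additions were necessary beyond the
plain cost:

1. **Free log-ratio offset per candidate.** The observed profile is
   median-centered, which need not coincide with the candidate's $\psi$
   normalization; with a 0.1-step $\psi$ grid the mismatch otherwise
   inflates the true candidate's cost across the whole genome.
2. **Regularization against scaled degeneracies.** Multiplying every state
   by $k$ while moving purity to $p' = p/(k - kp + p)$ reproduces the
   identical signal shape, so the pure cost cannot distinguish a diploid
   solution from its doubled or tripled ghost (and near-ghosts can corrupt
   LOH calls, e.g. mapping a hemizygous loss to $(4,1)$). The fit adds a
   self-consistency term $0.05\,(\hat\psi_{\rm implied} - \psi)^2$ and a
   small diploid-parsimony term $3\times10^{-4}\,(\psi - 2)^2$ (per-bp cost
   units). The parsimony weight is orders of magnitude below genuine
   misfit, so it only arbitrates between members of a degenerate family —
   the same convention (lowest plausible ploidy) used by established
   allele-specific copy-number tools. Residual exact ties break toward
   higher purity, then lower $\psi$.

## State assignment, LOH call, exclusions, score

`estimate_allele_specific_cn()` minimizes the SNP-count-weighted squared
residual over the integer grid $C_i \le 8$ (ties toward smaller $C_i$, then
larger $M_i$ — conservative against over-calling LOH) and reports a
confidence margin (second-best minus best cost). The margin is
SNP-weighted, i.e. on a log-likelihood-like scale: with the default
ambiguity threshold of 0.05 an *unweighted* margin would mark every segment
ambiguous below purity $\approx 0.45$, where the folded-BAF separation
between states is $\sim 0.2$.

A segment is in LOH iff $C_i \neq 0$ and $M_i = 0$ — copy-neutral LOH
counts, homozygous deletion does not. Before scoring, adjacent LOH segments
are merged into maximal runs and a run spanning $\ge 90\%$ of its
chromosome or of either arm is excluded (such events typically arise by
non-HRD mechanisms); segments with $< 5$ SNPs or margin $< 0.05$ are
excluded as ambiguous ("ambiguous" is never defined by the published
method; this is a documented proxy). Percent gLOH is then
$100 \times$ (length of non-excluded LOH) / (length of non-excluded
genome), autosomes only. Exclusion removes length from numerator *and*
denominator, so the score can legitimately *decrease* when added LOH pushes
a run over the arm threshold — the monotonicity property holds only below
it.

## Quality control

Two failure modes are named in the source material without thresholds;
the proxies here are:

* `low_tumor_content` — the fitted purity is below 0.20, or, for samples
  whose true purity lies below the grid floor of 0.10, the purity implied by
  the most significant imbalanced segment ($p = (1-2b)/(1-b)$ under the
  purity-generous hemizygous-loss reading) is below 0.20.
* `low_aneuploidy` — no segment shows statistically significant allelic
  imbalance or log-ratio deviation (z > 4) and under 2% of the genome is
  assigned a non-(2,1) state. A genuinely diploid tumor and an all-normal
  sample are indistinguishable here; the flag names the evidence, not the
  cause. `gloh_config(qc_override = TRUE)` still reports the score.

# Cohort statistics

## Inflection cutoff

The gLOH-high cutoff is derived from the ranked gLOH curve: sort ascending,
smooth with a moving-average kernel (bandwidth $\max(5, n/100)$ ranks —
raw finite differences of sorted data form a step function whose second
derivative is almost never exactly zero, so smoothing is what makes the
rule computable), and return the value at the second-derivative
zero-crossing nearest the first derivative's maximum. On a log-normal
sample the ranked curve is convex to the end, the first-derivative maximum
sits at the boundary, and the detected crossing lands in the extreme upper
tail (`boundary = TRUE`); the cutoff is then method- and
bandwidth-dependent. The synthetic reproduction is therefore *not* a
replication of the published 26.1% value — accuracy claims are made only on
planted quantile functions with analytic inflections, where the detector's
error is below 2% at large n and shrinks with n.

## Classification and summary

`classify_gloh_high()` counts values $\ge$ cutoff as high (tie-goes-high is
a documented choice). `summarize_distribution()` reports mean/SD,
maximum-likelihood log-normal parameters (zeros offset by 0.1), and a
KS-based goodness-of-fit indicator whose p-value, with estimated
parameters, is approximate and should be read only as a gross-departure
alarm.

# Association analyses

* **HR groups** (`assign_hr_groups()`): precedence BRCA2 homozygous
  deletion > other-HR-gene homozygous deletion > HR-gene mutation
  (rearrangement/truncation/missense) > intact. Amplifications are not
  mutations. The default gene list (BRCA1/2, ATM, ATR, BRIP1, CHEK2, NBN,
  PALB2, RAD51 and FANC families) is user-overridable; the exact published
  supplementary list is unavailable.
* **Group contrast**: classical one-way ANOVA plus pairwise Welch tests
  against the control group. Dunnett/Tukey adjustments are computed by
  seeded Monte-Carlo of the correlated max-|t| null (50,000 draws by
  default, deterministic given the seed); with one comparison the
  adjustment is exactly the identity.
* **Univariate screen**: closed-form simple OLS of gLOH on each binary
  (gene, class) indicator; Bonferroni $q = \min(1, m\,p)$ with $m$ = number
  of keys actually tested (prevalence strictly inside (0,1)), recorded in
  the output. Candidates satisfy $q < 0.1$ and observed prevalence
  $\ge 0.5\%$. The prevalence filter is applied strictly to the observed
  fraction; see the known-limitations note on its knife-edge behaviour.
* **Multivariate fit**: joint OLS with the uterine indicator; duplicated
  and collinear columns (the CDKN2A/CDKN2B deletion pair is the canonical
  case) are dropped with a warning and reported.
* **Differential prevalence**: per key, a 2x2 chi-squared test without
  continuity correction (exact test when an expected cell is < 1);
  significance is the conjunction |prevalence difference| > 10 points and
  p < 5e-5.
* **Mutual exclusivity**: two-sided Fisher exact test per pair (no method
  is named in the source; the exact test is the conservative default);
  infinite odds ratios are capped at 1e6.

# Survival

Median-gLOH dichotomization uses a strict ">" for high (ties go low).
Kaplan–Meier, log-rank and Cox (Efron ties by default) are backed by the
`survival` package behind this module's interface; the tests keep
independent oracles (hand product-limit computation, brute-force partial
likelihood). The endpoint is a generic time-to-event labelled from
configuration, as the source material is internally ambiguous between
disease-free interval and survival.

# What the generator emulates — and what a green test does not establish

Defaults are the published cohort's stated structure: n = 1658 scored
tumors, 39.3% uterine, baseline gLOH log-normal moment-matched to mean
12.9% / SD 6.9%, the eight signature alterations planted at their published
prevalences and *univariate* effect sizes (the multivariate BRCA2 row is a
typesetting duplicate of the NF1 row and is not used), a +0.86-point
uterine shift, zero-effect HR-pathway mutations at realistic prevalences,
uterine-differential ATRX/RB1 mutation prevalences (directions published,
magnitudes chosen here as 30%/12% and 10%/25% to clear the 10-point
threshold), and a 40-patient survival sub-cohort with hazard ratio 0.31 for
gLOH-high, exponential baseline with 36-month median, and 30% independent
censoring. Sex (80.3% female), age (normal 58 ± 11.9, truncated 19–85),
TMB (log-normal, mean 2.4) and MSI (0.4% high) are descriptive dressing.

The generator draws alteration indicators independently (optional
exclusivity constraints exist for testing), uses additive effects with
clamping to [0, 100], and knows nothing about real LMS biology beyond these
moments. A green suite therefore establishes that the *pipeline* recovers
what was planted under this stated world — not that the published effect
sizes, the 26.1% inflection, or the clinical hazard ratios are externally
reproduced; those derive from non-public data.

# Numerical choices and degenerate inputs

* All randomness flows from one seed; stages derive sub-seeds via
  `stage_seed()` (documented affine map mod $2^{31}-1$), and seeded
  internals restore the caller's RNG state.
* Copy-ratio floored at 0.01 before log2 so homozygous deletions at purity
  1 stay finite; at $C_i = 0$ the expected folded BAF is 0.5 (only normal
  cells contribute reads).
* Zero-depth sites are flagged NA and omitted; chromosomes with no usable
  sites become single zero-SNP segments, which the ambiguity rule excludes,
  keeping the bookkeeping identity (included + excluded = genome length)
  exact.
* Coordinates are 0-based half-open internally, 1-based inclusive on disk.
* Errors are classed conditions (`lohscape_error_*`), so callers can
  distinguish QC failures, undefined scores, schema problems and
  invalid arguments programmatically.

# Known limitations

* Subclonal states, phased haplotypes, telomeric allelic imbalance and
  large-scale state transitions are out of scope.
* The segmentation algorithm, ambiguity criterion and QC cutoffs of the
  commercial pipeline are unpublished; the implementations here are
  documented proxies and scores are not comparable to that assay's output.
* The candidate filter "prevalence $\ge$ 0.5%" sits on a knife edge at the
  published FBXW7 prevalence: at n = 1658 and true prevalence 0.005 the
  expected carrier count is 8.29 while the filter needs 9 observed
  carriers, so the probability a planted FBXW7 signal passes is only
  $P(\mathrm{Bin}(1658, 0.005) \ge 9) \approx 0.45$ — no screening
  implementation can jointly detect FBXW7 and NF1 in $\ge 80\%$ of
  replicates under Bernoulli sampling at these parameters. (The published
  table itself lists FBXW7 at "0.5%", i.e. 8/1658 = 0.48%, which passes its
  own filter only after rounding.) The corresponding acceptance test is
  deliberately left failing with this analysis.
* Purity below the 0.10 grid floor is detected (QC) but not estimated.
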