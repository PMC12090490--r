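---
title: "Mapping a recessive lethal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive lethal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalmapr)
```

`lethalmapr` implements the computational chain used in livestock genetics to
identify and characterise a recessive lethal variant from routine breed data:
pedigree contribution analysis, sliding-haplotype homozygosity mapping,
candidate-variant filtering against control panels, mating-type mortality
analysis with a closed-form penetrance expectation, mixed-model testing of
heterozygote effects, and multiple-testing control. A forward-in-time
population simulator generates data with the statistical structure these
analyses assume, so the whole chain is testable without animal data.

This vignette records the methods and, explicitly, the modelling decisions
behind each module.

## 1. Pedigree contributions

For an ancestor $a$ and individual $i$, the expected genetic contribution
$c_a(i)$ is the probability that a gene copy sampled at random in $i$
descends from $a$. It satisfies the recursion

$$c_a(i) = \tfrac12\, c_a(\mathrm{sire}(i)) + \tfrac12\, c_a(\mathrm{dam}(i)),
\qquad c_a(a) = 1,$$

with unknown parents contributing 0. `genetic_contribution()` evaluates this
in one topological pass; `contribution_ratio()` compares an ancestor's mean
contribution to a case group against a control group. An elevated ratio flags
the putative founder of a recessive defect, because every affected individual
must receive the deleterious allele through both parental lineages from that
founder. `common_ancestors()` counts, per candidate, the cases whose sire-side
and dam-side ancestries both contain the candidate — the signature of an
inbreeding loop.

The recursion is validated in the test suite against a Monte-Carlo
gene-dropping oracle (label an ancestor's two gene copies, drop them through
the pedigree, average the labelled fraction).

*Decision.* Contributions are expected proportions of genome, not
probabilities of carrying a specific allele; the two coincide in expectation
up to the factor introduced by the ancestor's own heterozygosity, and ranking
by ratio is invariant to that factor.

## 2. Homozygosity mapping

`hap_scan()` slides windows of 20 consecutive informative markers
(MAF > 0.01) along each chromosome, one marker at a time. An individual is
homozygous for a window haplotype when its two phased haplotypes agree across
all 20 markers. For every haplotype carried homozygously by at least one
case, the 2×2 table (cases homozygous / not, controls homozygous / not) is
tested with a two-sided Fisher exact test, implemented by point-probability
summation of the hypergeometric distribution (`fisher_exact_2x2()`), with a
relative tolerance of $10^{-7}$ guarding floating-point ties. The family-wise
5% significance line is the Bonferroni transform
`bonferroni_threshold(0.05, n_tests)` $= -\log_{10}(0.05/n)$.

`extract_interval()` merges overlapping windows for which *all* cases are
homozygous for one haplotype and *no* control is homozygous for it into
maximal marker runs, and keeps the longest run — the longest haplotype shared
by all cases and absent (in homozygous state) from all controls. The mapping
interval is then delimited by the most proximal informative markers *outside*
the run on either side; at a chromosome end the interval is truncated at the
run boundary with a message. `predict_status()` assigns each individual a
carrier dosage in {0, 1, 2} by counting its phased haplotypes identical to
the risk haplotype across the run.

*Decisions.*

- Window size 20 corresponds to roughly 1 Mb at 50K-array density, the scale
  at which identity by descent from a breed founder a handful of generations
  back survives recombination.
- All fully qualifying windows of a scan share one 2×2 table and therefore
  one p-value, so "the most significant window" does not discriminate between
  qualifying runs; run length does, and p-value breaks remaining ties.
- Exact windowed haplotype comparison is implemented by encoding 20 alleles
  as an integer in $[0, 2^{20})$ held exactly in a double, updated in a
  rolling fashion — an $O(n\,m)$ scan with no hashing or string operations.

## 3. Candidate-variant filtering

`filter_candidates()` applies, in order: (i) position inside the mapping
interval; (ii) homozygosity for the alternate allele in every sequenced case,
with a missing genotype failing the stage; (iii) absence from the
within-breed control panel, then from the multi-breed panel ("not segregating
at all" — any presence excludes). It returns a `filter_trace` with the count
after every stage, so the collapse from thousands of interval variants to a
handful of candidates is auditable. `sv_concordance()` retains structural
variant calls supported by two different callers on the same individual with
reciprocal overlap ≥ 0.70.

## 4. Mortality by mating type and penetrance

With ungenotyped dams, mating types are defined by the sire × maternal
grandsire (MGS) genotypes. For a heterozygous MGS, a surviving daughter is
wild-type or heterozygous with probabilities

$$P(\mathrm{wt}) = \frac{1-f_A}{2-f_A}, \qquad
  P(\mathrm{het}) = \frac{1}{2-f_A},$$

(`dam_genotype_probs()`): the daughter cannot be a surviving homozygote, and
the remaining two states are renormalised. Multiplying through Mendelian
segregation, the expected excess mortality of 1×1 matings over 0×0 matings
under complete penetrance is

$$\Delta = \frac{1}{4\,(2-f_A)}\,(1-\mu),$$

where $\mu$ is the baseline mortality (`expected_increase()`). At
$f_A = 0.026$ and $\mu = 0.0285$ this is 12.30 percentage points — the
package's headline reference value, recomputed by `scripts/acceptance.R`.

`fit_mating_model()` expands grouped (n, deaths) records to calf level and
fits a one-way fixed-effect linear model on the 0/100 scale, so the contrast
of each mating type against 0×0 equals the raw-mean difference, with its
model-based standard error and t-test. `penetrance_check()` compares the
observed/expected mortality ratio against an independent registration
proportion, reporting **both** a Pearson chi-square goodness-of-fit test and
a Fisher exact 2×2 test: the two can disagree materially at small counts, and
reporting both avoids a silent choice.

`simulate_matings()` draws calf outcomes for the four mating types under the
exact conditional model above and is used to verify the closed form by Monte
Carlo.

## 5. Heterozygote effects on quantitative traits

`grm()` builds the genomic relationship matrix
$G = WW^\top / 2\sum_j p_j(1-p_j)$ from centred dosages (VanRaden method 1),
optionally excluding the tested chromosome. `mlma()` fits

$$y = \mu + x b + u + e, \qquad u \sim N(0, \sigma_u^2 G),\ e \sim N(0,
\sigma_e^2 I)$$

by restricted maximum likelihood, profiling the single parameter
$h^2 = \sigma_u^2/(\sigma_u^2+\sigma_e^2)$ on the eigendecomposition of $G$
(one rotation, then each likelihood evaluation is $O(n)$), followed by
generalised least squares for $(\mu, b)$ and a Wald test. Effect sizes are
scaled by `effect_in_gsd()` into genetic standard deviations, the unit in
which breeders compare QTL.

`bh_qvalues()` implements the Benjamini–Hochberg step-up,
$q_{(k)} = \min_{j \ge k} p_{(j)} n / j$, cross-checked in the tests against
`stats::p.adjust`. The choice of family matters: adjusting a p-value of 0.04
within five performance traits gives $q = 0.20$, while the same arithmetic in
a five-contrast mortality family turns $1.59\times10^{-11}$ into
$3.98\times10^{-11}$. The package takes no position on the "right" family;
the function is explicit about its input.

## 6. The simulator

`simulate_population()` is a two-phase forward-in-time gene-dropping
simulator with discrete generations.

**Phase A (cheap):** pedigree structure, risk-locus transmission and
survival. Dams are monogamous; sires are drawn with replacement from
surviving males, mimicking the strong sire reuse of cattle breeding.
Homozygotes die according to per-period penetrances (default: complete
lethality at 0–2 days) and never breed; their trait values are missing, since
dead calves are not phenotyped.

**Phase B (expensive, run once per accepted attempt):** marker positions on a
jittered grid, founder haplotypes drawn at Hardy–Weinberg from
uniform-on-[floor, 0.5] frequencies, and a full marker gene drop with Poisson
crossovers at 1 cM/Mb. Transmission on the risk chromosome is constrained to
agree with the phase-A risk-allele transmission through the crossover parity
at the locus, so marker haplotypes and risk genotypes are always consistent.
A polygenic trait value follows the parent average plus a Mendelian-sampling
deviation; the heterozygote effect is additive with dosage capped at 1 among
survivors.

**Replicate acceptance.** Two documented conditions trigger a logged resample
with an incremented seed (`attempts`/`seed_used` are recorded in the result):

1. the realised final-generation allele frequency must land within
   `freq_tolerance` (default ±25% relative) of the target — under the default
   `"single_founder"` seeding the allele starts on one founder chromosome and
   drift would otherwise dominate;
2. the affected homozygotes must share a homozygous marker run of at least
   `min_shared_ibd_bp` (default 1.6 Mb) around the locus — the simulator's
   contract is a megabase-scale identical-by-descent lethal haplotype, and
   deep pedigrees occasionally recombine the shared segment below the scale
   the haplotype scan (or any 20-marker-window method) can see.

*Default parameters and rationale.* 20 founders and 7 generations give a
bottlenecked breed of ~5,000 individuals in which a single founder's
haplotype can plausibly rise to a few percent; 2,000 markers on 2 × 50 Mb
chromosomes reproduce 50K-array density (1 marker / 50 kb); polygenic and
residual variances (22.8, 53.1) give a trait heritability of 0.3 at a
phenotypic SD of about 8.7, typical of conformation scores; the heterozygote
effect of −1.0 is a small effect of the kind detectable only in large
national datasets. All of these are configuration, not assumptions baked into
the analysis code.

*What the simulator does not emulate:* genotyping or imputation error,
phasing error, selection and BLUP-driven mating decisions, overlapping
generations, sequence-level reads. The analyses therefore see idealised
phased data; robustness to data error is out of scope.

## 7. Splice-consequence toolkit

`gene_model()` + `build_isoform()` assemble mis-spliced transcripts by
inserting a segment (for example a cryptic exon) at an exon junction; the
insertion is treated as an exon of its own, contributing two junctions.
`orf_consequence()` translates from the reference start codon, flags a
frameshift when the inserted length is not a multiple of 3, locates a
premature termination codon (a stop before the reference protein length),
predicts nonsense-mediated decay by the canonical 50-nt rule (PTC at least
50 nt upstream of the final exon–exon junction; configurable), and reports
the fraction of the reference protein lost. `ese_scan()` scores exonic
splicing enhancer motifs with a user-supplied position-specific scoring
matrix using plain additive per-position scores; `ese_allelic_delta()`
reports per-site score changes between two alleles, antisymmetric under
allele swap. No scoring matrix ships as authoritative data; matrices are
user configuration.

## 8. Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
pop <- simulate_population(cfg)
cc <- sim_case_control(pop)

scan <- hap_scan(pop$genotypes, cc$cases, cc$controls)
mapping <- extract_interval(scan)
mapping

status <- predict_status(pop$genotypes, mapping)
table(status, pop$risk_dosage)
```

On default settings the scan localises the simulated lethal locus inside the
extracted interval, and haplotype-predicted carrier status agrees with the
true dosage for essentially all individuals (the rare disagreements are
recombinants between the run and the locus).

## 9. Known limitations

- The Fisher test is the conventional point-probability two-sided version;
  other two-sided definitions exist and give different p-values on asymmetric
  tables.
- `extract_interval()` requires *all* cases homozygous and *zero* homozygous
  controls; a single phenocopy or genotyping error breaks the run. This
  mirrors the fragility of the underlying field method rather than hiding it.
- REML in `mlma()` profiles a single variance ratio; multi-component models
  are out of scope.
- The chi-square statistic in `penetrance_check()` is asymptotic and
  unreliable at very small expected counts; that is precisely why the Fisher
  exact p-value is reported alongside.
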