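---
title: "Methods: array tagging and imputation accuracy in structured cattle populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array tagging and imputation accuracy in structured cattle populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

SNP genotyping arrays are designed around variants discovered in a handful
of (mostly European taurine) cattle breeds. When such an array is used on a
diverged population — African indicine or admixed taurine–indicine cattle —
two things degrade at once: the array's variants *tag* less of the
segregating variation (lower LD between array sites and off-array sites),
and genotype *imputation* from the array to sequence level becomes less
accurate, because the reference haplotypes matched by the imputation model
are a poorer fit. `herdimpute` provides the machinery to quantify both
effects end to end on synthetic cohorts whose population structure is under
the user's control: a cohort simulator, array-design emulators, allele
harmonization and QC, windowed LD tagging statistics, a Li–Stephens
imputation engine with leave-one-out accuracy, and an experiment driver.

Everything is exercised on simulated data. The package deliberately does
not ship or require real cattle genotypes; the value of the synthetic
route is that truth haplotypes, truth phase and truth ancestry are known
exactly, so accuracy metrics are computed against ground truth rather than
against a proxy.

## The cohort simulator

### Site frequencies: Balding–Nichols differentiation

Each site's ancestral allele frequency $p$ is drawn Uniform(0.02, 0.98).
Population $k$ with differentiation $F_k$ draws its frequency from

$$p_k \sim \mathrm{Beta}\!\left(p\,\frac{1-F_k}{F_k},\;
(1-p)\,\frac{1-F_k}{F_k}\right),$$

which has mean $p$ and variance $p(1-p)F_k$. $F = 0$ passes $p$ through
exactly; $F = 1$ is rejected as degenerate. Two populations at
$F_1 = F_2 = 0.2$ have a pairwise Hudson-type FST of about 0.2, the order
of magnitude of the taurine–indicine split; the default model uses exactly
that. Fixed ancestral sites stay fixed everywhere.

### Haplotypes: a founder-seeded copying model

Within each population, the first `n_founders` haplotypes are drawn
site-wise Bernoulli($p_k$); each later haplotype is a recombination mosaic
of the haplotypes generated before it. Between adjacent sites separated by
$d$ bp the template switches with probability $1 - e^{-\rho d}$, and each
copied allele flips with probability `mut_eps` ($10^{-3}$ by default).
Marginal frequencies are preserved in expectation, while shared founder
segments generate LD that decays with distance at a rate set by $\rho$.

Two parameters control the LD landscape and were fixed once, before the
test suite was written, so that the synthetic cohorts show the qualitative
behaviour real cohorts show:

* `copy_rho` — the per-bp switch rate. Defaults: $10^{-6}$ for the
  taurine-like population and $4\times 10^{-6}$ for the indicine-like one,
  giving mean shared-segment lengths of roughly 1 Mb and 250 kb. The
  indicine-like population therefore has the faster LD decay, reproducing
  the direction of the real taurine/indicine contrast, and LD is long
  enough relative to realistic array spacing for haplotype-based
  imputation to be informative rather than noise-dominated.
* `n_founders` — the number of independent founder haplotypes per
  population (default 32). This plays the role of an effective founder
  pool: background LD scales like $1/n_\mathrm{founders}$, and a finite
  pool makes rare alleles live on backgrounds that a finite reference
  panel can genuinely fail to carry — without this, every rare variant
  would be exactly matchable and imputation accuracy would not fall at low
  MAF, contrary to what is universally observed in practice.

A deliberate deviation from the simplest formulation: seeding with a
*single* Bernoulli haplotype and copying everything from it would collapse
the pool to near-monomorphism, so the founder block is drawn i.i.d. and
later haplotypes mosaic over all of their predecessors; the single-founder
process is the `n_founders = 1` special case.

### Cohorts: ancestry mosaics and observation error

A cohort is specified by admixture proportions $\alpha$ over the
populations. Each sampled haplotype is built segment-wise: breakpoints
follow the same exponential switch process (rate = the $\alpha$-weighted
mean of the population rates), each segment's ancestry is drawn from
$\alpha$, and the segment is copied from a random haplotype of that
population's pool. $\alpha = (1, 0)$ reduces to pure resampling from
population 1.

Genotypes are the site-wise sum of the two truth haplotypes. A symmetric
per-haplotype-call allele-flip error (default 0) and per-call missingness
(default 0) can be injected; these affect the *observed* haplotypes and
the genotype matrix only, never the truth panel, so accuracy is always
measured against clean truth. Per-site QUAL (log-normal around 500) and
per-call GQ (Poisson around 60 with a 3% low tail) are simulated so every
QC rule has something to act on.

### Arrays and impact labels

Three ascertainment schemes are emulated. `uniform-common` takes sites
with MAF at or above a threshold (default 0.05) *in a named discovery
population* and spaces them evenly — the classic design whose
informativeness drops in diverged populations. `functional-enriched`
takes impact-annotated sites (including rare ones) plus a small
common-variant backbone (15% by default), mimicking gene-centric arrays.
`random` samples polymorphic sites uniformly and is the neutral design
used for accuracy-by-MAF experiments, since it is the only scheme that
carries genuinely rare typed variants. Manifests carry both FORWARD
(ref/alt as simulated) and TOP (A allele in \{A, C\}) codings so the
harmonization path can be exercised.

Impact labels emulate effect-class annotation: HIGH labels are assigned
with weight proportional to $1/\mathrm{MAF}$ (capped at 100, MAF floored
at $10^{-3}$), reproducing the rare skew of strongly deleterious
variation; MODERATE and LOW are uniform; class counts are binomial at the
requested proportions.

## Harmonization and QC

Coordinate remapping is table-driven: mapped sites are re-coordinated and
re-sorted, strand-flagged rows have both alleles complemented, unmapped
sites and collisions are dropped with counts. Allele reconciliation
against a trusted reference classifies every record into exactly one of
OK / SWAPPED / STRAND_FLIP / SWAPPED_AND_FLIP / AMBIGUOUS_DISCARDED /
ABSENT_DISCARDED / NONBIALLELIC_DISCARDED. Ambiguity (A/T and C/G pairs,
which equal their own reverse complements) is intrinsic to the query
record and is checked first; such sites are always discarded rather than
frequency-resolved, because a strand error there is undetectable from the
alleles alone. For unambiguous pairs the four correction classes are
mutually exclusive, so no precedence rule is ever exercised (any overlap
would require an ambiguous pair). SWAPPED recodes genotypes $g \to 2-g$
and haplotype alleles $a \to 1-a$.

QC implements two preset regimes: array cohorts (site call rate $\ge$
0.90, MAF $\ge$ 0.01, sample missingness $\le$ 10%, duplicate pruning at
kinship $>$ 0.40) and sequence panels (QUAL $>$ 100, GQ $<$ 25 masked to
missing, call rate $\ge$ 0.75, per-group site missingness $\le$ 25%,
relatedness pruning at kinship $>$ 0.0625). Removal counts are attributed
to the first failing rule in the order MAF, call rate, missingness, QUAL;
a site with no usable calls has no defined MAF and is attributed to call
rate. Kinship is the KING-robust between-family estimator
$\hat\varphi = (N_{\mathrm{het,het}} - 2N_{\mathrm{opp.hom}}) /
(N_{\mathrm{het}}(i) + N_{\mathrm{het}}(j))$ over jointly non-missing
sites — 0.5 for duplicates, near 0 for unrelated pairs, invariant to
ref/alt swaps. Relatedness pruning is greedy: repeatedly drop the sample
with most over-threshold partners (ties: higher mean kinship, then input
order); the tool the thresholds come from does not specify which member
of a pair to drop, so the choice is ours and is documented here.

## LD and tagging

Pairwise LD is computed by exact haplotype counting:
$D = p_{AB} - p_A p_B$ and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, equal to
the squared Pearson correlation of the two allele-indicator vectors.
Monomorphic sites yield an undefined (flagged) result, never a zero. A
genotype-dosage correlation mode is implicit: the same formula applied to
diploid dosages is what the windowed engine's oracle uses, and on phased
data both agree.

A variant is *tagged* by an array if its best $r^2$ against any array
variant within $\pm$500 kb on the same chromosome strictly exceeds 0.8.
The window is a pair window around each variant, not a disjoint tiling —
the natural reading for an LD computation with a distance cutoff. Array
sites present in the evaluation panel tag themselves ($r^2 = 1$) and are
counted as tagged; because this convention inflates proportions for dense
arrays, the proportion excluding array sites is always reported alongside.
Per-population tagging uses only that population's haplotypes. The
windowed engine is block-structured but exact; an all-pairs brute force
reproduces it to $10^{-12}$.

LD decay curves report mean $r^2$ and pair counts per distance bin, with
undefined pairs excluded and a seeded uniform pair subsample once the pair
budget (200,000) is exceeded.

## The imputation engine

The imputation model is the haploid Li–Stephens HMM over the full
reference site grid. The hidden state is which of the $K$ reference
haplotypes is being copied; between adjacent grid sites at distance $d$ bp
the chain switches to a uniformly chosen template with probability
$1 - e^{-\rho_s d / K}$ (floored at `min_switch`); at typed sites the
observed allele matches the template with probability $1-\varepsilon$.
Defaults: $\varepsilon = 10^{-3}$, $\rho_s = 4\times10^{-8} \times N_e$
with $N_e = 100$ — all configurable, since these are modelling choices,
not measured quantities. Untyped sites emit nothing (emission 1), which
makes the full-grid formulation exact without typed-grid interpolation at
$O(KM)$ per haplotype via scaled forward–backward recursions; posteriors
are renormalized at every site and the worst deviation from 1 is carried
through to the result object (bounded by $10^{-9}$ in the test suite, and
by machine epsilon in practice).

The per-site allele posterior is
$\sum_k \gamma_t(k)\, h_k(t)$; diploid dosage is the sum over the
sample's two haplotypes, hence always in $[0, 2]$.

**Leave-one-out dosage.** At a typed site $t$ the leave-one-out posterior
uses the identity
$\gamma_t^{(-t)} \propto \big(A_t^\top \alpha_{t-1}\big)\odot \beta_t$:
the predictive forward distribution *before* the emission at $t$, times
the backward vector, which never includes the emission at $t$. This
equals re-running the whole chain with that one emission masked — the
definitional version is kept in the test suite as the oracle and the
identity is asserted exactly — but costs $O(K)$ per typed site instead of
a full re-run.

**Accuracy metrics.** At typed sites, ER² is the squared Pearson
correlation across samples between truth genotypes and leave-one-out
dosages (the squared form keeps ER² and dosage R² on one scale; the
underlying statistic is conventionally called the empirical R²). At
untyped sites, dosage R² is the squared correlation between truth and
imputed dosage. Sites with zero variance in either vector are flagged
undefined and excluded from aggregates — never zero-filled, which would
bias rare-variant summaries downward in proportion to monomorphism rather
than to imputation quality. MAF for stratification defaults to the truth
cohort but the reference-panel MAF is used in the shipped experiments,
since the reference panel is what an analyst would actually have; both
are available.

**Two-step imputation.** Sparse targets are first imputed to a dense
array grid against an intermediate panel (any sample shared with the
targets is removed from that panel first), each haplotype's posteriors
are hardened at 0.5 — ties going to the panel-major allele — and the
hardened haplotypes are imputed to the full grid against the final panel.
Hardening keeps step 2's inputs in the same alphabet as any real two-step
pipeline's; a dosage-passing variant is unnecessary here because the HMM
consumes alleles. When the sparse and dense grids coincide and the panels
match, the procedure provably reduces to one-step imputation, which the
suite asserts.

## Experiment designs

`run_experiment()` orchestrates the arms: tagging per array and
population; masked imputation (targets typed at post-QC array sites,
imputed against the full reference panel, ER²/dosage R² stratified by MAF
bin and impact class, per target group and overall); leave-one-out
cross-validation over reference samples; and the one-step/two-step
comparison against balanced single-population and combined panels (each
single-population panel at the size of the smallest group; the combined
panel of the *same total size*, half from each population, so composition
is compared at fixed panel size). Arrays whose post-QC site count falls
below `min_post_qc_variants` (default 10,000, scaled down in desk-scale
configs) are excluded from all arms and recorded with the reason. Reports
are long-format (one metric value per row) with full provenance;
`summarize_report()` computes n-weighted means. Any arm failure aborts
the run with the arm named; partial reports are never written silently.

## Problem sizes and reproducibility

The default scenario is two populations at $F = 0.2$, three cohorts
(pure taurine, pure indicine, 50:50 admixed), one 10-Mb chromosome with
20,000 sites, 100 reference and 50 target samples. The test suite and the
acceptance script run the imputation-heavy experiments on smaller slices
of the same scenario — 1,500–2,500 sites over 5–8 Mb, 50–60 reference
samples, arrays of 150–500 sites — sizes chosen so a full run completes
in minutes on a single core while keeping every directional property
(ascertainment bias, LD-decay contrast, panel-composition and two-step
gains, MAF gradient, rare-HIGH deficit) clearly resolved. Every stochastic
stage takes an explicit seed, sub-seeds are derived per stage, and
end-to-end runs are byte-identical under a fixed seed.

The accuracy-by-MAF experiments type targets from the observed haplotypes
with a 1% allele-flip error and use random-scheme arrays. Both choices
are part of the study conditions: arrays that carry only
discovery-common variants have no genuinely rare typed sites (so an
ER²-by-MAF curve over such an array is flat by construction), and with
error-free typing and truth-level phasing the copying model makes rare
haplotypes exactly matchable, which would suppress the low-MAF accuracy
deficit that real pipelines exhibit.

## What the simulator does not emulate

The generator reproduces the statistical structure the analysis needs —
differentiation, admixture, LD decay contrasts, ascertainment, rare-skewed
functional annotation, observation error — but not: genotype-calling
artefacts correlated along reads, reference-genome misassembly,
indels/multiallelics, sex chromosomes, selection, mutation-rate
heterogeneity, pedigree structure (beyond optional duplicates), or
statistical phasing error with realistic switch-error tracts (targets are
truth-phased; the observation error model flips alleles independently).
Passing the property suite therefore shows the *methods* behave correctly
and in the right direction under controlled structure; it does not
certify accuracy figures for any real cohort, whose values depend on
panel sizes, marker densities and error processes outside this model.

## Known limitations

* The engine is pure R; at $O(KM)$ per haplotype it is comfortable at
  desk scale (hundreds of haplotypes, tens of thousands of sites) but not
  at biobank scale.
* Unphased-target (diploid) imputation is out of scope; targets must be
  phased, and in the shipped experiments they are truth-phased.
* The kinship estimator and pruning reproduce one standard tool's
  statistic and thresholds; other estimators will rank borderline pairs
  differently.
* Tagging and LD use a single chromosome per run in the shipped
  scenarios; multi-chromosome site tables are supported by the data model
  but not exercised by the default experiments.
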