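# herdimpute

Genotyping-array evaluation and imputation accuracy for diverged and
admixed cattle populations.

## What problem this solves

Commercial bovine SNP arrays were ascertained largely in European taurine
breeds. Used on African indicine or taurine–indicine admixed cattle, they
capture less of the segregating variation (weaker LD between array sites
and off-array variants) and support less accurate imputation to sequence
level. Choosing an array, a reference-panel composition, and a one-step
vs two-step imputation route for such populations is therefore an
empirical question. `herdimpute` is an R package for answering it on
synthetic cohorts with controlled population structure, where truth
haplotypes are known exactly. It is aimed at quantitative/population
geneticists designing genotyping or imputation strategies for structured
livestock populations.

## What's inside

* **Cohort simulator** — Balding–Nichols site frequencies over diverged
  populations (per-population differentiation `F` from a shared ancestral
  pool; `Beta(p(1-F)/F, (1-p)(1-F)/F)` draws), a founder-seeded
  haplotype-copying model with per-bp template-switch rate `copy_rho`
  (sets the LD-decay scale per population), ancestry-mosaic admixed
  cohorts, array ascertainment schemes, rare-skewed functional impact
  labels, and QUAL/GQ/missingness/error fields so QC is exercisable.
* **LD & tagging** — exact haplotype-counting LD
  (`r² = D²/(pA(1−pA)pB(1−pB))`, `D = pAB − pA·pB`), windowed best-tag
  statistics (tagged ⇔ best `r² > 0.8` within ±500 kb), LD-decay curves.
* **Imputation** — a Li–Stephens HMM over the full reference grid
  (switch probability `1 − exp(−ρ·d/K)`, emission mismatch `ε`), with
  per-site posterior dosages, leave-one-out dosages at typed sites via a
  shared forward–backward identity, **ER²** (squared correlation of truth
  genotypes with leave-one-out dosages at typed sites), **dosage R²**
  (same at untyped sites), and two-step (sparse → dense → sequence)
  imputation with hardened intermediate haplotypes.
* **Harmonization & QC** — table-driven coordinate liftover, missing
  REF/ALT fill from array manifests (TOP/FORWARD codings), an exhaustive
  swap/strand-flip/ambiguity reconciliation truth table, site/sample
  filters (MAF, call rate, QUAL, GQ, missingness), KING-robust kinship
  and greedy relatedness pruning.
* **Experiment driver** — tagging, masked imputation, leave-one-out CV,
  and panel-composition / two-step arms, with long-format stratified
  reports and full seeded reproducibility.
* **I/O** — phased/unphased VCF 4.2 (via `vcfR` for parsing), manifest
  and coordinate-map CSV, CSV/JSON reports, dosage VCF with DS/LDS
  fields.

## Worked example

Simulate a two-population scenario (F = 0.2), design a 150-site array
ascertained in the taurine cohort, and measure how well it serves an
admixed target cohort:

```r
library(herdimpute)

model <- population_model(n_sites = 1500, chrom_length_bp = 5e6)
sim <- simulate_pools(model, n_pool_haps = 60, seed = 1)
reference <- simulate_cohort(model, sim$pools,
  spec = list(list(name = "taurine",  n = 30, alpha = c(taurine = 1, indicine = 0)),
              list(name = "indicine", n = 30, alpha = c(taurine = 0, indicine = 1))),
  seed = 2)
targets <- simulate_cohort(model, sim$pools,
  spec = list(list(name = "admixed", n = 8, alpha = c(taurine = 0.5, indicine = 0.5))),
  seed = 3)

array <- design_array(reference, "uniform-common", size = 150,
                      discovery = "taurine", seed = 4)
tag <- tagging_summary(targets$truth, array)

typed <- intersect_sites(reference$truth$sites, array)$idx_a
res <- impute_cohort(subset_sites(targets$truth, typed),
                     reference$truth, ls_params())
acc <- imputation_accuracy(res, collapse_haplotypes(targets$truth),
                           maf = site_maf(reference$truth))
```

With the seeds above this prints:

```
tagged: 14.4% of polymorphic sites (3.1% excluding array sites)
mean ER2 (typed): 0.319 over 142 sites
mean dosage R2 (untyped): 0.403 over 1065 sites
```

Reading: the ascertained array directly tags ~14% of the admixed
cohort's variation at r² > 0.8 (mostly by the array sites themselves —
only 3% of off-array variants are tagged at this sparse density), while
imputation against the 60-sample reference panel recovers untyped
genotypes with a mean dosage R² of 0.40 — imputation buys far more than
tagging alone at this array density. `run_experiment()` assembles the
same pieces into multi-arm, multi-array comparisons with MAF-bin and
impact-class stratification.

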