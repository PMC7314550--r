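---
title: "Methods: ultra-rare PTV burden and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultra-rare PTV burden and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical choices, and the design decisions behind
`ptvburden`.

## The scientific question

Every exome carries a small number of ultra-rare (minor allele
frequency below 10⁻⁴) protein-truncating variants (PTVs): stop gains,
frameshifts, and canonical splice donor/acceptor disruptions observed
on canonical transcripts. Because such alleles are strongly deleterious
and kept rare by purifying selection, their per-genome count ("burden")
is a candidate genetic determinant of lifespan and of healthspan (age
at first chronic disease). The package implements the burden
computation, two proportional-hazards models that estimate the burden
effect, the conversion of log-hazard effects into years, a bound on the
contribution of somatically acquired PTVs to mortality acceleration,
and gene-level constraint statistics.

## Hazard models and their assumptions

Both models assume proportional hazards with a Gompertz age profile:

$$h(t \mid x) = h_0 \, e^{\Gamma t} \, e^{x\beta},$$

with $t$ age in years, $h_0$ the baseline hazard at age 0 (per year),
$\Gamma$ the log-hazard slope (per year), and $x$ the covariates
(ultra-rare PTV count, sex, and nuisance terms such as genetic PCs and
assessment center indicators).

**Mortality (follow-up scale).** Death within a fixed follow-up window
after enrollment is analysed with a standard Cox model, `fit_cox()`,
on the follow-up clock, with age at assessment as a covariate. Under
the Gompertz profile the age coefficient estimates $\Gamma$, because
entering the window at a later age multiplies the hazard by
$e^{\Gamma \cdot \text{age}}$. Conditioning on survival to enrollment
makes this model robust to enrollment bias: the partial likelihood
never looks before the assessment.

**Morbidity (age scale).** A substantial fraction of participants have
their first chronic disease before enrollment, so the follow-up-scale
Cox model is unusable for healthspan. `fit_gompertz_ph()` instead
maximizes the full likelihood of the age at first disease (or the age
at the end of follow-up, censored):

$$\ell = \sum_i \left[ d_i(\ln h_0 + \Gamma t_i + x_i\beta)
  - \frac{h_0}{\Gamma} e^{x_i\beta}\left(e^{\Gamma t_i}-1\right)\right].$$

No left truncation is applied: the model assumes disease incidence does
not affect enrollment (reasonable when deaths during follow-up are
rare). $h_0$ is estimated jointly with $\Gamma$ and $\beta$ rather than
profiled out.

**Effect translation.** Equating log-hazard contributions, one unit of
a covariate shifts the hazard curve by $\beta/\Gamma$ years along the
age axis (`years_per_unit()`); a burden standard deviation of $s$
corresponds to $s\beta/\Gamma$ years of lifespan variability
(`burden_sd_effect()`); the hazard doubles every $\ln 2/\Gamma$ years
(`doubling_time()`). Published analyses of this design report both a
fitted age coefficient of 0.087/yr and a rounded acceleration rate of
0.093/yr and alternate between them in conversions; both are accepted
inputs, and the worked examples pair 0.093 with the lifespan effect and
0.087 with the healthspan effect, matching the printed conversions.

**Somatic accumulation.** With genome size $L$ (bp), somatic mutation
rate $R$ (per bp per year) and $\lambda$ the fraction of the genome at
which an ultra-rare PTV can arise, the expected somatic PTV burden at
age $t$ is $\lambda L R t$, contributing $\beta\lambda L R$ per year to
the log-hazard. `somatic_hazard_slope()` compares this slope to
$\Gamma$ and declares it negligible below a configurable ratio
threshold (default 10⁻²; at the defaults the ratio is about
5 × 10⁻⁵, so the verdict is insensitive to the threshold over three
orders of magnitude).

## Gene-level statistics

* `constraint_test()` builds, per gene, the 2×2 table of ultra-rare
  stop-gain/frameshift counts versus synonymous counts (gene versus
  rest of genome) and applies a two-sided Fisher exact test with
  Bonferroni adjustment. Splice-site variants are excluded upstream
  because their per-gene count scales with intron number, not with
  constraint. Synonymous counts normalize for sequencing coverage and
  gene length.
* `gene_burden_test()` splits the cohort into two equal halves by the
  ordered phenotype, counts unique carriers per gene in each half, and
  tests the imbalance against the halves' total carrier counts
  (two-sided Fisher, Benjamini–Hochberg FDR). "Unique cases" is read as
  per-individual uniqueness: an individual with two ultra-rare PTVs in
  the same gene counts once.
* `nmd_predict()` applies the 50-bp rule in spliced-transcript
  coordinates: a premature stop triggers nonsense-mediated decay iff it
  lies strictly more than 50 nt upstream of the last exon–exon
  junction; a stop exactly 50 nt upstream, or in the last exon,
  escapes. Single-exon transcripts never trigger NMD.
* `compare_gene_groups()` compares a constraint or expression metric
  between gene groups with the test used in the corresponding published
  comparison: Wilcoxon rank-sum, Student t, or Fisher (binary metrics).

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, at the study's stated operating point:

| parameter | default | origin |
|---|---|---|
| ultra-rare burden mean | 6 /genome | reported cohort mean |
| ultra-rare burden SD | 2.6 (dispersion 2.6²/6 ≈ 1.13) | reported SD; Poisson(6) would give only 2.45 |
| $\Gamma$ | 0.09 /yr | reported acceleration rate |
| $\beta$ burden, lifespan | 0.046 /mutation | reported Cox estimate |
| $\beta$ burden, healthspan | 0.014 /mutation | reported estimate |
| $\beta$ sex (M vs F), lifespan | 0.47 | reported Cox coefficient |
| $\beta$ sex, healthspan | 0.16 | reported coefficient |
| assessment age | uniform 40–70 yr | cohort age range |
| follow-up | 11 yr | study design |
| $h_0$ lifespan | 5 × 10⁻⁶ /yr | calibrated so ~2–3% of the cohort dies in follow-up (1,122/40,368 reported) |
| $h_0$ morbidity | 6 × 10⁻⁵ /yr | calibrated so ~25–30% have a first-disease event (11,704/40,368 reported) |

Event ages are drawn by inverse transform from the Gompertz-PH survival
function; $\Gamma = 0$ falls back to the exponential limit. Enrollment
requires being alive at assessment: death ages at or before the drawn
assessment age are replaced by a draw from the conditional distribution
given survival to assessment (the exact limit of rejection resampling,
and deterministic under the seed). Disease ages are generated
independently of assessment age, so events may precede enrollment, as
in the real design. Parental ages at death come from the same Gompertz
family with the child's burden entering at weight 0.5 (a Mendelian
transmission stand-in — no published generative model exists) plus an
independent burden draw, censored at the child's assessment plus a
28-year generation gap.

The variant-level table assigns variants to genes, effect categories
(including a synonymous background and non-coding classes) and MAFs
log-uniform within the four frequency bins `[0,1e-4)`, `[1e-4,1e-3)`,
`[1e-3,1e-2)`, `[1e-2,0.2)`. A configurable fraction of genes (default
10%) is kept free of ultra-rare PTVs and therefore surfaces downstream
as the iPTV set. Standalone variant tables draw carriers binomially at
each site's MAF; inside `simulate_cohort()` the ultra-rare PTV carriers
are instead assigned by distributing each individual's burden count
over the site pool (weights proportional to MAF), so the variant table
aggregates *exactly* to the burden matrix. The burden of the
non-ultra-rare bins uses arbitrary but fixed Poisson means (3, 5, 15),
since no joint distribution across bins is published.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, relatedness, population stratification (the PCs it
emits are pure noise), competing risks between death and disease,
calendar-time effects, and genotype-calling error. Tests passing on
synthetic cohorts therefore validate the estimators and the pipeline
plumbing under the model's own assumptions — not robustness to the
confounders real cohorts contain.

## Numerical choices

* **Cox fitter:** Newton–Raphson on the Efron-tied partial likelihood
  with step-halving; convergence when the gradient infinity-norm falls
  below `1e-8 * max(1, |loglik|)` (the attainable gradient norm scales
  with the summed likelihood terms), capped at 100 iterations. The
  linear predictor is mean-centered before exponentiation (the partial
  likelihood is exactly invariant). Monotone likelihoods (perfect
  separation) are detected by a diverging scaled coefficient and raised
  as errors, not returned silently. Rank-deficient or constant
  covariate matrices are rejected up front.
* **Gompertz fitter:** Newton–Raphson over $(\ln h_0, \ln\Gamma,
  \beta)$ so positivity is structural; analytic gradient; Hessian by
  central finite differences of the gradient (step `1e-5 * (1 + |θ|)`);
  step-halving; same convergence rule. Starting values: $\Gamma_0 =
  0.05$, $h_0$ at its no-covariate MLE given $\Gamma_0$, $\beta = 0$.
  Standard errors from the observed information; $h_0$ and $\Gamma$
  intervals are computed on the log scale and exponentiated. An
  `exponential` distribution option fixes $\Gamma = 0$ for the
  constant-hazard limit.
* **Ties and boundaries:** Efron's approximation for tied event times
  (accurate default; the data sources are silent on tie handling). MAF
  bins are half-open `[low, high)` so boundary values belong to the
  upper bin and the bins partition `[0, 0.2)` without gaps. Burden
  counting defaults to counting variant *sites* (het or hom = 1), since
  ultra-rare carriers are essentially never homozygous; an
  allele-dosage mode is available. With an odd cohort, the split-cohort
  burden test gives the extra individual to the first (shorter-lived)
  half after a stable sort by (phenotype, id), making the split
  deterministic.
* **p-values:** two-sided Wald throughout the hazard models (the
  reference analyses report Wald-style CIs); Fisher exact tests use
  `stats::fisher.test`; Bonferroni for the constraint scan and
  Benjamini–Hochberg for the phenotype burden scan, each following the
  convention of its analysis.

## Problem sizes used in the checks

Parameter-recovery checks run 50 replicate cohorts of n = 20,000 for
the Gompertz morbidity model and for the Cox mortality model; the
generator's log-hazard slope is verified against $\Gamma$ by binned
person-years regression at n = 10⁵; the null calibration of the
split-cohort scan uses 1,000 genes with Poisson(4,000) carriers in a
cohort of 400,000 — carriers per gene must be large for the exact-test
p-values to be effectively continuous, yet sparse in the cohort because
sampling a fixed carrier set without replacement shrinks the
split variance by a factor $1 - m/n$ relative to the conditional null
the Fisher test assumes. For the same reason, the constraint-test null
draws both the PTV and the synonymous margins multinomially from common
latent per-gene coverage weights; weighting PTVs by the *realized*
synonymous counts would remove the synonymous sampling noise and make
the exact test spuriously conservative.

## Known limitations

* The morbidity model ignores the competing risk of death; with few
  deaths inside the follow-up window the bias is small, but it is not
  zero.
* Burden effects are treated as age-constant; the somatic accumulation
  module bounds, rather than fits, a time-varying burden term.
* The UKBBN-style fit (age at death with sex and PCs only, no age
  term) differs structurally from the follow-up model; the package
  fits it with the same machinery but does not reconcile the two.
* X-chromosome analyses, weighted (CADD/SKAT-style) burden kernels,
  frailty terms and interval censoring are out of scope.
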