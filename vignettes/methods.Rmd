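---
title: "Risk-profile scores, chronicity, and prediction accuracy: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-profile scores, chronicity, and prediction accuracy: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoprs)
```

## The scientific problem

Genomic risk profile scores (GRPS, a synonym of polygenic risk scores)
summarise a person's inherited liability to a disorder as a weighted sum of
risk-allele dosages, with weights taken from an independent discovery GWAS.
For schizophrenia-like disorders two questions about such scores matter
beyond overall case-control discrimination:

1. **Chronicity.** Among cases, does a higher score predict a more chronic
   illness course — more health-care contacts, more inpatient admissions,
   longer cumulative hospitalization?
2. **Sample composition.** If the case series is enriched for chronic
   patients, or analysed separately by sex, does the variance the score
   explains in case-control status change?

`chronoprs` implements this full analysis as a reusable, seeded pipeline.
Because individual-level register and genotype data of this kind cannot be
shared, the package ships a calibrated synthetic-data generator that plays
the role of the discovery GWAS and the ascertained target cohort; every
statistical claim the package makes is demonstrated on data from that
generator.

## The generative model

### Discovery panel

`simulate_summary_stats()` draws `n_variants` unlinked variants with allele
frequencies $p_j$ uniform on `maf_range`. True effects on the
standardized-genotype scale are
$\beta_j \sim N(0, h^2/M)$, so the panel's total liability variance is
`h2_liability`. The reported (estimated) per-allele effect adds estimation
noise with the standard error of a one-SNP regression in a discovery sample
of `n_discovery` individuals, $\mathrm{se}_j = 1/\sqrt{2 p_j (1-p_j)\,
n_\mathrm{disc}}$, and the p-value is the two-sided Wald p. Variants are
independent: the panel emulates a clumped GWAS, and no LD, imputation
uncertainty, or population-structure confounding is simulated.

### Liability, sex, and ascertainment

Liability is $L = G + E$ with $G = \sum_j \beta_j z_j$ on standardized
dosages and $E \sim N(0, 1 - h^2)$, except that the female environmental
variance is multiplied by `female_noise_inflation` ($\geq 1$). An individual
is a case when $L$ exceeds the upper-`prevalence` quantile **of their own
sex's liability distribution**. Making the threshold sex-specific was a
genuinely open design choice: a single common threshold would let the
inflated female variance raise the female prevalence, conflating two
mechanisms. With per-sex thresholds each sex's case fraction equals
`prevalence` (testable per stratum), and the female prediction gap arises
purely from variance dilution — the genetic share of female liability
variance is $h^2 / (h^2 + (1-h^2)\,\kappa)$, which falls below the male
share $h^2$ whenever the inflation $\kappa > 1$.

The ascertained cohort is produced by rejection sampling per sex cell until
the configured case/control counts are reached, under a hard draw budget
(default $10^7$ individuals) with an explicit error when exhausted.
Rejection sampling was preferred over importance sampling for transparency:
every retained individual has an ordinary simulated genotype vector.

### Chronicity markers

For cases only, the four register-style markers are generated from
log-linear links on the population-standardized genetic value $g$:

* counts (total, inpatient, outpatient contacts): negative binomial with
  $\log \mu = a_x + b_x g\,(+\,\text{sex shift})$ and per-marker dispersion;
* cumulative hospitalization length (days): log-normal likewise.

Total contacts are **not** constrained to equal inpatient plus outpatient
contacts; the published marginals this generator is calibrated to are not
additive (total 27.38 vs 11.51 + 18.85), so each marker is drawn from its
own link. Outpatient contacts have $b = 0$ by default — they are
prearranged check-ups rather than severity-driven events, and decoupling
them genetically reproduces the known null for that marker. This is a
default, not hard-coded.

Default slopes $b = 0.25$ for the three coupled markers were fixed a
priori from effect-size arithmetic: a standardized case-only regression
coefficient near 0.08 for a score correlating roughly 0.3 with the true
genetic value implies a latent slope of about $0.08 / 0.3 \approx 0.25$ per
SD of genetic value. Intercepts and dispersions were then calibrated once,
numerically, so a default cohort reproduces the published case means and
sds (27.38/30.77 total, 11.51/13.72 inpatient, 18.85/25.44 outpatient,
641.84/932.83 days; male mean length 712.69 via the `hosp_length_male` log
shift, female excess outpatient contacts via `n_outpatient_female`), and
frozen. Follow-up (22 y, sd 8.22) and age at diagnosis (28 y — age 50 at
sampling minus 22 years of follow-up) are truncated normals.

Default sizes are the published ones: 2,457 cases (897 F / 1,560 M) and
2,702 controls (1,286 F / 1,416 M). `female_noise_inflation = 2` is the
default because it produces a male/female incremental-NkR² ratio of the
observed order (about 0.17 vs 0.12) at this sample size.

The panel defaults (`n_variants = 1500`, `n_discovery = 6000`,
`h2_liability = 0.25`) make the score capture roughly half of the panel
variance, i.e. $\sim 0.12$ of liability — chosen so the observed NkR²
magnitudes are of the right order at desk scale. `h2_liability` is the
variance attributable to the simulated panel (a SNP-heritability-like
quantity), not twin heritability.

## Scoring

`align_variants()` matches variants by id and harmonizes alleles: `keep`
when the counted allele is the effect allele, `flip` (dosage $\to 2-g$) when
the pair is swapped, `drop` with a logged reason otherwise. Palindromic A/T
and C/G variants are dropped by default (`drop_ambiguous = TRUE`) since
without strand information they cannot be oriented; the pipeline's own
simulated data are on the discovery strand by construction, so
`run_pipeline()` keeps them. `compute_grps()` applies a **strict** threshold
(`p < PT`; 0.05 primary, with 0.1 and 0.01 also reported), imputes missing
dosages as twice the target-sample allele frequency (no external reference
panel needed), and forms $s_i = \sum_j \hat\beta_j g_{ij}$. Scores are
z-scored within the analysis sample before modelling so coefficients are
per score SD; whether to standardize was open, and the package does so
because effect sizes of the observed magnitude (~0.07–0.10) are only
interpretable on that scale.

## Case-only chronicity models

"Admissions weighted by follow-up time" is operationalized as an annualized
rate: the default outcome is $z(\log(1 + \text{marker}/\text{follow-up
years}))$ across cases. The `log1p` step tames the heavy right tail (all
four markers have sd > mean); the transform is switchable
(`transform = "raw_z"`). Alternatives — an offset count model or weighted
least squares — were deliberately excluded from the analysis arm to keep the
estimand a linear coefficient.

`fit_case_only()` is OLS on GRPS + PCs + batch indicators (first batch
reference) + age at diagnosis, plus sex when unstratified; stratified fits
drop the sex term. `fit_interaction()` adds a GRPS×sex product. Two-sided
p-values throughout. Rank-deficient designs error naming the aliased
columns rather than silently dropping them.

## Prediction accuracy, enrichment, and the sex gap

`nagelkerke_r2()` rescales Cox–Snell $R^2 = 1 - \exp(2(\ell_0-\ell_1)/n)$
by its maximum $1 - \exp(2\ell_0/n)$. `incremental_nkr2()` fits logistic
`case ~ PCs` and `case ~ PCs + GRPS` by maximum likelihood on the selected
cases plus **all** controls and reports the difference of their NkR² values
against the intercept-only model. The incremental (difference) form is the
primary quantity; the full-model value is also emitted since published
tables do not always say which they print. The case-control null model uses
PCs only; batch can be added via `include_batch` (default off).

The four enrichment filters keep cases at or above the conventional
above-average thresholds — 27 total contacts, 12 inpatient contacts, 19
outpatient contacts, 640 hospitalization days — **one at a time**, giving
four subsamples rather than one union. `permutation_enrichment_test()`
draws `n_perm` uniform case subsets matched to the filtered count and uses
the add-one empirical p-value $(1 + \#\{\text{perm} \geq \text{obs}\}) /
(n_\text{perm} + 1)$, bounded below by $1/(n_\text{perm}+1)$. Enrichment is
one-sided (improvement) by default and switchable.

`sex_prediction_gap_test()` computes the male-minus-female difference in
incremental NkR², each sex with its own cases and controls, and permutes
sex labels across all individuals for a two-sided p. How the published
male/female permutation p was computed is not documented anywhere we know
of; this label-permutation scheme is a reasoned reconstruction and is
flagged as such.

## Numerical choices and degenerate inputs

* Logistic fits use IRLS (up to 100 iterations). Complete or quasi-complete
  separation — expected in tiny permuted subsets — is detected from fitted
  probabilities within $10^{-8}$ of 0/1 and reported once per session as a
  warning; the log-likelihood plateau is still usable for NkR². True
  non-convergence without separation is a hard error.
* A score that is constant in the analysis sample is pivoted out by the
  fitter and contributes an incremental NkR² of exactly 0.
* Zero-variance outcomes, zero-variance scores, empty aligned panels,
  thresholds selecting no variants, and empty filtered case sets are all
  explicit typed errors, never silent zeros.
* All randomness flows from one master seed through deterministic per-stage
  sub-seeds (sumstats / genotypes / phenotypes / covariates / each
  permutation test), so enlarging the variant panel does not shift the
  phenotype stream, and identical (config, seed) reruns are byte-identical
  down to the written report files.

## What the generator does and does not emulate

It emulates: polygenic liability with a realistic score-liability
correlation; case-control ascertainment with fixed sex composition;
severity-coupled, overdispersed, right-skewed chronicity markers with the
published marginals; sex-differential marker levels; a female-specific
non-genetic liability component; pure-noise PCs and batch. It does **not**
emulate LD, population stratification (PCs carry no confounding signal by
design — a confounded mode is out of scope), imputation error, diagnostic
misclassification, or time-varying admission processes. Passing tests
therefore demonstrate the statistical machinery and the qualitative
enrichment/sex-gap phenomena under these assumptions, not numeric
reproduction of coefficients estimated on any real cohort — those data are
not public, and no such reproduction is claimed.

## Problem sizes used in the shipped simulation studies

The test suite exercises replicate studies at sizes chosen as the smallest
that give clean statistical resolution: type-I calibration uses 200
replicate cohorts of 300+300 with 200 permutations; enrichment-direction
recovery uses 50 replicates of 1,200+1,200 (at 300+300 the subsample NkR²
difference is too noisy for direction calls); the sex-gap power study uses
50 replicates at the full 2,457+2,702 composition with a 200-variant panel,
where the gap test rejects essentially always under inflation 2 and at the
nominal rate under inflation 1. The calibration check runs one full-size
default cohort.

## Known limitations

* Negative-binomial and log-normal links are convenient severity models,
  not fitted to any admission-process data.
* The permutation scheme conditions on the observed sex composition and
  case count; it does not model uncertainty in ascertainment itself.
* With very small strata the NkR² difference is noisy and separation-limit
  likelihoods make the permutation distribution slightly conservative.
* No AUC or liability-scale $R^2$ conversions are provided, and no
  count-model (Poisson/negative-binomial) analysis arm — the scope is the
  linear-model analysis described above.
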