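---
title: "Admixture mapping of a zero-inflated trait in admixed sibship cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture mapping of a zero-inflated trait in admixed sibship cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The method

Admixture mapping exploits the mosaic genomes of recently admixed
populations. In African Americans, each chromosome is a patchwork of
African- and European-derived segments a few to tens of megabases long.
If a trait differs in prevalence or severity between the ancestral
populations — coronary artery calcification (CAC) is less prevalent and
less severe in people of African descent — then loci influencing the
trait should show an association between the trait and the *local
ancestry* at that position: the number of African-derived alleles (0, 1
or 2) an individual carries there.

`admixscan` implements the full analysis path for a two-way admixed
sibship cohort, together with a simulator that generates cohorts with
the same statistical structure, so every stage is testable without any
external data.

### Mixed-model ancestry scan

The association test at marker $j$ is the linear mixed model

$$ y = \mu + \beta_j a_j + u + \varepsilon, \qquad
   u \sim N(0,\ \sigma_g^2\, 2\Phi), \quad
   \varepsilon \sim N(0,\ \sigma_e^2 I), $$

where $y$ is the transformed phenotype, $a_j$ the vector of local
African-allele counts, and $\Phi$ the kinship matrix computed from the
pedigree by the classical recursion
($\phi_{ii} = \tfrac12(1+\phi_{f_i m_i})$,
$\phi_{ij} = \tfrac12(\phi_{f_i j}+\phi_{m_i j})$). $\beta_j$ is tested
with a Wald statistic against a standard-normal reference.

Numerically the model is fitted on the eigenbasis of $2\Phi$: writing
$V = \sigma^2\{h\,2\Phi + (1-h)I\}$ with
$h = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$, rotation by the eigenvectors
diagonalises $V$, REML in $h$ becomes a one-dimensional optimisation,
and each per-marker fit is a weighted least-squares regression. The
variance ratio $h$ is estimated once under the null model and held fixed
across markers (a score/Wald hybrid); the residual scale is re-estimated
per marker, so when $2\Phi = I$ the scan reduces *exactly* to ordinary
least squares — a property the test suite checks to machine precision.
Full per-marker REML is available via `reml_per_marker = TRUE`; at
desk scale it changes third digits, not conclusions. The boundary
$\sigma_g^2 = 0$ is evaluated explicitly, so the REML optimum is never
worse than the no-polygenic fit.

Age and sex are deliberately **not** covariates in the scan: they are
absorbed by the stratified phenotype transform described next (a
configurable choice — pass `covariates` to `scan_local_ancestry()` to
add them back).

### Phenotype transform

Raw CAC is non-negative, zero-inflated (roughly half the cohort scores
zero) and extremely right-skewed, so the scan operates on a Blom
rank-based inverse-normal score computed *within sex-by-age-group
strata*: the value with tie-averaged rank $r$ among $n$ maps to
$\Phi^{-1}\{(r - 3/8)/(n + 1/4)\}$. Tie handling matters enormously
here — all zeros in a stratum share one (negative) transformed value.
Age groups default to the conventional CAC-reporting decades
(<30, 30–39, 40–49, 50–59, ≥60), configurable; bins with fewer than 5
values are merged with their lower neighbour so sparse tails of the age
distribution cannot create degenerate strata. Missing scores are
excluded before ranking.

### Effective number of tests

Local-ancestry tests are strongly correlated along a chromosome, so a
marker-count Bonferroni correction would be absurd. Following the
spectral-density approach, each individual's ancestry series along the
genetic map is treated as a stationary series: an AR($p$) model is
fitted by Yule–Walker (order by AIC, $p \le 20$), the spectral density
at frequency zero is $S(0) = \hat\sigma_\varepsilon^2 / (1 -
\sum_k \hat\phi_k)^2$, and the effective sample size is
$\mathrm{ESS} = n\, s^2 / S(0)$, clipped to $[1, n]$. The $2\pi$
convention cancels between $s^2$ and $S(0)$, so the ratio is
convention-free. Per chromosome, the per-individual ESS values are
aggregated by the median (the aggregation is not dictated by the
method's sources; the mean is available via `agg = "mean"`, and a
pooled cohort-mean-series mode via `mode = "pooled"`); chromosome
values are summed, and the genome-wide threshold is
$\alpha / M_\mathrm{eff}$. With the published count of 245 effective
ancestry blocks this gives:

```{r}
genomewide_threshold(245, alpha = 0.05)
```

A caveat the test suite quantifies: compared with a phenotype-permutation
family-wise threshold, the spectral ESS is well calibrated (within a
factor of two) when marker spacing is an appreciable fraction of the
ancestry block length (≳0.1 Morgan in our simulations), but becomes
anti-conservative on very dense maps, where extreme-value behaviour
decorrelates faster than the long-run variance suggests. The permutation
cross-check in `test-meff.R` runs in the calibrated regime.

### Regions, informative markers, regional thresholds

Markers with $p < 10^{-3}$ are carried forward; peaks falling inside an
already-claimed envelope collapse to the single smallest-p lead. Each
lead's *target region* is the maximal contiguous run of markers whose
$-\log_{10}(p)$ stays within 2.0 units of the lead's; the outermost
qualifying markers are the bounds and their p-values the boundary
p-values (reported lower-coordinate first — the pairing of boundary
p-values with physical ends is otherwise ambiguous). An
exhaustive-window oracle in the test suite confirms the walking
algorithm on random profiles.

Inside a region, a SNP is *ancestry-informative* when
$\delta = |f_\mathrm{AFR} - f_\mathrm{EUR}| > 0.2$. The comparison is
strict by default (`strict = FALSE` gives $\ge$; published usage is
ambiguous at exactly 0.20, so both are exposed); deltas are rounded to
nine decimals first so a printed 0.20 sits on the boundary rather than a
float epsilon below it. The region-specific lookup threshold is
$\alpha / (n_{\delta>0.2} \times n_\mathrm{regions})$ — Bonferroni over
the informative SNPs looked up, further divided by the number of
regions considered:

```{r}
regional_threshold(c(1838, 416, 1479, 1215), n_regions = 4)
```

External association results (e.g. a published meta-analysis) are
ingested as a plain table (`snp, chrom, bp, p, effect, se`); SNPs below
the regional threshold are flagged as candidate drivers, those within
one order of magnitude as suggestive.

### Conditional adjustment

To ask whether a candidate SNP accounts for a region's ancestry signal,
the phenotype is regressed on the local ancestry at the candidate (or
its best LD proxy, $r^2 > 0.8$ within 500 kb, composite genotype
correlation) with the kinship random effect retained, and the marginal
residuals $y - X\hat\beta$ are re-scanned over the region. Retaining
the kinship term in stage 1 is our choice where the method's sources
are silent: residuals from a fixed-effects-only fit would re-introduce
family structure inconsistently between the stages
(`keep_kinship_stage1 = FALSE` provides that mode for sensitivity
analysis). Conditioning on the lead itself drives its own p-value to
≈1 (the residuals are orthogonal to it in the GLS metric); conditioning
on an uncorrelated chromosome leaves the signal unchanged — both limits
are exercised in the tests. The conditioning covariate is *ancestry*,
not genotype, mirroring the adjustment the scan itself tests; genotype
conditioning is available as an option.

## The simulator

`simulate_cohort()` generates the study conditions end to end:

* **Ancestry tracks** follow a hybrid-isolation Markov model: crossover
  events along the genetic map as a Poisson process at rate $g$ per
  Morgan ($g = 6$ by default, the conventional age of African American
  admixture), with ancestry redrawn African with probability $q$ at
  each event. $q$ is drawn per founder from a Beta with mean 0.85 and
  SD 0.075, matching the reported cohort mean (~85%) and per-sex SDs
  (~0.07–0.08). Offspring haplotypes are produced by meiosis (Haldane,
  one crossover per Morgan), so siblings share ancestry through
  transmission — the expected switch count per haplotype,
  $gL \cdot 2q(1-q)$, is verified against an event-level oracle.
* **Families** are sibships: 211 families of 2–4 siblings (expected
  total ≈622 before QC, settable exactly via `total_sibs`), with two
  simulated but un-phenotyped founder parents per family, excluded from
  the analysis matrices by default. The cohort is about one-third male.
* **Genotypes** are drawn per haplotype from the allele frequency of
  the local ancestral population, giving realistic admixture LD for the
  proxy search; a configurable fraction of markers (default 0.4) has
  $\delta > 0.2$ so the informativeness filter has material to work on.
* **Phenotypes** arise from a latent-threshold hurdle: latent = age
  effect + sex effect + causal ancestry effects + polygenic family
  effect (covariance $\sigma_g^2 2\Phi$) + noise; scores below the
  `zero_rate` quantile (default 0.47, reproducing ~38% zeros in men and
  ~51% in women) are zero, and the excess above it maps through
  a scaled `expm1`, giving the zero-inflated right skew of Agatston-like
  scores. A *negative* causal $\beta$ encodes the protective direction
  of African ancestry. Residual and polygenic scales default to a
  within-stratum latent SD near 1, so a configured $\beta$ is
  interpretable on the transformed scale.

Two QC-exercise knobs (`n_missing_pheno`, `n_low_afr`) inject missing
phenotypes and essentially-European individuals; the low-ancestry
override is rejection-sampled so the realised global proportion is
genuinely below the 1% exclusion boundary. With 622 siblings, 5 missing
phenotypes and 6 low-ancestry individuals the sample filter reproduces
the documented 622 → 611 accounting exactly.

What the simulator does **not** emulate: coalescent-exact haplotype
structure (background LD within ancestral populations is absent, so
proxy r² comes from admixture LD only), continuous gene flow,
genotyping error and Mendelian inconsistencies (simulated pedigrees are
error-free, so relationship QC is out of scope), the X chromosome, and
local-ancestry *inference* error — ancestry is observed truth here,
whereas real cohorts estimate it from haplotype panels. Passing tests
therefore validate the statistics given correct local ancestry, not
robustness to ancestry miscalls. One documented tension in the real
cohort — a mean age near 30 alongside appreciable CAC prevalence — is
not resolved; age and zero-rate are independent knobs, and we keep both
at their reported values.

## Numerical and design notes

* Global ancestry is reported as a *proportion* (African alleles /
  2·markers), so "85%" and the "<1%" filter are directly interpretable;
  the per-marker reading (÷ markers, a 0–2 scale) is available via
  `scale = "per_marker"`.
* Dual-reason exclusions (missing phenotype *and* low ancestry) are
  logged once, as missing-phenotype — matching the conventional
  ordering of the two filters. Marker-filter precedence is call rate,
  then MAF, then HWE; the published "call rate < 0.99%" is read as the
  evident typo for a 0.99 proportion.
* HWE uses the 1-df chi-square goodness-of-fit test; at a $10^{-6}$
  threshold on common variants the asymptotic test is adequate (an
  exact test would matter only for rare variants, which the MAF filter
  removes first).
* The quartile contrast at carried-forward sites is a pooled-variance
  two-sample t-test of African-allele counts between the lowest and
  highest raw-CAC quartiles; with more than 25% zeros the lower group
  is the zero scores (the only stable quartile definition under such
  ties). Counts and proportions give the identical t; both group means
  are reported.
* Degenerate inputs are flagged, not fatal, wherever a scan should
  continue: constant ancestry columns are skipped with a note,
  constant series are skipped per individual in the Meff estimator
  (with a count), a lead at a chromosome edge yields a one-sided,
  flagged region.
* All randomness flows from a single integer seed; a cohort, a
  pipeline run and its output files are bit-reproducible given the
  seed and configuration (the run manifest records both).

## Problem sizes used in the checks

The packaged tests run cohorts of 25–211 families (up to ~620
siblings), 2–4 chromosomes of 10–80 markers, 50-replicate recovery and
attenuation experiments, 300 phenotype permutations for the family-wise
oracle, and series of length 5,000 for the AR(1) closed-form checks —
sizes chosen so each statistical property is measured with comfortable
Monte-Carlo margin while the whole suite stays interactive.

## Known limitations

* The spectral Meff is anti-conservative on very dense maps (see
  above); for final thresholds on dense data, permutation is the safer
  arbiter and the pipeline makes that comparison easy.
* The Wald test uses a normal reference; at a few hundred individuals
  its far-tail p-values are mildly anti-conservative relative to a t
  reference. This cancels in before/after comparisons but is visible
  when comparing extreme empirical quantiles with theory.
* Effect sizes configured on the latent scale are attenuated by the
  hurdle + rank transform (by roughly 20–25% at the default zero rate);
  recovery tests quantify this rather than hide it.
* `find_proxy()` computes r² from typed genotypes, so a truly untyped
  index SNP needs its dosages supplied (`index_genotypes`) or an
  external LD source; querying LD databases is out of scope.
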