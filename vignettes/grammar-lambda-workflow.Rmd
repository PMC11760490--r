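---
title: "Two-stage GWAS with genomic-control recalibration for backcross families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage GWAS with genomic-control recalibration for backcross families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grlgwas)
```

## The model and the two-stage procedure

For a quantitative trait measured on n related individuals genotyped at M
SNPs, the single-SNP mixed model is

$$ y = z a + g + e, \qquad
   g \sim N(0, K\sigma^2_g), \quad e \sim N(0, I\sigma^2_e), $$

where $z$ holds additive genotype codes (0/1/2 copies of the reference
allele), $a$ is the SNP effect, and $K$ is the genomic relationship matrix
(VanRaden method 1: centered cross-product scaled by $2\sum_j p_j(1-p_j)$).
Fitting this model exactly for every SNP costs one generalized least squares
solve per marker. The GRAMMAR family of methods instead fits the **null**
polygenic model $y = g + e$ once, forms GBLUP breeding values $\hat g$ and
residuals $y - \hat g$, and tests each SNP by simple regression of the
residuals on its codes. The per-SNP statistic is the normal score
$U = \hat a / se(\hat a)$, squared into a 1-df chi-squared.

Because $\hat g$ is a *shrunken predictor built from all markers*, it absorbs
part of every QTN effect, so the residual-scan statistics are systematically
**deflated**: under a polygenic null their genome-wide mean falls below 1
(around 0.7 in the simulations below). The recalibration used here estimates
the deflation factor $\lambda$ as the mean (default; optionally the median
scaled by the 1-df chi-squared median 0.4549364) of the genome-wide
chi-squared statistics and divides every statistic by it:
$\chi^2_c = \chi^2 / \lambda$, referred to the 1-df chi-squared distribution.
With the mean method the corrected statistics average exactly 1 by
construction, which is also what the genomic-control summary table reports.

Significance uses the Bonferroni threshold $\alpha / M$; with
$\alpha = 0.05$ and the study array's 184,507 retained SNPs this is
$2.71\times10^{-7}$ ($-\log_{10} = 6.57$). Per-QTN variance explained is
$R^2 = \hat a^2 \mathrm{var}(z) / \mathrm{var}(y)$ with $y$ the adjusted
phenotype the scan analysed.

A second pass (the *joint* analysis) pools suggestive candidates (corrected
$p \le 10^{-4}$, collinearity-pruned at squared genotype correlation 0.99)
and runs backward elimination on the multiple regression of the residuals on
all candidate columns: at each step every candidate's partial Wald
chi-squared is divided by the *same* per-trait $\lambda$, and the candidate
with the largest corrected partial p is dropped (ties broken toward the
larger genome index, so the procedure is order-independent) until all
remaining candidates pass the Bonferroni level. The reported QTN table is the
union of marginal calls and joint-only additions, each row labelled by its
`source`.

## Preprocessing

Marker QC applies three marginal rules — MAF $\ge$ 0.05, call rate $\ge$
0.95, and genotype-code variance strictly $> 0.09$ — plus an optional
Mendelian-consistency rule when parental genotypes are available. The
variance rule exists because an (almost) all-heterozygous marker has MAF 0.5
yet zero additive contrast; it cannot be rescued by the frequency rule. MAF
and variance are computed on non-missing codes only, missingness being the
call-rate rule's job; the retained set is therefore invariant to the order
of rule application.

Phenotypes are adjusted *before* association: each head trait is regressed
on the cube root of body weight by least squares **within each family**, and
the residuals (which carry neither allometric body-weight signal nor
between-family means) are the $y$ of all models. Families of size 1 or with
a constant covariate fall back to family-mean centering with a warning.
Missing adjusted phenotypes are imputed with the mean of the observed
values; missing genotype codes are mean-imputed per SNP (preserving allele
frequency) before the GRM and the scan.

The null model's only fixed effect is an intercept: family structure is
handled by the within-family adjustment and by $K$, and no family covariate
is carried into the association stage.

## REML: numerical choices

The null fit eigendecomposes $K$ once ($K = UDU^\top$, eigenvalues clamped
at 0) and profiles the restricted likelihood down to a one-dimensional
function of $\log\delta$, $\delta = \sigma^2_g/\sigma^2_e$, maximised by
Brent search on $\log\delta \in [\log 10^{-6}, \log 10^{6}]$ with tolerance
$10^{-8}$; $\sigma^2_e$ and the intercept are profiled out analytically.
This is exact for the one-component model and costs a single $O(n^3)$
decomposition, reused across traits. The $\sigma^2_g = 0$ boundary is
evaluated explicitly; a boundary solution is a valid fit with zero breeding
values, flagged `boundary = TRUE`. GBLUP values use the same
decomposition: $\hat g = U\,\mathrm{diag}\{\sigma^2_g d_i/(\sigma^2_g d_i +
\sigma^2_e)\}\,U^\top(y - \hat\mu)$.

An exact per-SNP mixed-model scan (`exact_lmm_scan`, GLS Wald test with
variance components fixed from the null or refitted per SNP) ships as an
internal oracle for cross-checking on small problems; it is capped at
n = 1000 by design and is not the production scan.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the study design the package targets: nine
backcross families totalling 556 individuals (female purebred dams, one
shared F1 hybrid sire per family), three correlated head-size traits
(residual correlation 0.5) confounded with log-normal body weight
(meanlog = log 400 g, sdlog = 0.25, effect 0.2 units per cube-root gram) and
family shifts (SD 0.5 units). Variance components are scaled so
$\sigma^2_g + \sigma^2_e = 1$ with $h^2$ = 0.5 by default. The default
marker count (5,000) is a working scale for simulation studies; the array
scale is available by setting `n_snps`.

Genotypes follow the backcross law. A fraction of SNPs (default 0.3) is
fixed-divergent between the parental lines: every dam is AA, every sire AB,
so offspring are AA/AB with probability 1/2 each, *independently within and
between families*. Non-divergent SNPs draw the four parental alleles per
family from the channel-line frequency (uniform on [0.1, 0.5] by default)
and transmit Mendelianly, which creates within-family relatedness and
between-family frequency contrasts. The 0.3 divergence fraction is a design
choice, not an estimate: the divergence rate of the real array is not
published. Body weight is genotype-independent by default
(`bw_polygenic_cor` can correlate it with the polygenic value to stress-test
the adjustment).

Deliberately **not** modelled: linkage/LD (markers are independent given
parents — the analysis uses no LD structure), sex chromosomes, genotyping
error, deeper pedigrees, and any genotype-missingness mechanism beyond
completely-at-random. Two consequences matter when reading test results on
real data. First, with unlinked markers the realized-kinship variation
within families is small, so after within-family phenotype adjustment the
REML fit often lands on the $\sigma^2_g = 0$ boundary — the GBLUP stage is
then inert and the scan's calibration rests entirely on $\lambda$; on a real
array with LD, within-family kinship varies more and the null fit is
informative. Second, the sharp divergent/non-divergent dichotomy makes
per-SNP deflation **bimodal**: divergent markers carry no family structure
and are barely absorbed by GBLUP (mean raw $\chi^2 \approx 0.94$ in the null
calibration experiment), non-divergent markers are strongly absorbed
($\approx 0.55$). A single genome-wide $\lambda$ cannot calibrate both
classes at once, which the calibration experiment shows as a mild residual
excess of the corrected type-I error at $\alpha = 0.05$ (about 0.053) and a
Spearman rank agreement with the exact mixed-model scan of about 0.985
(0.99+ under a homogeneous marker design). This is a real, documented
limitation of scalar genomic control under strongly bimodal marker classes,
not of the implementation; real arrays with a continuous frequency spectrum
sit much closer to the homogeneous case.

The generating truth (planted effects, variance components, family effects)
travels in a separate `truth` element that no analysis function reads.

## Experiment sizes used by the tests and acceptance script

Chosen as the package's working scales: null calibration, 50 datasets of
n = 500, M = 5,000, $h^2 = 0.5$; oracle agreement, 10 datasets of n = 200,
M = 500 with two planted QTNs; heritability recovery, 100 datasets of
n = 300, M = 1,000; effect/R² recovery, 200 datasets of n = 100 on a
divergent-only design (where $\mathrm{var}(z) = 1/4$ and the GRM diagonal is
exactly 2/3, so the generating $R^2$ has a closed form; the squared-estimate
bias $E[\hat a^2] = a^2 + \mathrm{Var}(\hat a)$ is removed before
comparison); joint retention, 100 datasets of n = 300 with two orthogonal
QTNs of 2 phenotype-SD units per allele — large enough that each QTN's
marginal power exceeds 0.99, the stated precondition of that experiment.
Power experiments plant effects at markers that segregate within families,
because the within-family adjustment removes between-family genotype
contrasts: a marker homozygous in every parent pair carries no testable
signal afterwards.

## Other fixed conventions

Candidate-gene windows are closed intervals: a gene overlapping
$[pos - 150{,}000, pos + 150{,}000]$ (inclusive at both edges) is in the
window. Gene coordinates are 1-based inclusive; BED input is converted from
0-based half-open on read, and `chr` prefixes are stripped when matching
chromosome names. QQ plots use the $i/(M+1)$ expected-quantile convention.
$\lambda$ is estimated once per trait from all scanned SNPs, with no
exclusion of candidate regions and no re-estimation after the joint step.
The Bonferroni denominator is always the genome-wide tested-SNP count, also
for the joint analysis's partial tests. Constant genotype columns yield
flagged `NA` records rather than errors; all-missing SNPs fail call-rate QC
rather than erroring. All randomness flows from the configuration seed;
equal configurations give bit-identical datasets and byte-identical pipeline
output tables.
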