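---
title: "Detecting sex-specific transmission distortion in trio cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-specific transmission distortion in trio cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodistort)
```

## The problem and the model

Transmission distortion (TD) is non-Mendelian transmission: a heterozygous
parent passes one of its two alleles to offspring with probability
different from 1/2. When the distortion depends on the *sex of the
offspring* — one allele preferentially reaching sons, the other reaching
daughters — the locus behaves like a target of sexually antagonistic
selection acting between fertilization and birth, or of sex-biased meiotic
drive. Parent-offspring trio cohorts allow this to be observed directly:
each informative meiosis (a heterozygous parent on the autosomes, a
heterozygous mother on the X) is a Bernoulli trial whose outcome is read
off the child's genotype.

`triodistort` reduces each biallelic SNP to sex-stratified transmission
counts $(k_m, n_m, k_f, n_f)$ — $k$ transmissions of the alternative ("B")
allele out of $n$ informative meioses, to sons and daughters — and fits
three nested models for the per-meiosis B-transmission probability
$\tfrac12 + \varepsilon$:

* **M0** (Mendelian): $\varepsilon = 0$;
* **M1** (uniform TD): one free $\varepsilon \in [-\tfrac12, \tfrac12]$
  shared by both offspring sexes;
* **M2** (sex-specific TD): free $\varepsilon_m$ (sons) and
  $\varepsilon_f$ (daughters).

The log-likelihood is a sum of Bernoulli terms,
$\ell = \sum_{s \in \{m,f\}} k_s \log(\tfrac12+\varepsilon_s) +
(n_s - k_s)\log(\tfrac12-\varepsilon_s)$, with $0\log 0 \equiv 0$. The
het×het multinomial coefficient is a data-only constant and is omitted: it
cancels in every MLE, profile interval and likelihood-ratio test, which
are the only quantities the package reports (absolute log-likelihoods are
therefore defined up to a data-dependent constant). MLEs are closed-form
binomial proportions; deviances $d = 2(\ell_{big} - \ell_{small})$ are
referred to $\chi^2$ distributions with 1 df (M1 vs M0, M2 vs M1) or 2 df
(M2 vs M0). Boundary MLEs ($|\hat\varepsilon| = \tfrac12$) are allowed and
tested with the same plain $\chi^2$ reference — no $\tfrac12\chi^2$
mixture — keeping the analytic treatment uniform across sites. 95%
profile intervals are the set
$\{\varepsilon : \ell(\varepsilon) \ge \ell(\hat\varepsilon) -
q_{\chi^2_1}(0.95)/2\}$, solved by bisection to $10^{-6}$ and clipped to
$[-\tfrac12, \tfrac12]$.

```{r}
fit_site(list(k_m = 90, n_m = 120, k_f = 30, n_f = 120))[
  , c("eps_m", "eps_f", "d20", "p20")]
```

## From VCF to counts

`trio_counts()` applies the site filters before counting:

* biallelic SNPs only; optionally only FILTER `PASS`/`.` records;
* X pseudoautosomal regions excluded (defaults are the hg19 intervals
  chrX:60001–2699520 and chrX:154931044–155260560; override
  `par_intervals` for other builds);
* X sites with any heterozygous male genotype dropped (a hemizygous locus
  showing male heterozygosity indicates a genotyping or mapping problem);
* trio genotype configurations impossible under Mendelian rules are
  detected per trio; a site with `max_mendel_errors` (default 2) or more
  such trios is dropped, and at surviving sites the error trio's *child*
  genotype is set missing — attribution of the error to a specific trio
  member is impossible, and masking the child removes the trio from
  counting without discarding the parents' information elsewhere;
* sites with fewer than 150 (autosomes) / 75 (X) informative trios are
  dropped. These defaults reflect the power analysis below: ~150
  informative trios is where the sex-specific LRT reaches useful power
  for distortion gaps around 0.25–0.3.

Two conventions deserve note. First, an informative trio here requires
*both* parental genotypes non-missing: with one parent unknown, a
heterozygous other parent's transmission is not always resolvable, and a
het×unknown trio would contribute selectively (only when the child
genotype happens to resolve it), biasing counts. Second, a het×het trio
contributes two meioses whose transmitted-allele count is the child's B
dosage; the informative-trio threshold counts trios, not meioses. The "B"
allele is always the VCF ALT allele, so the sign of $\varepsilon$ follows
REF/ALT orientation; sign flips between adjacent SNPs reflect orientation,
not biology.

Sample sex is verified from X heterozygosity (`verify_sex_labels()`):
below 2% infers male, above 6% female, in between unassigned. The method
also assumes trios are genetically unrelated; this is documented, not
checked.

## Region calling: the local score

Per-SNP p-values of the M2-vs-M0 LRT are aggregated along each chromosome
with the Lindley recursion over scores $X_i = -\log_{10} p_i - \xi$:
$H_i = \max(0, H_{i-1} + X_i)$. A SNP contributes positively exactly when
$p < 10^{-\xi}$; $\xi = 1$ (default) aggregates $p < 0.1$, $\xi = 2$
aggregates $p < 0.01$. The running maximum of $H$ equals the best
contiguous-segment score sum, so excursions of $H$ are the candidate
regions.

Chromosome-wise significance thresholds come from Monte Carlo under
i.i.d. uniform p-values (`mc_threshold()`): the $1-\alpha$ quantile of the
maximal Lindley height over simulated chromosomes of the same SNP count.
This makes the independence assumption explicit: on strongly
LD-correlated data the effective number of independent tests is smaller,
and the i.i.d. threshold is mildly conservative for sparse maps and can
be anticonservative where correlation inflates excursion lengths. An
autocorrelation-aware analytic (Gumbel) threshold is a possible extension;
it is deliberately not bundled here.

A called region spans the first SNP of its excursion to the SNP achieving
the excursion maximum (first maximum on ties) — the segment that realises
the maximal score; the full excursion extent is kept as metadata, and both
a per-chromosome significance level and the boundary convention are
configurable because neither is canonical.

`estimate_pi0()` supports a genome-wide sanity check: after greedy
left-to-right thinning to SNPs ≥ 500 kb apart (reducing p-value
correlation from linkage), the standard $\lambda$-threshold estimator
$\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda) m)$ estimates the fraction of
null SNPs.

## Classification

Significant SNPs ($p_{20} <$ `snp_alpha`, default 0.05) inside called
regions are labelled from $(\hat\varepsilon_m, \hat\varepsilon_f)$ using
$s = |\hat\varepsilon_m + \hat\varepsilon_f|$ and
$M = \max(|\hat\varepsilon_m|, |\hat\varepsilon_f|)$ with threshold $t$
(default 0.05, the order of the genome-wide standard deviation of
$\hat\varepsilon$ in a 250-trio design):

* **SA** (sex-antagonistic), $s < M - t$: opposite-direction distortion
  cancels in the sum;
* **SD** (sex-differential), $s > M + t$: same-direction distortion
  inflates the sum;
* **SL** (sex-limited), $|s - M| \le t$: distortion confined to one sex
  leaves the sum near the larger magnitude.

Written as three inequalities these bands overlap near $M \pm t$; the
package implements the disjoint partition above, which is the only
self-consistent reading of the intended geometry and reduces to pure sign
logic at $t = 0$. A region is labelled with its modal category when that
category holds at least 75% of the classified SNPs, otherwise "mixed".
The 75% denominator is the *significant* SNPs of the region (not all
SNPs): non-significant estimates carry little information about direction,
and including them would dilute every label toward "mixed". Both the
majority threshold and the per-SNP cutoff are configurable.

## Intersexual F_ST

`wc_fst()` computes the Weir–Cockerham (1984) two-population $\hat\theta$
between the male and female cohorts per SNP, from per-sex genotype counts.
Negative estimates are reported as-is so that the null distribution stays
centred at zero. For X-linked sites males are treated as haploid: their
allele counts enter the frequency components with sample size equal to
the number of males and contribute no heterozygosity term
(`wc_fst_x()`); this is a pragmatic departure from the strictly diploid
1984 estimator and is flagged as such. The cohort (offspring vs parents)
is a flag, since the two address different questions — distortion in the
current generation vs accumulated structure. `matched_null_sample()`
builds an empirical null for region-level F_ST summaries by resampling
genomic regions matched (±20% by default) on length, SNP count and
diversity, and `quartile_enrichment()` tests region placement across
quartiles of a genomic covariate (e.g. recombination rate) with exact
binomial tests against the 25% null.

## Simulators and what they do (not) emulate

`simulate_counts()` draws per-site counts under the study design used for
the power analyses: each trio has a child of random sex
(`p_male_child = 0.5`) and contributes one informative meiosis —
`frac_double_het` adds het×het trios with two — transmitting B with
probability $\tfrac12 + \varepsilon_{sex}$. Sex-antagonistic scenarios
are parameterised by the gap $\delta = |\varepsilon_m - \varepsilon_f|$
with the symmetric split $\varepsilon_m = +\delta/2$,
$\varepsilon_f = -\delta/2$; with 150 one-meiosis trios and balanced
sexes this design gives 2-df LRT noncentrality
$\approx 4 \cdot 75 \cdot (\delta/2)^2$ per sex and analytic powers of
0.60/0.81/0.93 at $\delta = 0.2/0.25/0.3$, matching what
`power_analysis()` measures empirically at 500 replicates. For the 1-df
uniform-distortion test the same 150-meiosis design gives powers near
0.72/0.97/1.00 at $\varepsilon = 0.1/0.15/0.2$.

Two calibration facts are worth stating because they are properties of
the method, not artefacts of this implementation, and both were verified
against exact enumeration of the null law (all $2^{150}$-equivalent
outcomes reduced to binomial lattices):

* at exactly 150 meioses, the 1-df LRT rejects the null at rate 0.0655
  rather than 0.05 — the discrete lattice places the rejection boundary
  at $|k - 75| \ge 12$;
* the 2-df p-value's CDF deviates from the uniform by up to ~0.017. The
  p-values are uniform *for practical purposes* (FDR, local score), but a
  continuous Kolmogorov–Smirnov test against the uniform will reject with
  probability approaching 1 as the number of simulated sites grows. The
  test suite therefore calibrates the KS distance against the exact
  enumerated null distribution (parametric bootstrap) instead of the
  continuous KS reference.

`simulate_window_lengths()` implements the recombination-free-window
model: with recombination intensity $\lambda$ per unit distance (1 cM/Mb
read as $\lambda = 0.01$ events per Mb; unit conversion is the caller's
responsibility), the nearest breakpoint on each side of a focal SNP in
one trio is Exponential($\lambda$), the nearest across $N_T$ trios is
Exponential($N_T\lambda$), and the shared window — upstream plus
downstream minimum — is Gamma(shape 2, rate $N_T\lambda$), mean
$2/(N_T\lambda)$. The simulator draws per-trio distances explicitly and
returns method-of-moments shape/rate estimates.

`make_fixture()` writes a synthetic VCF 4.2 + pedigree + ground-truth
sidecar: Hardy–Weinberg parents at per-site MAFs (default uniform on
0.2–0.5, keeping most sites informative at realistic cohort sizes),
children generated by the per-meiosis transmission model with planted
distorted spans, an X block with hemizygous males, and optional Mendelian
errors (child genotype corrupted to an incompatible one where one exists)
and missingness. What it deliberately does **not** emulate: linkage
disequilibrium between sites (sites are independent given the planted
$\varepsilon$ track), realistic allele-frequency spectra, genotyping
error that is Mendelian-consistent, or relatedness between trios.
Passing end-to-end tests on these fixtures therefore demonstrates correct
counting, fitting and region logic — not robustness to LD-driven p-value
correlation, which on real data chiefly affects the local-score
threshold (above).

## Haplotype follow-up

For a candidate region with phased haplotypes, `asd_matrix()` (normalised
Hamming distance; genotype mode $\overline{|g_1-g_2|}/2$),
`classical_mds()` (double-centred eigendecomposition) and
`density_cluster()` (classic DBSCAN; border points join the
first-discovered cluster, so labels are deterministic given input order)
recover haplotype classes. `resolve_transmissions()` assigns each child
haplotype to a parent by minimal mismatch and
`haplotype_transmission_tests()` asks, per class, whether transmissions
are sex-biased: a two-sided exact binomial test of the son-fraction among
class-h transmissions against the son-fraction among *all* transmissions
from h-heterozygous parents (H0: transmission independent of offspring
sex; a fixed `p0 = 0.5` is available for even-split questions), plus a
2×2 Fisher exact test. `mantel_sex_test()` is the cohort-level QC that
the data are not genetically structured by sex: Pearson correlation
between genetic distances and a same/different-sex indicator, permutation
p-value two-sided on $|r|$. DBSCAN's `eps`/`min_pts` and the MDS
dimensionality have no canonical values for this task and are exposed as
configuration.

## Reproducibility and numerical choices

Every stochastic step takes a seed and restores the caller's RNG state;
`run_scan()` derives per-chromosome sub-seeds from a master seed and
writes a manifest (parameters, seeds, input/output checksums) so a rerun
is byte-identical. Numerical conventions: $0\log 0 = 0$; deviances are
clamped at zero against floating-point jitter; p-values of exactly 0
entering the local score are clamped to the smallest positive double; a
site with meioses in only one sex is fitted with M2 collapsed to M1 for
the missing sex and flagged (`one_sex_only`) rather than dropped.

Problem sizes used by the test and acceptance suites — 500 replicates per
power point, 2000 null replicates for calibration, $10^5$ windows for the
gamma check, 50 fixture seeds of 250 trios × 100 sites for end-to-end
recovery — were chosen to hold Monte-Carlo error comfortably inside the
assertion tolerances.

## Limitations

* One generation, one meiosis per parent: parent-of-origin effects
  (which parent distorts) are not modelled, only offspring sex.
* The informative-trio threshold restricts analysis to intermediate
  allele frequencies; this is an ascertainment filter, not a bug, but it
  biases any site-frequency-spectrum statistic computed downstream.
* The i.i.d. Monte-Carlo local-score threshold ignores LD (discussed
  above).
* The X-linked F_ST treatment of hemizygous males is nonstandard.
* The classification threshold $t$ is a scale parameter of the cohort;
  the 0.05 default is appropriate for ~250 trios and should be re-derived
  (as the genome-wide SD of $\hat\varepsilon$) for materially different
  designs.
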