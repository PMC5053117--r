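---
title: "Adaptive rank-test eQTL mapping with pedigree decorrelation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive rank-test eQTL mapping with pedigree decorrelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankqtl)
```

## The problem

In an experimental F2 cross, expression phenotypes measured on related
animals violate the two assumptions most association tests make:
observations are not independent (full and half sibs share polygenic
background, and all animals share herd-management effects), and
microarray expression values are frequently non-normal — right-skewed,
heavy-tailed or short-tailed — even after log transformation. `rankqtl`
addresses both: a per-transcript mixed model strips fixed effects and
family covariance from the expression values, and a two-stage adaptive
rank test chooses, per SNP-transcript pair, the k-sample linear rank
test best matched to the observed distributional shape.

## The sire-dam model

For transcript $y$ and animal $i$,

$$y_i = s_j + \beta x_i + \tfrac{1}{2}\,(a_{if} + a_{im}) + \varepsilon_i$$

with $s_j$ the fixed year-season class at slaughter, $x_i$ the age at
slaughter in days, and $a_{if}$, $a_{im}$ the additive-genetic effects
of animal $i$'s sire and dam. Writing $Z$ for the incidence matrix that
loads $0.5$ on each parent, the random part has covariance
$\sigma^2_a\, Z A Z' + \sigma^2_e I$, where $A$ is the numerator
relationship matrix over the parents, built from the complete pedigree
by the tabular method ($A_{ii} = 1 + \tfrac12 A_{fm}$,
$A_{ij} = \tfrac12 (A_{jf} + A_{jm})$, parents processed before
offspring). Unknown parents are treated as unrelated, non-inbred
founders — the standard tabular convention, and the only defensible
choice when founder relationships are unrecorded.

Because the individual animal effect is represented through its
parents, the residual $\varepsilon_i$ absorbs the Mendelian-sampling
deviation along with measurement noise; this is an interpretation of
the model, not an extra computation. The residuals are the
"de-correlated" expression values passed to the association stage.

### REML by profiling the variance ratio

Only the ratio $\lambda = \sigma^2_a/\sigma^2_e$ enters the shape of
the covariance. With the eigendecomposition $Z A Z' = U D U'$, rotating
$y$ and the fixed design $X$ by $U'$ makes the covariance diagonal,
$\sigma^2_e\,\mathrm{diag}(1 + \lambda d_k)$, so each restricted
log-likelihood evaluation is $O(n)$ after one $O(n^3)$
eigendecomposition **shared by all transcripts** (X and Z do not depend
on the transcript). The REML criterion is maximised over
$\lambda \in [0, 10^3]$ by Brent/golden-section search
(`stats::optimize`, tolerance $10^{-8}$), the endpoints are evaluated
explicitly, and the boundary solution $\lambda = 0$ — no detectable
polygenic variance, the fit degenerates to OLS — is allowed and
reported rather than treated as a failure. Fixed effects are the GLS
solution at the optimum, parent effects are BLUPs
$\hat u = \lambda A Z' (I + \lambda ZAZ')^{-1}(y - X\hat\beta)$, and
residuals are $y - X\hat\beta - Z\hat u$.

Degenerate inputs are handled explicitly: a constant transcript yields
a flagged zero-residual fit; season levels with zero observations are
dropped (levels are never merged — level occupancy is the user's
responsibility and is visible in the covariate table); a singular
fixed design (e.g. constant age within a single season level) is a
hard error naming the collinear columns. Per-transcript failures in
`decorrelate_expression()` are flagged in the report and never abort
the batch.

The test suite validates this path against an independent dense-matrix
REML implementation (direct `solve`/`determinant` evaluation of the
restricted likelihood, no eigendecomposition); residuals agree to
correlation > 0.999 and $\hat\lambda$ to $10^{-4}$.

## The adaptive linear rank test

### Selector statistics

For the pooled sample (labels ignored), with $\bar L_p$, $\bar U_p$ the
means of the $\lceil pN \rceil$ smallest/largest order statistics and
$\bar M_{.5}$ the mean of the central half (the central block is
widened by one observation when $N - \lceil N/2 \rceil$ is odd so it is
always symmetric — this makes $Q_1 = 1$ exact for symmetric samples and
gives the reflection property $Q_1 \mapsto 1/Q_1$ under $x \mapsto -x$):

$$Q_1 = \frac{\bar U_{.05} - \bar M_{.5}}{\bar M_{.5} - \bar L_{.05}},
  \qquad
  Q_2 = \frac{\bar U_{.05} - \bar L_{.05}}{\bar U_{.5} - \bar L_{.5}}.$$

$Q_1$ measures skewness (1 = symmetric), $Q_2$ tail weight (about 1.9
for a uniform sample, larger for heavier tails); both are location
invariant and $Q_2$ is scale invariant. The selector needs $N \ge 8$;
a vanishing denominator (near-constant data) flags the selector as
degenerate and the test falls back to Kruskal-Wallis.

### Decision table

The published description of the procedure names the six component
tests but not the selector cutoffs, which live in an unreproduced
methods reference. The default table is therefore an explicit,
configurable design choice in the Hogg tradition, with precedence:

| rule | region            | test            |
|------|-------------------|-----------------|
| 1    | $Q_2 \le 2$       | short tails     |
| 2    | $Q_2 \ge 7$       | median          |
| 3    | $4.5 \le Q_2 < 7$ | long tails      |
| 4    | $Q_1 \ge 2$       | right skewness  |
| 5    | $Q_1 \le 0.5$     | left skewness   |
| 6    | otherwise         | Kruskal-Wallis  |

`default_selector_rules()` returns this table as data; users can
substitute their own cutoffs without touching the test machinery. In
simulation the table behaves as intended: lognormal residuals route to
the right-skewness test in a large majority of draws, uniform residuals
to the short-tails test, and normal residuals to Kruskal-Wallis.

### Scores and the statistic

The six score families, for rank $R$ in a pooled sample of size $N$
(centre $c = (N+1)/2$): Wilcoxon $a(R) = R$; median
$a(R) = 1\{R > c\}$ (with $\tfrac12$ at $R = c$ for odd $N$);
long tails (winsorised Wilcoxon) $a(R) = \mathrm{clamp}(R - c, \pm N/4)$;
short tails $a(R) = R - c$ on the outer quartiles
($|R - c| > N/4$), 0 on the middle half; right skewness
$a(R) = \min(R, \lceil c \rceil)$; left skewness
$a(R) = \max(R, \lfloor c \rfloor)$. Ties receive mid-rank score
averages, which carries the tie correction into the realised-score
variance $s^2 = \sum (a_i - \bar a)^2/(N-1)$ automatically. The
statistic

$$T = \frac{1}{s^2} \sum_g \frac{(A_g - n_g \bar a)^2}{n_g}$$

is referred to $\chi^2_{g-1}$; with Wilcoxon scores it is exactly the
tie-corrected Kruskal-Wallis $H$ (verified against
`stats::kruskal.test` to $10^{-12}$). An exact mode (full enumeration
of group assignments when feasible, otherwise seeded Monte-Carlo
permutation) is provided for validation.

Because the selector is computed on the pooled, label-blind sample, the
two-stage procedure is level-$\alpha$ under the null; the suite
verifies the empirical type-I error at $\alpha \in \{0.05, 0.01\}$
within 3 binomial SE over 10,000 null replicates for normal, lognormal,
$t_3$ and uniform residuals at $n = 145$ with genotype groups from a
MAF-0.3 draw.

**Accuracy of the $\chi^2$ approximation.** Two honest caveats,
established empirically. First, at $n = 145$ the asymptotic p-values
are very slightly conservative (null mean p $\approx 0.51$, sup-norm
distance to uniform $\approx 0.02$) — negligible for FDR control but
detectable by a Kolmogorov-Smirnov test given 10,000 null p-values, so
the uniformity test asserts closeness (D < 0.03) rather than a literal
KS non-rejection. Second, for very small samples ($N \le 10$) the
$\chi^2$ approximation is genuinely poor, with discrepancies from the
exact permutation p as large as 0.5 for the coarse (median) scores; use
`p_mode = "exact"` at such sizes. The implementation's enumeration was
itself verified against an independent brute force over all group
assignments.

### Selector scope

Whether the selector should be computed once per transcript or per
SNP-transcript pair (after dropping samples with missing genotypes) is
not specified in the published description. The default is **per pair**
on the analysed subsample — the statistically cleaner choice, since the
test then adapts to exactly the sample it sees — with
`selector_scope = "per_transcript"` available; the two coincide
whenever a SNP has no missing genotypes, which makes the dense case
fast (scores are computed once per transcript and reused across SNPs
via matrix products).

## The genome-wide scan

Samples missing the tested genotype are dropped pair-wise. Genotype
classes with fewer than `min_group_count = 3` members are dropped from
a pair, and the pair is skipped (but counted) when fewer than two
classes survive; `m`, the number of *performed* tests, is what enters
the Benjamini-Hochberg step-up (`bh_adjust()` delegates to
`stats::p.adjust(..., n = m)`, with an independent brute-force step-up
oracle in the tests). The group-size rule is a reconstruction — the
original analysis reports performing fewer tests than the full
SNP × transcript product without stating the skip rule — and is fully
configurable. "Significant" means $p_{BH} \le \alpha$ (inclusive), with
$\alpha = 0.1$ by default.

Classification uses the chromosome rule: cis = SNP and gene on the same
chromosome, trans = different chromosomes, unknown = SNP position
unknown. In an F2 cross, linkage disequilibrium extends over tens of
megabases, so SNPs far from the gene on the same chromosome can carry a
genuine cis signal; the chromosome-level rule acknowledges that a
local/distant split within a chromosome is not identifiable here.
`summarize_scan()` additionally re-classifies by distance windows
(default 1 Mb and 5 Mb, `distance < w` to the annotated gene start,
strand ignored): within-window = cis, all other known-position records
— including same-chromosome pairs outside the window — = trans, and
records with unknown SNP position are excluded from the window split
and reported separately. (When comparing against published totals note
that some summaries fold unknown-position records into the trans count;
ours never does.) Two closed-form helpers expose the BH arithmetic:
`equivalent_fdr(alpha, m_sub, m_total)` = $\alpha\, m_{sub}/m_{total}$,
the FDR level at which a subset-only analysis matches the genome-wide
per-test threshold, and `threshold_from_rejections(k, m, alpha)` =
$k\alpha/m$, the raw-p boundary implied by $k$ rejections.

## The simulator

The generator reproduces the statistical structure the analysis
assumes, at configurable scale. Defaults mirror the study population:
5 purebred sires crossed to purebred dams of a second breed, 38 P0 and
52 F1 animals, and five F2 full/half-sib families of 49, 35, 52, 8 and
1 cows (145 F2, produced in MOET-style full-sib flushes of up to three
per F1 dam, with half-sib matings avoided); 25 year-season classes
assigned cyclically; age at slaughter uniform on 950–1250 days with a
fixed slope of 0.002 expression units/day.

* **Genotypes.** Founder allele frequencies are Beta(2,2) draws per
  breed pushed apart by `founder_freq_divergence` (0.6 by default;
  1 fixes the breeds for alternate alleles, making every F1
  heterozygous); gametes recombine by a Markov chain along each
  chromosome with Haldane crossover probability
  $r = (1 - e^{-2d})/2$ — the simplest standard map function, no
  interference. Physical positions use 1 cM = 1 Mb. The genome defaults
  to 5 chromosomes × 60 SNPs × 1 Morgan: large enough to exhibit
  F2-scale LD decay and chromosome-level cis/trans structure, small
  enough that simulated scans take seconds.
* **Expression.** The sire-dam model run generatively: season effects
  (SD 0.5), the age slope, parental additive effects drawn with
  covariance $\sigma^2_a A$ ($\sigma^2_a = 0.5$, $\sigma^2_e = 1$ by
  default, log2-RMA-scale units), planted per-allele eQTL effects
  (normal draws, or a fixed magnitude for calibrated power studies),
  and residuals from one of four families — normal,
  shifted lognormal (right skew), $t_3$ (heavy tails), uniform (short
  tails) — each centred and scaled so the residual variance is
  *exactly* $\sigma^2_e$, so the four families differ only in shape.
  `residual_family = "mixed"` cycles the four across transcripts, which
  is what exercises the selector.
* **Truth table.** Every planted effect, its class (cis genes are
  placed within 0.5 Mb of their causal SNP), and the per-transcript
  variance components and residual family are recorded for
  parameter-recovery and FDR tests.

What the simulator does **not** emulate: a realistic bovine genetic map
or real UMD3.1 coordinates, mutation, selection, sex chromosomes,
genotyping error, array normalisation artefacts, or correlated
transcripts (co-expression). Passing tests therefore demonstrate that
the statistical machinery is correct under the model's own assumptions
— not that those assumptions hold for any particular real dataset.

## Validation sizes and seeds

The test suite runs at deliberately chosen sizes: Monte-Carlo
gene-dropping validation of the relationship matrix at $10^5$
replicates (3-SE agreement); REML parameter recovery on 500 transcripts
at $\sigma^2_a = \sigma^2_e = 1$, $n = 145$ (mean $\hat h^2$ within 0.1
of 0.5); level checks at 10,000 null replicates per residual family;
power comparison against plain Kruskal-Wallis under a lognormal shift
at 1,000 replicates; and an end-to-end scan with planted effects of 1.5
residual SD (recovery of ≥ 80 % of planted cis effects at
$p < 10^{-4}$, realised false-discovery proportion within the BH
target). All randomness is seeded; identical seeds give byte-identical
simulated datasets on disk.

For the realised-FDR check, a discovery is counted as true when its SNP
lies on a chromosome carrying a causal SNP for that transcript: with
chromosome-scale LD, linked neighbours of the causal SNP are genuinely
associated, and counting them as false would misstate the error rate
the procedure actually controls.

## Known limitations

* Variance-component estimation at $n = 145$ with 5 sire lines has
  limited precision; per-transcript $\hat h^2$ is noisy (SD ≈ 0.15)
  even though it is unbiased on average, and $\lambda = 0$ boundary
  fits are common for low-heritability transcripts.
* The selector cutoffs are a documented stand-in for an unreproduced
  reference; they are sane (see the routing behaviour above) but not
  tuned to any published table.
* Asymptotic p-values should not be trusted below $N \approx 20$; use
  the exact mode.
* The scan treats genotype dosage as an unordered grouping; ordered
  (trend) alternatives and covariate-adjusted rank tests are out of
  scope — covariates are handled upstream by the decorrelation stage.
* `bh_adjust` controls FDR over the tests performed; pairs skipped by
  the group-size rule are silently untested, which is a (configurable)
  reconstruction of the original analysis.
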