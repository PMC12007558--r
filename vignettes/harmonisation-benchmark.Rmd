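---
title: "Benchmarking scanner harmonisation of imaging-derived phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking scanner harmonisation of imaging-derived phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmonybench)
```

## The problem

Multi-site neuroimaging studies pool imaging-derived phenotypes (IDPs) —
regional volumes, tract-averaged diffusion metrics, connectivity edge
weights — measured on different MRI scanners. Scanner ("batch") effects
shift and rescale these measurements for non-biological reasons, and a
travelling-heads design (the same subjects scanned on every scanner,
some re-scanned repeatedly on one scanner) is the cleanest way to
measure them: scanner effects become within-subject contrasts, and the
within-scanner repeats provide the test-retest noise floor against which
they are judged.

harmonybench implements the full evaluation loop at the
phenotype-table level: a synthetic travelling-heads cohort generator
with known ground truth, the descriptive statistics that map scanner
effects (between-session similarity, three-baseline coefficients of
variation, scanner bias, IQM z-scores, subject-ranking consistency with
a permutation null), and from-scratch ComBat/CovBat harmonisation with a
paired pre/post evaluation. Image-level processing is out of scope: the
package consumes tables, not scans.

## The reference design

The built-in preset (`preset_paper_like()`) mirrors a 10-subject,
6-scanner travelling-heads study spanning the three major vendors
(3 Siemens-like, 2 Philips-like, 1 GE-like scanners) at five sites.
Every subject has one primary session per scanner (60 sessions) and four
subjects have five extra within-scanner repeats each on four distinct
scanners (20 sessions), for 80 sessions in total. Ages are fixed within
24–48 years and the sex ratio is 8:2, matching the recruitment envelope
of published travelling-heads cohorts. The preset carries 379 IDPs in 8
categories across 4 modalities, including a functional-connectivity
block of 21 node amplitudes and the `choose(21, 2) = 210` edges of a
partial-correlation network matrix.

## The generative model

`simulate_idps()` draws, for session *r* of subject *s* on scanner *b*
and IDP *v*:

$$y_{sbrv} = \alpha_v + x_s^\top\beta_v + u_{sv} + \gamma_{bv}
  + \eta_{bsv} + \delta_{bv}\,\varepsilon_{sbrv}$$

with biological subject effects $u_{sv} \sim N(0, \tau_v^2)$, additive
scanner effects $\gamma_{bv} \sim N(0, \sigma_\gamma^2)$, multiplicative
scanner effects $\delta_{bv}$ log-uniform on a range around 1, a
subject-by-scanner interaction $\eta_{bsv} \sim N(0, \sigma_\eta^2)$,
and i.i.d. session noise $\varepsilon \sim N(0, \sigma_v^2)$. Covariates
are age (centred at 36 years) and sex. All draws flow from a single
seed through named sub-streams, so components are independently
reproducible and the whole table is bit-identical under a fixed seed.

The additive-location / multiplicative-scale part is exactly the model
class ComBat assumes, which is deliberate: harmonisation "success" then
has a well-defined truth (`GroundTruth$gamma`, `$delta`) and can be
scored by parameter recovery. The interaction term is the one deviation
from that model class, and it exists for a specific reason: **purely
additive scanner offsets cannot reorder subjects** (they cancel in any
within-scanner ranking), and multiplicative effects only rescale noise,
so a location/scale-only generator cannot reproduce the empirical
observation that subject rankings agree more between scanners of the
same vendor. A vendor-shared subject-by-scanner interaction (variance
share 0.9 at sd 1.5) produces exactly that phenomenon — think of
vendor-specific gradient-nonlinearity profiles interacting with head
anatomy. Because the interaction is outside ComBat's model, it also
survives harmonisation, which keeps the post-harmonisation
between/within CoV ratio realistically above 1 rather than collapsing
it to the noise floor.

Default magnitudes (chosen once, on the scale of a typical IDP with
baseline ~100): biological sd $\tau_v \in [5, 15]$ (~10% CoV), session
noise $\sigma_v \in [1.5, 2.5]$ (~2% CoV), additive scanner sd
$\sigma_\gamma = 7$, scale range $[0.9, 1.15]$. These place the median
between-scanner CoV at roughly 3–5 times the within-scanner CoV — the
regime reported for real multi-vendor IDPs, where between-scanner
variability can reach ~5 times the test-retest floor and rival
biological variability.

What the generator does **not** emulate: heavy-tailed or skewed IDP
distributions, missing data mechanisms, category-specific noise regimes
(real rfMRI edges are far noisier than T1w volumes; here all categories
share one noise envelope), longitudinal drift, motion artefacts, or
realistic IQM distributions. Passing tests on this generator therefore
demonstrate correctness of the statistical machinery and of
harmonisation under ComBat's own assumptions — not performance on real
data.

## Mapping scanner effects

**Between-session similarity.** For each IDP category *m*, the Spearman
rank correlation $R_{ijm}$ is computed between the category's IDP
vectors of sessions *i* and *j*; the similarity matrix is the entrywise
median across categories, each category carrying equal weight regardless
of its IDP count. For the connectivity-edge category only the strongest
edges enter (below). Session pairs are partitioned by subject/scanner
equality into four classes; in a sound dataset within-scanner
within-subject pairs are the most similar, and the harmonisation
challenge is visible as the gap to between-scanner within-subject pairs.

**Edge selection.** Partial-correlation edges are signed and mostly
near zero, so whole-network rank correlations are noise-dominated. The
package ranks edges by the absolute mean edge weight over all
within-scanner repeat sessions of the subjects that have repeats, and
keeps a fraction (default 5%, i.e. `round(0.05 * 210) = 10` edges) or an
explicit `k_override`. Published analyses of 210-edge netmats quote "top
5%" alongside an edge count of 31, which is arithmetically inconsistent
(5% of 210 is 10.5); both knobs are therefore exposed rather than
guessing an intent. Ties are broken lexicographically by edge name so
selection is deterministic.

**Three-baseline CoV.** For every IDP: the CoV (sd over absolute mean)
of each (subject, scanner) within-scanner repeat set, averaged over
qualifying subjects (the noise floor); the CoV of each subject's primary
sessions across scanners, averaged over subjects (the scanner effect);
and the CoV across subjects within each scanner, averaged over scanners
(biological variability). The sample sd (n−1) is the default because
repeat counts are small (typically 6); `ddof = 0` is available. Only
`repeat_index = 0` sessions represent a scanner in the between-scanner
class, so repeats never leak in; a `mean-of-repeats` policy is the
alternative. Means within $10^{-12}$ of zero (relative to the column
scale) return a missing CoV rather than an exploding one.

**Scanner bias.** Per (IDP, repeat-subject):
$100(\bar y_\text{between} - \bar y_\text{within})/\bar y_\text{within}$,
plus group means and a single-vendor-restricted variant.

**IQM z-scores.** Each image quality metric is z-scored per subject
across scanners (sample sd) and averaged over subjects — or the
transpose construction — after excluding within-scanner repeats, so no
scanner is over-represented. Metrics constant along the z-axis yield
missing entries, never zeros.

**Ranking consistency.** For each IDP and each unordered scanner pair,
the Spearman correlation between the two scanners' subject vectors
(primary sessions). The null baseline is the distribution of Spearman
correlations between independent random rankings: exact enumeration of
all $n!$ permutations against a fixed reference for $n \le 8$ (valid by
exchangeability), Monte-Carlo (default 10,000 seeded draws) otherwise.
Its interquartile range is the "no information" band. Scanner pairs with
fewer than 3 complete subjects are reported missing.

Missing values are handled pairwise-complete inside every correlation,
and a correlation over fewer than two complete pairs — or over a
constant vector — is reported missing rather than zero, so degenerate
inputs never masquerade as "no association".

## ComBat and CovBat

`fit_combat()` is a from-scratch parametric empirical-Bayes
location/scale batch adjustment: least-squares fit of batch offsets plus
covariates with a sample-size-weighted zero-sum constraint on the batch
offsets (preserving the grand mean rather than privileging an arbitrary
reference batch); pooled per-feature variance with divisor N;
standardisation; per-batch location/scale estimates; method-of-moments
hyperpriors (normal for locations, inverse-gamma for scales, with
$a = (2s_2 + m^2)/s_2$, $b = (ms_2 + m^3)/s_2$ from the mean and
variance of the scale estimates across features); and alternating
conditional posterior means iterated to a $10^{-4}$ maximum relative
change (cap 100 iterations, both configurable; iteration counts are kept
in the model). Sex enters as a 0/1 dummy and age is centred before
regression for numerical conditioning. When the across-feature variance
of the scale estimates is numerically zero, the inverse-gamma moments
are undefined and shrinkage is skipped for that batch, recorded in the
model. A single-batch fit is an exact no-op.

Two deliberate numerical choices deserve explanation:

* **Scale divisor.** The per-batch scale estimate uses the population
  (divisor $n_b$) variance by default, consistent with the divisor-N
  pooled variance. This makes the shrinkage-free adjustment *exactly*
  idempotent (the second fit finds scale 1 in every batch) and the
  single-batch fit an exact identity. `scale_divisor = "sample"`
  switches to the $n_b - 1$ convention of the reference neuroimaging
  implementations and then reproduces `sva::ComBat` elementwise (a test
  asserts equality at $10^{-6}$). With shrinkage on, exact idempotence
  is impossible in either convention: every pass applies a further
  empirical-Bayes pull on the remaining (already small) batch
  deviations, so re-harmonisation is a contraction, not a fixed point —
  the tests assert exactly that.
* **Fit sessions.** In a crossed travelling-heads design the balanced
  primary subset (one session per subject per scanner) is the right fit
  set for batch offsets: every batch then contains the same subjects
  with equal weight, so subject effects cancel exactly in batch
  contrasts. Fitting on all sessions over-weights the repeat subject in
  its repeat-scanner batch (6 of 15 sessions instead of 1 of 10) and
  leaks that subject's biology into the batch offset. The pipeline
  therefore fits on primary sessions and applies the adjustment to all
  sessions; `fit_sessions = "all"` (the `fit_combat()` default,
  matching how whole-cohort harmonisation is usually run) is available.

Because the adjustment is a strictly increasing affine map per
(feature, batch), a no-covariate fit preserves within-batch subject
orderings bit-for-bit — which is why harmonisation cannot repair
ranking inconsistency between scanners, only variability.

`fit_apply_covbat()` extends ComBat to covariance batch effects: the
covariate-adjusted residuals of the ComBat output are decomposed into
principal components across features; the smallest set of components
reaching a cumulative explained-variance fraction (default 0.95) is
retained; each retained score series gets a plain per-batch
location/scale standardisation (no shrinkage — a score is a single
"feature", so there is nothing to pool across); residuals are
reconstructed and the fitted mean structure re-added.

## Evaluation and pipeline

`evaluate_harmonisation()` runs the CoV profile and ranking consistency
on the table before and after harmonisation and pairs them per IDP. The
headline summary is the median between/within CoV ratio before (~3.3 on
the preset) and after (~1.2) harmonisation, and the median ranking
consistency before and after (identical by construction within batches).

`run_all()` executes the whole chain from one seeded configuration and
writes every artefact as TSV/JSON plus a manifest of MD5 hashes; two
runs with the same configuration and seed are byte-identical.
`render_report()` turns an output directory into a Markdown report with
the standard panels. All randomness in any stage flows from the single
config seed.

## Problem sizes in the test suite

The suite exercises the full preset (80 sessions × 379 IDPs) for the
framework-level checks — similarity orderings, vendor effects, parameter
recovery, determinism — and small constructed fixtures (3–24 subjects,
4–40 features) wherever a hand computation or an analytic construction
is the oracle. Exact permutation enumeration is used up to $n = 5$
(120 permutations) for the Spearman primitive and the ranking null;
the Monte-Carlo null uses 10,000 draws. These sizes keep every oracle
independently verifiable while matching the scale of the reference
design.

## Known limitations

* The generator's realism limits are listed above; in particular,
  homogeneous noise across categories means category-level contrasts
  (e.g. "rfMRI edges are the least reliable") are not emulated.
* Only parametric empirical-Bayes priors are implemented;
  non-parametric ComBat variants are out of scope.
* ComBat requires a complete feature table; impute or drop incomplete
  features upstream.
* The ranking null assumes exchangeable rankings; it is indicative, not
  a calibrated hypothesis test.
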