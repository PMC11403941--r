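---
title: "Genomic footprinting of promoters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic footprinting of promoters: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

# What the package does

`footprintr` implements the in-silico side of a genomic-footprinting study
of drug-regulated genes, of the kind used to dissect dose-dependent
transcriptional responses (for example anthracycline cardiotoxicity in the
rat heart). The pipeline runs from gene-level expression measurements to
candidate regulatory modules:

1. select differentially expressed genes (DEGs) per treatment arm and
   partition them (Venn regions, fold-change magnitude histograms,
   co-expression clusters);
2. extract strand-aware promoter windows around transcription start sites
   (TSSs) and split them into strongly regulated, moderately regulated and
   non-regulated (control) sets;
3. build position weight matrices (PWMs) from aligned, experimentally
   proven binding sites and scan the promoter sets with MATCH-style
   similarity scores;
4. test whether binding-site density and promoter coverage are higher in
   regulated than in control promoters, and search for composite modules of
   secondary motifs around anchor sites;
5. support the study design itself with body-surface-area dose translation
   and balanced one-way ANOVA power calculations.

A synthetic-data generator produces every input the pipeline needs, with
recorded ground truth, so all of the above is testable end to end without
any external data.

# The motif model

## PWM construction

Given `n` aligned binding sites of length `L`, the count matrix `c(i, b)`
tallies base `b` at position `i`. Frequencies use an additive pseudocount
`p` shared equally across the four bases:

$$f(i,b) = \frac{c(i,b) + p/4}{n + p}.$$

The default `p = 1` keeps every frequency strictly positive so the
logarithms below are always defined; `p = 0` reproduces raw frequencies.
Each position carries an information weight

$$I(i) = \sum_b f(i,b)\,\ln\!\big(4 f(i,b)\big), \qquad 0 \le I(i) \le \ln 4,$$

with the usual convention `0 * ln 0 = 0`. `I(i)` is zero for a uniform
column and maximal for a fixed base, so it up-weights the informative
positions during scanning. The *core* is the contiguous run of
`core_length = 5` positions with the largest summed information weight
(leftmost on ties), the classic convention of MATCH-family scanners.

## Matrix and core similarity scores

For a window `b_1..b_L` the score is the information-weighted frequency
sum, min-max normalised over the matrix:

$$\mathrm{Current} = \sum_i I(i) f(i, b_i), \qquad
\mathrm{mss} = \frac{\mathrm{Current} - \mathrm{Min}}{\mathrm{Max} - \mathrm{Min}},$$

where `Min`/`Max` substitute the per-position minimum/maximum frequencies.
The core similarity `css` is the same expression restricted to the core
positions. Both scores live in `[0, 1]`; the rank-1 consensus is the unique
maximiser (`mss = 1`) and the per-position minimum-frequency word the
minimiser (`mss = 0`). The published MATCH-style tools document this score
family but not one canonical equation; the definition above is this
package's normative one and is frozen by oracle tests (an independent
brute-force evaluator recomputes it from the raw counts).

Numerical choices:

* `N` bases in promoters are allowed and score the column-minimum
  frequency — the conservative reading, since an ambiguous base should
  never raise a score. Sites used to *build* a PWM must be unambiguous.
* A matrix with no informative position (`Max = Min`) scores every window
  1, consistent with "every window is a maximiser".
* Consensus ties are broken by fixed alphabet order A < C < G < T, making
  `consensus()` deterministic. Note a strict rank-2 readout always differs
  from rank 1 at every position; published "weak consensus" strings that
  repeat the dominant base at strong positions cannot be reproduced
  literally by any strict per-position ranking, so tests of the shipped
  synthetic example matrix compare rank 2 only where the weak consensus
  differs from the consensus.

## Scanning

`scan_pwm()` scores *every* window on the forward strand and, by default,
on the reverse complement, and reports each admissible hit exactly once
with 0-based forward-strand offsets. Overlapping hits are all kept — the
density statistics downstream must count every admissible site, so no
greedy masking is applied. The default cutoffs (`mss 0.75`, `css 0.80`)
are deliberately low to minimise false negatives; density comparisons are
robust to the common background this admits because foreground and
background are scanned identically. Tests enforce exact equality with an
exhaustive enumeration oracle and the strand-involution identity
(scanning the reverse complement mirrors offsets and flips strands).

# Promoter extraction and set labels

Coordinates are 0-based half-open everywhere internally; anything 1-based
is confined to display text. For a TSS at position `t`, the promoter spans
`U` bases upstream and `D` bases downstream *in transcript orientation*,
with the TSS base counted as downstream base 1:

* `+` strand: genomic interval `[t - U, t + D)`, sequence as-is;
* `-` strand: genomic interval `[t - D + 1, t + U + 1)`,
  reverse-complemented.

The extraction default is `U = 2900, D = 100` (3000 bp promoters); the
narrower `U = 1000, D = 100` window is the usual choice for footprinting
statistics and is the default length of the simulator. Windows that leave
the contig are an error unless clipping is explicitly requested, in which
case the clip is reported — silent truncation would bias per-kb densities.

Set labels follow the strongest response of a gene across treatments
(maximum `|log2fc|`): at least 4-fold with an FDR pass gives
`regulated_gt4`, between 2- and 4-fold `regulated_2to4`. "Non-regulated"
needs an explicit rule to be testable; the package requires
`|fold| < 1.2` *and* raw `p > 0.5` in every treatment (both configurable)
before a gene may serve as a control. Genes missing from the expression
table stay unlabeled with a warning.

# Differential expression stage

`compute_differential()` takes replicate log2 ratios (treated over
control), the natural unit when expression comes from two-colour ratio
experiments; the per-(gene, treatment) test is then a two-sided one-sample
t against zero, flagged as such in the output. Benjamini–Hochberg FDR is
applied across genes within each treatment. Zero-variance genes are
degenerate rather than wrong — synthetic data can produce them — and
receive `p = 1` with a warning.

DEG selection is the standard rule: `|log2fc| >= log2(fold)` (default
fold 2) *and* `p_fdr < 0.05`. The fold filter matters for specificity:
with realistic replicate noise a null gene essentially never reaches a
2-fold mean change, so false discoveries are suppressed well below what
FDR control alone guarantees. Venn partitioning, fold-change histograms
(left-closed bins `[2,3), [3,5), [5,10), [10,Inf)` by default),
average-linkage clustering on `1 - uncentered correlation` (the metric of
the classic expression-clustering tools, delegated to `stats::hclust`
and cross-checked against a naive O(n^3) agglomeration oracle),
delta-delta-Ct quantification with averaged housekeeping normalizers, and
hypergeometric over-representation with BH adjustment complete the stage.
Annotation is taken flat (no ontology-graph propagation).

# Footprint enrichment and composite modules

`promoter_coverage()` aggregates a scan over a promoter set into a
`density_stats` object: total sites, total bp, sites per 1000 bp, and the
fraction of promoters with at least one site. `density_enrichment()`
compares foreground against background three ways:

* `binomial_conditional` — condition on the total site count and test the
  foreground share against the exposure share `fg_bp / (fg_bp + bg_bp)`
  (exact binomial). This is the primary test; it is exact, fast and
  assumption-light.
* `poisson_rate` — exact two-sample Poisson rate comparison with bp
  exposures.
* `permutation` — promoter labels shuffled (default 10^4 times), p-value
  `(1 + #{perm >= obs}) / (1 + reps)`; the validity of this estimator
  under the null and its agreement with the binomial test are both under
  test.

Composite-module discovery reimplements the positive /
"false-positive" / "negative" contrast design with an exact surrogate:
windows of `site ± 100 bp` are cut around each anchor hit (clipped at
promoter ends; multiple anchor hits give multiple windows, never merged),
each secondary matrix of a library is reduced to presence/absence per
window, and a one-sided Fisher exact test ranks secondaries by enrichment
in the positive windows, BH-adjusted across the library. The two profile
designs differ only in the contrast set supplied (promoters of
non-regulated genes with an anchor site, versus anchor-free stretches of
non-regulated promoters), so identical contrast sets give identical
rankings by construction. The original module-finding tool is proprietary
and its algorithm unpublished; this presence/absence Fisher formulation is
deliberately simple, exact and fully testable, and is documented as this
package's normative definition rather than a reimplementation of that
tool's internals.

# Study-design calculators

Dose translation uses the standard body-surface-area km table
(mouse 3, rat 6, human 37; supplied as data, not constants): mg/kg × km =
mg/m², and cumulative doses multiply by the number of daily
administrations. For the rat this maps 1/10/20 mg/kg to 6/60/120 mg/m²
and the four regimens (3 or 6 daily doses) to 18/180/360/720 mg/m².

ANOVA power uses the exact noncentral-F formulation for a balanced
one-way design with `k` groups of `n`:
power `= P(F' > F_crit)` with `F' ~ F(k-1, k(n-1), lambda)`,
`lambda = f^2 k n` (Cohen's `f`, total-sample noncentrality). At `f = 0`
the power is exactly `alpha`; a Monte-Carlo ANOVA oracle cross-checks the
formula in the tests.

Two sample-size conventions coexist in practice and the package exposes
both. `min_n_for_power()` returns the smallest *integer* `n` whose power
meets the target — the rigorous reading of "minimum group size". Power
software, however, customarily solves the power equation over real `n`
and reports the continuous requirement, which users then round to whole
subjects; that value is returned as the `n_continuous` attribute. The two
can disagree by one subject when the continuous solution sits just above
an integer (e.g. `k = 3, f = 1.052626, alpha = 0.05, power = 0.8` gives
`n_continuous = 4.08`: integer minimum 5, whole-subject report 4, with
power 0.787 at `n = 4` and 0.902 at `n = 5`). Reporting both keeps the
package faithful to either convention.

# The synthetic-data generator

The generator defines the package's study conditions; its defaults are
fixed once and are not tuning knobs.

**Promoters.** Background bases i.i.d. uniform by default, length 1100 bp
(the −1000/+100 analysis window; 3000 bp available via the length
argument). Planted site counts are Poisson(`lambda * L / 1000`) per
promoter with `lambda` in sites/kb; sites are placed uniformly, on a
random strand, and never overlap a previously planted site (rejection
sampling with bounded retries) so that recall is well defined. Sites are
either exact consensus copies or draws from the PWM columns. Background
can still chance-produce matches; density-recovery tests therefore use
high-information matrices and exact-match cutoffs, which makes the
background contribution negligible rather than pretending it does not
exist.

**Binding-site collections.** 44 sequences by default, mirroring the size
of a typical published collection of experimentally proven sites; drawn
from PWM columns or mutated off a consensus at a per-base substitution
rate.

**Expression tables.** Four treatment arms by default with planted unique
DEG counts 102/52/20/79 and 53 genes shared between arms (306 planted
DEGs, 181 up and 125 down). Only the unique counts, the total and the
direction split are fixed by the emulated design; how the shared genes
distribute over the pairwise and triple regions is not, so the generator
uses a fixed realistic default (six pairwise regions of 6–10 genes, three
triple regions of 1 — multi-arm overlaps are rare in dose-regimen
designs) and keeps it configurable. Genes keep a consistent direction
across their arms. Replicate noise is Normal with `sigma = 0.25` log2
units and `n_reps = 6` biological replicates per arm — six animals per
group is the design the power calculation above supports — and planted
effect magnitudes are uniform on `[1.5, 3.5]` log2 units, i.e. roughly
3- to 11-fold, the range where a 2-fold selection rule should recover
essentially everything.

With these conditions the recovery tests ask for exact reconstruction:
the selection rule applied to a generated table must return the planted
totals, direction split and Venn uniques. That is a property of the
generator's signal-to-noise regime (mean standard error
`0.25/sqrt(6) ≈ 0.10` log2 units against effects ≥ 1.5, and the 2-fold
filter suppressing false positives), not of a lucky seed — the acceptance
test verifies ≥ 95% exact recovery across independent replicates.

**What passing does not show.** The generator draws independent genes,
independent Gaussian noise, uniform background DNA and independent
promoters. Real expression data have correlated genes, heavy-tailed
noise and array-level artefacts; real promoters have GC and repeat
structure that inflates chance motif matches, and real binding-site
collections carry alignment uncertainty. Passing the recovery tests shows
the estimators are correct under the stated model, not that the model
captures every property of microarray or genome data.

# Problem sizes used by the test suite

Desk-scale by design: scanner-oracle equivalence on 500 random instances
(matrices up to 8 positions, sequences up to ~120 bp), dendrogram oracle
up to 12 leaves, 200 simulated tables of 300 genes for FDR control, 20
full-size (2000-gene) end-to-end recovery replicates, and a 1.5×10^5-run
Monte-Carlo ANOVA oracle. These sizes give the Monte-Carlo checks
standard errors comfortably below the tolerances they are tested at.

# Known limitations

* Matrix-similarity scores are not p-value calibrated; cutoffs are score
  cutoffs, and cross-matrix comparisons inherit that.
* The composite-module surrogate reduces secondary evidence to
  presence/absence per window; it does not model site counts, spacing or
  orientation within a module.
* The one-sample t stage assumes ratio data; a full two-channel ANOVA
  over intensities (with dye and array effects) is out of scope, as is
  normalisation of raw intensities.
* TSS positions are inputs; the package does not predict promoters.
* Genome-wide (non-promoter) scanning and de-novo motif discovery are
  non-goals.
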