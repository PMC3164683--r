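---
title: "Calling crossovers in pedigrees and testing maternal-age effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling crossovers in pedigrees and testing maternal-age effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedrecomb)
```

## The problem

Each meiosis places a small number of crossovers on every chromosome.
In a nuclear family genotyped at hundreds of thousands of SNPs those
crossovers are visible as switches in which parental haplotype a child
carries, so dense genotypes of parents and two or more children let us
count and localize recombination events per transmission — one parental
meiosis observed through one child. The scientific question this package
serves is whether the number of crossovers transmitted by a mother
changes with her age at the child's birth, and whether any change is
genome-wide or concentrated on particular chromosomes and chromosomal
regions. Because low recombination predisposes chromosomes to
non-disjunction, and aneuploidy rises steeply with maternal age, the
sign and location of such an effect bears directly on the mechanism of
age-related aneuploidy.

## Crossover calling by sibling comparison

A marker is *informative* for a parent when that parent is heterozygous
and the co-parent homozygous: subtracting the co-parent's contribution
from the child's genotype identifies the transmitted allele. The caller
phases children against the first child (the *reference*): at each
informative marker every other child is in state 1 if it received the
same allele as the reference, state 2 otherwise. A switch between
consecutive informative markers is a crossover in that child, except
that a switch occurring simultaneously in *all* non-reference children
is more parsimoniously a single crossover in the reference child, and is
attributed there. For families of up to four children this rule provably
returns the global minimum-recombinant solution (per inter-marker
interval the attribution realizes `min(k, n − k)` switches, and
intervals are independent); the test suite checks equality against
exhaustive phase enumeration. Total family counts are invariant to which
child serves as reference; only the per-child attribution depends on it.
With exactly two children a switch cannot be assigned to either child,
so two-child families contribute family-level events only and are
excluded from per-transmission analyses.

Three safeguards shape the final counts:

* **Pre-treatment of tight double recombinants.** A single marker whose
  state disagrees with both neighbours implies two crossovers within the
  flanking span; within 1 Mb (about 1 cM at the genomic average) such
  patterns are nearly always genotyping errors, and the same spurious
  marker typically blips in many individuals. The *marker* is removed
  from the track (for all children), not the events: passes run left to
  right, removing every currently flagged marker, and repeat until a
  fixpoint. Removing markers rather than discarding events keeps
  genuinely supported switches (two or more consecutive markers) intact.
* **Unique events only.** Crossovers appearing in two or more children
  at the same inter-marker interval are removed entirely — coincident
  genuine crossovers at marker resolution are far rarer than shared
  artifacts. "Same interval" means the identical flanking-marker pair;
  partial overlap does not trigger removal, since the interval is the
  caller's native resolution.
* **Reduced families.** Removing shared events penalizes large sibships,
  where coincidental sharing is more likely. Families with four or more
  children are therefore partitioned into all `choose(n, 3)` 3-child
  subsets; the full caller (including deduplication, applied within each
  subset) runs on each, and a child's unbiased count is the mean over
  the `choose(n−1, 2)` subsets containing it.

Coordinates are 1-based and intervals closed internally, as in BIM
files; the BED writer converts to 0-based half-open at the boundary and
nowhere else.

## Quality control

`qc_filter()` applies, in order: Mendelian screening over all genotyped
trios (inconsistent child calls are set missing; SNPs inconsistent in
more than one family are removed), a 95% call-rate filter, and an exact
Hardy–Weinberg test at α = 0.01 computed on founders only — children
share alleles with their parents and would distort genotype frequencies.
Masking Mendelian errors before measuring call rates makes the filter
idempotent. Because the caller compares counts *across* families, a
separate filter (`filter_family_missing()`) removes every SNP with a
missing call in any member of any calling-eligible family, so all
families are evaluated on an identical SNP set. Both parents' genotypes
count as "members" here: the informative-marker definition needs the
co-parent's genotype at every evaluated SNP.

## The age statistics

Let `y_ij` be the crossover count of mother `i`'s transmission `j` and
`a_ij` her age at that birth.

* **Family adjustment** subtracts the within-mother mean from both
  variables; the regression of adjusted counts on adjusted ages cannot
  be confounded by differences among mothers (e.g. high-recombining
  mothers having children late). The adjustment is an orthogonal
  projection, so it is idempotent and adjusted group means are exactly
  zero.
* **The mixed model** `y = β₀ + β_age a (+ β_nc n_children) + u_mother + ε`
  (REML, via `lme4`) uses unadjusted values and absorbs mother-level
  correlation into a random intercept. The number-of-children covariate
  guards against the selection effect whereby mothers of large families
  are enriched for high-recombination oocytes.
* **The penalized spline** uses the truncated-line basis
  `(a − κ_j)₊` with a knot at every distinct age except the largest
  (whose basis function is identically zero). Spline coefficients are
  i.i.d. random effects with common variance and a mother random
  intercept is retained; everything is estimated by REML through
  `nlme::lme` with a `pdIdent` structure, and the smoothing parameter is
  reported as `λ = σ²_ε / σ²_u`. As `λ → ∞` the fit collapses to the
  linear mixed model; `spline_predict(fit, ages, lambda = Inf)` exposes
  that limit, and `penalized_spline()` provides the fixed-λ ridge
  solution for direct inspection. The improvement of the spline over the
  line is assessed by a REML likelihood ratio whose null distribution
  comes from permutation — the variance component sits on the boundary
  of its parameter space, so the usual chi-squared reference does not
  apply.

**Permutation conventions.** All permutation p-values use
`p = (b + 1)/(n_perm + 1)`, which is never zero and is exactly uniform
on its discrete grid under the null. Exchangeability units follow the
analysis: ages permuted across transmissions for unadjusted analyses,
within mothers for family-adjusted ones, and children reassigned to
parents (family sizes preserved) for among-parent variation tests.
Two-sided extremeness is measured by absolute value; one-sided variants
are exposed where a direction is pre-specified, and both conventions are
available for the headline regression slope since the choice is a
judgment call.

**Categorical analyses** group ages into under-25, 25–29, 30–34 and 35+
with left-closed bins, so an age of exactly 30 falls in 30–34 and, in
the two-group analyses, a parent of exactly 30 is in the over-30 group.
`round_ages()` reproduces coarse-age designs by rounding *individual*
current ages up to 5-year multiples and differencing, which is why the
simulator carries current ages alongside ages at birth.

## Chromosome-specific effects and genomic position

Per-chromosome counts are normalized by the cohort chromosome means so
shifts are comparable across chromosomes; the under/over-30 shift test
permutes group labels, one-sided for a decrease by default.
`redistribute_simulation()` asks how many chromosomes would reach
per-chromosome significance if the age effect were purely genome-wide:
each transmission's total is reallocated across chromosomes by a
multinomial draw with probabilities proportional to cohort chromosome
means (or uniform), conserving every total exactly, and the shift tests
are rerun per simulated cohort. The closed forms
`sign_test(n, n) = 0.5^n` and
`p_chr = [1 − P(X=0) − P(X=1)]·0.25, X ~ Binomial(22, p)` cover the
remaining-chromosome direction argument and the at-least-two-chromosomes
argument respectively; the 0.25 factor assumes a shift is equally likely
to be positive or negative on each of the two chromosomes.

Event positions along arms use the interval midpoint (the point
representation is a package choice), rescaled to 0 at the centromere and
1 at the telomere of the containing arm; events spanning the centromere
are assigned by midpoint and flagged. Binning uses `floor(rel/width)`
with the last bin closed. Hotspot congruence restricts to events
localized within 30 kb and compares the observed any-overlap fraction
with the interval-dilation expectation
`min(1, Σ_h (len_h + w) / L)` per chromosome — an approximation that
ignores edge effects and is capped at one. No human centromere table
ships with the package: centromere coordinates are assembly-specific
and easy to supply from the UCSC Table Browser as a three-column TSV
(`read_centromeres()`), while the simulator's genomes come with their
own geometry. Shipping a table whose provenance the package cannot
verify seemed worse than requiring one explicit input.

## The non-disjunction protection model

Take an age-invariant distribution `π(r)` of crossover counts among
oocytes and let `P_k(r)` be the probability that an oocyte with `r`
crossovers disjoins properly in age period `k`. Then

* `E_N(k) = Σ r π(r) P_k(r) / Σ π(r) P_k(r)` (normal conceptions),
* `E_A(k) = Σ r π(r)(1 − P_k(r)) / Σ π(r)(1 − P_k(r))` (aneuploid),

and the law of total expectation
`Σ r π(r) = (1 − rate_k) E_N(k) + rate_k E_A(k)` holds identically —
the test suite checks it to 1e-12. Whenever `P_k` is non-decreasing in
`r`, selection implies `E_A(k) ≤ E[π] ≤ E_N(k)`.

A point worth making explicit, because it is easy to get backwards: a
*uniform* weakening of protection with age (all `P_k(r)` scaled down,
or the whole curve shifted) makes selection on the surviving pool
*stronger* and pushes `E_N` up with age. What produces the predicted
signature — `E_N` decreasing while `E_A` increases — is a weakening of
the *selectivity* of protection: the gradient of `P_k` in `r` must
flatten, so that high-crossover oocytes progressively lose their
disjunction advantage. Both conditional means are then squeezed toward
the population mean `E[π]` from opposite sides. The three shipped
presets (`linear` with shrinking slope, `logistic` with widening scale,
`mixture` with a growing admixture of indiscriminate disjunction) all
implement gradient flattening and are verified per-preset by the tests;
`check_monotonicity()` deliberately *reports* rather than asserts the
trends for user-supplied models, since arbitrary `P` matrices need not
produce them.

## The synthetic cohort generator

`simulate_cohort()` draws founder haplotypes from per-SNP allele
frequencies (uniform MAF in a configurable range), then builds each
gamete by drawing a per-chromosome crossover count
`Poisson(max(0, base + slope · age))`, placing crossovers uniformly on
physical distance (optionally, a fraction lands inside supplied hotspot
intervals, length-weighted), and alternating parental haplotypes across
the crossover positions. Genotyping errors are symmetric single-step
code flips (rarely double-step), which is exactly the error mode that
creates the isolated state blips the pre-treatment targets; missingness
is independent per call. Default parameters describe the package's
reference study conditions: 40 nuclear families of three children,
four chromosomes of 150 Mb with 2,000 SNPs each, maternal age at first
birth `N(26, 4)` with 1.5–3.5-year spacing, a maternal slope of −0.5
crossovers/year split evenly across chromosomes (base 6 per chromosome,
so roughly 10 maternal events per meiosis at typical ages), and no
paternal age effect. These sizes keep a full simulate–call–test cycle in
seconds while leaving the slope recoverable within two standard errors,
and they are the sizes the test suite runs at.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: linkage disequilibrium among founder
haplotypes (informative markers are denser and more independent than on
a real array), crossover interference (counts are Poisson, positions
independent), sex-specific genetic maps beyond per-sex base/slope,
population structure, and genotyping error that clusters by probe or
batch. The caller's accuracy on real arrays therefore has to be judged
by its internal consistency checks (call-rate correlations, shared-event
rates) rather than by the simulator alone.

## Numerical and degenerate-input choices

* Genotypes are allele-B dosages 0/1/2 with `NA` for missing — missing
  is never a numeric code. Non-autosomal SNPs are dropped at
  construction.
* The HWE exact test sums conditional probabilities no greater than the
  observed table's, with a `1 + 1e-9` relative guard against ties lost
  to floating point.
* A constant response in the regressions is reported as `r = 0` with a
  `degenerate` flag rather than `NaN`; all-singleton families are an
  error, since family adjustment leaves no information.
* Mixed-model and spline fits that fail to converge return flagged
  results rather than raising, so pipelines over many replicates can
  proceed; the zero-variance boundary is accepted silently (it is the
  correct collapse to ordinary least squares).
* Permutation extremeness comparisons use a relative `1e-12` tolerance
  so ties are counted as "at least as extreme".
* `redistribute_simulation()` guards empty simulated chromosomes (their
  normalized counts are all zero anyway) and asserts total conservation
  on every draw.

## Known limitations

Two-child families are structurally uninformative for per-transmission
counts; gene conversions and crossovers outside the span of informative
markers are invisible; the caller is a parsimony heuristic, not a
probabilistic model, so closely spaced true double crossovers within
the pre-treatment window are removed along with artifacts; and with
five or more children the reference-attribution rule is no longer
guaranteed to be globally minimal (the reduced-family machinery is the
practical answer for large sibships).
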