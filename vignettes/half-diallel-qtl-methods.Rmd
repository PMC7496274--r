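---
title: "Models and methods behind diallelQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind diallelQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelQTL)
```

diallelQTL analyses flavor-trait QTL experiments built on a four-parent
half diallel: four homozygous founder lines (two cherry-type, two
round-type tomato parents), all six pairwise F2 populations, F6
recombinant inbred lines (RILs) derived from some of the crosses by
single-seed descent (SSD), a diversity panel of commercial hybrids, and a
germplasm collection scored for founder haplotypes. This vignette
describes the generative model of the simulator, the three association
models, the haplotype-representation and fine-mapping procedures, and the
numerical and design choices a maintainer would want stated explicitly.

## The simulator

### Meiosis and population development

Gametes are formed under the Haldane model: the number of crossovers per
chromosome is Poisson with mean equal to the chromosome's genetic length
(a uniform rate in cM/Mbp, default 2.0, times physical length), crossover
positions are uniform in physical position, and there is no interference.
The founder origin of every allele is tracked through all generations, so
the encoder, recombinant detection and the rin correction can all be
checked against exact truth.

F2 individuals are selfed F1s; F6 RILs take one selfed seed per line per
generation for four generations (the expected residual heterozygosity per
locus is $(1/2)^5 = 3.125\%$, a property the test suite checks). Founders
are fully homozygous inbreds: the crossed parents are the inbred parents
of commercial hybrids, and residual parental heterozygosity is out of
scope. One parent carries a homozygous ripening-mutation (*rin*) allele;
the mutation is identified with the carrier's alleles at a designated
marker (by default mid-chromosome 5 — a placement convention, not a claim
about the true locus; no test depends on it). When rin selection is
enabled, mutant homozygotes are excluded from SSD entry and the selfing
chain is redrawn from the same F2 plant until the F5 plant is homozygous
wild type, so F6 output contains no mutant carriers.

Founder alleles are drawn i.i.d. per founder with an allele frequency
chosen so each unordered pair of founders differs, in expectation, at a
configurable fraction of markers (default 0.4). Because markers are
biallelic, four founders cannot differ pairwise at a single marker;
requested fractions above one half are therefore realised as balanced 2/2
allele splits, the maximally polymorphic configuration, in which each
pair differs at 2/3 of markers. A consequence worth knowing: a biallelic
marker is informative (parents carry different homozygous alleles) in
either three or four of the six crosses, never in five or six.

### Traits

A trait value is baseline $+$ founder-allelic QTL effects (effect per
inherited allele, per founder) $+$ rin effects (additive code: mutant
dosage $-$ 1; dominance code: heterozygote indicator; both zero outside
carrier crosses) $+$ a per-genotype cross-background draw with a
per-cross SD $+$ a per-observation residual. Metabolite traits are then
exponentiated (base 2) onto a positive abundance scale and multiplied by
a per-trial batch factor. Batch effects are multiplicative on the
abundance scale *by design*, so that log2 transformation followed by
trial-mean centering removes them exactly — the preprocessing the
analysis side applies. Sensory attributes are weighted sums of log2
compound abundances plus noise, through an optional monotone link.

The simulator emulates the statistical structure the analysis assumes —
founder-allelic effects, per-cross background variance, trial batch
factors, SSD genetics. It does not emulate biology it has no model for:
no epistasis, no genotype-by-trial interaction, no metabolic-pathway
constraints between compounds, no panelist-level sensory noise structure.
Green tests therefore certify the machinery under its stated assumptions,
not the behavior of real fruit data.

### Replicates

Whether trait values enter the scan as single-plant values or genotype
means is left open by the design being emulated; the simulator supports
both through a replicates-per-genotype parameter, and the scans aggregate
to genotype means by default before fitting (unweighted means over
non-missing replicates).

## The three association models

### Diversity panel

`scan_dp()` fits ordinary least squares of trait on fruit type plus
marker dosage and t-tests the marker coefficient. Type is coded
two-level, cherry versus round/beef, with a three-level option — the
two-level coding is the default because the contrast that matters for
these panels is cherry against the rest.

### F2 half diallel

`scan_f2()` fits, per marker, a mixed model with a random genotype effect
whose variance is cross-specific (REML), the rin nuisance design, and the
marker term: the $n \times 4$ matrix of parental allele counts. Points
that deserve explanation:

* **Collapsed variance components.** On genotype means every genotype has
  one observation, so per-cross genetic and residual variances are
  jointly unidentifiable; the likelihood's identifiable parameterization
  is a per-cross *total* variance (heteroscedastic GLS). The fit flags
  this with `collapsed = TRUE`. With replicated data both components are
  estimated per cross.
* **Fixed cross intercepts.** The fixed part includes per-cross
  intercepts. This is part of correcting for the genetic background: the
  four parental columns contain between-cross information (a founder's
  column is nonzero only in its own crosses), so without fixed cross
  means, the cross-mean differences produced by a QTL *anywhere* in the
  genome load onto the founder columns of *every* marker and the scan
  loses localization almost entirely. The localization experiment in the
  test suite (a planted +1 SD single-founder QTL, 100 seeded scans of a
  12-chromosome genome) passes only with the cross intercepts present.
  With them, founder effects are identified from within-cross
  segregation, which is the information single-marker interval mapping is
  supposed to use.
* **Sum-to-zero constraint.** The four parental columns sum rowwise to 2
  and are collinear with the intercepts; they enter through a sum-to-zero
  contrast basis. The Wald statistic is invariant to the basis (tested
  against a Helmert basis), so the choice is cosmetic.
* **Wald test with small-sample reference.** The marker term is tested by
  a Wald statistic on its estimable subspace, with degrees of freedom
  equal to the subspace rank (at most 3; less when founders are
  confounded with other terms, e.g. the carrier founder's column at the
  rin locus itself). Because the per-cross variances are estimated from
  roughly 50 genotypes each, the naive Wald-against-chi-square reference
  is mildly anticonservative. The coefficient covariance therefore
  receives the Kackar-Harville correction for estimated variance
  parameters and the statistic is referred to a Kenward-Roger F
  approximation with estimated denominator degrees of freedom; the
  calibration test in the suite (1000 null simulations) checks that the
  resulting empirical size sits in a tight band around the nominal 0.05.
  As the denominator df grow the reference converges to the chi-square.
* **Uninformative markers are skipped per cross** (individuals of crosses
  where the marker's parents share an allele are excluded marker-wise),
  and the effective sample size is reported, rather than imputing origin
  from flanking markers: the model is single-marker by construction, and
  no hidden-Markov reconstruction is attempted.

### F6 RILs

`scan_f6()` fits trait on marker dosage by OLS separately within each
cross (the crosses are heterogeneous and are never pooled), reporting the
within-cross $R^2$ — identical to the squared Pearson correlation — as
explained variance.

### Kruskal-Wallis

`kruskal_wallis_assoc()` wraps the standard tie-corrected H test for the
fine-mapping marker/trait contrasts, with the all-tied degenerate input
mapped to H = 0, P = 1 before the test is attempted.

### Thresholds and the QTL map

Log P is $-\log_{10} P$, capped at 300 to keep machine-zero P values
finite. The map summarization keeps associations with Log P strictly
above 3.5 (no further multiple-testing correction — the fixed threshold
is the convention being reproduced), bins them every 5 Mbp
(bin index $= \lfloor \text{pos}/5\,\text{Mbp} \rfloor$), and reports the
per-trait, per-bin maximum with the contributing crosses.

## Haplotype representation

Region haplotypes are unphased genotype strings (symbols 0/1/2, "." for
missing) over the region's markers. An accession is represented in a
region if its string matches some founder reference string at every
non-missing position: missing positions are wildcards, guarded by a
minimum callable fraction (default 0.8) so matches cannot become vacuous.
Heterozygous symbols match only themselves — the panels contain hybrids,
and with unphased genotypes, exact genotype-string matching is the
reproducible reading; no phase inference is attempted. The marker-missing
filter default (0.23) is set so that attrition of roughly a quarter of
assayed markers — the magnitude such assay panels show in practice — is
representable; the criterion is fully configurable because no specific
value is canonical.

## Fine mapping

Recombinants are individuals whose founder-origin assignment changes
between consecutive informative markers in the region; the breakpoint is
the open interval between those marker positions. Allelic classes of a
family are contrasted by a two-sided t-test by default (Kruskal-Wallis
as the rank-based alternative, matching the test used for such tables).
`refine_interval()` intersects the differential segments of significant
families and subtracts those of non-significant families, with set
semantics (order-independent, tested); contradictions — disjoint
significant segments, an exclusion that empties or splits the interval —
are errors naming the families, never silent guesses. Both refinement
routes (exclusion by non-significant families, or by new recombinants
narrowing the significant segment) are therefore expressible.

Printed Mbp endpoints are interpreted as exact (54.52 Mbp =
54,520,000 bp) and interval width in kbp is the endpoint difference
divided by 1000; BED input/output is 0-based half-open, converted to the
internal 1-based inclusive convention at the boundary and nowhere else.

## Sensory-chemical modelling

Preprocessing replaces zeros by half the compound's minimum positive
value (a choice — the handling of zero abundances is not dictated by
anything upstream), log2-transforms, and centers each compound by its
trial mean on the log scale; dividing by the raw-scale arithmetic trial
mean is available as an alternative. PCA is the singular value
decomposition of the column-centered matrix with per-column mean
imputation of missing cells.

The sensory model is a regression random forest (500 trees by default,
feature subset size $\lfloor p/3 \rfloor$, bootstrap with out-of-bag
tracking). Importance is the increase in out-of-bag MSE after permuting a
compound's out-of-bag values — 500 permutations per tree by default —
standardized by the standard deviation of the per-tree differences;
per-tree averaging precedes standardization, which is the convention of
the reference implementation used (`randomForest`). Directionality is
the sign of the Pearson correlation between compound and attribute on the
preprocessed data.

## Numerical choices

* REML maximizes the restricted likelihood by bounded quasi-Newton
  (L-BFGS-B) over non-negative components, with an analytic gradient in
  the collapsed case (weighted QR plus the envelope theorem) and
  finite differences otherwise. Per-genotype compound-symmetry blocks are
  handled in their eigenbasis (deviation space and mean direction), which
  avoids the catastrophic cancellation a naive
  $X'X - \sum_b s_b s_b'$ formulation suffers when blocks have one
  observation.
* Starting values come from per-cross moments, or from the null-model
  fit when scanning many markers (the fit is refit per marker; only the
  starting values are shared).
* Rank deficiency anywhere in a fixed design is resolved by pivoted QR;
  dropped columns get NA coefficients (the `lm` convention) and tests use
  the estimable subspace with its rank as df.
* A constant response short-circuits to all components at the zero bound,
  an exact OLS fit, and P = 1 for every marker term.
* Degenerate family contrasts (identical constants in both classes)
  return P = 1; distinct constants with zero within-class variance
  return P = 0.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on simulated data
at desk scale, chosen to keep each experiment's Monte-Carlo error well
inside its decision margin: null calibration on 1000 trait simulations
over a fixed 6 x 50 half diallel (180 markers); localization on 100
scans of a 360-marker, 12-chromosome genome (the acceptance script uses
40); SSD physics on 100 RIL lines by 24 loci; haplotype recovery on 500
accessions; forest recovery at n = 273 with 20 compounds and a 200-tree
ensemble (the rank/sign decision is insensitive to ensemble size beyond
this). The emulated array is an order of magnitude denser (thousands of
SNPs); density matters only through inter-marker linkage, and 2-Mbp
spacing at 2 cM/Mbp already gives adjacent-marker recombination
fractions under 8%.

## Known limitations

* The F2 model is single-marker: no composite-interval mapping, no
  kinship matrix, no epistasis scan.
* Germplasm panels are modelled as mixtures of founder and mutated
  haplotypes without population structure; representation estimates on
  structured real panels inherit none of the simulator's guarantees.
* The Kenward-Roger machinery is implemented for the collapsed
  (genotype-means) model; replicated fits fall back to the unadjusted
  chi-square reference.
* Sensory attributes are statistical constructs (weighted log-abundance
  sums); the package deliberately has no model of panelist behavior.
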