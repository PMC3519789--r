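---
title: "Methods behind macromap: statistics of genome macro-structure on genetic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind macromap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macromap)
```

# The setting

Conifer genomes are enormous and, for most species, unsequenced at
chromosome scale; what is available instead is a dense gene-based
genetic linkage map: a thousand or more expressed genes placed at
centiMorgan positions on twelve linkage groups. `macromap` implements
the statistics that turn such a map — together with per-family
bootstrap consensus gene trees and cross-species homology tables —
into statements about genome macro-structure: whether genes cluster,
where the gene-rich regions are, how gene families disperse over
chromosomes, which gene duplications predate the split of gymnosperms
from angiosperms (the GA split, roughly 300 Mya), and how much of the
genome's gene order is conserved between two genera.

Every analysis in the package works on the same data model: a
`genetic_map` is a set of linkage groups with lengths in cM carrying
loci on the half-open interval $[0, L)$; ties in position are allowed
and meaningful (loci with no observed recombinants print at identical
positions). A seeded generator module produces every input the
pipeline consumes, with recorded ground truth, so each stage can be
validated end to end.

# Uniformity of gene distribution

For each chromosome of length $L$ with $n$ mapped genes, the
Kolmogorov–Smirnov statistic

$$D_n = \sup_x \lvert F_n(x) - x/L \rvert$$

is evaluated on both sides of every jump of the empirical CDF $F_n$
(the supremum against a continuous null is attained at a jump; ties
contribute multiple steps). Because critical values of $D_n$ depend on
$n$, the test uses the rescaled statistic

$$D^*_n = D_n\,(\sqrt{n} - 0.01 + 0.85/\sqrt{n}),$$

whose critical values are sample-size free: 0.775 (15%), 0.819 (10%),
0.895 (5%), 0.955 (2.5%), 1.035 (1%). `modified_ks_test()` reports the
tightest band reached; exact finite-sample p-values are deliberately
out of scope.

**A calibration caveat that users should know.** This multiplier and
critical table belong to the estimated-parameter (Lilliefors-type)
family of modified statistics. Against a *fully specified* uniform
null they are markedly anticonservative: in simulation, about 40% of
uniform chromosomes with $n = 150$ exceed the 0.895 value, whereas the
true 5% point of $D^*_n$ under that null is near 1.36. The package
implements the rescaling and critical table exactly as published for
this analysis — the bundled per-chromosome summary reproduces the
published $D^*_n$ column from $(n, D_n)$ to about $10^{-3}$ on most
chromosomes — but significance bands from `uniformity_test()` should
be read as the method's convention, not as calibrated uniform-null
error rates.

# Gene density and gene-rich regions

`adaptive_density()` estimates the gene density per chromosome with a
two-stage adaptive kernel. A Gaussian pilot estimate with Silverman's
rule-of-thumb bandwidth $h = 0.9\,\min(\hat\sigma,
\mathrm{IQR}/1.349)\, n^{-1/5}$ is evaluated at the data points; local
bandwidth factors

$$\lambda_i = \left( g / \tilde f(x_i) \right)^{1/2}, \qquad
g = \text{geometric mean of } \tilde f(x_i)$$

widen the kernel where genes are sparse and narrow it where they are
dense. The final estimate is $\hat f(x) = n^{-1}\sum_i
K_{h\lambda_i}(x - x_i)$ with reflection of every kernel at both
chromosome ends (0 and $L$), which conserves unit mass on the
chromosome (the trapezoid integral is checked to within 0.01 in the
tests) and removes the downward bias that otherwise suppresses
detection near the ends. A pointwise variability band at level
$\alpha$ uses the sample variance of the per-locus kernel
contributions,

$$\hat V(x) = \frac{1}{n(n-1)} \sum_i \big(K_i(x) - \hat f(x)\big)^2,
\qquad \hat f(x) \pm z_{1-\alpha/2}\sqrt{\hat V(x)}.$$

A **gene-rich region** (GRR) is a maximal interval where the lower
band limit exceeds the uniform density $1/L$; `call_grrs()` refines
the interval ends by linear interpolation between grid points
(default grid step 0.1 cM) and reports the member gene count and
genes/cM. Chromosomes are tested independently at fixed $\alpha$; no
genome-wide multiplicity correction is applied.

Properties worth knowing, all exercised by the test suite:

* calls at $\alpha = 0.01$ are interval subsets of calls at
  $\alpha = 0.05$;
* at the map sizes this analysis targets (roughly 130–180 genes per
  chromosome), fewer than 10% of uniform chromosomes yield any call at
  $\alpha = 0.01$, while planted clusters at enrichment factor 4 are
  recovered in over 95% of replicates;
* the band is a sampling-variability band around the estimator's
  mean, not a bias-corrected confidence band: when $n$ grows toward a
  thousand loci per chromosome the band tightens faster than the
  smoothing bias shrinks and false calls become common (about 18% in
  simulation at $n = 1000$). The defaults are therefore appropriate
  for maps of the density this package addresses, not for arbitrarily
  dense ones;
* call boundaries extend roughly one pilot bandwidth beyond a planted
  cluster, so the within-call density understates the true enrichment
  of clusters much narrower than the bandwidth.

# Tandem arrays and family dispersion

`detect_tags()` chains same-family loci on a chromosome by single
linkage with a 5 cM gap cap; chains of two or more loci are tandem
arrays (TAGs), classed `"1cM"` when every consecutive gap is at most
1 cM. Single-linkage chaining was chosen over a span cap so that array
membership does not depend on traversal order.

`permute_family_dispersion()` asks whether families occupy fewer
chromosomes than chance predicts. The observed statistic tallies
families by the number of distinct chromosomes their members occupy
($k = 1..C$). The null redistributes the family members over the
positions of *all* mapped loci (so chromosome occupancy follows the
realized per-chromosome locus counts), re-tallying over $R$ replicates
(default 1000). The chi-square compares observed to mean simulated
category counts; categories with simulated expectation below 1 are
pooled into the adjacent lower category before summation, and the
degrees of freedom are reported as $C - 1$. Each family also gets an
empirical $p$: the fraction of replicates whose simulated chromosome
count is at most the observed one; families at $p \le 0.05$ are
flagged as concentrated.

One structural fact shapes both the generator and the interpretation:
with $C = 12$ chromosomes a two-member family on one chromosome can
never be flagged, because its null probability of landing on a single
chromosome is about $1/12 > 0.05$. Concentration is detectable only
from three members up, which is why the generator's planted
concentrated families carry at least three members.

# Dating duplications against the GA split

Trees arrive as Newick with bootstrap supports on internal nodes and
leaves classified by label prefix (defaults: `Pg` focal gymnosperm,
`Pt` other gymnosperm, `AT`/`Os` angiosperm). Internally a tree is its
set of non-trivial bipartitions, each represented by the leaf side not
containing the first (sorted) label — under this canonical form two
splits are compatible exactly when they nest or are disjoint, which
reduces consensus to set algebra: `majority_rule_consensus()` keeps
the splits present in strictly more than half of the inputs (annotated
with their percentage), `strict_consensus()` intersects two split
sets, and `collapse_splits()` removes splits below a support
threshold. Both consensus operations are verified in the tests against
independent bipartition enumeration of the same trees.

`classify_pair_age()` implements the temporal logic. After collapsing
splits below 50% support (configurable), the tree is rooted on the
lexicographically smallest angiosperm leaf — a deterministic
convention; a property test re-roots on every angiosperm leaf and
checks that recent/ancient calls never change (only
polytomy-ambiguous cases may). For the most recent common ancestor
(MRCA) clade of the two focal genes:

* no angiosperm leaf inside the clade → **recent** (the duplication
  postdates the GA split: no angiosperm lineage intervenes);
* an angiosperm inside the MRCA child holding either gene, or a
  binary MRCA → **ancient**;
* a multifurcate MRCA whose angiosperm leaves all sit in *other*
  children → **undetermined** (the polytomy withholds the placement;
  lack of support is never resolved in favour of either age).

Other-gymnosperm (pine) leaves are neutral throughout: they can never
make a pair ancient. A tree with no angiosperm leaf is an error — the
family is not anchored to the GA reference. One bias is accepted
knowingly: an ancient duplicate lost independently in both sampled
angiosperm lineages would masquerade as recent; with two divergent
angiosperm genomes sampled this is rare, and it would only deflate the
ancient:recent ratio, which the analysis already finds heavily skewed
toward ancient.

`classify_families()` classifies every within-family pair of mapped
focal genes independently on the NJ and MP consensus trees; the final
label is the shared one, else `incongruent` (also when a gene is
missing from one tree). Tallies obey two identities checked in the
tests: ancient + recent + undetermined = congruent, and congruent +
incongruent = total. The strict consensus tree is emitted per family
as an artifact.

`duplicate_distance_stats()` then combines age labels with map
positions: same-chromosome versus translocated counts per age class,
each tested against a 50:50 expectation with a Pearson chi-square
(`equal_expected_chisq()`; this equal-expectation null exactly
reproduces the published statistics from the published counts, which
is why it was adopted), same-chromosome cM distances with class means,
and a Welch two-sample $t$ (unequal variances, Welch–Satterthwaite
df) comparing the recent and ancient distance sets.

# Two-map synteny and collinearity

`reciprocal_best_hits()` resolves orthology from BLAST-tabular hit
tables: a pair survives when each gene is the other's best hit at or
above 80% identity, with a fully deterministic ordering key (bitscore,
then identity, then subject id) that makes the output one-to-one and
symmetric in its inputs. `synteny_links()` pairs chromosomes by
plurality of links (homoeologs) and marks links syntenic when they
connect a homoeologous pair. `collinearity()` defines the collinear
subset as a longest nondecreasing subsequence of map-B positions after
sorting by map-A position — ties in either coordinate are compatible,
so co-segregating loci never break collinearity — with an
orientation-aware option that accepts the better of the forward and
reverse directions (a wholly inverted chromosome conserves order).
The LIS is checked against exhaustive search in the tests.
`conserved_segments()` groups collinear links into maximal runs with
inter-link gaps of at most 20 cM (configurable) on both maps; coverage
percentages are sums of segment spans over total map length and are
therefore properties of the gap-cap configuration, not
parameter-free quantities.

# The synthetic scenario and what it does (not) show

`scenario_config()` fixes the study conditions the generators emulate:
twelve chromosomes with the published composite-map lengths
(120.4–204.5 cM), about 150 genes per chromosome, 157 gene families
with sizes $2 + \mathrm{Geom}(0.42)$ (mean ≈ 3.4, matching 527 genes
in 157 families), a fraction 8/9 of duplication events predating the
GA split, translocation probabilities 0.919 (ancient) and 0.425
(recent), and same-chromosome offset distributions that are
exponential with means 47.0 cM (ancient) and 4.3 cM (recent),
truncated at the chromosome length. The truncation matters: an
exponential with mean 47 on a 120–205 cM chromosome realises a mean
3–5 cM lower, and recovery tests allow for exactly that analytic bias.

`simulate_family_trees()` builds each family's history by sequential
coalescence of the focal gene copies — recent joins first, then
ancient — and attaches, to every lineage crossing the GA split, a pine
sister leaf and an angiosperm cherry. This construction makes the true
age of every pair's MRCA known, and makes ancient duplications carry
intervening angiosperm lineages by construction. Emitted NJ-like and
MP-like trees are two independently degraded copies of the truth
(random NNI moves, random split collapsing), with support 100 on
retained splits. With zero noise, the classifier recovers 100% of the
true labels; under collapsing noise, the undetermined + incongruent
fraction rises, as it should.

Synthetic data deliberately omits several features of real inputs:
no sequence evolution or alignment error behind the hit identities
(they are drawn from a truncated normal around 92%), no real
bootstrap variation (supports are 0/100 after noise), no map-order
error beyond Gaussian jitter, no gene loss in the angiosperm lineages
by default (so ancient labels stay identifiable; a loss probability
would reintroduce the masquerading bias discussed above), and no
linkage-map estimation at all — marker ordering is taken as given.
Passing the recovery tests therefore demonstrates the correctness of
the statistical chain on well-posed inputs, not robustness to
upstream mapping or alignment artifacts.

Pair-level and event-level quantities differ in multi-gene families:
all $\binom{k}{2}$ within-family pairs are classified, and most pairs
in a large family cross an ancient node, so the pair-level
ancient:recent ratio exceeds the event-level 8:1 under the default
sizes. Validation of event-level parameters (translocation rates,
distance means) therefore uses two-member families, where pairs and
events coincide.

# Numerical conventions

* Positions are 0-based cM floats; ties allowed everywhere.
* Default thresholds: 50% support collapse before dating, 80% RBH
  identity, 1/5 cM TAG windows, 1000 permutation replicates, 0.1 cM
  density grid, 20 cM segment gap cap.
* Every stochastic routine takes or requires a seed; generators are
  pure functions of their configuration, and pipeline reruns with the
  same configuration and seed are byte-identical.
* Co-localization groups default to exact position ties
  (`epsilon = 0`); a tolerance can be supplied, in which case maximal
  groups may overlap. Co-expression flags use one-sided positive
  Pearson correlation by default (co-regulation, not anti-regulation),
  with a two-sided switch. Enrichment uses two-sided Fisher tests with
  Benjamini–Hochberg FDR.
* Donor-map loci are transferred onto the reference map only inside
  their flanking-anchor span (midpoint rule; no extrapolation), and an
  inconsistent anchor order between maps is an error for that
  chromosome, not silently reordered.
* Test-suite problem sizes: 100-replicate calibration and power runs
  for the density caller at $n = 150$–240 loci per chromosome,
  1000-replicate uniformity calibration at $n = 150$, 600 two-member
  families for parameter recovery, and 150-gene map pairs for synteny
  — sizes chosen to keep Monte-Carlo error well below the asserted
  tolerances.
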