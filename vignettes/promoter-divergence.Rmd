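---
title: "Promoter-architecture divergence and duplicate retention: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-architecture divergence and duplicate retention: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdiv)
```

# The question

After a gene duplication, two models dominate explanations of why both
copies survive. Under duplication–degeneration–complementation (DDC), each
paralog loses a complementary subset of the ancestral regulatory modules,
so both are needed to cover the ancestral expression domain; the paralogs'
promoters should then look like degenerate subsets of one ancestral
promoter and remain partly similar. Under regulatory neo-functionalization,
one paralog acquires a new expression site through a new promoter
architecture; its promoter should look unlike its relatives', be improbable
as a chance arrangement of binding sites, and drive expression in a domain
the ancestor never had. `promdiv` implements the quantitative apparatus for
telling these apart from promoter architectures (ChIP-seq binding
repertoires around transcription start sites), CAGE-style expression
matrices, gene-order conservation, and published codon-model likelihoods.

# Promoter architectures

## Windows

A promoter window is a fixed-width interval centred on the midpoint of a
CAGE TSS cluster: `[m - h, m + h)` with `m = floor((start + end) / 2)` and
halfwidth `h = 3000` by default, i.e. 6-kb windows. Windows are
strand-agnostic; the published reference windows for the roundabout
promoters are symmetric spans around their 1-kb clusters regardless of
strand, and `build_promoter_windows()` reproduces them (one printed window
start is 45 bp off the midpoint rule and is treated as a typo). All
internal coordinates are 0-based half-open; the in-built fixture tables
store the printed assembly coordinates unmodified and interpret them as
half-open spans, which makes the printed cluster width exactly 1000 and
window width exactly 6000 and reproduces the printed window arithmetic
exactly. An asymmetric `upstream_only` mode (the full `2h` span upstream of
the midpoint by strand) supports promoter-proximal scans of the kind used
when focusing on one cell type. Windows are clamped to `[0,
contig_length)` when contig lengths are supplied.

## Strength split and assembly

ENCODE-style quality scores (0–1000) split peaks at a strict cutoff:
strong iff `QS > 500`; a peak exactly at the cutoff is weak. Peaks are
assigned to windows by half-open interval overlap of at least one base on
the same chromosome (`IRanges::findOverlaps`; intersectBed semantics, so a
boundary-spanning peak counts fully and no fractional weighting is
applied). A peak overlapping two windows counts once in each. Polymerase II
peaks are excluded by a configurable blacklist (default `POLR2A`) because
their counts track expression level trivially. Duplicate identical records
are kept unless `dedupe = TRUE`: merged multi-cell-line tracks legitimately
repeat TF/interval combinations, and how the upstream merge collapsed
replicates is not recoverable, so deduplication is the user's call.

## Encodings

The TF panel — the dimension set of all vector encodings — is a property of
the dataset, not the method: it defaults to the distinct TFs observed in
the peak file and is configurable (161 TFs in the emulated resource). Count
vectors include strong and weak peaks by default; binary vectors are their
0/1 collapse. Set-level reports ("strong architectures") use strong peaks
only. These defaults reflect that distance comparisons are better powered
by counts, while the probability model and Venn-style reports are defined
on presence/absence. The published average-distance figures for the
roundabout promoters are not exactly recoverable from the published
strong-site lists alone (they almost certainly encode peak counts that the
printed tables do not carry), so both encodings are exposed and neither is
asserted to reproduce those figures.

# Comparing architectures

Manhattan distance is the workhorse: on count vectors it sums per-TF count
differences; on binary vectors it equals the symmetric-difference
cardinality, so it stays small for small architectures (unlike the Jaccard
index, which can be large for single-element differences between small
sets — both are provided). A worked identity used in testing: two
two-element sets sharing one element have Jaccard index 1/3 and binary
Manhattan distance 2. `background_distances()` enumerates all pairwise
distances, or samples unordered pairs uniformly without replacement under a
seed when the pair count is genome-scale (hundreds of millions) —
identical expectation at desk-scale cost. Group comparisons use the
Wilcoxon–Mann–Whitney test: exact enumeration when both groups have at
most 8 values, otherwise the normal approximation with continuity and tie
correction (the variant is not dictated by the source analysis, which
names only the test). Fully tied comparisons return P = 1.

# The architecture probability model

Each TF is a Bernoulli variable with marginal `p_k` = fraction of
promoters binding it. Under independence, a binary architecture has
expected probability

$$P_E = \prod_{k\ \mathrm{present}} p_k \times \prod_{k\ \mathrm{absent}} (1 - p_k),$$

which normalises to 1 over the `2^n` architecture space (asserted to
1e-12 on a 10-TF panel in the tests). The observed probability `P_O` is
the exact-match frequency of the binary pattern among all promoters, and
`P_O / P_E` measures enrichment of the TF combination over chance. A zero
`P_E` with positive `P_O` — possible when marginals are supplied
externally — is reported as infinite enrichment with a flag rather than an
error. Architecture-size summaries use the Fisher–Pearson moment
coefficient of skewness and excess kurtosis (e1071 type 1); the convention
behind the published moments is unstated, so ours is documented rather
than matched.

# Co-expression statistics

Correlations are Pearson product-moment coefficients on raw TPM (no
transform by default; `log1p` is available). The asymptotic P-value is the
two-sided t tail of `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
freedom — trustworthy only under normality, which heavy-tailed CAGE data
violate; hence the randomization test. The null is built by permuting each
library's values across TSSes (independently per library, destroying
inter-row correlation but preserving each library's value distribution;
a shared-permutation variant is behind a flag), then pooling the Pearson
correlations of all unordered pairs inside a fresh random row subset, for
1000 permutations of subsets of 1000 by default. The empirical P-value is
one-sided in the direction of the observed deviation from the null median
— the lower-tail fraction for observations below the median, its
complement above — because both strongly negative and strongly positive
correlations are of interest. The raw fraction is reported without a
pseudocount, so an observation outside the null range gives an exact 0;
the `(r+1)/(N+1)` estimator is available as an option. Under a null
generator this P-value is approximately Uniform(0, 0.5), which the test
suite checks with a Kolmogorov–Smirnov test at alpha = 0.01 over 200
replicates (null built at 100 permutations of 100-row subsets over 100
libraries — sizes chosen to keep the default suite fast while leaving the
calibration check well powered).

Maximal expression (ME) is the highest TPM a TSS attains in any library
(ties take the first library in column order and are flagged); a promoter
region is called conserved when its ME strictly exceeds the 10-TPM
expressed-gene cutoff. Group enrichment is the ratio of mean in-group to
mean out-group expression; enrichment ranks use competition ranking (ties
share the minimum rank) with percentile `1 - (rank - 1)/N`. The rank-sum
enrichment z-score is `(U - mu_U)/sigma_U` with tie-corrected variance,
positive when the category ranks higher; how the original analysis handled
overlapping ontology categories is unstated, so categories are treated as
a flat list, scored one at a time.

# DDC simulations

Both simulators start from the merged ancestral promoter of a paralog
pair. The independent-site model keeps the union of the TF sets; each of
two descendant copies loses uniformly random TFs one at a time until its
cardinality is at most the corresponding observed paralog's TF-set size
(sequential loss is equivalent to keeping a uniform random subset, which
is unit-tested against an exhaustive enumeration oracle). The
clustered-site model keeps the sites' window-relative coordinates on a
simulated 6-kb region and erodes each descendant with cumulative random
100-bp deletions (start uniform, positions on the original coordinate
system, overlapping deletions allowed, any one-base overlap destroys a
site) until the distinct-TF count reaches the target — so co-located sites
are lost together, as they would be on real DNA. Descendants are fully
independent (whether they might share pre-divergence deletions is
unknowable; the independent reading matches the first model's structure).
Stopping uses distinct-TF cardinality, not site count, because the
observed paralog quantities are TF-set sizes. The empirical P-value is the
fraction of runs whose descendant intersection is at most the observed
shared count; it is non-decreasing in the observation by construction. An
unreachable target (a TF with sites everywhere) aborts a run with a
diagnostic after a cycle cap rather than looping forever.

# Synteny conservation

Human gene pairs are all unordered same-chromosome pairs with
transcription starts strictly less than 100 kb apart; the start is
strand-aware (5' end) by default since "gene start" is otherwise
ambiguous, with a leftmost-coordinate mode available. The same-chromosome
requirement is imposed explicitly (a start-distance criterion is
meaningless across chromosomes). A pair is conserved in a species iff both
members have one-to-one orthologs there, on one chromosome, with starts
strictly within 200 kb. Both thresholds are strict and boundary cases are
unit-tested; conservation is symmetric in the pair and monotone in the
span. Arrangements (tail-to-tail, head-to-head, co-oriented) are reported
but never filtered on, since whether the original pairing implied an
orientation constraint is unstated.

# Selection support

The likelihood-ratio statistic `2(l_alt - l_null)` is always computed from
the supplied log-likelihoods, never taken from a published table; where a
published statistic is supplied it is cross-checked and flagged when
discrepant (one published roundabout entry disagrees with its own
likelihoods by a factor of two, and one printed P-value does not match the
chi-square tail of its own statistic — the recomputed values are
reported). The alternative must strictly nest the null; negative
statistics within numerical tolerance clamp to zero with a warning.
P-values are upper chi-square tails with df equal to the parameter-count
difference. Positively selected sites are those with BEB posterior
strictly above 0.95 by default.

# The synthetic-data generators

The generators emulate the statistical structure of the real resources so
that every stage runs, and every estimator can be checked against known
truth, without downloads. Defaults are the study conditions of the
emulated data: a 161-TF panel (the fixture TF symbols padded with
`TFnnn` fillers, so fixtures and synthetic data share a namespace), 513
libraries of which 28 are endothelial, a 98-fold implanted endothelial
enrichment, implanted latent correlations of 0.3/0.7/0.87, and a 7-species
synteny scenario with conservation probability 0.6. Where the source
states no value we fixed one realistic choice: per-TF marginals follow a
deterministic heavy-tailed profile (`k^-0.8`, rescaled to a mean
architecture size of 9.2 TFs — matching the reported mean — and capped at
0.95); background TPM is log-normal (meanlog `log 5`, sdlog 1), chosen
because CAGE TPM distributions are heavy-tailed — a generator assumption,
not a claim about the real atlas; 30% of peaks are strong; present TFs
carry `1 + Poisson(0.5)` peaks of width 200 at uniform window positions.
Correlated TSS pairs are built from a shared latent Gaussian factor
(`sqrt(rho) z + sqrt(1-rho) e`), affine-scaled into a positive TPM range
so the Pearson correlation survives.

What the generators do **not** emulate: real genomic sequence and peak
shape, the ontology hierarchy behind library categories (a flat label list
stands in), inter-TF binding correlations (synthetic presence is
independent per TF, which is exactly what makes the probability model's
calibration checkable), library-specific depth effects, and assembly
artefacts. Passing tests on synthetic data therefore demonstrate that the
estimators recover known truth under the stated statistical structure —
not that real data satisfy that structure.

# Numerical conventions and degenerate inputs

All intervals are 0-based half-open and lengths are always `end - start`.
Strictness at thresholds: strong is `QS > 500`, expressed is `ME > 10`,
pairing is `gap < 100000`, conservation is `span < 200000`, selected is
`BEB > 0.95`. Empty-vs-empty Jaccard is 1 (identical sets at distance
zero). Zero-variance profiles make correlation an error, not NA. The
empty architecture is a legal all-zero vector. Seeds: every stochastic
function takes an explicit seed; `run_pipeline()` derives per-stage
substreams from one master seed so toggling one stage never changes
another's results.

# Problem sizes used in the checks

The packaged checks run at desk scale by choice: the set-level and
window-arithmetic reproductions are exact and instantaneous; the
enumeration-oracle comparison for the independent-loss law uses ancestral
sets of six TFs at 20,000 runs; randomization-P calibration uses 200
replicates against a null of 100 permutations of 100-row subsets;
parameter-recovery checks use 500 libraries, 2,000 promoters, and 500
synteny pairs. These sizes give the assertions comfortable statistical
power while keeping the default suite under half a minute.

# Known limitations

The architecture probability model assumes site independence; real TF
co-binding violates it, which is precisely why `P_O / P_E` is informative
but also why `P_E` should not be read as a calibrated probability. The
randomization null conditions on the observed value distributions per
library; it does not model library-specific technical noise. The DDC
simulators model loss only — no site gain, turnover, or selection — so
they bound the sub-functionalization hypothesis, not the full history.
The synteny rule uses gene starts only and ignores intervening
rearrangements. Published-likelihood arithmetic inherits whatever
optimisation error the upstream codon-model fits carried.
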