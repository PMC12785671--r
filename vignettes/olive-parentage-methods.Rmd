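---
title: "Kinship and parentage inference from codominant SSR genotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship and parentage inference from codominant SSR genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivekin)
```

## The problem

Many clonally propagated crop cultivars — olive prominently among them —
arose from open pollination or assumed self-pollination, so their paternal
parent is unknown. Given a panel of cultivars genotyped at a dozen
multi-allelic codominant loci (microsatellites and indels, scored as two
allele fragment lengths in bp per individual), the question "who is the
father of cultivar X, given its known mother?" can be answered by
combining three lines of evidence:

1. **genetic distance and clustering** to shortlist candidates,
2. **pairwise relatedness** ($r$) to quantify kinship for every dyad, and
3. **Mendelian trio compatibility** plus **self-incompatibility (SI)
   group logic** to confirm or exclude specific candidates.

`olivekin` implements that chain end to end, together with a pedigree
simulator that provides exact ground truth for validating every stage.

## Genotype model and allele frequencies

A `genotype_table` stores two allele-length matrices in canonical
(non-decreasing) order per call; a call is either fully scored or fully
missing (half-calls are rejected at input). Allele identity is exact
integer bp — the package assumes fragment sizes were validated and binned
upstream, as is standard for curated SSR reference panels. Missing data
are written as `0` on disk (the GenAlEx convention) and handled by
per-locus pairwise deletion throughout: a locus missing in either member
of a comparison is dropped from that comparison only, and reports carry
the number of loci actually used so low-overlap results remain visible.

Allele frequencies are plain counts over scored samples,
$p_a = n_a / 2N_\text{scored}$. By default the focal dyad is included in
the counts (the behaviour of the common relatedness tools); an
`exclude_focal` switch re-estimates per dyad without the pair.

## Genetic distance, trees, bootstrap

The codominant distance encodes each single-locus genotype as an
allele-count vector $x$ (entries 0/1/2) and sums
$d^2_\ell = \tfrac12\sum_a (x_a - y_a)^2$ over scored loci, giving the
per-locus values 0, 1, 2, 3, 4 familiar from GenAlEx-style analyses.
Neighbour-joining uses the Saitou–Nei criterion (via `ape`); negative
branch lengths, which NJ can produce on non-additive input, are clamped to
zero with the deficit moved to the sister edge. UPGMA and Ward trees are
average-linkage and minimum-variance agglomerations (`hclust`, methods
`average` and `ward.D2`); ties in any merge criterion resolve to the
lowest-index pair, which makes all tree outputs deterministic. Bootstrap
support resamples **loci** with replacement — the natural resampling unit
for a multilocus distance tree — rebuilds the tree per replicate, and
annotates each internal bipartition of the full-data tree with its
replicate percentage.

Newick serialisation quotes labels containing spaces or syntax characters
(`'Ascolana Tenera'`). The writer is implemented in the package because
the stock `ape` serialiser substitutes underscores for spaces, which would
break round-tripping of cultivar names.

## Pairwise relatedness

Relatedness is parameterised by the IBD coefficients $(k_0, k_1, k_2)$ —
the probabilities that a non-inbred dyad shares 0, 1 or 2 alleles
identical by descent at a locus — with $r = k_1/2 + k_2$. Expected values
are 0.5 for parent–offspring and full sibs, 0.25 for half sibs and
avuncular pairs, 0.125 for first cousins, 1 for clones.

Three estimators are provided:

* **Queller–Goodnight moment estimator** (`moment_r`): the multilocus
  ratio-of-sums form, symmetrised by averaging the two reference
  orientations. It is unbiased but unbounded; out-of-range estimates are
  reported untruncated and flagged. On very small panels (e.g. a 4-sample
  table) its frequency denominators are noisy and values can be strongly
  negative — it is a tie-breaker there, not evidence.
* **Dyadic maximum likelihood** (`dyadic_ml_r`): maximises
  $\sum_\ell \log P(g_1, g_2 \mid k)$ over the $(k_0,k_1,k_2)$ simplex,
  where the single-locus kernel is
  $P = k_2 P_2 + k_1 P_1 + k_0 P_0$ with $P_0 = P(g_1)P(g_2)$,
  $P_2 = P(g_1)\,[g_1{=}g_2]$, and $P_1$ the standard one-shared-allele
  configuration probabilities under Hardy–Weinberg
  ($(ii,ii) \to p_i^3$; $(ii,ij) \to p_i^2 p_j$;
  $(ij,ij) \to p_i p_j (p_i+p_j)$; $(ij,ik) \to p_i p_j p_k$; else 0).
  The kernel sums to 1 over all genotype pairs for any $k$ on the
  simplex, which the test suite verifies by exhaustive enumeration. The
  optimiser is a dense simplex grid (step 0.01) followed by Nelder–Mead
  refinement on a softmax reparameterisation (relative tolerance
  $10^{-8}$); the grid guarantees the global optimum to 0.01 before
  refinement, which matters because the likelihood can be bimodal at few
  loci. Inbreeding is assumed absent (3-state rather than 9-state
  identity modes): the intended use is cultivar panels where selfing is
  blocked by self-incompatibility; a 9-state extension is a documented
  extension point, not implemented.
* **Triadic reference mode** (`triadic_ml_r`): in the spirit of
  triadic-likelihood estimation, each of `n_refs` randomly drawn
  reference individuals is used to stabilise the information entering the
  dyadic fit: the reference's alleles are folded into the allele-frequency
  estimate ($p' = (2Np + c_\text{ref})/(2N+2)$ per locus) and the dyadic
  ML fit repeated; per-reference estimates are combined by a
  likelihood-weighted mean and constrained to $[0,1]$. This is a
  deliberate, documented simplification of the full seven-state triad
  likelihood: the reference enters through the frequency model rather
  than through joint triad IBD modes. An entirely missing reference
  leaves the frequencies untouched, so the mode reduces exactly to the
  dyadic fit — a contract the tests assert to $10^{-9}$. Reference draws
  for per-reference fits use the grid without Nelder–Mead refinement
  (0.01 resolution), which keeps a 100-reference estimate at ~0.1 s.

Confidence intervals are percentile intervals over loci resampled with
replacement (default 1000 replicates). With 12 loci such intervals are
wide and their coverage approximate — they quantify marker sampling noise,
not frequency-estimation noise.

**Known accuracy at panel scale.** Across 500 simulated parent–offspring
dyads at 12 loci in 100-founder panels the dyadic ML mean is close to 0.5
with a small positive bias (≈ +0.02, SD ≈ 0.04 per dyad), driven by
estimating allele frequencies from the same ~100-sample panel and by the
$[0,1]$ truncation. At 100 loci the mean absolute bias across true
$r \in \{0, 0.125, 0.25, 0.5\}$ is ≈ 0.01. The validation driver
`analysis/05_estimator_validation.R` recomputes both tables.

## Kinship categories

Dyads are binned into six categories ordered by expected $r$: unrelated,
second cousins, first cousins, half-sib/uncle/grandparent, parent–child or
full sibs, and identity (clones). The default cut points
$(0.016, 0.078, 0.1875, 0.39, 0.75)$ are midpoints between the canonical
expectations $(0, 1/32, 1/8, 1/4, 1/2, 1)$, except that the fourth cut is
raised from 0.375 to 0.39: empirical collections show half-sib-class
dyads up to $r \approx 0.379$ and parent–child-class dyads from
$r \approx 0.4003$, and the default respects both observed ranges.
Intervals are half-open, closed on the left, so classification is
deterministic at boundaries; thresholds are fully configurable because
published analyses rarely print their cut points. Percentages in category
summaries are rounded **half-up** to two decimals, matching how such
tables are conventionally reported (`round()`'s half-to-even rule does
not reproduce them).

Estimates near a cut point classify noisily — at 100 loci the unrelated /
second-cousin boundary (0.016) is within one standard error of a true-zero
estimate — so categories are descriptive summaries, not tests.

## Parentage testing

A locus is **trio-compatible** when some ordering of the offspring's two
alleles puts one in the mother's genotype and the other in the father's
(ordered-assignment semantics: one allele inherited from each parent, not
mere set coverage). The implementation is verified against brute-force
enumeration of the four possible transmissions over all genotype
combinations on four alleles. Missing loci are skipped, never counted as
mismatches. Offspring alleles found in neither parent are reported as
*orphan alleles* — candidate mutations, genotyping errors, or evidence of
wrong parentage.

The candidate scan tests every possible father (or every parent pair when
no mother is known) and tolerates `max_mismatch` mismatching loci,
defaulting to 1: a single-locus incompatibility in an otherwise perfect
trio is the signature of a sporadic microsatellite mutation, and rejecting
such trios outright would discard true parents. Ranking is by SI
exclusion, then mismatch count, then relatedness (tie-breaker only — no
likelihood-ratio paternity score is computed; that is out of scope), then
id. SI-excluded candidates are retained and flagged rather than silently
dropped, so the report shows *why* a genetically compatible candidate is
rejected.

## Self-incompatibility model

Olive SI is diallelic sporophytic: one S locus, two alleles, S2 dominant
over S1, giving phenotype groups G1 (S1S2) and G2 (S1S1); crosses fail
within a group and succeed between groups. A candidate father in the
mother's group is therefore excluded outright, while the offspring's own
group never excludes a legitimate between-group cross (both offspring
groups arise from any compatible mating). The S2S2 genotype, not observed
in the field, is mapped to G1 by dominance and can only be produced under
the pseudo-self-compatibility switch in simulations; no default
pseudo-selfing rate is claimed because none is established.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws founder allele frequencies from a symmetric
Dirichlet (concentration 1 by default) over 2–10 alleles per locus placed
on a dinucleotide grid between 120 and 470 bp, genotypes founders under
Hardy–Weinberg, and gene-drops alleles through scenario pedigrees under
SI-constrained matings. Transmitted alleles mutate stepwise (±1 motif
step, reflecting at the range bounds) at $\mu = 10^{-3}$ per allele per
meiosis by default — a conventional microsatellite order of magnitude, not
an organism-specific estimate; a stepwise rather than infinite-alleles
model is used because an orphan allele a few bp from the parental alleles
is exactly what single-step SSR mutation produces. Genotyping error
replaces an allele with a random in-locus allele at a configurable rate
(0 by default). Founder draws, transmission, mutation, error, SI
assignment and bootstrap draws all consume independently seeded named
streams, so changing one rate never perturbs another stage and identical
configurations are byte-identical.

The `olive_like_102` scenario emulates the shape of a real cultivar
collection — 102 individuals at 12 loci with embedded clone pairs
(synonyms), two-offspring families, a half sib, full sibs, first and
second cousins, and a large unrelated background. What it deliberately
does **not** emulate: population structure and drift among geographic
origins, linkage between loci, allele-frequency correlation across
related founders (founders are exactly unrelated), null alleles, or
binning artefacts. Passing tests therefore demonstrate estimator and
pipeline correctness under the stated generative model, not robustness to
every artefact of real fragment data.

Ground truth is the kinship coefficient recursion ($\varphi(i,i) =
(1+\varphi(m_i,f_i))/2$; $\varphi(i,j) = (\varphi(m_i,j) +
\varphi(f_i,j))/2$ taking the later individual's parents; founders
unrelated and non-inbred), reported as $r = 2\varphi$ capped at 1, and
cross-checked against gene-dropping Monte-Carlo IBD sharing to ±0.005.
For dyads involving inbred individuals — possible only under pseudo-self
matings — $2\varphi$ exceeds the three-state relatedness the estimators
target (a selfed offspring with its parent: $2\varphi = 1$, gamete
enumeration of shared-IBD classes 0.75). The mismatch is reported
unrenormalised and documented here rather than hidden, because the
estimators' no-inbreeding assumption is itself part of what the selfing
scenario is meant to probe.

## Numerical and design choices

* Grid step 0.01 + Nelder–Mead, tolerance $10^{-8}$; likelihoods floored
  at $10^{-300}$ before logging to avoid `-Inf` at simplex vertices.
* Monomorphic loci carry no likelihood information and are retained but
  inert; an all-monomorphic overlap is an error, not a silent 0.
* Distances: pairwise deletion without rescaling by default; an optional
  `rescale_missing` multiplies by total/scored loci.
* Problem sizes in the shipped tests and validation drivers (500
  parent–offspring dyads at 12 loci, 100 dyads per class at 100 loci,
  2×10^5 gene-dropping replicates) were chosen as the smallest sizes at
  which Monte-Carlo noise is comfortably below the asserted tolerances.
* The fixture SI table encodes the one cultivar whose printed group
  membership is internally inconsistent in the source material by its
  textual (not tabular) value, with a comment in the file.

## Limitations

No inbreeding coefficients per individual; no CERVUS-style LOD paternity
statistics or exclusion probabilities; no genotyping-error model inside
the trio test (the mismatch tolerance covers both error and mutation); no
graphical rendering (trees and matrices are emitted as Newick/CSV for
external viewers). Bit-exact agreement with any particular relatedness
program is a non-goal: the acceptance surface is parameter recovery under
the simulator's ground truth and the published worked examples.
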