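# olivekin

Kinship and parentage inference for clonally propagated crops typed with
codominant SSR/indel markers.

Many olive cultivars were obtained by mass selection from open- or
self-pollinated seedlings, so their paternal parent is unknown. Given a
panel of cultivars genotyped at multi-allelic codominant loci (two allele
fragment lengths in bp per individual per locus), `olivekin` identifies
candidate fathers by combining:

* **codominant genetic distances** (per-locus
  `d² = ½ Σₐ (xₐ − yₐ)²` on allele-count vectors) with
  neighbour-joining, UPGMA and Ward trees and locus-bootstrap support;
* **pairwise relatedness** `r = k₁/2 + k₂` over the IBD coefficients
  `(k₀, k₁, k₂)`, via the Queller–Goodnight moment estimator and a
  maximum-likelihood estimator on the k-simplex (with a
  reference-individual triadic mode and locus-bootstrap CIs), for all
  n(n−1)/2 dyads;
* **six kinship categories** (unrelated → second cousins → first cousins
  → half-sib/uncle/grandparent → parent–child/full sibs → identity) with
  configurable thresholds, plus the heat-map matrix and `1 − r` trees;
* **Mendelian trio tests** with orphan-allele reporting and a mutation
  tolerance (default: one mismatching locus), selfing and duo tests, and
  exhaustive candidate scans;
* **diallelic self-incompatibility (DSI) logic** — groups G1 (S1S2) and
  G2 (S1S1), S2 dominant, crosses fail within a group — to exclude
  candidates that could not have sired the offspring;
* a **pedigree simulator** (Dirichlet founder frequencies, HWE,
  SI-constrained matings, stepwise SSR mutation, genotyping error) with
  an exact expected-relatedness truth table for validation.

See `vignettes/olive-parentage-methods.Rmd` for the models, defaults and
design decisions, and `analysis/01…05` for the narrative drivers that
produce the tables under `results/`.

## Worked example

The package ships the published four-cultivar genotype table (two
candidate offspring, the known mother, and the putative father; 12 loci)
and the corresponding SI group labels:

```r
library(olivekin)
tab <- read_genotype_csv(system.file("extdata", "table1_genotypes.csv", package = "olivekin"))
si  <- read_si_csv(system.file("extdata", "table2_si_groups.csv", package = "olivekin"))

trio_test(tab, "Don Carlo", "Frantoio", "Ascolana Tenera")
#> trio test: Don Carlo | mother Frantoio x father Ascolana Tenera
#>   1 mismatching loci (DCA18); 0 skipped

selfing_test(tab, "Don Carlo", "Frantoio")$mismatch_count
#> [1] 8

rep <- run_full_workflow(tab, offspring = c("Don Carlo", "FS-17"),
                         mother = "Frantoio", si = si,
                         estimator = "moment", seed = 1)
rep
#> parentage report (seed 1)
#>   Don Carlo: top candidate Ascolana Tenera (1 mismatching loci, r = -0.0737)
#>   FS-17: top candidate Ascolana Tenera (0 mismatching loci, r = -0.0193)
```

Reading: FS-17 is Mendelian-compatible with the Frantoio × Ascolana
Tenera trio at all 12 loci. Don Carlo is compatible at 11 loci and
carries a single orphan allele (165 bp at DCA18, a few bp below the
parental 173/177/179 alleles — the signature of a sporadic stepwise SSR
mutation), so it is retained under the default one-mismatch tolerance.
Its selfing test fails at 8 of 12 loci, rejecting a self-pollination
origin outright. The SI check excludes any G1 candidate (the mother's
group — e.g. Leccino) and retains the G2 candidate Ascolana Tenera:

```r
paternity_si_exclusion("G1", "G2", "G1")   # mother G1, candidate Leccino G1
#> [1] "excluded"
```

The moment-estimator r values printed above are tie-breakers computed
from a 4-sample frequency panel and are not meaningful kinship estimates
at that panel size; the trio and SI evidence carries the conclusion.

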