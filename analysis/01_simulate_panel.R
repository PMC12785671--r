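#!/usr/bin/env Rscript
# Simulate the benchmark cultivar collection: 102 individuals typed at 12
# multi-allelic SSR/indel loci, containing clone pairs (synonyms), two
# two-offspring families, a half sib, full sibs, first and second cousins,
# and a large unrelated background -- together with the exact
# pedigree-expected relatedness of every dyad.

library(olivekin)

seed <- 20251001
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg, "olive_like_102")

write_genotype_csv(sim$table, file.path(out, "panel_genotypes.csv"))
write_genalex(sim$table, file.path(out, "panel_genotypes_genalex.csv"))
write.csv(sim$si, file.path(out, "panel_si_groups.csv"), row.names = FALSE)
write.csv(sim$truth, file.path(out, "panel_truth.csv"), row.names = FALSE)
write.csv(as.data.frame(sim$pedigree), file.path(out, "panel_pedigree.csv"),
          row.names = FALSE)

cat(sprintf("panel: %d samples x %d loci (seed %d)\n",
            n_samples(sim$table), n_loci(sim$table), seed))
cat(sprintf("truth table: %d dyads\n", nrow(sim$truth)))
print(table(sim$truth$relationship))
cat("SI groups:\n")
print(table(sim$si$si_group))
cat("written under", out, "\n")
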