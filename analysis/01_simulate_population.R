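#!/usr/bin/env Rscript
# Build the synthetic study population: the published cross table (35
# full-sib families, 1,011 offspring from 23 table parents) drives a gene
# dropping over a 19-chromosome genome; one growth-like trait battery is
# attached. Bulky intermediates go to scratch/, small summaries to results/.

library(popgs)

seed <- 20260928L
dir.create("scratch/population", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

counts <- read.csv(system.file("extdata", "poplar_family_counts.csv",
                               package = "popgs"))
des <- design_from_family_table(counts)
ped <- simulate_pedigree(des)

fg <- simulate_founders(length(des$sires), length(des$dams),
                        n_markers = 3000, maf_range = c(0.05, 0.5),
                        n_chromosomes = 19, seed = seed,
                        sire_ids = des$sires, dam_ids = des$dams)
gd <- drop_genes(ped, fg, recomb_rate_per_mb = 0.04, seed = seed + 1)

# seven correlated traits of moderate-to-high heritability, as in the
# field evaluation (growth, phenology, rust scores)
rho <- 0.4
cors <- matrix(rho, 7, 7)
diag(cors) <- 1
arch <- trait_architecture(n_traits = 7, n_qtl = 100,
                           genetic_correlation = cors,
                           target_h2 = c(.75, .55, .7, .8, .8, .75, .75),
                           n_blocks = 6, spatial_range = 8,
                           spatial_variance_fraction = 0.25)
truth <- simulate_traits(gd, arch, seed = seed + 2)

write_pedigree(ped, "scratch/population/pedigree.csv")
write_dosage(gd, "scratch/population/dosage.tsv",
             "scratch/population/marker_map.tsv")
write_truth(truth, "scratch/population/truth.csv")
saveRDS(list(seed = seed, arch = arch, design = des, base_freq = gd$base_freq),
        "scratch/population/meta.rds")
# parameter/seed sidecar next to the result tables
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(seed = seed, n_markers = 3000, n_chromosomes = 19,
         maf_range = c(0.05, 0.5), recomb_rate_per_mb = 0.04,
         n_traits = arch$n_traits, n_qtl = arch$n_qtl,
         genetic_correlation = rho, target_h2 = arch$target_h2,
         n_blocks = arch$n_blocks, spatial_range = arch$spatial_range,
         spatial_variance_fraction = arch$spatial_variance_fraction),
    "results/01_parameters.json", auto_unbox = TRUE, digits = NA)
}

fam <- table(na.omit(family_map(ped)$family))
summary <- data.frame(
  quantity = c("parents", "offspring", "families", "min_family",
               "max_family", "mean_family", "markers", "chromosomes"),
  value = c(length(founders(ped)), sum(fam), length(fam), min(fam),
            max(fam), round(mean(fam), 1), ncol(gd$dosage), 19))
write.csv(summary, "results/01_population_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat("\nPopulation written to scratch/population/ (",
    nrow(gd$dosage), "individuals x", ncol(gd$dosage), "markers )\n")
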