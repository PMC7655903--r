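#!/usr/bin/env Rscript
# The evaluation grid: pedigree (true and corrupted) vs genomic
# relationship matrices under individual- and family-sampling
# cross-validation at two training fractions, with the youngest families
# held out as an independent TestSet. Metrics: predictive ability,
# accuracy (scaled by the A-model heritability), Spearman, bias slope.

library(popgs)

ped <- read_pedigree("scratch/population/pedigree.csv")
gd <- read_dosage("scratch/population/dosage.tsv",
                  "scratch/population/marker_map.tsv")
meta <- readRDS("scratch/population/meta.rds")
seed <- meta$seed + 40

truth <- read.csv("scratch/population/truth.csv")
t1 <- truth[truth$trait == "trait1", ]
set.seed(seed)
tbv <- setNames(t1$tbv, t1$id)
h2_true <- 0.6
y <- tbv + rnorm(length(tbv), 0, sqrt(var(tbv) * (1 - h2_true) / h2_true))

A <- read_relmat("scratch/matrices/A.tsv")
G <- regularize(read_relmat("scratch/matrices/G.tsv"), 1e-4)
bad <- corrupt_pedigree(ped, 0.15, seed = seed + 1)
Abad <- a_matrix(bad$pedigree)

fm <- family_map(ped)
off <- ped$id[!is.na(ped$sire)]
# TestSet: the last five families, a stand-in for the youngest cohort of
# selection candidates
fam_order <- unique(na.omit(fm$family[match(ped$id, fm$id)]))
test_fams <- tail(fam_order, 5)
test_set <- off[fm$family[match(off, fm$id)] %in% test_fams]
cat("TestSet:", length(test_set), "offspring in", length(test_fams),
    "families\n")

h2A <- fit_reml(y, list(additive = A))$h2
cat(sprintf("reference h2 (A model, all data): %.3f\n", h2A))

# labels follow the study's comparison: "A" is the operational pedigree
# carrying 15% paternity errors, "Acor" the marker-corrected one (here:
# the truth), "G" the genomic matrix
res <- run_scenario(
  phenotypes = list(trait1 = y[off]),
  matrices = list(A = Abad, Acor = A, G = G),
  family_map = fm,
  schemes = expand.grid(composition = c("individual", "family"),
                        fraction = c(0.5, 0.25), stringsAsFactors = FALSE),
  n_repetitions = 10, test_set = test_set,
  h2_ref = c(trait1 = h2A), seed = seed + 2)

write.csv(as.data.frame(res), "results/05_evaluation_long.csv",
          row.names = FALSE)
df <- as.data.frame(res)
sm <- aggregate(value ~ matrix + scheme + fraction + population + metric,
                df, mean)
sm <- sm[sm$metric %in% c("accuracy", "slope"), ]
sm <- sm[order(sm$metric, sm$population, sm$scheme, sm$fraction), ]
write.csv(sm, "results/05_evaluation_summary.csv", row.names = FALSE)
print(reshape(sm[sm$metric == "accuracy", c("matrix", "scheme", "fraction",
                                            "population", "value")],
              idvar = c("scheme", "fraction", "population"),
              timevar = "matrix", direction = "wide"), row.names = FALSE)
cat("\nNote the drop from individual- to family-sampling accuracy, the",
    "\nfurther drop on the independent TestSet, and the penalty the",
    "\nerror-laden pedigree 'A' pays relative to the corrected 'Acor'.\n")
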