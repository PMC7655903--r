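#!/usr/bin/env Rscript
# Build the relationship matrices the evaluation compares: pedigree A
# (true and corrupted), pedigree dominance D, genomic G (VanRaden,
# trace-normalized) and genomic dominance, plus a thinned-panel G. Writes
# dense TSVs to scratch/ and a compact summary to results/.

library(popgs)

ped <- read_pedigree("scratch/population/pedigree.csv")
gd <- read_dosage("scratch/population/dosage.tsv",
                  "scratch/population/marker_map.tsv")
meta <- readRDS("scratch/population/meta.rds")

A <- a_matrix(ped)
D <- d_matrix_pedigree(ped, A)
G <- g_matrix(gd)
Dg <- d_matrix_genomic(gd)

# a thinned panel: one marker per 150 kb window by imputation quality
set.seed(meta$seed + 30)
qc <- marker_qc(gd$map$marker, gd$map$chrom, gd$map$pos_bp,
                props = runif(nrow(gd$map), 0.85, 1),
                cprops = runif(nrow(gd$map), 0.5, 1),
                maf = pmin(colMeans(gd$dosage) / 2,
                           1 - colMeans(gd$dosage) / 2))
panel <- thin_markers(qc[qc$marker %in% filter_markers(qc), ], 150000)
G_thin <- g_matrix(gd$dosage[, panel])
cat("thinned panel:", length(panel), "of", nrow(qc), "markers\n")

dir.create("scratch/matrices", showWarnings = FALSE)
for (nm in c("A", "D", "G", "Dg", "G_thin")) {
  write_relmat(get(nm), file.path("scratch/matrices", paste0(nm, ".tsv")))
}

off <- ped$id[!is.na(ped$sire)]
pairs_fs <- local({
  fm <- family_map(ped)
  do.call(rbind, lapply(split(off, fm$family[match(off, fm$id)]), function(ids) {
    if (length(ids) < 2) return(NULL)
    t(combn(ids, 2))
  }))
})
fs_G <- mean(G[pairs_fs])
fs_A <- mean(A[pairs_fs])
out <- data.frame(
  quantity = c("trace_A_over_n", "trace_G_over_n", "trace_Dgen_over_n",
               "mean_fullsib_A", "mean_fullsib_G", "cor_offdiag_A_G",
               "markers_full", "markers_thinned"),
  value = c(mean(diag(A)), mean(diag(G)), mean(diag(Dg)), fs_A, fs_G,
            cor(A[upper.tri(A)], G[upper.tri(G)]),
            ncol(gd$dosage), length(panel)))
write.csv(out, "results/04_matrix_summary.csv", row.names = FALSE)
print(out, row.names = FALSE)
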