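test_that("founder simulation is deterministic and respects the MAF range", {
  g1 <- simulate_founders(3, 3, 200, c(0.05, 0.5), n_chromosomes = 4, seed = 9)
  g2 <- simulate_founders(3, 3, 200, c(0.05, 0.5), n_chromosomes = 4, seed = 9)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$map, g2$map)
  # positions strictly increasing within chromosome
  for (ch in unique(g1$map$chrom)) {
    expect_true(all(diff(g1$map$pos_bp[g1$map$chrom == ch]) > 0))
  }
  expect_error(simulate_founders(0, 3, 100), "positive")
  expect_error(simulate_founders(3, 3, 100, c(0, 0.5)), "maf_range")
})

test_that("symmetric allele frequency gives mean dosage 1", {
  g <- simulate_founders(60, 60, 300, c(0.5, 0.5), n_chromosomes = 3, seed = 2)
  # expected heterozygosity 0.5, mean dosage 1; SE of the overall mean
  mu <- mean(g$dosage)
  se <- sqrt(0.5 / length(g$dosage))
  expect_lt(abs(mu - 1), 3 * se)
})

test_that("empirical founder MAF matches a Monte-Carlo oracle", {
  g <- simulate_founders(50, 50, 1000, c(0.05, 0.5), n_chromosomes = 5,
                         seed = 31)
  n <- nrow(g$dosage)
  phat <- colMeans(g$dosage) / 2
  maf <- pmin(phat, 1 - phat)
  expect_true(all(maf >= 0 & maf <= 0.5))
  # oracle: Monte-Carlo draws of the same sampling scheme
  set.seed(99)
  oracle <- replicate(10000, {
    p <- runif(1, 0.05, 0.5)
    ph <- rbinom(1, 2L * n, p) / (2 * n)
    min(ph, 1 - ph)
  })
  se <- sd(oracle) / sqrt(length(maf))
  expect_lt(abs(mean(maf) - mean(oracle)), 3 * se)
})

test_that("pedigree simulation counts families and offspring correctly", {
  des <- factorial_design(paste0("s", 1:4), paste0("d", 1:4), 10)
  ped <- simulate_pedigree(des)
  fm <- family_map(ped)
  expect_equal(length(unique(na.omit(fm$family))), 16)
  expect_equal(sum(!is.na(ped$sire)), 160)
  # founders first, with unknown parents
  expect_equal(founders(ped), c(paste0("s", 1:4), paste0("d", 1:4)))
  # empty cross list -> founders only
  des0 <- mating_design("s1", "d1",
                        data.frame(sire = character(), dam = character(),
                                   n_offspring = numeric()))
  expect_equal(nrow(simulate_pedigree(des0)), 2)
})

test_that("the published cross table yields 35 families of 1,011 offspring", {
  counts <- read.csv(system.file("extdata", "poplar_family_counts.csv",
                                 package = "popgs"))
  des <- design_from_family_table(counts)
  ped <- simulate_pedigree(des)
  fam <- family_map(ped)
  sizes <- table(na.omit(fam$family))
  expect_equal(length(sizes), 35L)
  expect_equal(sum(sizes), 1011L)
  expect_equal(max(sizes), 118L)
})

test_that("gene dropping is Mendelian-consistent and recombination-aware", {
  pop <- make_population(n_markers = 400, seed = 51)
  ped <- pop$ped
  gd <- pop$geno
  off <- ped$id[!is.na(ped$sire)]
  # zero opposing homozygotes with both true parents
  for (o in off[1:10]) {
    i <- match(o, ped$id)
    expect_equal(opposing_homozygotes(gd, o, ped$sire[i]), 0)
    expect_equal(opposing_homozygotes(gd, o, ped$dam[i]), 0)
  }
  # zero recombination on one chromosome: paternal haplotype is one
  # unbroken parental haplotype
  fg1 <- simulate_founders(2, 2, 100, c(0.2, 0.5), n_chromosomes = 1,
                           seed = 52)
  ped1 <- simulate_pedigree(pair_design("S1", "D1", 5))
  gd1 <- drop_genes(ped1, fg1, recomb_rate_per_mb = 0, seed = 53)
  for (o in setdiff(ped1$id, c("S1", "D1"))) {
    h <- gd1$haplotypes$H1[o, ]
    expect_true(identical(h, gd1$haplotypes$H1["S1", ]) ||
                identical(h, gd1$haplotypes$H2["S1", ]))
  }
  # determinism
  gd2 <- drop_genes(ped1, fg1, recomb_rate_per_mb = 0, seed = 53)
  expect_identical(gd1$dosage, gd2$dosage)
  # ungenotyped founder / unknown parent errors
  expect_error(drop_genes(pedigree(c("S1", "q", "x"), c(NA, NA, "S1"),
                                   c(NA, NA, "q")), fg1), "ungenotyped")
})

test_that("realized genomic relationships match pedigree expectations", {
  pop <- make_population(n_sires = 4, n_dams = 4, n_per_cross = 13,
                         n_markers = 5000, seed = 61)
  ped <- pop$ped
  G <- g_matrix(pop$geno, freq = pop$geno$base_freq)
  fm <- family_map(ped)
  off <- ped$id[!is.na(ped$sire)]
  fam <- fm$family[match(off, fm$id)]
  fs <- c()
  for (f in unique(fam)) {
    ids <- off[fam == f]
    gg <- G[ids, ids]
    fs <- c(fs, gg[upper.tri(gg)])
  }
  # >= 200 full-sib pairs at 5,000 markers
  expect_gte(length(fs), 200)
  expect_lt(abs(mean(fs) - 0.5), 3 * sd(fs) / sqrt(length(fs)))
  po <- mapply(function(o, s) G[o, s], off, ped$sire[match(off, ped$id)])
  expect_lt(abs(mean(po) - 0.5), 3 * sd(po) / sqrt(length(po)))
  # half sibs (share exactly one parent)
  hs <- c()
  sire <- ped$sire[match(off, ped$id)]
  dam <- ped$dam[match(off, ped$id)]
  for (i in seq_along(off)) {
    j <- which(seq_along(off) > i &
               xor(sire == sire[i], dam == dam[i]))
    if (length(j)) hs <- c(hs, G[off[i], off[j]])
  }
  expect_lt(abs(mean(hs) - 0.25), 3 * sd(hs) / sqrt(length(hs)))
})

test_that("trait simulation honors dominance ratio and genetic correlation", {
  pop <- make_population(n_sires = 8, n_dams = 8, n_per_cross = 16,
                         n_markers = 800, seed = 71)
  # dominance_ratio = 0 -> TDV identically zero
  # (n_qtl sets the effective dof of the realized trait correlation, so a
  # quasi-polygenic architecture is used for the independence bound)
  arch0 <- trait_architecture(n_traits = 2, n_qtl = 400)
  tr0 <- simulate_traits(pop$geno, arch0, seed = 72)
  expect_true(all(tr0$tdv == 0))
  expect_lt(max(abs(colMeans(tr0$tbv))), 1e-10)  # centered
  # identity correlation: |r| below sampling bound at n ~ 1000
  expect_lt(abs(cor(tr0$tbv)[1, 2]), 0.15)
  # strong correlation recovered
  archr <- trait_architecture(n_traits = 2, n_qtl = 400,
                              genetic_correlation = matrix(c(1, .9, .9, 1), 2))
  trr <- simulate_traits(pop$geno, archr, seed = 73)
  r <- cor(trr$tbv)[1, 2]
  se <- (1 - 0.9^2) / sqrt(400)  # effective dof ~ n_qtl
  expect_lt(abs(r - 0.9), 3 * se + 0.02)
  # dominance scaling
  archd <- trait_architecture(n_traits = 1, n_qtl = 100,
                              dominance_ratio = 0.5)
  trd <- simulate_traits(pop$geno, archd, seed = 74)
  expect_lt(abs(var(trd$tdv[, 1]) / var(trd$tbv[, 1]) - 0.5), 1e-6)
  expect_error(trait_architecture(n_traits = 2,
                                  genetic_correlation = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("field trials reproduce the requested variance structure", {
  pop <- make_population(n_per_cross = 6, n_markers = 300, seed = 81)
  arch <- trait_architecture(n_traits = 1, n_qtl = 50, target_h2 = 0.5,
                             n_blocks = 6, spatial_variance_fraction = 0)
  tr <- simulate_traits(pop$geno, arch, seed = 82)
  obs <- simulate_field_trial(tr, layout = c(26, 26), architecture = arch,
                              seed = 83)
  # no spatial term: replicate deviations are iid; variance of replicate
  # means ~ sigma_e^2 / n_blocks
  vg <- var(tr$gv[, 1])
  sig_e2 <- 6 * vg * (1 - 0.5) / 0.5
  dev <- obs$value - tr$gv[obs$genotype, 1]
  expect_lt(abs(var(dev) - sig_e2) / sig_e2, 0.15)
  rm <- tapply(dev, obs$genotype, mean)
  expect_lt(abs(var(rm) - sig_e2 / 6) / (sig_e2 / 6), 0.35)
  # h2 = 1: replicates identical up to the (zero) spatial term
  arch1 <- trait_architecture(n_traits = 1, n_qtl = 50, target_h2 = 1,
                              spatial_variance_fraction = 0)
  tr1 <- simulate_traits(pop$geno, arch1, seed = 84)
  obs1 <- simulate_field_trial(tr1, layout = c(26, 26), architecture = arch1,
                               seed = 85)
  expect_equal(tapply(obs1$value, obs1$genotype, function(v) diff(range(v))),
               tapply(obs1$value, obs1$genotype, function(v) 0))
  expect_error(simulate_field_trial(tr1, layout = c(5, 5)), "too small")
})

test_that("pedigree corruption hits the requested family-block fraction", {
  counts <- read.csv(system.file("extdata", "poplar_family_counts.csv",
                                 package = "popgs"))
  ped <- simulate_pedigree(design_from_family_table(counts))
  # rate 0: untouched
  c0 <- corrupt_pedigree(ped, 0)
  expect_identical(c0$pedigree, ped)
  expect_equal(nrow(c0$changes), 0)
  # rate 1: every offspring's sire differs
  c1 <- corrupt_pedigree(ped, 1, seed = 5)
  off <- !is.na(ped$sire)
  expect_true(all(c1$pedigree$sire[off] != ped$sire[off]))
  # rate 0.15 on ~1,000 offspring: within [0.10, 0.20] at family-block
  # granularity
  c15 <- corrupt_pedigree(ped, 0.15, seed = 6)
  frac <- mean(c15$pedigree$sire[off] != ped$sire[off])
  expect_gte(frac, 0.10)
  expect_lte(frac, 0.20)
  # change-log lists exactly the substitutions
  expect_equal(sort(c15$changes$id),
               sort(ped$id[off][c15$pedigree$sire[off] != ped$sire[off]]))
  expect_error(corrupt_pedigree(simulate_pedigree(pair_design("s", "d", 4)),
                                0.5), "2 declared sires")
})
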