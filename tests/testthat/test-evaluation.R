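toy_family_map <- function(ids, fams) {
  data.frame(id = ids, family = fams, stringsAsFactors = FALSE)
}

test_that("partitions respect sizes, families and the TestSet", {
  ids <- paste0("i", 1:100)
  fm <- toy_family_map(ids, rep(paste0("f", 1:10), each = 10))
  p <- make_partitions(ids, fm, "individual", fraction = 0.5,
                       n_repetitions = 5, seed = 3)
  for (pt in p) {
    expect_equal(length(pt$train), 50)
    expect_length(intersect(pt$train, pt$validation), 0)
    expect_setequal(c(pt$train, pt$validation), ids)
  }
  # family mode: no family straddles the split
  pf <- make_partitions(ids, fm, "family", fraction = 0.5,
                        n_repetitions = 5, seed = 4)
  for (pt in pf) {
    tf <- unique(fm$family[match(pt$train, fm$id)])
    vf <- unique(fm$family[match(pt$validation, fm$id)])
    expect_length(intersect(tf, vf), 0)
  }
  # TestSet ids never reach training (nor validation)
  ts <- paste0("i", 1:10)
  pts <- make_partitions(ids, fm, "individual", 0.5, 5, seed = 5,
                         test_set = ts)
  for (pt in pts) {
    expect_length(intersect(pt$train, ts), 0)
    expect_length(intersect(pt$validation, ts), 0)
  }
  # 8 equal families at fraction 0.25 -> 2 training families, and the
  # sampler's support matches exhaustive enumeration of C(8,2)
  ids8 <- paste0("x", 1:80)
  fm8 <- toy_family_map(ids8, rep(paste0("g", 1:8), each = 10))
  seen <- character(0)
  for (r in 1:60) {
    pr <- make_partitions(ids8, fm8, "family", 0.25, 1, seed = 100 + r)[[1]]
    tf <- sort(unique(fm8$family[match(pr$train, fm8$id)]))
    expect_length(tf, 2)
    seen <- c(seen, paste(tf, collapse = "+"))
  }
  support <- apply(combn(paste0("g", 1:8), 2), 2, paste, collapse = "+")
  expect_true(all(seen %in% support))
  expect_gt(length(unique(seen)), 15)  # draws spread over the support
  expect_error(make_partitions(paste0("z", 1:3), NULL, "individual", 0.01),
               "empty side")
})

test_that("metric identities hold", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(predictive_ability(x, x), 1)
  expect_equal(predictive_ability(-x, x), -1)
  # 5-point toy set against the hand-expanded formula
  pred <- c(1, 2, 3, 4, 5)
  obs <- c(2, 1, 4, 3, 5)
  num <- sum(pred * obs) - 5 * mean(pred) * mean(obs)
  den <- sqrt((sum(pred^2) - 5 * mean(pred)^2) *
              (sum(obs^2) - 5 * mean(obs)^2))
  expect_equal(predictive_ability(pred, obs), num / den, tolerance = 1e-12)
  expect_error(predictive_ability(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  # accuracy arithmetic and homogeneity
  expect_equal(accuracy(0.5, 0.25), 1.0)
  expect_equal(accuracy(0.9, 1), 0.9)
  expect_equal(accuracy(0.8, 0.64), 1.0)
  expect_equal(accuracy(2 * 0.3, 0.5), 2 * accuracy(0.3, 0.5))
  expect_equal(accuracy(0.3, 0.25), accuracy(0.3, 1) / sqrt(0.25))
  expect_error(accuracy(0.5, 0), "h2_ref")
  # bias regression
  expect_equal(bias_regression(x, x), c(intercept = 0, slope = 1))
  expect_equal(bias_regression(x, 0.5 * x)["slope"], c(slope = 2))
  set.seed(9)
  o4 <- c(3, 1, 4, 1.5)
  p4 <- c(2, 2, 5, 1)
  fitlm <- lm(o4 ~ p4)
  expect_equal(unname(bias_regression(o4, p4)),
               unname(coef(fitlm)), tolerance = 1e-12)
})

test_that("tier-wise rank metrics are consistent", {
  set.seed(11)
  obs <- rnorm(200)
  pred <- exp(obs)  # strictly monotone transform
  rm <- rank_metrics(pred, obs)
  expect_equal(rm$spearman, rep(1, 4), tolerance = 1e-12)
  # the 100% tier Pearson equals predictive ability on the full set
  rm2 <- rank_metrics(pred <- rnorm(200) + 0.5 * obs, obs)
  expect_equal(rm2$pearson[rm2$tier == "0-100%"],
               predictive_ability(pred, obs))
  expect_equal(sum(rm2$n[1:3]), 100)  # 5% + 5% + 40% of 200
  # direction flips which end is "best"
  rl <- rank_metrics(pred, obs, direction = "low")
  ix_low <- order(obs)[1:10]
  expect_equal(rl$n[1], 10)
  # tiny tier -> NA, flagged not dropped
  rs <- rank_metrics(rnorm(30), rnorm(30), tiers = c(0.05, 1))
  expect_true(is.na(rs$pearson[1]))
  expect_equal(nrow(rs), 2)
})

test_that("random predictions give tier Spearman centered at zero", {
  set.seed(13)
  obs <- rnorm(1000)
  sp <- replicate(200, {
    rank_metrics(rnorm(1000), obs)$spearman[1]  # top-5% tier, n = 50
  })
  expect_lt(abs(mean(sp)), 3 * sd(sp) / sqrt(200))
  # SD close to the closed form 1/sqrt(n_tier - 1)
  expect_lt(abs(sd(sp) - 1 / sqrt(49)) / (1 / sqrt(49)), 0.2)
})

test_that("within-family gain weights and conventions hold", {
  ids <- paste0("i", 1:40)
  fm <- toy_family_map(ids, rep(c("fa", "fb"), each = 20))
  set.seed(15)
  obs <- setNames(rnorm(40), ids)
  pg <- setNames(rnorm(40), ids)
  # identical prediction sets -> all gains zero
  g0 <- within_family_gain(pg, pg, obs, fm)
  expect_true(all(g0$per_family$gain == 0))
  expect_equal(g0$weighted_mean, 0)
  # constant pedigree predictions within family -> pedigree PA 0 by
  # convention; gain equals the genomic within-family PA
  pp <- setNames(rep(c(1, 2), each = 20), ids)
  g1 <- within_family_gain(pg, pp, obs, fm)
  expect_equal(g1$per_family$pa_pedigree, c(0, 0))
  expect_equal(g1$per_family$gain, g1$per_family$pa_genomic)
  # weighted mean arithmetic: sizes 10 and 30 with gains 0.4 and 0
  ids2 <- paste0("j", 1:40)
  fm2 <- toy_family_map(ids2, rep(c("s", "t"), c(10, 30)))
  gd <- list(per_family = data.frame(family = c("s", "t"), n = c(10, 30),
                                     gain = c(0.4, 0)))
  wm <- sum(gd$per_family$gain * gd$per_family$n) / sum(gd$per_family$n)
  expect_equal(wm, 0.1)
  # weighted mean is bracketed by the extremes
  expect_gte(g1$weighted_mean, min(g1$per_family$gain) - 1e-12)
  expect_lte(g1$weighted_mean, max(g1$per_family$gain) + 1e-12)
  # small families are skipped with a log entry
  fm3 <- toy_family_map(ids, c(rep("big", 38), "tiny", "tiny"))
  g3 <- within_family_gain(pg, pg, obs, fm3)
  expect_equal(g3$skipped, "tiny")
})

test_that("run_scenario executes the grid deterministically", {
  pop <- make_population(n_sires = 3, n_dams = 3, n_per_cross = 10,
                         n_markers = 600, seed = 701)
  arch <- trait_architecture(n_qtl = 60, target_h2 = 0.6)
  tr <- simulate_traits(pop$geno, arch, seed = 702)
  y <- pheno_from_tbv(setNames(tr$tbv[, 1], rownames(tr$tbv)), 0.6, 703)
  off <- pop$ped$id[!is.na(pop$ped$sire)]
  y <- y[off]
  A <- a_matrix(pop$ped)
  G <- regularize(g_matrix(pop$geno), 1e-4)
  fm <- family_map(pop$ped)
  schemes <- data.frame(composition = "individual", fraction = 0.5)
  res <- run_scenario(list(h = y), list(A = A, G = G), fm,
                      schemes = schemes, n_repetitions = 10, seed = 41)
  # bookkeeping: 1 trait x 2 matrices x 1 scheme x 10 reps x 5 metrics
  expect_equal(nrow(res), 2 * 10 * 5)
  expect_length(attr(res, "failures"), 0)
  expect_true(all(abs(res$value[res$metric == "predictive_ability"]) <= 1))
  # determinism
  res2 <- run_scenario(list(h = y), list(A = A, G = G), fm,
                       schemes = schemes, n_repetitions = 10, seed = 41)
  expect_identical(res$value, res2$value)
  # a failing matrix is recorded, not fatal
  bad <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  res3 <- run_scenario(list(h = y), list(A = A, bad = bad), fm,
                       schemes = schemes, n_repetitions = 2, seed = 42)
  expect_gt(length(attr(res3, "failures")), 0)
  expect_true(all(res3$matrix == "A"))
})
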