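# shared fixture: pedigree A with TBV drawn from N(0, A) -- no markers
# needed for variance-component recovery checks
sim_a_pheno <- function(n_per_cross, h2, seed) {
  ped <- simulate_pedigree(factorial_design(paste0("S", 1:4),
                                            paste0("D", 1:4), n_per_cross))
  A <- a_matrix(ped)
  set.seed(seed)
  tbv <- drop(crossprod(chol(A), rnorm(nrow(A))))
  names(tbv) <- rownames(A)
  y <- pheno_from_tbv(tbv, h2, seed + 1)
  list(ped = ped, A = A, tbv = tbv, y = y)
}

test_that("EM-REML on an iid grouping matches lme4 exactly", {
  set.seed(7)
  g <- rep(1:30, each = 5)
  u <- rnorm(30, 0, 2)
  y <- 1 + u[g] + rnorm(150, 0, 1.5)
  K <- diag(30)
  dimnames(K) <- list(paste0("g", 1:30), paste0("g", 1:30))
  Z <- popgs:::incidence(paste0("g", g), rownames(K))
  fit <- popgs:::reml_em(y, matrix(1, 150, 1),
                         list(list(name = "g", Z = Z, Kinv = diag(30),
                                   logdetK = 0, q = 30)))
  skip_if_not_installed("lme4")
  m <- lme4::lmer(y ~ (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(fit$varcomp, vc, tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(logLik(m)), tolerance = 1e-7)
})

test_that("eigen and EM algorithms agree on a relationship-matrix model", {
  d <- sim_a_pheno(10, h2 = 0.5, seed = 11)
  f1 <- fit_reml(d$y, list(additive = d$A), algorithm = "eigen")
  f2 <- fit_reml(d$y, list(additive = d$A), algorithm = "em")
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-4)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_gt(cor(f1$blup$additive, f2$blup$additive), 0.999999)
  # logL matches the direct V-based restricted likelihood at the optimum
  ph <- names(d$y)
  direct <- -0.5 * neg2_reml_direct(unname(d$y),
                                    matrix(1, length(d$y), 1),
                                    list(d$A[ph, ph]), f1$varcomp)
  expect_equal(f1$logLik, direct, tolerance = 1e-6)
})

test_that("restricted log-likelihood is non-decreasing across EM iterations", {
  d <- sim_a_pheno(8, h2 = 0.4, seed = 13)
  f <- fit_reml(d$y, list(additive = d$A), algorithm = "em")
  expect_true(all(diff(f$trace) > -1e-7))
})

test_that("pure noise drives the additive variance to zero", {
  set.seed(17)
  pa_h2 <- replicate(10, {
    ids <- paste0("i", 1:300)
    K <- diag(300)
    dimnames(K) <- list(ids, ids)
    y <- setNames(rnorm(300), ids)
    fit_reml(y, list(additive = K))$h2
  })
  expect_lt(mean(pa_h2), 0.1)
})

test_that("REML recovers a true heritability of 0.5", {
  h2s <- vapply(1:10, function(r) {
    d <- sim_a_pheno(10, h2 = 0.5, seed = 700 + r)
    fit_reml(d$y, list(additive = d$A))$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.5), 0.07)
})

test_that("estimates are scale-equivariant", {
  d <- sim_a_pheno(8, h2 = 0.5, seed = 19)
  f1 <- fit_reml(d$y, list(additive = d$A))
  f2 <- fit_reml(d$y * 2, list(additive = d$A))
  expect_equal(f2$varcomp, f1$varcomp * 4, tolerance = 1e-5)
  expect_equal(unname(f2$blup$additive), unname(f1$blup$additive * 2),
               tolerance = 1e-4)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
})

test_that("the MME solution satisfies the normal equations", {
  d <- sim_a_pheno(6, h2 = 0.5, seed = 23)
  ph <- names(d$y)
  f <- fit_reml(d$y, list(additive = d$A), algorithm = "em")
  # rebuild the MME at the estimates and check the residual
  ids <- rownames(d$A)
  Z <- as.matrix(popgs:::incidence(ph, ids))
  X <- matrix(1, length(d$y), 1)
  alpha <- f$varcomp["residual"] / f$varcomp["additive"]
  Kinv <- solve(d$A)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + Kinv * alpha))
  rhs <- c(crossprod(X, unname(d$y)), crossprod(Z, unname(d$y)))
  theta <- c(f$fixef, f$blup$additive)
  expect_lt(sqrt(sum((C %*% theta - rhs)^2)) / sqrt(sum(rhs^2)), 1e-6)
})

test_that("A-model and G-model agree on dense-marker gene drops", {
  # a 19-chromosome genome keeps Mendelian-sampling deviations of realized
  # relationships small; at 10,000 markers G then approximates A entrywise
  # and the two BLUP vectors align. The residual gap is intrinsic: G sees
  # within-family deviations that A cannot, so the correlation does not
  # reach 1 even with a perfect G.
  fg0 <- simulate_founders(4, 4, 10000, c(0.1, 0.5), n_chromosomes = 19,
                           seed = 29)
  ped <- simulate_pedigree(factorial_design(paste0("S", 1:4),
                                            paste0("D", 1:4), 12))
  gd <- drop_genes(ped, fg0, recomb_rate_per_mb = 0.04, seed = 30)
  A <- a_matrix(ped)
  G <- regularize(g_matrix(gd, freq = gd$base_freq), 1e-4)
  expect_lt(sqrt(mean((G - A)[upper.tri(A)]^2)), 0.05)
  arch <- trait_architecture(n_qtl = 1000, target_h2 = 0.5)
  tr <- simulate_traits(gd, arch, seed = 31)
  y <- pheno_from_tbv(setNames(tr$tbv[, 1], rownames(tr$tbv)), 0.5, 32)
  fa <- fit_reml(y, list(additive = A))
  fgm <- fit_reml(y, list(additive = G))
  expect_gt(cor(fa$blup$additive, fgm$blup$additive), 0.95)
})

test_that("additive+dominance model is penalized when dominance is absent", {
  wins <- vapply(1:10, function(r) {
    d <- sim_a_pheno(8, h2 = 0.5, seed = 400 + r)
    Dp <- d_matrix_pedigree(d$ped)
    fa <- fit_reml(d$y, list(additive = d$A))
    fad <- suppressWarnings(
      fit_reml(d$y, list(additive = d$A, dominance = regularize(Dp, 1e-6)),
               algorithm = "em", max_iter = 200, tol_logl = 1e-7))
    fa$aic <= fad$aic
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("GEBV extraction and no-information predictions behave", {
  d <- sim_a_pheno(6, h2 = 0.5, seed = 37)
  # an unrelated, unphenotyped individual has zero covariance with all
  # phenotyped ones -> GEBV 0
  ids <- c(rownames(d$A), "stranger")
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K[rownames(d$A), colnames(d$A)] <- d$A
  f <- fit_reml(d$y, list(additive = K))
  expect_equal(unname(predict_gebv(f, "stranger")), 0, tolerance = 1e-10)
  expect_error(predict_gebv(f, "nobody"), "unknown")
  # heritability arithmetic
  expect_equal(heritability(c(a = 1, e = 1)), 0.5)
  expect_equal(heritability(c(a = 0, e = 2)), 0)
  expect_equal(heritability(c(a = 3, d = 1, e = 1)), 0.6)
  expect_error(heritability(c(a = 0, e = 0)), "zero total")
})

test_that("masked phenotypes are predicted better than by noise alone", {
  d <- sim_a_pheno(12, h2 = 0.5, seed = 41)
  off <- d$ped$id[!is.na(d$ped$sire)]
  set.seed(42)
  mask <- sample(off, 60)
  f <- fit_reml(d$y[setdiff(names(d$y), mask)], list(additive = d$A))
  pred <- predict_gebv(f, mask)
  r_tbv <- cor(pred, d$tbv[mask])
  noise <- rnorm(length(mask))
  expect_gt(r_tbv, cor(noise, d$tbv[mask]) + 0.3)
  expect_gt(r_tbv, 0.3)
})
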