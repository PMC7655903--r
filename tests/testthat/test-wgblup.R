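test_that("marker-effect back-solving satisfies its identities", {
  pop <- make_population(n_per_cross = 6, n_markers = 500, seed = 501)
  G <- regularize(g_matrix(pop$geno), 1e-6)
  Xc <- popgs:::centered_coding(pop$geno$dosage, "additive")
  m <- ncol(Xc)
  # zero BLUPs -> zero effects
  zero <- setNames(rep(0, nrow(G)), rownames(G))
  expect_equal(backsolve_effects(G, Xc, rep(1, m), zero), rep(0, m))
  # round trip: centered-M %*% u / c reconstructs the BLUPs
  arch <- trait_architecture(n_qtl = 50, target_h2 = 0.6)
  tr <- simulate_traits(pop$geno, arch, seed = 502)
  y <- pheno_from_tbv(setNames(tr$tbv[, 1], rownames(tr$tbv)), 0.6, 503)
  fit <- fit_reml(y, list(additive = G))
  u <- backsolve_effects(G, Xc, rep(1, m), fit$blup$additive)
  rec <- drop(Xc %*% u) / attr(G, "norm_const")
  expect_gt(cor(rec, fit$blup$additive[rownames(Xc)]), 0.999)
})

test_that("single-marker back-solving matches direct least squares", {
  # with one marker (plus a second to satisfy the 2-marker minimum, but
  # weight 0 on it) the effect is proportional to the regression of ghat
  # on the centered marker
  set.seed(504)
  M <- matrix(rbinom(40, 2, 0.4), 20, 2,
              dimnames = list(paste0("i", 1:20), c("m1", "m2")))
  w <- c(1, 0)
  G <- regularize(g_matrix(M, weights = w), 1e-8)
  Xc <- popgs:::centered_coding(M, "additive")
  ghat <- setNames(Xc[, 1] * 0.7, rownames(M))  # in the column space of m1
  u <- backsolve_effects(G, Xc, w, ghat)
  ls <- sum(Xc[, 1] * ghat) / sum(Xc[, 1]^2)
  expect_equal(u[1] / u[1], 1)
  expect_lt(abs(u[1] / attr(G, "norm_const") * sum(Xc[, 1]^2) /
                sum(Xc[, 1] * ghat) - 1), 1e-6)
  expect_equal(u[2], 0)
})

test_that("weight updates square, scale to mean one, and keep order", {
  expect_equal(update_weights(c(2, 2, 2)), c(1, 1, 1))
  w1 <- update_weights(c(0, 0, 3, 0))
  expect_equal(w1, c(0, 0, 4, 0))  # one signal among m markers gets m
  expect_warning(w0 <- update_weights(rep(0, 5)), "zero")
  expect_equal(w0, rep(1, 5))
  set.seed(505)
  u <- rnorm(200)
  w <- update_weights(u)
  expect_lt(abs(sum(w) - 200), 1e-9)
  expect_equal(order(w), order(u^2))
  expect_error(update_weights(c(1, NA)), "finite")
})

test_that("identity weights are a fixed point of the weighting loop", {
  pop <- make_population(n_per_cross = 5, n_markers = 400, seed = 511)
  arch <- trait_architecture(n_qtl = 40, target_h2 = 0.6)
  tr <- simulate_traits(pop$geno, arch, seed = 512)
  y <- pheno_from_tbv(setNames(tr$tbv[, 1], rownames(tr$tbv)), 0.6, 513)
  w <- iterate_wgblup(pop$geno, y, n_iter = 2)
  # trace normalization preserved at every iteration
  for (it in w$iterations) {
    expect_equal(mean(diag(it$G)), 1, tolerance = 1e-12)
    expect_equal(mean(it$weights), 1, tolerance = 1e-12)
    expect_equal(it$G, t(it$G))
  }
  # frozen at identity: rebuilding G with unit weights reproduces
  # iteration 0 exactly
  G0 <- g_matrix(pop$geno, rep(1, ncol(pop$geno$dosage)))
  expect_equal(G0, w$base$G, tolerance = 1e-14)
  f0 <- fit_reml(y, list(additive = regularize(G0, 1e-6)))
  expect_equal(f0$varcomp, w$base$fit$varcomp, tolerance = 1e-10)
  # weights are invariant to a phenotype location shift
  w2 <- iterate_wgblup(pop$geno, y + 100, n_iter = 1)
  expect_equal(w2$iterations[[1]]$weights, w$iterations[[1]]$weights,
               tolerance = 1e-6)
})

test_that("weighting enriches markers linked to the simulated QTL", {
  enrich <- vapply(1:5, function(r) {
    pop <- make_population(n_sires = 4, n_dams = 4, n_per_cross = 15,
                           n_markers = 2000, seed = 520 + r)
    arch <- trait_architecture(n_qtl = 10, target_h2 = 0.6)
    tr <- simulate_traits(pop$geno, arch, seed = 540 + r)
    y <- pheno_from_tbv(setNames(tr$tbv[, 1], rownames(tr$tbv)), 0.6,
                        560 + r)
    w <- iterate_wgblup(pop$geno, y, n_iter = 1)
    wt <- w$iterations[[1]]$weights
    near <- unique(pmin(pmax(rep(tr$qtl, each = 3) + (-1):1, 1), 2000))
    mean(wt[near]) / mean(wt)
  }, numeric(1))
  expect_gt(mean(enrich), 1)
  expect_gte(mean(enrich > 1), 0.8)
})

test_that("dominance weighting runs only when requested", {
  pop <- make_population(n_per_cross = 5, n_markers = 300, seed = 571)
  arch <- trait_architecture(n_qtl = 30, dominance_ratio = 0.3,
                             target_h2 = 0.7)
  tr <- simulate_traits(pop$geno, arch, seed = 572)
  y <- pheno_from_tbv(setNames(tr$gv[, 1], rownames(tr$gv)), 0.7, 573)
  wd <- suppressWarnings(
    iterate_wgblup(pop$geno, y, include_dominance = TRUE, n_iter = 1,
                   algorithm = "em", max_iter = 120, tol_logl = 1e-6))
  it <- wd$iterations[[1]]
  expect_true(!is.null(it$weights_d))
  expect_true(!is.null(it$D))
  expect_equal(mean(diag(it$D)), 1, tolerance = 1e-12)
  wa <- iterate_wgblup(pop$geno, y, include_dominance = FALSE, n_iter = 1)
  expect_null(wa$iterations[[1]]$weights_d)
})
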