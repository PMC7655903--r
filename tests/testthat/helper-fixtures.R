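# Shared fixtures and independent oracles, all built in code.

# small nuclear pedigree: two founders, two full sibs
nuclear_ped <- function() {
  pedigree(c("s", "d", "o1", "o2"), c(NA, NA, "s", "s"), c(NA, NA, "d", "d"))
}

# a gene-dropped population from a factorial cross, reused across tests
make_population <- function(n_sires = 4, n_dams = 4, n_per_cross = 8,
                            n_markers = 1000, seed = 101,
                            recomb_rate_per_mb = 0.02) {
  fg <- simulate_founders(n_sires, n_dams, n_markers, c(0.1, 0.5),
                          n_chromosomes = 5, seed = seed)
  ped <- simulate_pedigree(factorial_design(paste0("S", seq_len(n_sires)),
                                            paste0("D", seq_len(n_dams)),
                                            n_per_cross))
  gd <- drop_genes(ped, fg, recomb_rate_per_mb = recomb_rate_per_mb,
                   seed = seed + 1)
  list(founders = fg, ped = ped, geno = gd)
}

# oracle: expected relationship matrix by IBD gene dropping of uniquely
# labelled founder alleles (independent of a_matrix's tabular recursion)
ibd_oracle <- function(ped, n_loci = 2000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  acc <- matrix(0, n, n)
  for (l in seq_len(n_loci)) {
    a1 <- integer(n)
    a2 <- integer(n)
    nxt <- 1L
    for (i in seq_len(n)) {
      if (is.na(si[i])) {
        a1[i] <- nxt; a2[i] <- nxt + 1L; nxt <- nxt + 2L
      } else {
        a1[i] <- if (stats::runif(1) < 0.5) a1[si[i]] else a2[si[i]]
        a2[i] <- if (stats::runif(1) < 0.5) a1[di[i]] else a2[di[i]]
      }
    }
    for (i in seq_len(n)) {
      ibd <- (outer(a1[i], a1, "==") + outer(a1[i], a2, "==") +
              outer(a2[i], a1, "==") + outer(a2[i], a2, "==")) / 2
      acc[i, ] <- acc[i, ] + ibd
    }
  }
  A <- acc / n_loci
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# oracle: plain matrix arithmetic for VanRaden G on a tiny example
grm_oracle <- function(M, w = rep(1, ncol(M)), freq = NULL) {
  p <- if (is.null(freq)) colMeans(M) / 2 else freq
  Z <- sweep(M, 2, 2 * p)
  G <- Z %*% diag(w, ncol(M)) %*% t(Z)
  G / (sum(diag(G)) / nrow(M))
}

dgrm_oracle <- function(M, w = rep(1, ncol(M))) {
  p <- colMeans(M) / 2
  X <- (M == 1) * 1
  Z <- sweep(X, 2, 2 * p * (1 - p))
  G <- Z %*% diag(w, ncol(M)) %*% t(Z)
  G / (sum(diag(G)) / nrow(M))
}

# direct REML -2 logLik via the variance matrix V (small-n oracle)
neg2_reml_direct <- function(y, X, Vlist, sig) {
  n <- length(y)
  V <- diag(n) * sig[length(sig)]
  for (k in seq_along(Vlist)) V <- V + sig[k] * Vlist[[k]]
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
  as.numeric(determinant(V)$modulus + determinant(XtVX)$modulus +
             t(y) %*% P %*% y + (n - ncol(X)) * log(2 * pi))
}

# phenotypes from true breeding values at a chosen clonal-mean h2
pheno_from_tbv <- function(tbv, h2, seed) {
  set.seed(seed)
  vg <- stats::var(tbv)
  e <- stats::rnorm(length(tbv), 0, sqrt(vg * (1 - h2) / h2))
  stats::setNames(tbv + e, names(tbv))
}
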