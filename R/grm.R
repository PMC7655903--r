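#' Genomic additive relationship matrix (VanRaden, trace-normalized)
#'
#' `G = (M - P1) W (M - P1)' / c` with `c = trace[(M - P1) W (M - P1)'] / n`,
#' where `M` is the allele-dosage matrix, `P1` the matrix of `2 p_i`
#' (observed allele frequencies), and `W` a diagonal of non-negative marker
#' weights (identity for plain G-BLUP). The trace normalization forces
#' `trace(G)/n = 1`, the scaling used for compatibility with the pedigree
#' matrix. Missing dosages are imputed to the marker mean beforehand.
#'
#' @param g a [geno()] object or a dosage matrix with id rownames.
#' @param weights per-marker weights (non-negative; default all 1). They
#'   are used as given; see [update_weights()] for the mean-1 scaling.
#' @param freq optional base-population allele frequencies (one per
#'   marker). By default frequencies observed in the genotyped set are
#'   used; supply founder frequencies to reference an explicit base
#'   population (relationship expectations then match the pedigree ones).
#' @return symmetric matrix with attributes `kind = "G"`, `norm_const`
#'   (the trace constant `c`) and `freq` (allele frequencies).
#' @export
g_matrix <- function(g, weights = NULL, freq = NULL) {
  M <- impute_mean(if (inherits(g, "geno")) g$dosage else as.matrix(g))
  build_grm(M, weights, coding = "additive", freq = freq)
}

#' Genomic dominance relationship matrix (heterozygosity coding)
#'
#' `D = (X - P2) W (X - P2)' / c`, trace-normalized as in [g_matrix()],
#' where `X` codes 1 for heterozygotes and 0 for homozygotes and `P2` is
#' the matrix of Hardy-Weinberg heterozygosity `2 p_i q_i`.
#'
#' @inheritParams g_matrix
#' @return symmetric matrix with attribute `kind = "D_gen"`.
#' @export
d_matrix_genomic <- function(g, weights = NULL, freq = NULL) {
  M <- impute_mean(if (inherits(g, "geno")) g$dosage else as.matrix(g))
  build_grm(M, weights, coding = "dominance", freq = freq)
}

impute_mean <- function(M) {
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- mu[na[, 2]]
  }
  M
}

build_grm <- function(M, weights, coding, freq = NULL) {
  n <- nrow(M)
  m <- ncol(M)
  if (m < 2) stop("need at least 2 markers")
  if (is.null(rownames(M))) stop("dosage matrix must have id rownames")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("weights length must equal marker count")
  if (any(weights < 0)) stop("weights must be non-negative")
  p <- if (is.null(freq)) colMeans(M) / 2 else rep_len(freq, m)
  if (coding == "additive") {
    Z <- sweep(M, 2, 2 * p)
    kind <- "G"
  } else {
    X <- (M == 1) * 1
    if (all(X == matrix(X[1, ], n, m, byrow = TRUE))) {
      stop("degenerate dominance coding: no heterozygosity variation ",
           "between individuals")
    }
    Z <- sweep(X, 2, 2 * p * (1 - p))
    kind <- "D_gen"
  }
  K <- tcrossprod(sweep(Z, 2, weights, "*"), Z)
  cst <- sum(diag(K)) / n
  if (cst <= 0) {
    stop("zero trace: all markers are monomorphic (or carry zero weight) ",
         "under the ", kind, " coding")
  }
  K <- K / cst
  dimnames(K) <- list(rownames(M), rownames(M))
  attr(K, "kind") <- kind
  attr(K, "norm_const") <- cst
  attr(K, "freq") <- p
  K
}

#' Shrink a relationship matrix toward the identity
#'
#' `K' = (1 - epsilon) K + epsilon I`. For `epsilon > 0` and `K` positive
#' semi-definite, `K'` is positive definite, which guarantees invertibility
#' in the mixed-model equations and in marker-effect back-solving.
#'
#' @param K symmetric relationship matrix.
#' @param epsilon shrinkage in \[0, 1\].
#' @return regularized matrix (attributes of `K` preserved).
#' @export
regularize <- function(K, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon == 0) return(K)
  out <- (1 - epsilon) * K + epsilon * diag(nrow(K))
  dimnames(out) <- dimnames(K)
  for (a in c("kind", "norm_const", "freq")) {
    attr(out, a) <- attr(K, a)
  }
  out
}

# centered coding used in G (additive) or D (dominance) construction;
# needed by marker-effect back-solving so the coding matches the matrix.
centered_coding <- function(g, coding = c("additive", "dominance")) {
  coding <- match.arg(coding)
  M <- impute_mean(if (inherits(g, "geno")) g$dosage else as.matrix(g))
  p <- colMeans(M) / 2
  if (coding == "additive") {
    sweep(M, 2, 2 * p)
  } else {
    sweep((M == 1) * 1, 2, 2 * p * (1 - p))
  }
}

#' Write / read a relationship matrix as TSV with id headers
#'
#' @param K symmetric matrix with id dimnames.
#' @param path file path.
#' @return `read_relmat` returns the matrix.
#' @export
write_relmat <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  K
}
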