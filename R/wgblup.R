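#' Back-solve marker effects from BLUPs
#'
#' Given a genomic relationship matrix built from a centered marker coding
#' `Xc` and diagonal weights `w`, the marker effects consistent with the
#' BLUPs `ghat` are `u = w * Xc' K^{-1} ghat`. The reconstruction
#' `Xc %*% u / c`, with `c` the matrix's trace-normalization constant,
#' returns `ghat` exactly when `K` is non-singular.
#'
#' @param K genomic relationship (additive [g_matrix()] or dominance
#'   [d_matrix_genomic()]), regularized if needed.
#' @param Xc centered marker coding consistent with `K`'s construction
#'   (internally produced by [iterate_wgblup()]).
#' @param weights per-marker weights used to build `K`.
#' @param blups named BLUP vector aligned to `K`'s ids.
#' @return numeric vector of per-marker effects.
#' @export
backsolve_effects <- function(K, Xc, weights, blups) {
  ids <- rownames(K)
  if (!is.null(names(blups))) blups <- blups[ids]
  if (anyNA(blups)) stop("blups must cover every id of K")
  sol <- tryCatch(solve(K, blups), error = function(e) {
    stop("K is singular; regularize() it before back-solving")
  })
  as.numeric(weights * crossprod(Xc[ids, , drop = FALSE], sol))
}

#' Squared-effect marker weights, scaled to mean 1
#'
#' `w_j = u_j^2`, rescaled so the mean weight is 1 (sum equals the marker
#' count), which keeps the trace-normalized relationship matrices
#' comparable across weighting iterations.
#'
#' @param effects per-marker effect vector.
#' @return non-negative weight vector with mean 1.
#' @export
update_weights <- function(effects) {
  if (any(!is.finite(effects))) stop("effects must be finite")
  w <- effects^2
  s <- sum(w)
  if (s == 0) {
    warning("all marker effects are zero; returning uniform weights")
    return(rep(1, length(w)))
  }
  w * length(w) / s
}

#' Iterative weighted G-BLUP
#'
#' Runs the weighted G-BLUP scheme: start from identity weights (plain
#' G-BLUP), then repeatedly back-solve marker effects from the current
#' BLUPs, square them into weights (scaled to mean 1), rebuild the weighted
#' relationship matrices, and refit. Iterations 1..`n_iter` yield
#' `Gw1..Gw3` by default. When `include_dominance` is `TRUE`, a dominance
#' term with its own weights and weighted dominance matrix is carried
#' through the same scheme.
#'
#' @param g a [geno()] object (or dosage matrix).
#' @param y named phenotype vector (adjusted clonal means).
#' @param include_dominance also fit and weight a dominance term.
#' @param n_iter number of weighting iterations (default 3).
#' @param epsilon shrinkage applied before matrix inversion (default 1e-6).
#' @param ... passed to [fit_reml()].
#' @return list of class `"wgblup"`: `base` (iteration 0: plain G-BLUP fit,
#'   `G`, unit `weights`) and `iterations`, a list with one element per
#'   weighting step carrying `weights` (`weights_d`), `G` (`D`), `fit`.
#' @export
iterate_wgblup <- function(g, y, include_dominance = FALSE, n_iter = 3,
                           epsilon = 1e-6, ...) {
  stopifnot(n_iter >= 1)
  M <- if (inherits(g, "geno")) g$dosage else as.matrix(g)
  m <- ncol(M)
  Xa <- centered_coding(M, "additive")
  Xd <- if (include_dominance) centered_coding(M, "dominance") else NULL
  wa <- rep(1, m)
  wd <- rep(1, m)

  fit_once <- function(G, D) {
    random <- if (include_dominance) {
      list(additive = regularize(G, epsilon),
           dominance = regularize(D, epsilon))
    } else {
      list(additive = regularize(G, epsilon))
    }
    fit_reml(y, random, ...)
  }

  G <- g_matrix(M, wa)
  D <- if (include_dominance) d_matrix_genomic(M, wd) else NULL
  fit <- fit_once(G, D)
  base <- list(weights = wa, G = G, D = D, fit = fit)

  iterations <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    ua <- backsolve_effects(regularize(G, epsilon), Xa, wa,
                            fit$blup$additive)
    wa <- update_weights(ua)
    if (include_dominance) {
      ud <- backsolve_effects(regularize(D, epsilon), Xd, wd,
                              fit$blup$dominance)
      wd <- update_weights(ud)
    }
    G <- g_matrix(M, wa)
    if (include_dominance) D <- d_matrix_genomic(M, wd)
    fit <- tryCatch(fit_once(G, D), error = function(e) {
      stop("wGBLUP iteration ", i, " failed: ", conditionMessage(e))
    })
    iterations[[i]] <- c(list(weights = wa),
                         if (include_dominance) list(weights_d = wd),
                         list(G = G),
                         if (include_dominance) list(D = D),
                         list(fit = fit))
  }
  structure(list(base = base, iterations = iterations,
                 include_dominance = include_dominance),
            class = "wgblup")
}
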