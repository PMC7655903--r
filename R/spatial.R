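#' Tensor-product cubic B-spline surface design
#'
#' Builds the design matrix of a bi-spline surface over integer plot
#' coordinates: cubic B-spline bases anchored at `n_knots_row`
#' (`n_knots_col`) equally spaced knots spanning the coordinate range,
#' giving `(k + 2)` basis functions per axis and `(kr + 2) * (kc + 2)`
#' tensor-product coefficients. Every row sums to 1 (partition of unity).
#'
#' @param rows,cols plot coordinates (equal length vectors).
#' @param n_knots_row,n_knots_col knot counts (>= 2), at most the number of
#'   distinct coordinates on the axis.
#' @return sparse design matrix, one row per plot.
#' @export
bspline_surface_design <- function(rows, cols, n_knots_row, n_knots_col) {
  stopifnot(length(rows) == length(cols))
  Br <- bspline_basis_1d(rows, n_knots_row)
  Bc <- bspline_basis_1d(cols, n_knots_col)
  # row-wise tensor product
  n <- nrow(Br)
  out <- matrix(0, n, ncol(Br) * ncol(Bc))
  for (j in seq_len(ncol(Bc))) {
    out[, (j - 1L) * ncol(Br) + seq_len(ncol(Br))] <- Br * Bc[, j]
  }
  Matrix::Matrix(out, sparse = TRUE)
}

bspline_basis_1d <- function(x, n_knots) {
  if (n_knots < 2) stop("need at least 2 knots")
  if (n_knots > length(unique(x))) {
    stop("more knots (", n_knots, ") than distinct coordinates (",
         length(unique(x)), ")")
  }
  kn <- seq(min(x), max(x), length.out = n_knots)
  all_kn <- c(rep(kn[1], 3), kn, rep(kn[n_knots], 3))
  splines::splineDesign(all_kn, x, ord = 4)
}

#' Fit a spatial model to replicated field observations
#'
#' Model per plot: `y = mu + genotype + surface + e`, where the genotype
#' effect is random with covariance `sigma_g^2 * K`, the surface is a
#' tensor-product B-spline with i.i.d. random coefficients (one common
#' variance), nested within trial, and the residual is i.i.d. The model is
#' fitted by EM-REML for every knot pair in `knot_grid`; the fit minimizing
#' AIC is returned.
#'
#' @param obs a `field_obs` data.frame (single trait; columns `trial`,
#'   `row`, `col`, `genotype`, `value`, optionally `trait`).
#' @param genotype_K relationship matrix covering all genotypes (e.g.
#'   pedigree A).
#' @param knot_grid matrix/data.frame with columns `(kr, kc)`; default the
#'   grid \{4, 6, 8, 10\}^2.
#' @param epsilon shrinkage applied to `genotype_K` before inversion.
#' @param max_iter,tol_logl,tol_var REML controls (see [fit_reml()]).
#' @return object of class `"spatial_fit"`: `knots`, `varcomp`, `logLik`,
#'   `aic`, `surface` (per-plot surface value, centered within trial),
#'   `genetic` (per-genotype BLUPs), `obs` (the input rows, with `surface`
#'   attached), `aic_table` (all knot pairs tried).
#' @export
fit_spatial <- function(obs, genotype_K,
                        knot_grid = as.matrix(expand.grid(kr = c(4, 6, 8, 10),
                                                          kc = c(4, 6, 8, 10))),
                        epsilon = 1e-6, max_iter = 300, tol_logl = 1e-8,
                        tol_var = 1e-6) {
  obs <- as.data.frame(obs)
  if ("trait" %in% names(obs) && length(unique(obs$trait)) > 1) {
    stop("fit_spatial adjusts one trait at a time; subset obs first")
  }
  need <- c("trial", "row", "col", "genotype", "value")
  if (!all(need %in% names(obs))) {
    stop("obs needs columns ", paste(need, collapse = ", "))
  }
  gids <- rownames(genotype_K)
  missing <- setdiff(unique(obs$genotype), gids)
  if (length(missing)) {
    stop("genotypes absent from K: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  Kr <- regularize(genotype_K, epsilon)
  Kinv <- chol2inv(chol(Kr))
  logdetK <- as.numeric(determinant(Kr)$modulus)
  y <- obs$value
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  Zg <- incidence(obs$genotype, gids)
  trials <- sort(unique(obs$trial))

  knot_grid <- as.matrix(knot_grid)
  fits <- vector("list", nrow(knot_grid))
  aics <- rep(NA_real_, nrow(knot_grid))
  errs <- character(nrow(knot_grid))
  for (k in seq_len(nrow(knot_grid))) {
    kr <- knot_grid[k, 1]
    kc <- knot_grid[k, 2]
    res <- tryCatch({
      # surface nested within trial: block design matrix
      Bs <- lapply(trials, function(tr) {
        ix <- obs$trial == tr
        B <- bspline_surface_design(obs$row[ix], obs$col[ix], kr, kc)
        out <- Matrix::Matrix(0, length(y), ncol(B), sparse = TRUE)
        out[ix, ] <- B
        out
      })
      B <- do.call(cbind, Bs)
      terms <- list(
        list(name = "genotype", Z = Zg, Kinv = Kinv, logdetK = logdetK,
             q = length(gids)),
        list(name = "surface", Z = B, Kinv = NULL, logdetK = 0,
             q = ncol(B)))
      fit <- suppressWarnings(
        reml_em(y, X, terms, max_iter = max_iter,
                tol_logl = tol_logl, tol_var = tol_var))
      k_par <- length(fit$varcomp)
      list(fit = fit, B = B, aic = -2 * fit$logLik + 2 * k_par)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errs[k] <- res
    } else {
      fits[[k]] <- res
      aics[k] <- res$aic
    }
  }
  if (all(is.na(aics))) {
    stop("no knot pair converged:\n",
         paste(sprintf("  (%g,%g): %s", knot_grid[, 1], knot_grid[, 2], errs),
               collapse = "\n"))
  }
  best <- which.min(aics)
  fit <- fits[[best]]$fit
  B <- fits[[best]]$B
  coef_s <- fit$u[[2]]
  surface <- as.numeric(B %*% coef_s)
  # identifiability: the surface level is absorbed by the intercept;
  # report the surface centered within each trial
  for (tr in trials) {
    ix <- obs$trial == tr
    surface[ix] <- surface[ix] - mean(surface[ix])
  }
  obs$surface <- surface
  vc <- stats::setNames(fit$varcomp, c("genetic", "spatial", "residual"))
  structure(list(knots = stats::setNames(knot_grid[best, ], c("kr", "kc")),
                 varcomp = vc, logLik = fit$logLik, aic = aics[best],
                 surface = surface,
                 genetic = stats::setNames(fit$u[[1]], gids),
                 obs = obs,
                 aic_table = data.frame(kr = knot_grid[, 1],
                                        kc = knot_grid[, 2], aic = aics),
                 converged = fit$converged),
            class = "spatial_fit")
}

#' Spatially adjusted clonal means
#'
#' Subtracts the fitted micro-environmental surface from each observation
#' and averages the adjusted values per genotype over the retained blocks.
#' Genotypes absent from the retained blocks are dropped and listed in the
#' `dropped` attribute.
#'
#' @param fit a [fit_spatial()] result.
#' @param blocks blocks to keep (default all observed blocks; the degraded
#'   variant uses e.g. `c(1, 3, 5)`).
#' @return data.frame `genotype`, `mean`, `n_reps_used`, with attributes
#'   `blocks_used` and `dropped`.
#' @export
adjust_and_average <- function(fit, blocks = NULL) {
  stopifnot(inherits(fit, "spatial_fit"))
  obs <- fit$obs
  all_blocks <- sort(unique(obs$block))
  if (is.null(blocks)) blocks <- all_blocks
  if (!length(blocks)) stop("empty block subset")
  if (length(setdiff(blocks, all_blocks))) {
    stop("unknown blocks: ", paste(setdiff(blocks, all_blocks), collapse = ", "))
  }
  keep <- obs$block %in% blocks
  adj <- obs$value[keep] - obs$surface[keep]
  g <- obs$genotype[keep]
  means <- tapply(adj, g, mean)
  nrep <- tapply(adj, g, length)
  dropped <- setdiff(unique(obs$genotype), names(means))
  out <- data.frame(genotype = names(means), mean = as.numeric(means),
                    n_reps_used = as.integer(nrep), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "blocks_used") <- blocks
  attr(out, "dropped") <- dropped
  out
}
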