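#' Training/validation partitions for cross-validation
#'
#' Draws `n_repetitions` independent training/validation splits. With
#' `composition = "individual"` a fraction of individuals is sampled into
#' training irrespective of family; with `"family"` whole full-sib families
#' are sampled so that no family straddles the two sides. Ids listed in
#' `test_set` are excluded from every training set (they form the
#' independent TestSet). `mode = "folds"` instead partitions into disjoint
#' folds of the requested fraction.
#'
#' @param individuals candidate ids.
#' @param family_map data.frame `(id, family)` covering all individuals
#'   (required for family composition).
#' @param composition `"individual"` or `"family"`.
#' @param fraction training fraction (the study scenarios are 0.5 and
#'   0.25).
#' @param n_repetitions number of splits (default 10).
#' @param seed base seed; repetition `r` uses `seed + r`.
#' @param test_set ids never allowed into training.
#' @param mode `"resample"` (independent draws, default) or `"folds"`.
#' @return list of `list(train, validation)` id vectors.
#' @export
make_partitions <- function(individuals, family_map = NULL,
                            composition = c("individual", "family"),
                            fraction = 0.5, n_repetitions = 10, seed = 1,
                            test_set = NULL, mode = c("resample", "folds")) {
  composition <- match.arg(composition)
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  pool <- setdiff(individuals, test_set)
  if (composition == "family") {
    if (is.null(family_map)) stop("family composition needs a family_map")
    fam <- family_map$family[match(pool, family_map$id)]
    if (anyNA(fam)) stop("family_map does not cover all individuals")
    fam_ids <- unique(fam)
  }
  out <- vector("list", n_repetitions)
  if (mode == "resample") {
    for (r in seq_len(n_repetitions)) {
      set.seed(seed + r)
      if (composition == "individual") {
        n_tr <- round(fraction * length(pool))
        if (n_tr < 1 || n_tr >= length(pool)) stop("fraction yields an empty side")
        train <- sample(pool, n_tr)
      } else {
        n_f <- round(fraction * length(fam_ids))
        if (n_f < 1 || n_f >= length(fam_ids)) stop("fraction yields an empty side")
        train_f <- sample(fam_ids, n_f)
        train <- pool[fam %in% train_f]
      }
      out[[r]] <- list(train = sort(train),
                       validation = sort(setdiff(pool, train)))
    }
  } else {
    set.seed(seed)
    k <- max(2L, round(1 / fraction))
    if (composition == "individual") {
      fold <- sample(rep_len(seq_len(k), length(pool)))
      out <- lapply(seq_len(min(k, n_repetitions)), function(f) {
        list(train = sort(pool[fold == f]),
             validation = sort(pool[fold != f]))
      })
    } else {
      ffold <- sample(rep_len(seq_len(k), length(fam_ids)))
      out <- lapply(seq_len(min(k, n_repetitions)), function(f) {
        train <- pool[fam %in% fam_ids[ffold == f]]
        list(train = sort(train), validation = sort(setdiff(pool, train)))
      })
    }
  }
  out
}

#' Predictive ability
#'
#' Pearson correlation between predictions (GEBVs) and observed adjusted
#' clonal means.
#'
#' @param predicted,observed aligned numeric vectors (>= 3 pairs, both with
#'   nonzero variance).
#' @return correlation coefficient.
#' @export
predictive_ability <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  ok <- !is.na(predicted) & !is.na(observed)
  if (sum(ok) < 3) stop("need at least 3 paired values")
  if (stats::sd(predicted[ok]) == 0 || stats::sd(observed[ok]) == 0) {
    stop("zero variance in predictions or observations")
  }
  stats::cor(predicted[ok], observed[ok])
}

#' Prediction accuracy
#'
#' Predictive ability divided by the square root of a reference
#' heritability (that of the pedigree A model for the trait). Values above
#' 1 are possible and retained.
#'
#' @param pa predictive ability.
#' @param h2_ref reference heritability in (0, 1].
#' @return accuracy.
#' @export
accuracy <- function(pa, h2_ref) {
  if (any(h2_ref <= 0) || any(h2_ref > 1)) stop("h2_ref must lie in (0, 1]")
  pa / sqrt(h2_ref)
}

#' Tier-wise rank and linear correlations
#'
#' Splits the evaluated set into tiers by quantiles of the observed values
#' (best first) and reports Spearman and Pearson correlations between
#' predictions and observations within each tier. Default tiers: top 5%,
#' 5-10%, 10-50%, and the full set. Tiers with fewer than 3 members get
#' `NA` correlations (flagged, not dropped).
#'
#' @param predicted,observed aligned numeric vectors.
#' @param tiers upper quantile bounds of the nested tiers
#'   (default `c(0.05, 0.10, 0.50, 1)`).
#' @param direction `"high"` when large observed values are best,
#'   `"low"` for traits where small values are best (e.g. rust score).
#' @return data.frame `tier`, `n`, `pearson`, `spearman`.
#' @export
rank_metrics <- function(predicted, observed, tiers = c(0.05, 0.1, 0.5, 1),
                         direction = c("high", "low")) {
  direction <- match.arg(direction)
  stopifnot(length(predicted) == length(observed))
  n <- length(observed)
  rk <- if (direction == "high") rank(-observed, ties.method = "first")
        else rank(observed, ties.method = "first")
  lo <- c(0, utils::head(tiers, -1))
  # the full-set tier (upper bound 1 with lower 0.5 from nesting) spans all
  lo[tiers == 1] <- 0
  out <- data.frame(tier = sprintf("%g-%g%%", 100 * lo, 100 * tiers),
                    n = NA_integer_, pearson = NA_real_, spearman = NA_real_)
  for (i in seq_along(tiers)) {
    ix <- which(rk > lo[i] * n & rk <= tiers[i] * n)
    out$n[i] <- length(ix)
    if (length(ix) >= 3 && stats::sd(observed[ix]) > 0 &&
        stats::sd(predicted[ix]) > 0) {
      out$pearson[i] <- stats::cor(predicted[ix], observed[ix])
      out$spearman[i] <- stats::cor(predicted[ix], observed[ix],
                                    method = "spearman")
    }
  }
  out
}

#' Bias regression of observations on predictions
#'
#' Least-squares regression of the adjusted clonal means on the GEBVs.
#' Slope 1 and intercept 0 indicate unbiased predictions; slopes above 1
#' flag shrunken (under-dispersed) predictions.
#'
#' @param observed,predicted aligned numeric vectors (>= 3 pairs).
#' @return named vector `c(intercept, slope)`.
#' @export
bias_regression <- function(observed, predicted) {
  stopifnot(length(predicted) == length(observed))
  ok <- !is.na(predicted) & !is.na(observed)
  if (sum(ok) < 3) stop("need at least 3 paired values")
  x <- predicted[ok]
  if (stats::var(x) == 0) stop("zero variance in predictions")
  slope <- stats::cov(observed[ok], x) / stats::var(x)
  c(intercept = mean(observed[ok]) - slope * mean(x), slope = unname(slope))
}

#' Within-family gain of genomic over pedigree predictions
#'
#' For each full-sib family with at least `min_size` evaluated members,
#' computes `Pearson(genomic predictions, observed) - Pearson(pedigree
#' predictions, observed)` and averages the differences weighted by family
#' size. Pedigree predictions that are constant within a family (pure
#' parent averages carry no within-family information) contribute a
#' correlation of 0 by convention.
#'
#' @param predicted_g,predicted_p named genomic and pedigree prediction
#'   vectors.
#' @param observed named observed values (the evaluated set).
#' @param family_map data.frame `(id, family)`.
#' @param min_size minimum family size (default 3).
#' @return list: `per_family` (data.frame family, n, pa_genomic,
#'   pa_pedigree, gain), `weighted_mean`, `skipped` (families below size).
#' @export
within_family_gain <- function(predicted_g, predicted_p, observed,
                               family_map, min_size = 3) {
  ids <- names(observed)
  stopifnot(!is.null(ids), all(ids %in% names(predicted_g)),
            all(ids %in% names(predicted_p)))
  fam <- family_map$family[match(ids, family_map$id)]
  if (anyNA(fam)) stop("family_map does not cover the evaluated set")
  res <- list()
  skipped <- character(0)
  safe_cor <- function(p, o) {
    if (stats::sd(p) == 0 || stats::sd(o) == 0) 0 else stats::cor(p, o)
  }
  for (f in unique(fam)) {
    ix <- ids[fam == f]
    if (length(ix) < min_size) {
      skipped <- c(skipped, f)
      next
    }
    pg <- safe_cor(predicted_g[ix], observed[ix])
    pp <- safe_cor(predicted_p[ix], observed[ix])
    res[[length(res) + 1L]] <- data.frame(
      family = f, n = length(ix), pa_genomic = pg, pa_pedigree = pp,
      gain = pg - pp, stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no family reaches the minimum size")
  per_family <- do.call(rbind, res)
  list(per_family = per_family,
       weighted_mean = sum(per_family$gain * per_family$n) / sum(per_family$n),
       skipped = skipped)
}

#' Run a full evaluation scenario grid
#'
#' Executes the factorial grid (trait) x (relationship matrix) x (scheme) x
#' (repetition): for every repetition of every scheme the training
#' phenotypes are fitted with each matrix, validation-set and TestSet
#' individuals are predicted through the matrix, and the metric battery is
#' computed. Validation and TestSet phenotypes never enter a fit (asserted
#' programmatically). Failures of individual cells are recorded and the run
#' continues.
#'
#' @param phenotypes named vector (single trait) or a named list of such
#'   vectors per trait (adjusted clonal means).
#' @param matrices named list of relationship matrices to compare
#'   (e.g. `list(A = A, Acor = Acor, G = G)`).
#' @param family_map data.frame `(id, family)`.
#' @param schemes data.frame with columns `composition` and `fraction`
#'   (default: individual/family x 0.5/0.25).
#' @param n_repetitions repetitions per scheme (default 10).
#' @param test_set ids excluded from all training (independent TestSet);
#'   may be empty.
#' @param h2_ref named per-trait reference heritabilities; when `NULL` and
#'   a matrix named `"A"` is supplied, they are estimated from the full
#'   data with that matrix.
#' @param direction per-trait best-is-high/low for tier metrics.
#' @param seed base seed.
#' @param ... passed to [fit_reml()].
#' @return data.frame of class `"evaluation_result"` in long format:
#'   `trait, matrix, scheme, fraction, repetition, population, metric,
#'   value`, with attributes `failures` (per-cell error messages) and
#'   `h2_ref`.
#' @export
run_scenario <- function(phenotypes, matrices, family_map,
                         schemes = expand.grid(
                           composition = c("individual", "family"),
                           fraction = c(0.5, 0.25),
                           stringsAsFactors = FALSE),
                         n_repetitions = 10, test_set = character(0),
                         h2_ref = NULL, direction = "high", seed = 1, ...) {
  if (!is.list(phenotypes)) phenotypes <- list(trait1 = phenotypes)
  traits <- names(phenotypes)
  direction <- rep_len(direction, length(traits))
  names(direction) <- traits
  if (is.null(names(matrices))) stop("matrices must be named")

  if (is.null(h2_ref)) {
    if (!"A" %in% names(matrices)) {
      stop("supply h2_ref or include a matrix named 'A' to estimate it from")
    }
    h2_ref <- vapply(phenotypes, function(y) {
      fit_reml(y, list(additive = matrices[["A"]]), ...)$h2
    }, numeric(1))
  }
  h2_ref <- rep_len(h2_ref, length(traits))
  names(h2_ref) <- traits

  rows <- list()
  failures <- list()
  scheme_tags <- paste0(substr(schemes$composition, 1, 1), "T",
                        schemes$fraction * 100)
  for (t in traits) {
    y <- phenotypes[[t]]
    cand <- setdiff(names(y), test_set)
    for (s in seq_len(nrow(schemes))) {
      parts <- make_partitions(cand, family_map,
                               composition = schemes$composition[s],
                               fraction = schemes$fraction[s],
                               n_repetitions = n_repetitions,
                               seed = seed + 1000 * s, test_set = test_set)
      for (r in seq_len(n_repetitions)) {
        train <- parts[[r]]$train
        valid <- parts[[r]]$validation
        stopifnot(length(intersect(train, valid)) == 0,
                  length(intersect(train, test_set)) == 0)
        for (mk in names(matrices)) {
          cell <- sprintf("%s|%s|%s|rep%d", t, mk, scheme_tags[s], r)
          res <- tryCatch({
            fit <- fit_reml(y[train], list(additive = matrices[[mk]]), ...)
            met <- list()
            for (popn in c("VS", "TestSet")) {
              ids <- if (popn == "VS") valid else intersect(test_set, names(y))
              if (length(ids) < 3) next
              pred <- predict_gebv(fit, ids)
              obs <- y[ids]
              pa <- predictive_ability(pred, obs)
              br <- bias_regression(obs, pred)
              sp <- stats::cor(pred, obs, method = "spearman")
              met[[popn]] <- data.frame(
                metric = c("predictive_ability", "accuracy", "spearman",
                           "slope", "intercept"),
                value = c(pa, accuracy(pa, h2_ref[t]), sp,
                          br["slope"], br["intercept"]))
            }
            met
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failures[[cell]] <- conditionMessage(res)
            next
          }
          for (popn in names(res)) {
            df <- res[[popn]]
            rows[[length(rows) + 1L]] <- data.frame(
              trait = t, matrix = mk, scheme = schemes$composition[s],
              fraction = schemes$fraction[s], repetition = r,
              population = popn, metric = df$metric, value = df$value,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(), matrix = character(),
               scheme = character(), fraction = numeric(),
               repetition = integer(), population = character(),
               metric = character(), value = numeric())
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  attr(out, "h2_ref") <- h2_ref
  class(out) <- c("evaluation_result", "data.frame")
  out
}
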