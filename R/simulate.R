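#' Mating designs
#'
#' A mating design lists founder sires and dams and a table of crosses
#' `(sire, dam, n_offspring)`. `factorial_design()` crosses every sire with
#' every dam; `pair_design()` mates them pairwise; `mating_design()` accepts
#' an arbitrary cross table (e.g. read from a published family-size table).
#'
#' @param sires,dams character vectors of founder ids.
#' @param n_offspring offspring per cross (recycled).
#' @param crosses data.frame with columns `sire`, `dam`, `n_offspring`.
#' @param design_kind tag: `"factorial"`, `"pair"` or `"mixed"`.
#' @return object of class `"mating_design"`.
#' @export
mating_design <- function(sires, dams, crosses, design_kind = "mixed") {
  sires <- as.character(sires)
  dams <- as.character(dams)
  stopifnot(all(c("sire", "dam", "n_offspring") %in% names(crosses)))
  crosses$sire <- as.character(crosses$sire)
  crosses$dam <- as.character(crosses$dam)
  if (length(intersect(sires, dams))) {
    stop("a founder cannot be both sire and dam: ",
         paste(intersect(sires, dams), collapse = ", "))
  }
  if (!all(crosses$sire %in% sires)) stop("cross references undeclared sire")
  if (!all(crosses$dam %in% dams)) stop("cross references undeclared dam")
  if (any(crosses$n_offspring < 1)) stop("n_offspring must be >= 1")
  structure(list(sires = sires, dams = dams,
                 crosses = crosses[, c("sire", "dam", "n_offspring")],
                 design_kind = design_kind),
            class = "mating_design")
}

#' @rdname mating_design
#' @export
factorial_design <- function(sires, dams, n_offspring) {
  cr <- expand.grid(sire = sires, dam = dams, stringsAsFactors = FALSE)
  cr$n_offspring <- rep_len(n_offspring, nrow(cr))
  mating_design(sires, dams, cr, design_kind = "factorial")
}

#' @rdname mating_design
#' @export
pair_design <- function(sires, dams, n_offspring) {
  stopifnot(length(sires) == length(dams))
  cr <- data.frame(sire = sires, dam = dams,
                   n_offspring = rep_len(n_offspring, length(sires)),
                   stringsAsFactors = FALSE)
  mating_design(sires, dams, cr, design_kind = "pair")
}

#' Mating design from a family-count table
#'
#' Builds a `"mixed"` design from a table with columns `mother`, `father`
#' and `n_offspring`, such as a published cross table.
#'
#' @param counts data.frame with columns `mother`, `father`, `n_offspring`.
#' @return a [mating_design()].
#' @export
design_from_family_table <- function(counts) {
  stopifnot(all(c("mother", "father", "n_offspring") %in% names(counts)))
  mating_design(sires = unique(counts$father), dams = unique(counts$mother),
                crosses = data.frame(sire = counts$father,
                                     dam = counts$mother,
                                     n_offspring = counts$n_offspring,
                                     stringsAsFactors = FALSE),
                design_kind = "mixed")
}

#' Simulate founder genotypes
#'
#' Founder haplotypes are drawn independently per marker at allele
#' frequencies uniform on `maf_range`, giving Hardy-Weinberg genotype
#' proportions. Markers are spread over `n_chromosomes` chromosomes with
#' strictly increasing, uniformly sampled positions.
#'
#' @param n_sires,n_dams founder counts (ids `S1..`, `D1..` unless
#'   `sire_ids`/`dam_ids` are given).
#' @param sire_ids,dam_ids optional explicit founder ids (e.g. the parent
#'   names of a published cross table).
#' @param n_markers total marker count.
#' @param maf_range interval within (0, 0.5] for allele frequencies.
#' @param n_chromosomes chromosome count (default 19, the poplar karyotype).
#' @param chrom_length_mb physical length per chromosome.
#' @param seed integer seed (all randomness is derived from it).
#' @return a phased [geno()] object for the founders.
#' @export
simulate_founders <- function(n_sires, n_dams, n_markers,
                              maf_range = c(0.05, 0.5),
                              n_chromosomes = 19, chrom_length_mb = 25,
                              seed = 1, sire_ids = NULL, dam_ids = NULL) {
  if (n_sires < 1 || n_dams < 1 || n_markers < 1 || n_chromosomes < 1) {
    stop("counts must be positive")
  }
  if (!is.null(sire_ids) && length(sire_ids) != n_sires) {
    stop("sire_ids length must equal n_sires")
  }
  if (!is.null(dam_ids) && length(dam_ids) != n_dams) {
    stop("dam_ids length must equal n_dams")
  }
  if (n_markers < n_chromosomes) stop("need at least one marker per chromosome")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  set.seed(seed)
  ids <- c(if (is.null(sire_ids)) paste0("S", seq_len(n_sires)) else sire_ids,
           if (is.null(dam_ids)) paste0("D", seq_len(n_dams)) else dam_ids)
  n <- length(ids)
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_markers))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(ix) {
    sort(sample.int(chrom_length_mb * 1e6, length(ix)))
  }), use.names = FALSE)
  map <- data.frame(marker = sprintf("M%05d", seq_len(n_markers)),
                    chrom = chrom, pos_bp = pos, stringsAsFactors = FALSE)
  p <- stats::runif(n_markers, maf_range[1], maf_range[2])
  draw <- function() {
    h <- matrix(stats::rbinom(n * n_markers, 1L, rep(p, each = n)),
                nrow = n, ncol = n_markers,
                dimnames = list(ids, map$marker))
    h
  }
  H1 <- draw()
  H2 <- draw()
  out <- geno(H1 + H2, map, haplotypes = list(H1 = H1, H2 = H2))
  out$base_freq <- p  # true sampling frequencies of the base population
  out
}

#' Simulate a pedigree from a mating design
#'
#' Founders (sires then dams) are listed first with unknown parents;
#' offspring follow, grouped by cross, with ids `F<k>_<j>` for cross `k`.
#'
#' @param design a [mating_design()].
#' @param seed integer seed (reserved; offspring layout is deterministic).
#' @return a [pedigree()].
#' @export
simulate_pedigree <- function(design, seed = 1) {
  stopifnot(inherits(design, "mating_design"))
  cr <- design$crosses
  off_id <- character(0)
  off_sire <- character(0)
  off_dam <- character(0)
  if (nrow(cr)) {
    for (k in seq_len(nrow(cr))) {
      nk <- cr$n_offspring[k]
      off_id <- c(off_id, sprintf("F%02d_%03d", k, seq_len(nk)))
      off_sire <- c(off_sire, rep(cr$sire[k], nk))
      off_dam <- c(off_dam, rep(cr$dam[k], nk))
    }
  }
  fo <- c(design$sires, design$dams)
  pedigree(id = c(fo, off_id),
           sire = c(rep(NA_character_, length(fo)), off_sire),
           dam = c(rep(NA_character_, length(fo)), off_dam))
}

# one recombined gamete from a phased parent
make_gamete <- function(H1, H2, map, recomb_rate_per_mb) {
  m <- length(H1)
  out <- numeric(m)
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    pos <- map$pos_bp[ix]
    len_mb <- max(pos) / 1e6
    n_cross <- stats::rpois(1L, recomb_rate_per_mb * len_mb)
    cuts <- sort(stats::runif(n_cross, 0, max(pos)))
    phase <- (findInterval(pos, cuts) + stats::rbinom(1L, 1L, 0.5)) %% 2L
    out[ix] <- ifelse(phase == 0L, H1[ix], H2[ix])
  }
  out
}

#' Gene dropping through a pedigree
#'
#' Each offspring receives one recombined gamete per parent. Crossovers per
#' chromosome are Poisson with mean `recomb_rate_per_mb * length_mb`, placed
#' uniformly, with no interference. Offspring genotypes are therefore
#' Mendelian-consistent with their parents at every marker.
#'
#' @param ped a [pedigree()] whose founders are all present in
#'   `founder_geno`.
#' @param founder_geno phased [geno()] (from [simulate_founders()]).
#' @param recomb_rate_per_mb crossovers per megabase (0.01 = 1 cM/Mb).
#' @param seed integer seed.
#' @return a phased [geno()] for all pedigree members.
#' @export
drop_genes <- function(ped, founder_geno, recomb_rate_per_mb = 0.02,
                       seed = 1) {
  stopifnot(inherits(founder_geno, "geno"))
  if (is.null(founder_geno$haplotypes)) {
    stop("founder genotypes must be phased (simulate_founders output)")
  }
  set.seed(seed)
  map <- founder_geno$map
  m <- nrow(map)
  n <- nrow(ped)
  H1 <- matrix(NA_real_, n, m, dimnames = list(ped$id, map$marker))
  H2 <- H1
  fnd <- founders(ped)
  missing <- setdiff(fnd, rownames(founder_geno$dosage))
  if (length(missing)) {
    stop("ungenotyped founders: ", paste(missing, collapse = ", "))
  }
  H1[fnd, ] <- founder_geno$haplotypes$H1[fnd, , drop = FALSE]
  H2[fnd, ] <- founder_geno$haplotypes$H2[fnd, , drop = FALSE]
  for (i in seq_len(n)) {
    id <- ped$id[i]
    if (id %in% fnd) next
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (is.na(s) || is.na(d)) {
      stop("non-founder ", id, " has an unknown parent; cannot gene-drop")
    }
    H1[i, ] <- make_gamete(H1[s, ], H2[s, ], map, recomb_rate_per_mb)
    H2[i, ] <- make_gamete(H1[d, ], H2[d, ], map, recomb_rate_per_mb)
  }
  out <- geno(H1 + H2, map, haplotypes = list(H1 = H1, H2 = H2))
  out$base_freq <- founder_geno$base_freq
  out
}

#' Trait architecture for the simulator
#'
#' Describes the generative model for a battery of correlated traits on a
#' clonally replicated trial: a finite-QTL additive(+dominance) genetic
#' architecture, target broad-sense clonal-mean heritabilities, and the
#' trial structure (block count, spatial autocorrelation).
#'
#' @param n_traits number of traits.
#' @param n_qtl QTL per trait (shared across traits; pleiotropy carries the
#'   genetic correlation).
#' @param dominance_ratio ratio of dominance to additive variance at QTL,
#'   in \[0, 1\].
#' @param genetic_correlation trait correlation matrix (symmetric, unit
#'   diagonal, positive definite).
#' @param target_h2 vector of broad-sense clonal-mean heritabilities in
#'   (0, 1\].
#' @param n_blocks clonal replicates (complete blocks), default 6.
#' @param spatial_range correlation length of the micro-environment in plot
#'   units (used as the B-spline knot spacing of the simulated surface).
#' @param spatial_variance_fraction fraction of plot-level variance due to
#'   the spatial surface, in \[0, 1).
#' @return object of class `"trait_architecture"`.
#' @export
trait_architecture <- function(n_traits = 1, n_qtl = 100,
                               dominance_ratio = 0,
                               genetic_correlation = diag(n_traits),
                               target_h2 = rep(0.6, n_traits),
                               n_blocks = 6, spatial_range = 10,
                               spatial_variance_fraction = 0.2) {
  genetic_correlation <- as.matrix(genetic_correlation)
  if (!isTRUE(all.equal(genetic_correlation, t(genetic_correlation))) ||
      !isTRUE(all.equal(unname(diag(genetic_correlation)),
                        rep(1, n_traits)))) {
    stop("genetic_correlation must be symmetric with unit diagonal")
  }
  if (min(eigen(genetic_correlation, symmetric = TRUE,
                only.values = TRUE)$values) <= 1e-10) {
    stop("genetic_correlation must be positive definite")
  }
  if (any(target_h2 <= 0) || any(target_h2 > 1)) {
    stop("target_h2 must lie in (0, 1]")
  }
  if (dominance_ratio < 0 || dominance_ratio > 1) {
    stop("dominance_ratio must lie in [0, 1]")
  }
  if (spatial_variance_fraction < 0 || spatial_variance_fraction >= 1) {
    stop("spatial_variance_fraction must lie in [0, 1)")
  }
  structure(list(n_traits = n_traits, n_qtl = n_qtl,
                 dominance_ratio = dominance_ratio,
                 genetic_correlation = genetic_correlation,
                 target_h2 = rep_len(target_h2, n_traits),
                 n_blocks = n_blocks, spatial_range = spatial_range,
                 spatial_variance_fraction = spatial_variance_fraction),
            class = "trait_architecture")
}

#' Simulate true genetic values under a finite-QTL model
#'
#' QTL are sampled from the marker panel. Per-QTL additive effects are drawn
#' from a multivariate normal across traits with the architecture's genetic
#' correlation; dominance deviations (effects on the heterozygosity coding)
#' are drawn likewise and rescaled so that `var(TDV) = dominance_ratio *
#' var(TBV)` per trait. True breeding values are centered by construction.
#'
#' @param g a [geno()] object for the whole population.
#' @param architecture a [trait_architecture()].
#' @param seed integer seed.
#' @return list of class `"truth"`: `tbv`, `tdv`, `gv` (n x traits
#'   matrices), `qtl` (marker indices), `architecture`.
#' @export
simulate_traits <- function(g, architecture, seed = 1) {
  stopifnot(inherits(g, "geno"), inherits(architecture, "trait_architecture"))
  arch <- architecture
  m <- ncol(g$dosage)
  if (arch$n_qtl > m) stop("n_qtl exceeds the number of markers")
  set.seed(seed)
  qtl <- sort(sample.int(m, arch$n_qtl))
  M <- g$dosage[, qtl, drop = FALSE]
  Mc <- scale(M, center = TRUE, scale = FALSE)
  L <- chol(arch$genetic_correlation)
  B <- matrix(stats::rnorm(arch$n_qtl * arch$n_traits), arch$n_qtl) %*% L
  tbv <- Mc %*% B
  # rescale each trait to additive variance 1
  sda <- apply(tbv, 2, stats::sd)
  if (any(sda == 0)) stop("degenerate additive values (monomorphic QTL set?)")
  tbv <- sweep(tbv, 2, sda, "/")
  tbv <- scale(tbv, center = TRUE, scale = FALSE)
  if (arch$dominance_ratio > 0) {
    X <- (M == 1) * 1
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Dd <- matrix(stats::rnorm(arch$n_qtl * arch$n_traits), arch$n_qtl) %*% L
    tdv <- Xc %*% Dd
    sdd <- apply(tdv, 2, stats::sd)
    sdd[sdd == 0] <- 1
    tdv <- sweep(tdv, 2, sqrt(arch$dominance_ratio) / sdd, "*")
    tdv <- scale(tdv, center = TRUE, scale = FALSE)
  } else {
    tdv <- matrix(0, nrow(M), arch$n_traits)
  }
  tn <- paste0("trait", seq_len(arch$n_traits))
  dimnames(tbv) <- dimnames(tdv) <- list(rownames(g$dosage), tn)
  structure(list(tbv = tbv, tdv = tdv, gv = tbv + tdv, qtl = qtl,
                 architecture = arch),
            class = "truth")
}

# smooth low-rank B-spline surface over a rows x cols field, variance 1
draw_spline_surface <- function(n_rows, n_cols, knot_spacing) {
  kr <- max(3L, round(n_rows / knot_spacing) + 1L)
  kc <- max(3L, round(n_cols / knot_spacing) + 1L)
  B <- bspline_surface_design(rep(seq_len(n_rows), times = n_cols),
                              rep(seq_len(n_cols), each = n_rows), kr, kc)
  s <- as.vector(B %*% stats::rnorm(ncol(B)))
  s <- s - mean(s)
  sdv <- stats::sd(s)
  if (sdv > 0) s <- s / sdv
  matrix(s, n_rows, n_cols)
}

#' Simulate a clonally replicated field trial
#'
#' Every genotype is planted once per block on a `n_rows x n_cols` grid
#' (blocks occupy contiguous runs of plots, genotype order randomized
#' within block). The observation is `genotypic value + spatial surface +
#' residual`. The residual variance is set so the broad-sense clonal-mean
#' heritability equals `target_h2`:
#' `H2 = var(gv) / (var(gv) + sigma_e^2 / n_blocks)`; the surface (a smooth
#' low-rank B-spline draw with knot spacing `spatial_range`) is scaled so it
#' accounts for `spatial_variance_fraction` of the plot-level variance.
#'
#' @param truth output of [simulate_traits()].
#' @param layout integer pair `(n_rows, n_cols)`; must hold
#'   `n_blocks * n_genotypes` plots.
#' @param architecture the [trait_architecture()] (block count, spatial
#'   settings, target heritabilities).
#' @param seed integer seed.
#' @return data.frame of class `"field_obs"` with columns
#'   `trial, block, row, col, genotype, trait, value`; the simulated
#'   micro-environmental value per plot is attached as attribute
#'   `"true_surface"` for recovery checks.
#' @export
simulate_field_trial <- function(truth, layout, architecture = truth$architecture,
                                 seed = 1) {
  stopifnot(inherits(truth, "truth"))
  arch <- architecture
  gv <- truth$gv
  ids <- rownames(gv)
  n_g <- length(ids)
  n_rows <- layout[1]
  n_cols <- layout[2]
  n_plots <- n_rows * n_cols
  need <- n_g * arch$n_blocks
  if (n_plots < need) {
    stop("layout too small: ", n_plots, " plots for ", need, " plantings")
  }
  set.seed(seed)
  # column-major plot order; block b takes plots ((b-1)*n_g+1):(b*n_g)
  plot_row <- rep(seq_len(n_rows), times = n_cols)
  plot_col <- rep(seq_len(n_cols), each = n_rows)
  recs <- vector("list", arch$n_traits)
  assign_block <- lapply(seq_len(arch$n_blocks), function(b) sample(ids))
  for (t in seq_len(arch$n_traits)) {
    vg <- stats::var(gv[, t])
    h2 <- arch$target_h2[t]
    sig_e2 <- if (h2 >= 1) 0 else arch$n_blocks * vg * (1 - h2) / h2
    f <- arch$spatial_variance_fraction
    sig_s2 <- if (f > 0) f * (vg + sig_e2) / (1 - f) else 0
    surf <- if (sig_s2 > 0) {
      sqrt(sig_s2) * draw_spline_surface(n_rows, n_cols, arch$spatial_range)
    } else {
      matrix(0, n_rows, n_cols)
    }
    rows <- vector("list", arch$n_blocks)
    for (b in seq_len(arch$n_blocks)) {
      gset <- assign_block[[b]]
      pix <- (b - 1L) * n_g + seq_len(n_g)
      r <- plot_row[pix]
      cc <- plot_col[pix]
      e <- if (sig_e2 > 0) stats::rnorm(n_g, 0, sqrt(sig_e2)) else 0
      sv <- surf[cbind(r, cc)]
      rows[[b]] <- data.frame(
        trial = 1L, block = b, row = r, col = cc, genotype = gset,
        trait = colnames(gv)[t],
        value = gv[gset, t] + sv + e,
        .surface = sv,
        stringsAsFactors = FALSE)
    }
    recs[[t]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  true_surface <- out$.surface
  out$.surface <- NULL
  attr(out, "true_surface") <- true_surface
  class(out) <- c("field_obs", "data.frame")
  out
}

#' Introduce paternity errors into a pedigree
#'
#' Mimics the dominant error mode of operational crossing records: wrong
#' paternity attribution of complete or partial full-sib families. Families
#' are visited in random order; within a family a contiguous run of
#' offspring (the whole family while the error budget allows, else the
#' remainder) is reassigned to a single different declared sire.
#'
#' @param ped a [pedigree()] with at least 2 distinct sires.
#' @param error_rate fraction of offspring to corrupt, in \[0, 1\].
#' @param seed integer seed.
#' @return list: `pedigree` (corrupted), `changes` (data.frame id,
#'   old_sire, new_sire).
#' @export
corrupt_pedigree <- function(ped, error_rate, seed = 1) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  sires <- unique(stats::na.omit(ped$sire))
  off <- which(!is.na(ped$sire))
  if (error_rate > 0 && length(sires) < 2) {
    stop("need at least 2 declared sires to corrupt paternity")
  }
  empty_log <- data.frame(id = character(), old_sire = character(),
                          new_sire = character(), stringsAsFactors = FALSE)
  if (error_rate == 0 || !length(off)) {
    return(list(pedigree = ped, changes = empty_log))
  }
  set.seed(seed)
  target <- round(error_rate * length(off))
  fam <- paste(ped$sire[off], ped$dam[off])
  fam_list <- split(off, fam)
  fam_list <- fam_list[sample.int(length(fam_list))]
  new_sire <- ped$sire
  log <- list()
  corrupted <- 0L
  for (block in fam_list) {
    if (corrupted >= target) break
    take <- min(length(block), target - corrupted)
    rows <- block[seq_len(take)]  # contiguous run within the family
    old <- ped$sire[rows[1]]
    wrong <- sample(setdiff(sires, old), 1L)
    new_sire[rows] <- wrong
    log[[length(log) + 1L]] <- data.frame(
      id = ped$id[rows], old_sire = old, new_sire = wrong,
      stringsAsFactors = FALSE)
    corrupted <- corrupted + take
  }
  list(pedigree = pedigree(ped$id, new_sire, ped$dam),
       changes = if (length(log)) do.call(rbind, log) else empty_log)
}

#' Write field observations / truth tables
#'
#' Plain CSV writers matching the simulator's long formats.
#'
#' @param x a `"field_obs"` data.frame or `"truth"` object.
#' @param path output CSV.
#' @export
write_field_obs <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_obs
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "truth"))
  df <- data.frame(id = rownames(x$tbv),
                   trait = rep(colnames(x$tbv), each = nrow(x$tbv)),
                   tbv = as.vector(x$tbv), tdv = as.vector(x$tdv),
                   gv = as.vector(x$gv), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
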