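#' Count opposing homozygotes between two individuals
#'
#' Opposing homozygotes are markers at which one individual carries dosage 0
#' and the other dosage 2. Under error-free genotyping a true parent and
#' offspring share an allele everywhere, so the count is 0; unrelated pairs
#' accumulate counts in proportion to `2 p^2 q^2` per marker under
#' Hardy-Weinberg.
#'
#' @param g a [geno()] object (or plain dosage matrix with id rownames).
#' @param offspring,candidate individual ids present in `g`.
#' @return integer count over shared non-missing markers.
#' @export
opposing_homozygotes <- function(g, offspring, candidate) {
  M <- if (inherits(g, "geno")) g$dosage else g
  for (id in c(offspring, candidate)) {
    if (!id %in% rownames(M)) stop("id not genotyped: ", id)
  }
  a <- M[offspring, ]
  b <- M[candidate, ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no shared non-missing markers between ", offspring,
                     " and ", candidate)
  sum((a[ok] == 0 & b[ok] == 2) | (a[ok] == 2 & b[ok] == 0))
}

oh_rate <- function(M, a, b) {
  x <- M[a, ]
  y <- M[b, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(c(count = NA_real_, rate = NA_real_, shared = 0))
  cnt <- sum((x[ok] == 0 & y[ok] == 2) | (x[ok] == 2 & y[ok] == 0))
  c(count = cnt, rate = cnt / sum(ok), shared = sum(ok))
}

#' Correct a pedigree with marker information
#'
#' For each offspring, the declared sire (and, symmetrically, dam) is tested
#' by opposing-homozygote exclusion. When the declared parent's
#' opposing-homozygote fraction exceeds `oh_threshold_fraction`, the parent
#' is reassigned to the declared parent (same sex role) with the smallest
#' fraction, provided that fraction falls below the threshold; otherwise the
#' parent is set to unknown. Candidates are the parents already declared in
#' the pedigree for that role, so no novel parents are invented.
#'
#' @param ped a [pedigree()].
#' @param g a [geno()] object covering all parents and offspring involved.
#' @param oh_threshold_fraction exclusion threshold as a fraction of
#'   compared markers (default 0.01, tolerating some genotyping error).
#' @param sire_candidates,dam_candidates parental rosters to reassign
#'   from. They default to the parents declared in `ped`; pass the full
#'   known roster when recorded errors may have displaced a parent from
#'   every one of its crosses.
#' @return list with elements `pedigree` (corrected) and `changes`
#'   (data.frame: id, role, old, new, oh_old, oh_new).
#' @export
correct_pedigree <- function(ped, g, oh_threshold_fraction = 0.01,
                             sire_candidates = NULL,
                             dam_candidates = NULL) {
  M <- if (inherits(g, "geno")) g$dosage else g
  sires <- if (is.null(sire_candidates)) {
    unique(stats::na.omit(ped$sire))
  } else {
    as.character(sire_candidates)
  }
  dams <- if (is.null(dam_candidates)) {
    unique(stats::na.omit(ped$dam))
  } else {
    as.character(dam_candidates)
  }
  changes <- list()
  new_sire <- ped$sire
  new_dam <- ped$dam

  fix_role <- function(i, declared, candidates, role) {
    id <- ped$id[i]
    if (is.na(declared) || !id %in% rownames(M)) return(declared)
    if (!declared %in% rownames(M)) return(declared)
    cur <- oh_rate(M, id, declared)
    if (is.na(cur["rate"]) || cur["rate"] <= oh_threshold_fraction) {
      return(declared)
    }
    cands <- setdiff(candidates[candidates %in% rownames(M)], id)
    rates <- vapply(cands, function(p) oh_rate(M, id, p)["rate"], numeric(1))
    best <- which.min(rates)
    repl <- if (length(best) && rates[best] <= oh_threshold_fraction) {
      cands[best]
    } else {
      NA_character_
    }
    changes[[length(changes) + 1L]] <<- data.frame(
      id = id, role = role, old = declared,
      new = if (is.na(repl)) "0" else repl,
      oh_old = unname(cur["rate"]),
      oh_new = if (is.na(repl)) NA_real_ else unname(rates[best]),
      stringsAsFactors = FALSE)
    repl
  }

  for (i in seq_len(nrow(ped))) {
    new_sire[i] <- fix_role(i, ped$sire[i], sires, "sire")
    new_dam[i] <- fix_role(i, ped$dam[i], dams, "dam")
  }
  out <- pedigree(ped$id, new_sire, new_dam)
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(id = character(), role = character(), old = character(),
               new = character(), oh_old = numeric(), oh_new = numeric(),
               stringsAsFactors = FALSE)
  list(pedigree = out, changes = changes)
}
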