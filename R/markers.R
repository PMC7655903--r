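#' Marker quality-control table
#'
#' Validates a per-marker QC table with imputation-quality scores and allele
#' frequency: `Props` (proportion of alleles correctly imputed), `cProps`
#' (Props corrected for the probability of correct imputation by chance)
#' and `maf`, plus map columns.
#'
#' @param marker,chrom,pos_bp marker map columns.
#' @param props,cprops,maf per-marker quality scores; `props` in \[0,1\],
#'   `maf` in \[0, 0.5\].
#' @return data.frame of class `"marker_qc"`.
#' @export
marker_qc <- function(marker, chrom, pos_bp, props, cprops, maf) {
  if (any(props < 0 | props > 1)) stop("Props must lie in [0, 1]")
  if (any(maf < 0 | maf > 0.5)) stop("MAF must lie in [0, 0.5]")
  qc <- data.frame(marker = as.character(marker), chrom = chrom,
                   pos_bp = pos_bp, props = props, cprops = cprops,
                   maf = maf, stringsAsFactors = FALSE)
  for (ch in unique(qc$chrom)) {
    p <- qc$pos_bp[qc$chrom == ch]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome ", ch)
  }
  class(qc) <- c("marker_qc", "data.frame")
  qc
}

#' Filter markers on imputation quality and allele frequency
#'
#' Keeps markers with `Props > props_min`, `cProps > cprops_min` and
#' `MAF > maf_min` (all strict inequalities, "higher than"), preserving the
#' original marker order.
#'
#' @param qc a [marker_qc()] table.
#' @param props_min,cprops_min,maf_min thresholds (defaults 0.90, 0.60,
#'   0.05).
#' @return character vector of retained marker names.
#' @export
filter_markers <- function(qc, props_min = 0.90, cprops_min = 0.60,
                           maf_min = 0.05) {
  stopifnot(props_min >= 0, props_min <= 1, maf_min >= 0, maf_min <= 1)
  keep <- qc$props > props_min & qc$cprops > cprops_min & qc$maf > maf_min
  qc$marker[keep]
}

#' Thin markers to one per genomic window
#'
#' Windows are half-open intervals of `window_bp` base pairs anchored at
#' position 1 (1-based coordinates), per chromosome. Within each window the
#' marker with the highest `Props` is kept; ties are broken by highest
#' `cProps`, then by lowest position.
#'
#' @param qc a [marker_qc()] table (positions sorted within chromosome).
#' @param window_bp window width in base pairs.
#' @return character vector of retained marker names, in original order.
#' @export
thin_markers <- function(qc, window_bp) {
  stopifnot(window_bp >= 1)
  win <- (qc$pos_bp - 1) %/% window_bp
  key <- paste(qc$chrom, win, sep = "_")
  keep_idx <- vapply(split(seq_len(nrow(qc)), key), function(ix) {
    o <- order(-qc$props[ix], -qc$cprops[ix], qc$pos_bp[ix])
    ix[o[1]]
  }, integer(1))
  qc$marker[sort(unname(keep_idx))]
}
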