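#' Genotype container
#'
#' Bundles an individuals-by-markers allele-dosage matrix (0/1/2 counts of
#' the alternate allele) with its marker map, and optionally the phased
#' haplotypes the simulator produced (two 0/1 matrices of the same shape).
#'
#' @param dosage numeric matrix, individuals in rows (rownames = ids),
#'   markers in columns (colnames = marker names).
#' @param map data.frame with columns `marker`, `chrom`, `pos_bp`, in the
#'   same marker order as `dosage`.
#' @param haplotypes optional list of two 0/1 matrices (`H1`, `H2`).
#' @return an object of class `"geno"`.
#' @export
geno <- function(dosage, map, haplotypes = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage must have individual ids as rownames")
  if (!all(c("marker", "chrom", "pos_bp") %in% names(map))) {
    stop("map needs columns marker, chrom, pos_bp")
  }
  if (nrow(map) != ncol(dosage)) stop("map rows must match dosage columns")
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  stopifnot(identical(colnames(dosage), as.character(map$marker)))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  # positions strictly increasing within chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("marker positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosage = dosage, map = map, haplotypes = haplotypes),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d individuals x %d markers on %d chromosome(s)%s\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              if (!is.null(x$haplotypes)) ", phased" else ""))
  invisible(x)
}

#' Read/write a dosage matrix and marker map as TSV
#'
#' The dosage file has marker names as column header and individual ids in
#' the first column; the map file has columns `marker`, `chrom`, `pos_bp`.
#'
#' @param g a [geno()] object.
#' @param dosage_path,map_path file paths.
#' @return `write_dosage` the paths, invisibly; `read_dosage` a [geno()].
#' @export
write_dosage <- function(g, dosage_path, map_path) {
  df <- data.frame(id = rownames(g$dosage), g$dosage, check.names = FALSE)
  utils::write.table(df, dosage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosage_path, map_path))
}

#' @rdname write_dosage
#' @export
read_dosage <- function(dosage_path, map_path) {
  df <- utils::read.table(dosage_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  map <- utils::read.table(map_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  geno(m, map)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Plain-text VCFv4.2 with one sample column per individual; dosages are
#' written as unphased GT (`0/0`, `0/1`, `1/1`, missing `./.`).
#'
#' @param g a [geno()] object.
#' @param path output file (uncompressed `.vcf`).
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popgs",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  ids <- rownames(g$dosage)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(g$dosage))) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(as.character(g$map$chrom[j]), g$map$pos_bp[j],
                       as.character(g$map$marker[j]), "A", "B", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF into a [geno()] object
#'
#' Uses the vcfR package; GT calls are converted to alternate-allele dosages.
#'
#' @param path VCF file.
#' @return a [geno()] object.
#' @export
read_vcf_geno <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c("./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", s), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  d <- apply(gt, 2, count_alt)
  d <- t(d)  # individuals x markers
  colnames(d) <- rownames(gt)
  map <- data.frame(marker = vcfR::getID(v), chrom = vcfR::getCHROM(v),
                    pos_bp = vcfR::getPOS(v), stringsAsFactors = FALSE)
  geno(d, map)
}
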