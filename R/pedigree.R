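#' Construct and validate a pedigree
#'
#' A pedigree is an ordered table of `(id, sire, dam)` records. Unknown
#' parents are coded `NA` (the strings `"0"` and `""` are also accepted on
#' input). Records are topologically sorted so that every parent appears
#' before any of its offspring; a cycle (an individual that is its own
#' ancestor) is an error.
#'
#' @param id,sire,dam character vectors of equal length.
#' @return A `data.frame` with class `"pedigree"` and columns
#'   `id`, `sire`, `dam`, in parents-first order.
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  if (anyNA(id) || any(id == "")) stop("missing or empty individual id")
  if (anyDuplicated(id)) {
    stop("duplicate pedigree ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(stats::na.omit(c(sire, dam) == rep(id, 2)))) {
    stop("an individual cannot be its own parent")
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  ped <- topo_sort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

# Kahn's algorithm; parents referenced but not listed become founders.
topo_sort_pedigree <- function(ped) {
  known <- ped$id
  implicit <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), known)
  if (length(implicit)) {
    ped <- rbind(data.frame(id = implicit, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  }
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    # take founders/resolved in original order for determinism
    i <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), order)], collapse = ", "))
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pedigree from a delimited text file
#'
#' Expects three columns `id, sire, dam` (header optional, comma- or
#' tab-delimited); `"0"`, empty fields and `NA` denote unknown parents.
#'
#' @param path file path.
#' @return a validated [pedigree()].
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("id", strsplit(first, sep)[[1]][1], ignore.case = TRUE)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3) stop("pedigree file must have 3 columns (id, sire, dam)")
  pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree to CSV
#'
#' Unknown parents are written as `"0"`.
#'
#' @param ped a [pedigree()].
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Founders and family labels
#'
#' `founders()` returns ids with both parents unknown. `family_map()` labels
#' every non-founder by its parent pair (full-sib family); founders get `NA`.
#'
#' @param ped a [pedigree()].
#' @return character vector of ids, or a data.frame `id`, `family`.
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$sire) & is.na(ped$dam)]
}

#' @rdname founders
#' @export
family_map <- function(ped) {
  fam <- ifelse(is.na(ped$sire) & is.na(ped$dam), NA_character_,
                paste(ifelse(is.na(ped$sire), "?", ped$sire),
                      ifelse(is.na(ped$dam), "?", ped$dam), sep = ":"))
  data.frame(id = ped$id, family = fam, stringsAsFactors = FALSE)
}

#' Numerator (additive) relationship matrix from a pedigree
#'
#' Tabular method: founders are treated as unrelated and non-inbred;
#' `A[i,i] = 1 + 0.5 * A[sire, dam]`, `A[i,j] = 0.5 * (A[j,sire] + A[j,dam])`
#' for `j` earlier in the (parents-first) order. An unknown parent
#' contributes relationship zero.
#'
#' @param ped a [pedigree()].
#' @return symmetric matrix with `kind` attribute `"A"`, dimnames = ids.
#' @export
a_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  # augmented matrix: row/col 1 is a phantom unrelated founder (all zeros)
  A <- matrix(0, n + 1L, n + 1L)
  s1 <- ifelse(is.na(si), 1L, si + 1L)
  d1 <- ifelse(is.na(di), 1L, di + 1L)
  for (i in seq_len(n)) {
    ii <- i + 1L
    if (i > 1L) {
      prev <- seq(2L, ii - 1L)  # augmented columns of individuals 1..(i-1)
      A[prev, ii] <- 0.5 * (A[prev, s1[i]] + A[prev, d1[i]])
      A[ii, prev] <- A[prev, ii]
    }
    A[ii, ii] <- 1 + 0.5 * A[s1[i], d1[i]]
  }
  A <- A[-1L, -1L, drop = FALSE]
  dimnames(A) <- list(ped$id, ped$id)
  attr(A, "kind") <- "A"
  A
}

#' Pedigree dominance relationship matrix
#'
#' For individuals X (parents a, b) and Y (parents c, d):
#' `D[X,Y] = 0.25 * (A[a,c] * A[b,d] + A[a,d] * A[b,c])`. The diagonal is set
#' to 1 (non-inbred convention); pairs involving a founder or an unknown
#' parent get 0 off-diagonal.
#'
#' @param ped a [pedigree()].
#' @param A optional precomputed [a_matrix()] of the same pedigree.
#' @return symmetric matrix with `kind` attribute `"D_ped"`.
#' @export
d_matrix_pedigree <- function(ped, A = NULL) {
  if (is.null(A)) A <- a_matrix(ped)
  if (!identical(rownames(A), ped$id)) {
    stop("A must be computed from the same pedigree (id order mismatch)")
  }
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  Aaug <- rbind(0, cbind(0, A))  # phantom row/col for unknown parents
  s1 <- ifelse(is.na(si), 1L, si + 1L)
  d1 <- ifelse(is.na(di), 1L, di + 1L)
  D <- 0.25 * (Aaug[s1, s1] * Aaug[d1, d1] + Aaug[s1, d1] * Aaug[d1, s1])
  diag(D) <- 1
  dimnames(D) <- list(ped$id, ped$id)
  attr(D, "kind") <- "D_ped"
  D
}

#' Effective population size from a coancestry matrix
#'
#' Status effective number `Ns = 1 / (2 * fbar)` where `fbar` is the mean of
#' the coancestry matrix `C = K / 2` over all ordered pairs of the group,
#' self-pairs included. For `n` unrelated non-inbred individuals
#' `fbar = 0.5 / n` and `Ns = n`.
#'
#' @param K relationship matrix (additive scale, e.g. from [a_matrix()]).
#' @param group ids over which to compute the mean; defaults to all ids of
#'   `K`. In breeding-population use this is typically the parental set.
#' @return effective size (scalar).
#' @export
effective_size <- function(K, group = rownames(K)) {
  if (is.null(rownames(K))) stop("K must carry ids as dimnames")
  missing <- setdiff(group, rownames(K))
  if (length(missing)) {
    stop("group ids absent from K: ", paste(missing, collapse = ", "))
  }
  C <- K[group, group, drop = FALSE] / 2
  fbar <- mean(C)
  if (fbar <= 0) stop("mean coancestry is zero; effective size undefined")
  1 / (2 * fbar)
}
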