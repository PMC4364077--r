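#' Construct a genotype matrix with its genetic map
#'
#' The central container of the package: coded biallelic genotypes for a set
#' of individuals, aligned to an ordered marker map.  Genotypes are coded
#' `0` (homozygous reference), `1` (heterozygous), `2` (homozygous
#' alternate) and `NA` (missing).  Conflicting homozygosity depends only on
#' the presence of both homozygote classes, so which allele is labelled
#' reference at a marker is immaterial.
#'
#' Markers are sorted by (chromosome, bp).  Within a chromosome bp must be
#' strictly increasing after sorting (duplicated positions are dropped,
#' keeping the first) and cM must be non-decreasing.  cM positions may be
#' `NA` (e.g. straight from a VCF); attach them with
#' [attach_genetic_map()] before any run analysis.
#'
#' @param geno integer matrix, markers in rows and individuals in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param map data frame with columns `chrom`, `id`, `bp`, `cm`, one row
#'   per marker, in the same order as the rows of `geno`.
#' @param individuals character vector of individual identifiers; defaults
#'   to `colnames(geno)`.
#' @return An object of class `cch_geno`: a list with elements `geno`
#'   (markers x individuals integer matrix) and `map`.
#' @examples
#' map <- data.frame(chrom = "1", id = c("s1", "s2"), bp = c(100L, 200L),
#'                   cm = c(0.01, 0.02))
#' g <- matrix(c(0L, 2L, 1L, 0L), nrow = 2,
#'             dimnames = list(NULL, c("a", "b")))
#' cch_genotypes(g, map)
#' @export
cch_genotypes <- function(geno, map, individuals = colnames(geno)) {
  if (!is.matrix(geno)) stop("`geno` must be a matrix")
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map)
  need <- c("chrom", "id", "bp", "cm")
  if (!all(need %in% names(map)))
    stop("`map` must have columns ", paste(need, collapse = ", "))
  if (nrow(map) != nrow(geno))
    stop("map has ", nrow(map), " markers but geno has ", nrow(geno), " rows")
  if (is.null(individuals)) individuals <- paste0("I", seq_len(ncol(geno)))
  if (anyDuplicated(individuals))
    stop("duplicated individual identifiers")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")

  map$chrom <- as.character(map$chrom)
  map$bp <- as.integer(map$bp)
  map$cm <- as.numeric(map$cm)
  ord <- order(.chrom_rank(map$chrom), map$bp)
  map <- map[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]

  dup <- unlist(lapply(split(seq_len(nrow(map)), .chrom_rank(map$chrom)),
                       function(i) i[duplicated(map$bp[i])]),
                use.names = FALSE)
  if (length(dup)) {
    warning(length(dup), " marker(s) at duplicated bp positions dropped ",
            "(first kept)")
    map <- map[-dup, , drop = FALSE]
    geno <- geno[-dup, , drop = FALSE]
  }
  for (idx in split(seq_len(nrow(map)), map$chrom)) {
    cmv <- map$cm[idx]
    if (any(diff(cmv[!is.na(cmv)]) < 0))
      stop("cM positions decrease along chromosome ", map$chrom[idx[1]])
  }
  rownames(map) <- NULL
  colnames(geno) <- individuals
  rownames(geno) <- map$id
  structure(list(geno = geno, map = map), class = "cch_geno")
}

# Natural chromosome ordering: numeric labels first in numeric order, then
# the rest alphabetically.
.chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  r <- order(is.na(num), num, u)
  match(chrom, u[r])
}

#' @export
print.cch_geno <- function(x, ...) {
  cat("cch_geno: ", ncol(x$geno), " individuals x ", nrow(x$geno),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n",
      sep = "")
  if (all(is.na(x$map$cm)))
    cat("  (no cM positions; run attach_genetic_map() before analysis)\n")
  invisible(x)
}

#' Individual identifiers of a genotype set
#' @param x a `cch_geno` object.
#' @return Character vector of identifiers.
#' @export
individuals <- function(x) colnames(x$geno)

#' Number of markers of a genotype set
#' @param x a `cch_geno` object.
#' @return Integer marker count.
#' @export
n_markers <- function(x) nrow(x$geno)

# Resolve subset identifiers to column indices, failing loudly on unknowns.
.subset_index <- function(x, subset) {
  if (is.numeric(subset)) {
    idx <- as.integer(subset)
    if (any(idx < 1L | idx > ncol(x$geno))) stop("subset index out of range")
    return(idx)
  }
  idx <- match(subset, colnames(x$geno))
  if (anyNA(idx))
    stop("individual(s) not in genotype matrix: ",
         paste(subset[is.na(idx)], collapse = ", "))
  idx
}

# Canonical subset key: sorted identifiers joined with "+".
.subset_id <- function(ids) paste(sort(ids), collapse = "+")

# 0-based chromosome block offsets/lengths in map order.
.chrom_blocks <- function(map) {
  r <- rle(map$chrom)
  len <- r$lengths
  list(chrom = r$values, off = cumsum(c(0L, len[-length(len)])),
       m = as.integer(len))
}

# Pack genotypes into per-chromosome homozygote bit planes (C++ layout).
.pack <- function(x) {
  blk <- .chrom_blocks(x$map)
  packed <- pack_genotypes_cpp(x$geno, blk$off, blk$m)
  packed$chrom <- blk$chrom
  packed$cm <- lapply(seq_along(blk$m), function(c)
    x$map$cm[(blk$off[c] + 1L):(blk$off[c] + blk$m[c])])
  packed
}

#' Conflicting homozygosity status at one or more markers
#'
#' A marker shows conflicting homozygosity (CH) for a set of individuals
#' when at least two of them are homozygous for opposite alleles (an IBS0
#' pair), which excludes shared inheritance of a haplotype spanning the
#' marker.  Missing genotypes conflict with nothing.
#'
#' @param g either a vector of genotype codes (one marker, one element per
#'   subset member) or a matrix with markers in rows and subset members in
#'   columns.
#' @return Logical: `TRUE` where both homozygote classes occur among
#'   non-missing genotypes.  A vector input yields a single value.
#' @examples
#' ch_status(c(0L, 1L, 2L))  # AA, AB, BB -> conflict
#' ch_status(c(0L, 0L, 1L))  # no conflict
#' @export
ch_status <- function(g) {
  if (is.matrix(g)) {
    if (ncol(g) == 0L) stop("empty subset")
    rowSums(g == 0L, na.rm = TRUE) > 0L & rowSums(g == 2L, na.rm = TRUE) > 0L
  } else {
    if (length(g) == 0L) stop("empty subset")
    any(g == 0L, na.rm = TRUE) && any(g == 2L, na.rm = TRUE)
  }
}
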