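#' Read genotypes from PLINK ped/map text files
#'
#' The ped file carries six leading columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele columns per marker; `0`
#' denotes a missing allele.  The map file is the 4-column PLINK dialect:
#' chromosome, marker id, cM position, bp position.  Alleles are coded
#' per marker against the first allele observed in file order; since
#' conflicting homozygosity only asks whether both homozygote classes are
#' present, this choice cannot affect any downstream result.  Markers with
#' three or more observed alleles are dropped with a warning.
#'
#' Sex chromosomes and mitochondrial markers are excluded by default: the
#' run analysis is autosomal, and hemizygous male genotypes would create
#' spurious homozygosity.
#'
#' @param ped_path,map_path paths to the ped and map files.
#' @param include_x keep X-chromosome markers, treating genotypes as given.
#' @return A [cch_genotypes()] object.
#' @export
read_ped_map <- function(ped_path, map_path, include_x = FALSE) {
  map <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(map) != 4L)
    stop("map file must have 4 columns (chrom, id, cM, bp), found ",
         ncol(map))
  names(map) <- c("chrom", "id", "cm", "bp")
  map$cm <- as.numeric(map$cm)
  map$bp <- as.integer(map$bp)
  nmark <- nrow(map)

  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(ped) != 6L + 2L * nmark)
    stop("ped file implies ", (ncol(ped) - 6L) / 2, " markers but map has ",
         nmark)
  ids <- ped[[2L]]
  if (anyDuplicated(ids)) ids <- paste(ped[[1L]], ped[[2L]], sep = "_")
  n <- nrow(ped)

  geno <- matrix(NA_integer_, nmark, n)
  drop <- logical(nmark)
  for (j in seq_len(nmark)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    obs <- as.vector(rbind(a1, a2)) # individual-major, first allele first
    obs <- obs[obs != "0"]
    al <- unique(obs)
    if (length(al) > 2L) {
      warning("marker ", map$id[j], " has ", length(al),
              " alleles; dropped")
      drop[j] <- TRUE
      next
    }
    ref <- if (length(al)) al[1L] else "0"
    g <- (a1 != ref) + (a2 != ref)
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    geno[j, ] <- as.integer(g)
  }
  if (any(drop)) {
    geno <- geno[!drop, , drop = FALSE]
    map <- map[!drop, , drop = FALSE]
  }
  keep <- .autosome_filter(map$chrom, include_x)
  geno <- geno[keep, , drop = FALSE]
  map <- map[keep, , drop = FALSE]
  cch_genotypes(geno, map, individuals = ids)
}

.autosome_filter <- function(chrom, include_x) {
  excl <- .sex_chroms
  if (include_x) excl <- setdiff(excl, c("X", "23", "chrX"))
  keep <- !(chrom %in% excl)
  if (any(!keep))
    message(sum(!keep), " non-autosomal marker(s) excluded")
  keep
}

#' Write genotypes to PLINK ped/map text files
#'
#' Inverse of [read_ped_map()]: codes 0/1/2 become `A A`, `A B`, `B B`
#' (per-marker abstract allele labels) and `NA` becomes `0 0`.  Reading the
#' emitted pair back reproduces the genotype codes exactly.
#'
#' @param x a `cch_geno` object.
#' @param ped_path,map_path output paths.
#' @param ped optional pedigree (see [pedigree()]) supplying the six
#'   leading ped columns for the matching individuals.
#' @return Invisibly, `x`.
#' @export
write_ped_map <- function(x, ped_path, map_path, ped = NULL) {
  map <- x$map
  data.table::fwrite(map[, c("chrom", "id", "cm", "bp")], map_path,
                     sep = "\t", col.names = FALSE)
  ids <- colnames(x$geno)
  lead <- data.frame(fid = ids, iid = ids, pat = "0", mat = "0",
                     sex = "0", pheno = "-9", stringsAsFactors = FALSE)
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    ok <- !is.na(i)
    lead$pat[ok] <- ped$father[i[ok]]
    lead$mat[ok] <- ped$mother[i[ok]]
    lead$sex[ok] <- as.character(ped$sex[i[ok]])
    lead$pheno[ok] <- ifelse(ped$affected[i[ok]], "2", "1")
  }
  g <- x$geno # markers x individuals
  a1 <- ifelse(is.na(g), "0", ifelse(g == 2L, "B", "A"))
  a2 <- ifelse(is.na(g), "0", ifelse(g == 0L, "A", "B"))
  # interleave alleles marker-major, then lay out one row per individual
  al <- matrix("", 2L * nrow(g), ncol(g))
  al[seq(1L, 2L * nrow(g), 2L), ] <- a1
  al[seq(2L, 2L * nrow(g), 2L), ] <- a2
  out <- cbind(lead, as.data.frame(t(al), stringsAsFactors = FALSE))
  data.table::fwrite(out, ped_path, sep = "\t", col.names = FALSE)
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Keeps biallelic SNP records only (single-base REF and ALT); the count of
#' dropped records is reported.  GT fields are parsed ignoring phase:
#' `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2; any GT containing `.` (or a
#' haploid call) is missing.  VCFs carry no genetic-map positions, so `cm`
#' is `NA` until [attach_genetic_map()] is applied.
#'
#' @param vcf_path path to a plain or bgzipped VCF.
#' @param include_x keep X-chromosome records.
#' @return A [cch_genotypes()] object with `NA` cM positions.
#' @export
read_vcf <- function(vcf_path, include_x = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix # always a matrix, unlike getFIX() on single records
  if (nrow(fix) == 0L) stop("no records in ", vcf_path)
  fmt <- v@gt[, 1L]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF has records without a GT format field")
  for (idx in split(seq_len(nrow(fix)), fix[, "CHROM"]))
    if (is.unsorted(as.numeric(fix[idx, "POS"])))
      stop("VCF records are not sorted by position")

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sum(!snp), " non-biallelic-SNP record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  g <- matrix(code[gsub("|", "/", gt, fixed = TRUE)],
              nrow = nrow(gt), ncol = ncol(gt))
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[, "CHROM"], ":",
                                      fix[, "POS"])[is.na(id) | id == "."]
  map <- data.frame(chrom = fix[, "CHROM"], id = id,
                    bp = as.integer(fix[, "POS"]), cm = NA_real_,
                    stringsAsFactors = FALSE)
  keep <- .autosome_filter(map$chrom, include_x)
  cch_genotypes(g[keep, , drop = FALSE], map[keep, , drop = FALSE],
                individuals = colnames(gt))
}

#' Attach genetic-map (cM) positions to markers
#'
#' Sets each marker's cM position by linear interpolation between anchor
#' points of a genetic map; beyond the terminal anchors positions are
#' extrapolated at `fallback_rate`.  Without an anchor table (or for
#' chromosomes absent from it) `cm = bp * fallback_rate / 1e6`, i.e. a
#' uniform recombination rate, with a warning.
#'
#' @param x a `cch_geno` object.
#' @param map_table data frame of anchors with columns `chrom`, `bp`, `cm`,
#'   sorted by position within chromosome; cM must be non-decreasing.
#' @param fallback_rate recombination rate in cM per Mb used beyond anchors
#'   and for unanchored chromosomes (default 1, the genome average).
#' @return `x` with finite, non-decreasing `cm` positions.
#' @export
attach_genetic_map <- function(x, map_table = NULL, fallback_rate = 1) {
  map <- x$map
  if (is.null(map_table)) {
    warning("no genetic map supplied; using uniform ", fallback_rate,
            " cM/Mb")
    map$cm <- map$bp * fallback_rate / 1e6
  } else {
    map_table <- as.data.frame(map_table)
    map_table$chrom <- as.character(map_table$chrom)
    for (ch in unique(map$chrom)) {
      i <- which(map$chrom == ch)
      a <- map_table[map_table$chrom == ch, , drop = FALSE]
      if (nrow(a) == 0L) {
        warning("chromosome ", ch, " absent from map_table; using uniform ",
                fallback_rate, " cM/Mb")
        map$cm[i] <- map$bp[i] * fallback_rate / 1e6
        next
      }
      a <- a[order(a$bp), , drop = FALSE]
      if (any(diff(a$cm) < 0))
        stop("map_table cM decreases along chromosome ", ch)
      cm <- approx(a$bp, a$cm, xout = map$bp[i], rule = 1)$y
      lo <- map$bp[i] < a$bp[1L]
      hi <- map$bp[i] > a$bp[nrow(a)]
      cm[lo] <- a$cm[1L] - (a$bp[1L] - map$bp[i][lo]) * fallback_rate / 1e6
      cm[hi] <- a$cm[nrow(a)] +
        (map$bp[i][hi] - a$bp[nrow(a)]) * fallback_rate / 1e6
      map$cm[i] <- cummax(pmax(cm, 0))
    }
  }
  x$map <- map
  x
}

#' Write detected runs to a TSV (and optionally BED) file
#'
#' @param runs run table from [find_runs()] or [cch_scan()]; an empty table
#'   yields a header-only file.
#' @param out_path output TSV path.
#' @param bed_path optional BED output of the run intervals (0-based
#'   half-open bp coordinates).
#' @return Invisibly, the written data frame.
#' @export
write_runs <- function(runs, out_path, bed_path = NULL) {
  cols <- c("subset_id", "k", "chromosome", "start_bp", "end_bp",
            "start_cm", "end_cm", "n_snps", "length_cm",
            "tolerated_ch_count", "p_raw", "p_adjusted")
  runs <- as.data.frame(runs)
  for (cc in setdiff(cols, names(runs))) runs[[cc]] <- rep(NA, nrow(runs))
  out <- runs[, cols, drop = FALSE]
  data.table::fwrite(out, out_path, sep = "\t", na = "NA")
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = out$chromosome,
                      start = out$start_bp - 1L, end = out$end_bp)
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  invisible(out)
}

#' Read a run table written by [write_runs()]
#' @param path TSV path.
#' @return Data frame of runs.
#' @export
read_runs <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = list(character = c("subset_id",
                                                    "chromosome")))
}

#' Write a per-marker maximum-sharing profile to TSV
#'
#' @param profile profile from [aggregate_max_k()]: one row per marker with
#'   `chromosome`, `bp`, `cm`, `max_k`.
#' @param out_path output path.
#' @return Invisibly, the profile.
#' @export
write_profile <- function(profile, out_path) {
  data.table::fwrite(profile[, c("chromosome", "bp", "cm", "max_k")],
                     out_path, sep = "\t")
  invisible(profile)
}

#' Read a profile written by [write_profile()]
#' @param path TSV path.
#' @return Data frame with `chromosome`, `bp`, `cm`, `max_k`.
#' @export
read_profile <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = list(character = "chromosome"))
}
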