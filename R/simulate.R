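#' Build a synthetic marker map
#'
#' Marker cM positions are uniform random over each chromosome (sorted),
#' giving the target mean density `markers_per_chrom / chrom_length_cm`;
#' bp positions follow at 1 Mb per cM (the genome-average recombination
#' rate), rounded and made strictly increasing.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param chrom_length_cm genetic length of each chromosome in cM.
#' @param seed optional integer seed (the caller's RNG stream is
#'   preserved).
#' @return A map data frame with columns `chrom`, `id`, `bp`, `cm`.
#' @export
make_map <- function(n_chrom, markers_per_chrom, chrom_length_cm,
                     seed = NULL) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 1, chrom_length_cm > 0)
  with_seed(seed, {
    maps <- lapply(seq_len(n_chrom), function(ch) {
      cm <- sort(runif(markers_per_chrom, 0, chrom_length_cm))
      bp <- as.integer(round(cm * 1e6))
      for (i in seq_along(bp)[-1L])
        if (bp[i] <= bp[i - 1L]) bp[i] <- bp[i - 1L] + 1L
      data.frame(chrom = as.character(ch),
                 id = sprintf("snp%d_%d", ch, seq_len(markers_per_chrom)),
                 bp = bp, cm = cm, stringsAsFactors = FALSE)
    })
    do.call(rbind, maps)
  })
}

#' Simulate unrelated individuals under Hardy-Weinberg equilibrium
#'
#' Per-marker minor-allele frequencies are drawn uniformly on
#' `[maf_low, maf_high]` and genotypes independently per individual under
#' HWE, with independent markers (no linkage disequilibrium).  For null
#' run-length calibration this is conservative: real LD only lengthens
#' chance runs of no conflicting homozygosity, never shortens them.
#' The default MAF floor of 0.05 mirrors routine pre-analysis QC that
#' removes rarer markers.
#'
#' @param n_individuals number of individuals.
#' @param map marker map (see [make_map()]).
#' @param maf_low,maf_high MAF range, `0 < maf_low <= maf_high <= 0.5`.
#' @param seed optional integer seed.
#' @return A [cch_genotypes()] object (per-marker MAFs in the `maf`
#'   attribute).
#' @export
simulate_unrelated <- function(n_individuals, map, maf_low = 0.05,
                               maf_high = 0.5, seed = NULL) {
  stopifnot(n_individuals >= 1, maf_low > 0, maf_low <= maf_high,
            maf_high <= 0.5)
  m <- nrow(map)
  with_seed(seed, {
    maf <- runif(m, maf_low, maf_high)
    g <- matrix(rbinom(m * n_individuals, 2L, maf), m, n_individuals)
    x <- cch_genotypes(g, map,
                       individuals = paste0("I", seq_len(n_individuals)))
    attr(x, "maf") <- maf
    x
  })
}

#' Construct a pedigree
#'
#' @param id character identifiers, unique.
#' @param father,mother identifiers of the parents, `"0"` (or `NA`) for
#'   founders; both parents must be present or both absent, and all named
#'   parents must themselves be rows of the pedigree.
#' @param sex 1 = male, 2 = female, 0 = unknown.
#' @param affected logical; in this package the flag marks the genotyped,
#'   phenotype-positive members handed to the combinatorial scan.
#' @return Data frame of class `cch_pedigree`, in an order where parents
#'   precede children.
#' @export
pedigree <- function(id, father, mother, sex = 0L, affected = FALSE) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  father[is.na(father)] <- "0"
  mother[is.na(mother)] <- "0"
  if (anyDuplicated(id)) stop("duplicated individual identifiers")
  if (any((father == "0") != (mother == "0")))
    stop("both parents must be given, or neither")
  miss <- setdiff(c(father, mother), c("0", id))
  if (length(miss))
    stop("parent(s) absent from pedigree: ", paste(miss, collapse = ", "))
  ped <- data.frame(id = id, father = father, mother = mother,
                    sex = as.integer(sex),
                    affected = as.logical(affected),
                    stringsAsFactors = FALSE)
  # topological order (Kahn); failure to place everyone means a cycle
  placed <- character(0)
  order_idx <- integer(0)
  remaining <- seq_len(nrow(ped))
  while (length(remaining)) {
    ready <- remaining[(ped$father[remaining] %in% c("0", placed)) &
                         (ped$mother[remaining] %in% c("0", placed))]
    if (!length(ready)) stop("pedigree contains a cycle")
    order_idx <- c(order_idx, ready)
    placed <- c(placed, ped$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  ped <- ped[order_idx, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("cch_pedigree", "data.frame")
  ped
}

#' Founder members of a pedigree
#' @param ped a `cch_pedigree`.
#' @return Character ids of individuals with no parents.
#' @export
founders <- function(ped) ped$id[ped$father == "0"]

#' Read / write pedigrees in PLINK .fam-style text
#'
#' Columns: family id, individual id, father, mother, sex, phenotype
#' (2 = affected, 1 = unaffected).
#'
#' @param path file path.
#' @return For `read_pedigree`, a `cch_pedigree`.
#' @export
read_pedigree <- function(path) {
  f <- data.table::fread(path, header = FALSE, colClasses = "character",
                         data.table = FALSE)
  if (ncol(f) < 6L) stop(".fam file needs 6 columns")
  pedigree(f[[2L]], f[[3L]], f[[4L]], as.integer(f[[5L]]), f[[6L]] == "2")
}

#' @rdname read_pedigree
#' @param ped a `cch_pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(fid = "FAM1", iid = ped$id, pat = ped$father,
                    mat = ped$mother, sex = ped$sex,
                    pheno = ifelse(ped$affected, 2L, 1L))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' The built-in evaluation pedigree
#'
#' A four-generation extended family carrying 17 genotyped,
#' phenotype-positive members connected through ungenotyped relatives —
#' the setting in which combinatorial CH analysis is used.  A founder
#' couple (generation I) has four ungenotyped children (generation II),
#' each married to a founder spouse; every generation-II couple has three
#' children (twelve genotyped first cousins in generation III); five
#' generation-III members, spread across the four branches, each have one
#' genotyped child (generation IV).  At these depths a top-founder
#' haplotype is carried by any given genotyped member with probability
#' 1/4 (generation III) or 1/8 (generation IV), so segments shared
#' identically by descent by seven or more of the 17 arise intermittently
#' rather than genome-wide, with genetic lengths on the cM scale.  All
#' founders carry globally distinct haplotype labels, so every IBD segment
#' among members arises inside the pedigree.
#'
#' @return A `cch_pedigree` with 32 members, 17 of them flagged affected.
#' @export
default_pedigree <- function() {
  gii <- paste0("GII-", 1:4)
  sp <- paste0("SP-", 1:4)
  giii <- paste0("GIII-", 1:12)
  # three children per generation-II couple
  giii_fa <- rep(gii, each = 3)
  giii_mo <- rep(sp, each = 3)
  # five generation-IV children from generation-III members 1,4,7,10,12
  giv_par <- giii[c(1, 4, 7, 10, 12)]
  tsp <- paste0("TSP-", 1:5)
  giv <- paste0("GIV-", 1:5)
  pedigree(
    id = c("GI-1", "GI-2", gii, sp, giii, tsp, giv),
    father = c("0", "0", rep("GI-1", 4), rep("0", 4), giii_fa,
               rep("0", 5), giv_par),
    mother = c("0", "0", rep("GI-2", 4), rep("0", 4), giii_mo,
               rep("0", 5), tsp),
    sex = c(1L, 2L, rep(1L, 4), rep(2L, 4),
            rep(1L, 12), rep(2L, 5), rep(1L, 5)),
    affected = c(FALSE, FALSE, rep(FALSE, 4), rep(FALSE, 4),
                 rep(TRUE, 12), rep(FALSE, 5), rep(TRUE, 5))
  )
}

# Crossover positions for one meiosis on a chromosome of length L cM:
# Haldane model (no interference), count ~ Poisson(L/100), positions
# uniform.
.sim_crossovers <- function(L) {
  n <- rpois(1L, L / 100)
  if (n == 0L) numeric(0) else sort(runif(n, 0, L))
}

# Which parental haplotype (1 or 2) is transmitted at each marker of one
# chromosome, given marker cM positions.
.meiosis_pattern <- function(cm) {
  xo <- .sim_crossovers(max(cm))
  start <- rbinom(1L, 1L, 0.5)
  1L + (start + findInterval(cm, xo)) %% 2L
}

#' Gene-dropping simulation through a pedigree
#'
#' Founder haplotypes are drawn marker-by-marker at random allele
#' frequencies (as in [simulate_unrelated()]) and tagged with globally
#' unique labels, two per founder.  Each meiosis recombines the two
#' parental haplotypes under the Haldane model (crossover count Poisson
#' with mean cM-length/100, positions uniform, no interference) and
#' transmits one recombinant.  Genotypes are the unordered allele pairs;
#' the returned truth track records the founder label of both haplotypes
#' of every individual at every marker, giving exact IBD ground truth.
#'
#' @param ped a [pedigree()].
#' @param map marker map.
#' @param maf_low,maf_high founder allele-frequency range.
#' @param seed optional integer seed.
#' @return List with `genotypes` (a `cch_geno` over all pedigree members)
#'   and `truth` (class `cch_truth`: matrices `lab1`, `lab2` of founder
#'   labels, markers x individuals, plus the founder/label table).
#' @export
gene_drop <- function(ped, map, maf_low = 0.05, maf_high = 0.5,
                      seed = NULL) {
  if (!inherits(ped, "cch_pedigree")) ped <- pedigree(ped$id, ped$father,
                                                      ped$mother, ped$sex,
                                                      ped$affected)
  m <- nrow(map)
  blocks <- split(seq_len(m), .chrom_rank(as.character(map$chrom)))
  cm_blocks <- lapply(blocks, function(i) map$cm[i])
  N <- nrow(ped)
  fnd <- founders(ped)

  with_seed(seed, {
    maf <- runif(m, maf_low, maf_high)
    h1 <- matrix(0L, m, N, dimnames = list(NULL, ped$id))
    h2 <- matrix(0L, m, N, dimnames = list(NULL, ped$id))
    l1 <- matrix(0L, m, N, dimnames = list(NULL, ped$id))
    l2 <- matrix(0L, m, N, dimnames = list(NULL, ped$id))
    for (i in seq_len(N)) {
      who <- ped$id[i]
      if (ped$father[i] == "0") {
        f <- match(who, fnd)
        h1[, i] <- rbinom(m, 1L, maf)
        h2[, i] <- rbinom(m, 1L, maf)
        l1[, i] <- 2L * f - 1L
        l2[, i] <- 2L * f
      } else {
        for (side in 1:2) {
          p <- match(if (side == 1L) ped$father[i] else ped$mother[i],
                     ped$id)
          al <- integer(m)
          lb <- integer(m)
          for (b in seq_along(blocks)) {
            idx <- blocks[[b]]
            use <- .meiosis_pattern(cm_blocks[[b]])
            al[idx] <- ifelse(use == 1L, h1[idx, p], h2[idx, p])
            lb[idx] <- ifelse(use == 1L, l1[idx, p], l2[idx, p])
          }
          if (side == 1L) {
            h1[, i] <- al
            l1[, i] <- lb
          } else {
            h2[, i] <- al
            l2[, i] <- lb
          }
        }
      }
    }
    geno <- h1 + h2
    x <- cch_genotypes(geno, map, individuals = ped$id)
    # cch_genotypes may reorder/drop markers; mirror that in the truth
    ord <- match(x$map$id, map$id)
    truth <- structure(list(lab1 = l1[ord, , drop = FALSE],
                            lab2 = l2[ord, , drop = FALSE],
                            founder_labels = data.frame(
                              founder = fnd,
                              label1 = 2L * seq_along(fnd) - 1L,
                              label2 = 2L * seq_along(fnd)),
                            map = x$map),
                       class = "cch_truth")
    attr(x, "maf") <- maf[ord]
    list(genotypes = x, truth = truth)
  })
}

#' True per-marker maximum IBD sharing from founder labels
#'
#' For each marker, the largest number of `members` carrying the same
#' founder-haplotype label on at least one of their two haplotypes; counts
#' below 2 are reported as 0 (a label carried by one person is not
#' sharing).
#'
#' @param truth a `cch_truth` object from [gene_drop()].
#' @param members identifiers to count over (default: all individuals in
#'   the truth track).
#' @return Integer vector, one entry per marker.
#' @export
truth_max_k <- function(truth, members = colnames(truth$lab1)) {
  i <- match(members, colnames(truth$lab1))
  if (anyNA(i))
    stop("member(s) not in truth track: ",
         paste(members[is.na(i)], collapse = ", "))
  a <- truth$lab1[, i, drop = FALSE]
  b <- truth$lab2[, i, drop = FALSE]
  best <- integer(nrow(a))
  for (L in sort(unique(c(a, b)))) {
    cnt <- as.integer(rowSums((a == L) | (b == L)))
    best <- pmax(best, cnt)
  }
  best[best < 2L] <- 0L
  best
}

#' Write a gene-drop truth track to TSV
#'
#' One row per individual per marker: individual, chromosome, marker index
#' (within chromosome), label1, label2.
#'
#' @param truth a `cch_truth` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  map <- truth$map
  within_idx <- stats::ave(seq_len(nrow(map)), map$chrom,
                           FUN = seq_along)
  ids <- colnames(truth$lab1)
  out <- data.frame(
    individual = rep(ids, each = nrow(map)),
    chromosome = rep(map$chrom, times = length(ids)),
    marker = rep(within_idx, times = length(ids)),
    label1 = as.vector(truth$lab1),
    label2 = as.vector(truth$lab2))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a truth track written by [write_truth()]
#' @param path TSV path.
#' @param map marker map the track belongs to.
#' @return A `cch_truth` object.
#' @export
read_truth <- function(path, map) {
  tt <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = c("individual",
                                                          "chromosome")))
  ids <- unique(tt$individual)
  m <- nrow(map)
  if (nrow(tt) != m * length(ids))
    stop("truth table size does not match the map")
  lab1 <- matrix(tt$label1, m, length(ids), dimnames = list(NULL, ids))
  lab2 <- matrix(tt$label2, m, length(ids), dimnames = list(NULL, ids))
  structure(list(lab1 = lab1, lab2 = lab2, founder_labels = NULL,
                 map = map), class = "cch_truth")
}

#' Perturb genotypes with random errors
#'
#' Each non-missing genotype is independently replaced, with probability
#' `error_rate`, by one of the other two codes chosen uniformly — the
#' perturbation the single-error tolerance rule of [find_runs()] defends
#' against.
#'
#' @param x a `cch_geno` object.
#' @param error_rate per-genotype error probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return `x` with errors injected.
#' @export
inject_errors <- function(x, error_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1)
  if (error_rate == 0) return(x)
  with_seed(seed, {
    g <- x$geno
    hit <- which(!is.na(g) & runif(length(g)) < error_rate)
    if (length(hit))
      g[hit] <- (g[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
    x$geno <- g
    x
  })
}
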