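#' Find runs of no conflicting homozygosity for one subset
#'
#' Computes the per-marker conflicting-homozygosity (CH) track for the
#' subset on every chromosome, takes maximal stretches of consecutive
#' CH-free markers as raw runs, and (optionally) applies the single-error
#' tolerance rule: an isolated CH marker directly separating two runs is
#' ignored whenever the merged span (cM of the last marker minus cM of the
#' first) reaches `min_cm`.  Two consecutive CH markers always terminate a
#' run.  A merged run may absorb further isolated CH markers under the same
#' rule; merging proceeds deterministically left to right and the number of
#' tolerated markers is reported per run.
#'
#' Qualifying runs must span at least `min_cm` centimorgans *and* contain
#' at least `min_snps` markers; the SNP floor prevents sparse marker
#' coverage from masquerading as a long CH-free region.  Runs never cross
#' chromosome boundaries, and a single-marker run has length 0 cM.
#'
#' @param x a [cch_genotypes()] object with finite cM positions.
#' @param subset character identifiers (or column indices) of at least two
#'   individuals.
#' @param min_cm minimum genetic length of a qualifying run, in cM
#'   (default 4).
#' @param min_snps minimum marker count of a qualifying run (default 100,
#'   matching a ~100 SNPs/cM array at the default `min_cm`).
#' @param tolerate_single_ch apply the single-error tolerance rule
#'   (default `TRUE`).
#' @param all_runs return every run (still merged under the tolerance
#'   rule) instead of qualifying runs only; used to collect null
#'   run-length distributions.
#' @param min_snps_report with `all_runs = TRUE`, report only runs of at
#'   least this many markers (default 1).
#' @return Data frame with one row per run: `subset_id`, `k`,
#'   `chromosome`, `start_idx`, `end_idx` (1-based marker indices into the
#'   map), `start_bp`, `end_bp`, `start_cm`, `end_cm`, `n_snps`,
#'   `length_cm`, `tolerated_ch_count`.
#' @seealso [genome_scan()], [cch_scan()]
#' @export
find_runs <- function(x, subset, min_cm = 4, min_snps = 100,
                      tolerate_single_ch = TRUE, all_runs = FALSE,
                      min_snps_report = 1L) {
  idx <- .subset_index(x, subset)
  if (length(idx) < 2L) stop("subset must contain at least two individuals")
  if (anyNA(x$map$cm))
    stop("markers lack cM positions; run attach_genetic_map() first")
  packed <- .pack(x)
  res <- .scan_packed(packed, matrix(idx - 1L, ncol = 1L), min_cm, min_snps,
                      tolerate_single_ch, !all_runs, min_snps_report)
  ids <- colnames(x$geno)[idx]
  .runs_as_df(res, x, list(.subset_id(ids)), length(idx))
}

# Shared C++ dispatch; subsets are 0-based index columns.
.scan_packed <- function(packed, subsets, min_cm, min_snps, tolerate,
                         qualify, min_snps_report) {
  cch_scan_cpp(packed, packed$cm, subsets, min_cm, as.integer(min_snps),
               tolerate, qualify, as.integer(min_snps_report))
}

# Decorate raw C++ run records with map coordinates and subset identity.
.runs_as_df <- function(res, x, subset_ids, k) {
  chrom_levels <- .chrom_blocks(x$map)$chrom
  df <- data.frame(
    subset_id = as.character(unlist(subset_ids))[res$subset],
    k = if (length(k) == 1L) rep(k, length(res$subset)) else k[res$subset],
    chromosome = chrom_levels[res$chrom],
    start_idx = res$start_idx,
    end_idx = res$end_idx,
    start_bp = x$map$bp[res$start_idx],
    end_bp = x$map$bp[res$end_idx],
    start_cm = res$start_cm,
    end_cm = res$end_cm,
    n_snps = res$n_snps,
    length_cm = res$length_cm,
    tolerated_ch_count = res$tolerated_ch_count,
    stringsAsFactors = FALSE
  )
  df <- df[order(res$subset, res$start_idx), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Genome-wide scan for one subset
#'
#' [find_runs()] applied across all chromosomes of the matrix, results in
#' genome order.  Provided as the single-analysis entry point mirroring
#' the per-subset unit of the combinatorial scan.
#'
#' @inheritParams find_runs
#' @param ... passed to [find_runs()].
#' @return As [find_runs()].
#' @export
genome_scan <- function(x, subset, ...) find_runs(x, subset, ...)
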