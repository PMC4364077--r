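#' Number of k-subsets of n individuals
#'
#' The binomial coefficient n! / (k! (n-k)!), i.e. the number of
#' independent genome-wide analyses performed when testing all subsets of
#' size k, and hence the Bonferroni factor for that level.  Computed by the
#' exact multiplicative scheme; every intermediate value is an integer, so
#' results are exact while they remain below 2^53.
#'
#' @param n group size.
#' @param k subset size, `0 <= k <= n`.
#' @return The coefficient as a numeric scalar.
#' @examples
#' count_subsets(17, 11) # 12376
#' @export
count_subsets <- function(n, k) {
  if (k > n) stop("k must not exceed n")
  if (k < 0 || n < 0) stop("n and k must be non-negative")
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) r <- r * (n - k + i) / i
  if (r > 2^53) warning("count exceeds 2^53; value is approximate")
  round(r)
}

# r-th (1-based) k-combination of 1..n in lexicographic order (combinadic
# unranking); lets chunked enumeration start mid-sequence without
# materialising the full list.
.nth_combination <- function(n, k, r) {
  out <- integer(k)
  r <- r - 1
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      rest <- count_subsets(n - x, k - i)
      if (r < rest) break
      r <- r - rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

# Lexicographic index range [from, to] of chunk `index` of `total` over S
# items; chunk sizes differ by at most one (larger chunks first).
.chunk_range <- function(S, index, total) {
  if (total < 1L || index < 1L || index > total)
    stop("invalid chunk specification: ", index, "/", total)
  base <- S %/% total
  rem <- S %% total
  sizes <- rep(base, total) + (seq_len(total) <= rem)
  to <- cumsum(sizes)
  from <- to - sizes + 1L
  c(from[index], to[index])
}

#' Enumerate k-subsets of a set of individuals
#'
#' Subsets are emitted in lexicographic order over the ranks of the sorted
#' members.  With a chunk specification `c(index, total)` the full sequence
#' is split into `total` contiguous blocks whose sizes differ by at most
#' one, and block `index` is returned; the union over all blocks is exactly
#' the full enumeration.  This is the parallelisation contract: each block
#' is an independent unit of work.
#'
#' @param members character vector of identifiers (sorted internally).
#' @param k subset size.
#' @param chunk optional `c(index, total)` (or a string `"index/total"`).
#' @return List of character vectors, each a sorted k-subset.
#' @examples
#' enumerate_subsets(c("a", "b", "c"), 2)
#' enumerate_subsets(c("a", "b", "c"), 2, chunk = c(2, 3))
#' @export
enumerate_subsets <- function(members, k, chunk = NULL) {
  members <- sort(members)
  n <- length(members)
  if (k < 1L || k > n) stop("k must be between 1 and the number of members")
  S <- count_subsets(n, k)
  if (is.null(chunk)) {
    idx <- combn(n, k)
    return(lapply(seq_len(ncol(idx)), function(i) members[idx[, i]]))
  }
  chunk <- .parse_chunk(chunk)
  rng <- .chunk_range(S, chunk[1L], chunk[2L])
  if (rng[1L] > rng[2L]) return(list())
  lapply(seq(rng[1L], rng[2L]),
         function(r) members[.nth_combination(n, k, r)])
}

.parse_chunk <- function(chunk) {
  if (is.character(chunk)) {
    parts <- strsplit(chunk, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("chunk must be \"index/total\"")
    chunk <- as.integer(parts)
  }
  chunk <- as.integer(chunk)
  if (length(chunk) != 2L || anyNA(chunk))
    stop("chunk must be c(index, total)")
  chunk
}

#' Combinatorial CH scan over all subsets of a group
#'
#' Runs the genome-wide CH analysis on every subset of size `k_max` down to
#' `k_min` drawn from `members`.  Only subsets with at least one qualifying
#' run appear in the output; the total number of analyses performed (the
#' Bonferroni denominator) is recorded in the `n_analyses` attribute.
#' Scanning in descending subset size mirrors the discovery workflow for a
#' trait with an unknown number of phenocopies: start with everyone and
#' relax until loci appear.
#'
#' @inheritParams find_runs
#' @param members character identifiers of the group (default: everyone in
#'   the matrix).
#' @param k_min,k_max subset size range, `2 <= k_min <= k_max`.
#' @param chunk optional `c(index, total)`: analyse only this block of each
#'   size level's lexicographic enumeration (see [enumerate_subsets()]).
#' @param stop_after_loci if set, stop descending once a size level has
#'   produced at least this many qualifying runs.
#' @param analysis_budget warn when the planned number of analyses exceeds
#'   this count (default 1e7).
#' @param all_runs report every run (of at least `min_snps_report`
#'   markers) instead of qualifying runs only; used to collect null
#'   run-length distributions over many subsets.
#' @param min_snps_report reporting floor for `all_runs = TRUE`.
#' @return Data frame of qualifying runs as in [find_runs()], with
#'   attributes `n_analyses` (analyses actually performed) and `k_levels`.
#' @export
cch_scan <- function(x, members = individuals(x), k_min = 2L,
                     k_max = length(members), min_cm = 4, min_snps = 100,
                     tolerate_single_ch = TRUE, chunk = NULL,
                     stop_after_loci = NULL, analysis_budget = 1e7,
                     all_runs = FALSE, min_snps_report = 1L) {
  members <- sort(members)
  idx <- .subset_index(x, members)
  n <- length(members)
  if (k_min < 2L || k_min > k_max || k_max > n)
    stop("need 2 <= k_min <= k_max <= number of members")
  if (anyNA(x$map$cm))
    stop("markers lack cM positions; run attach_genetic_map() first")
  planned <- sum(vapply(k_min:k_max, function(k) count_subsets(n, k),
                        numeric(1)))
  if (planned > analysis_budget)
    warning("planned ", format(planned, big.mark = ","),
            " analyses exceed the budget of ",
            format(analysis_budget, big.mark = ","))

  packed <- .pack(x)
  out <- list()
  n_analyses <- 0
  for (k in seq(k_max, k_min)) {
    if (is.null(chunk)) {
      sub <- combn(n, k)
    } else {
      subs <- enumerate_subsets(seq_len(n), k, chunk)
      if (length(subs) == 0L) next
      sub <- matrix(unlist(subs), nrow = k)
    }
    res <- .scan_packed(packed, matrix(idx[sub] - 1L, nrow = k),
                        min_cm, min_snps, tolerate_single_ch, !all_runs,
                        min_snps_report)
    n_analyses <- n_analyses + ncol(sub)
    if (length(res$subset)) {
      ids <- lapply(seq_len(ncol(sub)), function(i)
        .subset_id(members[sub[, i]]))
      out[[length(out) + 1L]] <- .runs_as_df(res, x, ids, k)
    }
    if (!is.null(stop_after_loci) && length(res$subset) &&
        length(res$subset) >= stop_after_loci)
      break
  }
  runs <- if (length(out)) do.call(rbind, out) else .runs_as_df(
    list(subset = integer(), chrom = integer(), start_idx = integer(),
         end_idx = integer(), n_snps = integer(), length_cm = numeric(),
         start_cm = numeric(), end_cm = numeric(),
         tolerated_ch_count = integer()), x, list(), integer())
  rownames(runs) <- NULL
  attr(runs, "n_analyses") <- n_analyses
  attr(runs, "k_levels") <- seq(k_max, k_min)
  runs
}

#' Per-marker maximum IBD sharing profile
#'
#' For every marker, the largest subset size k over all analysed subsets
#' whose qualifying run covers the marker ("how many individuals share a
#' haplotype here"), 0 where no qualifying run covers it.
#'
#' @param results run table from [cch_scan()] (or [find_runs()]).
#' @param map marker map of the matrix the runs were computed on
#'   (`x$map`).
#' @param track_subsets also record, per marker, the subset ids attaining
#'   the maximum (capped at `max_tracked` ids per marker).
#' @param max_tracked cap for `track_subsets`.
#' @return Data frame with one row per marker: `chromosome`, `bp`, `cm`,
#'   `max_k` (and a `subsets` list-column when tracked).
#' @export
aggregate_max_k <- function(results, map, track_subsets = FALSE,
                            max_tracked = 10L) {
  m <- nrow(map)
  if (nrow(results) &&
      (max(results$end_idx) > m || min(results$start_idx) < 1L))
    stop("run indices out of map bounds")
  max_k <- integer(m)
  for (i in seq_len(nrow(results))) {
    r <- results$start_idx[i]:results$end_idx[i]
    max_k[r] <- pmax(max_k[r], results$k[i])
  }
  prof <- data.frame(chromosome = map$chrom, bp = map$bp, cm = map$cm,
                     max_k = max_k, stringsAsFactors = FALSE)
  if (track_subsets) {
    subs <- vector("list", m)
    for (i in seq_len(nrow(results))) {
      r <- results$start_idx[i]:results$end_idx[i]
      hit <- r[max_k[r] == results$k[i]]
      for (j in hit)
        if (length(subs[[j]]) < max_tracked)
          subs[[j]] <- unique(c(subs[[j]], results$subset_id[i]))
    }
    prof$subsets <- subs
  }
  prof
}
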