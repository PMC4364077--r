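# Independent brute-force reference implementation of the no-CH run search,
# built from first principles (explicit pairwise IBS0 checks, rle-based run
# extraction, restart-scan merging).  Shares no code with the package's
# scanning path.

oracle_ch_track <- function(g) {
  # g: markers x members; TRUE where some pair is homozygous for opposite
  # alleles
  apply(g, 1L, function(v) {
    conflict <- FALSE
    n <- length(v)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j && !is.na(v[i]) && !is.na(v[j]) &&
            ((v[i] == 0L && v[j] == 2L) || (v[i] == 2L && v[j] == 0L)))
          conflict <- TRUE
      }
    }
    conflict
  })
}

oracle_runs <- function(x, subset, min_cm, min_snps, tolerate,
                        all_runs = FALSE, min_snps_report = 1L) {
  out <- NULL
  for (ch in unique(x$map$chrom)) {
    idx <- which(x$map$chrom == ch)
    track <- oracle_ch_track(x$geno[idx, subset, drop = FALSE])
    cm <- x$map$cm[idx]
    r <- rle(!track)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(s = starts[r$values], e = ends[r$values], tol = 0L)
    if (tolerate && nrow(runs) > 1L) {
      repeat {
        merged <- FALSE
        for (i in seq_len(nrow(runs) - 1L)) {
          gap_one <- runs$s[i + 1L] == runs$e[i] + 2L
          if (gap_one && cm[runs$e[i + 1L]] - cm[runs$s[i]] >= min_cm) {
            runs$e[i] <- runs$e[i + 1L]
            runs$tol[i] <- runs$tol[i] + runs$tol[i + 1L] + 1L
            runs <- runs[-(i + 1L), , drop = FALSE]
            merged <- TRUE
            break
          }
        }
        if (!merged) break
      }
    }
    if (nrow(runs)) {
      runs$n <- runs$e - runs$s + 1L
      runs$len <- cm[runs$e] - cm[runs$s]
      keep <- if (all_runs) runs$n >= min_snps_report
              else runs$len >= min_cm & runs$n >= min_snps
      runs <- runs[keep, , drop = FALSE]
    }
    if (nrow(runs))
      out <- rbind(out, data.frame(chromosome = ch,
                                   start_idx = idx[runs$s],
                                   end_idx = idx[runs$e],
                                   n_snps = runs$n,
                                   length_cm = runs$len,
                                   tolerated_ch_count = runs$tol))
  }
  if (is.null(out))
    out <- data.frame(chromosome = character(), start_idx = integer(),
                      end_idx = integer(), n_snps = integer(),
                      length_cm = numeric(), tolerated_ch_count = integer())
  rownames(out) <- NULL
  out
}

# A deterministic hand-sized genotype set for io/engine unit tests: one
# chromosome with explicit cM positions and an all-heterozygous background
# (never any CH) onto which tests paint conflicts.
blank_geno <- function(n_ind, cm, chrom = "1") {
  m <- length(cm)
  map <- data.frame(chrom = chrom, id = paste0("m", seq_len(m)),
                    bp = as.integer(round(cm * 1e6)) + seq_len(m),
                    cm = cm)
  g <- matrix(1L, m, n_ind,
              dimnames = list(NULL, paste0("I", seq_len(n_ind))))
  cch_genotypes(g, map)
}

random_geno <- function(n_ind, m, len_cm, seed, miss = 0.02,
                        n_chrom = 1L) {
  map <- make_map(n_chrom, m, len_cm, seed = seed)
  x <- simulate_unrelated(n_ind, map, seed = seed + 1L)
  if (miss > 0) {
    set.seed(seed + 2L)
    x$geno[runif(length(x$geno)) < miss] <- NA_integer_
  }
  x
}
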