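#' Markers inside true IBD segments at a sharing level
#'
#' Maximal contiguous stretches of markers where the true sharing profile
#' is at least `k`, kept when their cM span (last minus first marker)
#' reaches `min_cm`; segments never cross chromosome boundaries.  These
#' markers form the denominator of sensitivity at that level and
#' threshold.
#'
#' @param truth_k integer vector: true per-marker maximum sharing (from
#'   [truth_max_k()]).
#' @param map marker map aligned with `truth_k`.
#' @param k sharing level.
#' @param min_cm minimum segment span in cM.
#' @return Sorted integer vector of (global) marker indices.
#' @export
truth_ibd_segments <- function(truth_k, map, k, min_cm) {
  if (length(truth_k) != nrow(map))
    stop("truth profile and map differ in length")
  out <- integer(0)
  blk <- .chrom_blocks(map)
  for (c in seq_along(blk$m)) {
    idx <- (blk$off[c] + 1L):(blk$off[c] + blk$m[c])
    r <- rle(truth_k[idx] >= k)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- idx[starts[j]]
      e <- idx[ends[j]]
      if (map$cm[e] - map$cm[s] >= min_cm) out <- c(out, s:e)
    }
  }
  out
}

#' Threshold-detectable true sharing profile
#'
#' The raw truth profile counts sharing however short-lived; a scan
#' restricted to runs of at least `min_cm` cannot resolve sub-threshold
#' fluctuations of the truth, so evaluation compares like with like.  For
#' each level in `k_levels`, markers lying in true segments of that level
#' spanning at least `min_cm` are assigned that level; the profile is the
#' pointwise maximum over levels (0 elsewhere).
#'
#' @inheritParams truth_ibd_segments
#' @param k_levels sharing levels considered (typically the scanned k
#'   range).
#' @return Integer vector, one entry per marker.
#' @export
truth_detectable_max_k <- function(truth_k, map, k_levels, min_cm) {
  prof <- integer(length(truth_k))
  for (k in sort(k_levels)) {
    idx <- truth_ibd_segments(truth_k, map, k, min_cm)
    prof[idx] <- k
  }
  prof
}

#' Score a detected sharing profile against gene-drop truth
#'
#' Sensitivity: of the markers in true IBD segments of level `k` spanning
#' at least `min_cm`, the proportion identified correctly by the scan.
#' What counts as correct is set by `match`: `"exact"` requires the
#' detected maximum to equal the true maximum at the marker; `"level"`
#' requires the marker to be identified as shared at the level defining
#' the locus (detected >= k), the reading matching a "regions inherited
#' IBD in k or more individuals" analysis; `"at_least"` requires
#' detected >= truth.  Specificity: of the markers called at level `k` or
#' higher, the proportion at which the truth supports at least the
#' detected level.  Empty denominators yield `NA` ("absent"), not 0.
#'
#' @param detected integer vector of detected per-marker maximum sharing
#'   (the `max_k` column of [aggregate_max_k()]), or the profile data
#'   frame itself.
#' @param truth_k true per-marker profile on the same map — typically the
#'   [truth_detectable_max_k()] profile, so that both sides of the
#'   comparison are subject to the same cM threshold.
#' @param map marker map.
#' @param k sharing level scored.
#' @param min_cm cM threshold.
#' @param match sensitivity matching rule: `"exact"` (default),
#'   `"level"` or `"at_least"`; see Details.
#' @param replicate optional replicate index carried into the result.
#' @return One-row data frame: `threshold_cm`, `k_level`, `sensitivity`,
#'   `specificity`, `n_truth_snps`, `n_called_snps`, `replicate`.
#' @export
score_detection <- function(detected, truth_k, map, k, min_cm,
                            match = c("exact", "level", "at_least"),
                            replicate = NA_integer_) {
  match <- match.arg(match)
  if (is.data.frame(detected)) detected <- detected$max_k
  if (length(detected) != nrow(map) || length(truth_k) != nrow(map))
    stop("profiles and map differ in length")
  tru <- truth_ibd_segments(truth_k, map, k, min_cm)
  called <- which(detected >= k)
  sens <- if (length(tru) == 0L) NA_real_ else {
    ok <- switch(match,
                 exact = detected[tru] == truth_k[tru],
                 level = detected[tru] >= k,
                 at_least = detected[tru] >= truth_k[tru])
    mean(ok)
  }
  spec <- if (length(called) == 0L) NA_real_
          else mean(truth_k[called] >= detected[called])
  data.frame(threshold_cm = min_cm, k_level = k, sensitivity = sens,
             specificity = spec, n_truth_snps = length(tru),
             n_called_snps = length(called), replicate = replicate)
}

#' Summarise evaluation results across replicates
#'
#' @param results row-bound [score_detection()] results.
#' @return Per (k_level, threshold_cm): the median and percentile 95%
#'   interval (2.5th and 97.5th percentiles across replicates) of
#'   sensitivity and specificity, with the number of replicates in which
#'   each was defined.
#' @export
summarise_scores <- function(results) {
  if (nrow(results) < 1L) stop("no results to summarise")
  groups <- split(results, list(results$k_level, results$threshold_cm),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    q <- function(v) quantile(v, c(0.5, 0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
    s <- q(g$sensitivity)
    p <- q(g$specificity)
    data.frame(k_level = g$k_level[1L], threshold_cm = g$threshold_cm[1L],
               n_replicates = nrow(g),
               sens_median = s[1L], sens_lo = s[2L], sens_hi = s[3L],
               sens_defined = sum(!is.na(g$sensitivity)),
               spec_median = p[1L], spec_lo = p[2L], spec_hi = p[3L],
               spec_defined = sum(!is.na(g$specificity)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
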