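#' Fit the exponential null distribution of no-CH run lengths
#'
#' Among unrelated individuals, the genetic lengths of runs free of
#' conflicting homozygosity are exponentially distributed; the fitted rate
#' underpins tail p-values for observed runs.  Runs with fewer than
#' `min_snps` markers are excluded before fitting, since very short runs
#' are dominated by marker-spacing artefacts (a single-marker run has
#' length 0 by construction).  The maximum-likelihood rate is
#' 1 / mean(length); a left-truncated variant (rate
#' `1 / (mean - truncate_at)`, valid by the memorylessness of the
#' exponential) is available for sensitivity analysis.  A quantile-quantile
#' correlation against exponential quantiles is reported as a
#' goodness-of-fit summary.
#'
#' @param run_lengths_cm numeric vector of run lengths in cM.
#' @param n_snps integer vector of marker counts per run (same length), or
#'   `NULL` to skip the SNP filter.
#' @param min_snps SNP-count floor applied before fitting (default 20).
#' @param truncate_at optional left-truncation point in cM.
#' @param n_analyses number of combinatorial analyses behind the runs; the
#'   Bonferroni denominator used by [run_pvalue()].
#' @return Object of class `cch_null`: list with `rate` (per cM),
#'   `n_runs_fit`, `min_snps_fit`, `n_analyses`, `qq_cor`.
#' @export
fit_exponential <- function(run_lengths_cm, n_snps = NULL, min_snps = 20L,
                            truncate_at = NULL, n_analyses = NA_real_) {
  x <- as.numeric(run_lengths_cm)
  if (!is.null(n_snps)) {
    if (length(n_snps) != length(x))
      stop("run_lengths_cm and n_snps differ in length")
    x <- x[n_snps >= min_snps]
  }
  if (length(x) < 2L)
    stop("fewer than 2 run lengths retained after the SNP filter")
  mu <- mean(x)
  rate <- if (is.null(truncate_at)) 1 / mu else {
    if (mu <= truncate_at) stop("mean length not above truncation point")
    1 / (mu - truncate_at)
  }
  qq <- if (length(unique(x)) < 2L) NA_real_
        else cor(sort(x), qexp(ppoints(length(x)), rate = rate))
  structure(list(rate = rate, n_runs_fit = length(x),
                 min_snps_fit = if (is.null(n_snps)) 0L else min_snps,
                 n_analyses = n_analyses, qq_cor = qq),
            class = "cch_null")
}

#' @export
print.cch_null <- function(x, ...) {
  cat("Exponential null for no-CH run lengths\n",
      "  rate: ", format(x$rate), " per cM (mean run ",
      format(1 / x$rate), " cM)\n",
      "  fitted on ", x$n_runs_fit, " runs (>= ", x$min_snps_fit,
      " SNPs); QQ correlation ", round(x$qq_cor, 4), "\n",
      "  analyses for correction: ", format(x$n_analyses), "\n", sep = "")
  invisible(x)
}

#' Tail p-value for an observed no-CH run
#'
#' `p_raw = exp(-rate * length_cm)` is the probability, under the fitted
#' exponential null, of a run at least this long arising without recent
#' shared ancestry; with `correct = TRUE` a Bonferroni adjustment
#' multiplies by the number of genome-wide subset analyses performed.  The
#' p-value attaches to IBD inheritance of the locus by the subset, not to
#' causation of any trait.
#'
#' @param length_cm observed run length in cM (non-negative).
#' @param model a `cch_null` fit from [fit_exponential()].
#' @param correct apply the Bonferroni correction (requires `n_analyses`
#'   in the model).
#' @return Named list with `p_raw` and `p_adjusted` (`NA` when
#'   `correct = FALSE`).
#' @export
run_pvalue <- function(length_cm, model, correct = TRUE) {
  if (any(length_cm < 0)) stop("length_cm must be non-negative")
  p_raw <- exp(-model$rate * length_cm)
  if (correct) {
    if (is.na(model$n_analyses))
      stop("model has no n_analyses; set it to Bonferroni-correct")
    p_adj <- pmin(1, p_raw * model$n_analyses)
  } else p_adj <- rep(NA_real_, length(p_raw))
  list(p_raw = p_raw, p_adjusted = p_adj)
}

#' Attach null p-values to a run table
#'
#' @param runs run table from [cch_scan()] or [find_runs()].
#' @param model a `cch_null` fit.
#' @param n_analyses Bonferroni denominator; defaults to the run table's
#'   `n_analyses` attribute, then the model's.
#' @return `runs` with `p_raw` and `p_adjusted` columns filled.
#' @export
attach_pvalues <- function(runs, model, n_analyses = NULL) {
  if (is.null(n_analyses))
    n_analyses <- attr(runs, "n_analyses") %||% model$n_analyses
  model$n_analyses <- n_analyses
  p <- run_pvalue(runs$length_cm, model, correct = !is.na(n_analyses))
  runs$p_raw <- p$p_raw
  runs$p_adjusted <- p$p_adjusted
  runs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected number of affected individuals under a binomial model
#'
#' Under a model in which each of `n` family members independently shows
#' the phenotype with the population prevalence (ignoring heritability),
#' the expected affected count is `n * prevalence`, reported to one
#' decimal place.  Used to judge whether an observed number of phenocopies
#' needs any explanation beyond chance.
#'
#' @param n number of individuals with phenotype information.
#' @param prevalence population prevalence in `[0, 1]`.
#' @return Expected count, rounded to one decimal.
#' @examples
#' binom_expected(48, 0.16) # 7.7
#' @export
binom_expected <- function(n, prevalence) {
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  round(n * prevalence, 1)
}

#' Exact binomial upper-tail probability P(X > k)
#'
#' @param n number of trials.
#' @param k observed count; the tail is strictly greater than `k`.
#' @param prevalence success probability.
#' @return `P(X > k)` for `X ~ Binomial(n, prevalence)`, computed exactly.
#' @export
binom_tail <- function(n, k, prevalence) {
  if (k < 0 || k > n) stop("k must be in [0, n]")
  pbinom(k, n, prevalence, lower.tail = FALSE)
}

#' Smallest prevalence making an affected count unsurprising
#'
#' Grid-searches the population prevalence (steps of `grid_step`) for the
#' smallest value at which the exact binomial probability of observing more
#' than `k` affected among `n` exceeds `alpha`; above this prevalence the
#' observed count of phenocopies is compatible with chance.
#'
#' @param n number of individuals.
#' @param k affected count; the tail is `P(X > k)`.
#' @param alpha significance level in (0, 1).
#' @param grid_step grid resolution (default 0.001, i.e. 0.1%).
#' @return Smallest grid prevalence with `binom_tail(n, k, p) > alpha`.
#' @examples
#' min_prevalence_exceeding(48, 5, 0.05) # 0.056
#' @export
min_prevalence_exceeding <- function(n, k, alpha, grid_step = 0.001) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  grid <- seq(grid_step, 1, by = grid_step)
  hit <- which(pbinom(k, n, grid, lower.tail = FALSE) > alpha)
  if (!length(hit))
    stop("no grid prevalence below 1 gives a tail above alpha")
  grid[hit[1L]]
}

#' Serialise a fitted null model to JSON
#' @param model a `cch_null` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_null_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a null model written by [write_null_model()]
#' @param path JSON path.
#' @return A `cch_null` object.
#' @export
read_null_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$n_analyses <- m$n_analyses %||% NA_real_
  structure(m, class = "cch_null")
}
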