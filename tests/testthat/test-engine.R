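test_that("ch_status flags exactly the opposite-homozygote configurations", {
  expect_true(ch_status(c(0L, 1L, 2L)))
  expect_false(ch_status(c(0L, 0L, 1L)))
  expect_true(ch_status(c(0L, NA, 2L)))
  expect_false(ch_status(c(0L, NA, 1L)))
  expect_error(ch_status(integer(0)), "empty")

  # brute-force pairwise IBS0 agreement on random genotype vectors
  set.seed(42)
  for (rep in 1:200) {
    v <- sample(c(0L, 1L, 2L, NA), sample(2:8, 1), replace = TRUE)
    pairwise <- FALSE
    for (i in seq_along(v)) for (j in seq_along(v))
      if (i < j && isTRUE(abs(v[i] - v[j]) == 2L)) pairwise <- TRUE
    expect_identical(ch_status(v), pairwise)
  }
})

test_that("a conflict-free chromosome yields one run spanning it", {
  cm <- seq(0, 10, length.out = 1000)
  x <- blank_geno(3, cm)
  r <- find_runs(x, c("I1", "I2"), min_cm = 4, min_snps = 100)
  expect_equal(nrow(r), 1L)
  expect_equal(r$length_cm, 10)
  expect_equal(r$n_snps, 1000L)
  expect_equal(r$tolerated_ch_count, 0L)
})

test_that("an isolated CH marker is tolerated when the merged span qualifies", {
  cm <- seq(0, 6, by = 0.1) # 61 markers
  x <- blank_geno(2, cm)
  x$geno[31, ] <- c(0L, 2L) # single conflict at 3.0 cM
  r <- find_runs(x, c("I1", "I2"), min_cm = 4, min_snps = 10)
  expect_equal(nrow(r), 1L)
  expect_equal(r$length_cm, 6)
  expect_equal(r$n_snps, 61L)
  expect_equal(r$tolerated_ch_count, 1L)

  # the same conflict is fatal when tolerance is off, or when the merged
  # span stays below the threshold
  r2 <- find_runs(x, c("I1", "I2"), min_cm = 4, min_snps = 10,
                  tolerate_single_ch = FALSE)
  expect_equal(nrow(r2), 0L)
  r3 <- find_runs(x, c("I1", "I2"), min_cm = 7, min_snps = 10)
  expect_equal(nrow(r3), 0L)
})

test_that("two consecutive CH markers always terminate a run", {
  cm <- seq(0, 10, by = 0.1)
  x <- blank_geno(2, cm)
  x$geno[50, ] <- c(0L, 2L)
  x$geno[51, ] <- c(2L, 0L)
  r <- find_runs(x, c("I1", "I2"), min_cm = 4, min_snps = 10)
  expect_true(all(r$tolerated_ch_count == 0L))
  expect_true(all(r$end_idx < 50L | r$start_idx > 51L))
})

test_that("find_runs matches the brute-force oracle on random instances", {
  cases <- expand.grid(seed = c(11L, 23L, 87L), tol = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    x <- random_geno(12, 500, 25, seed = cases$seed[i], n_chrom = 2L)
    subset <- paste0("I", c(2, 5, 7, 11))
    got <- find_runs(x, subset, min_cm = 2, min_snps = 20,
                     tolerate_single_ch = cases$tol[i])
    want <- oracle_runs(x, subset, min_cm = 2, min_snps = 20,
                        tolerate = cases$tol[i])
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
  }
  # larger instance, near the method's defaults
  x <- random_geno(15, 2000, 20, seed = 5, n_chrom = 1L)
  subset <- paste0("I", c(1, 4, 8, 9, 14))
  got <- find_runs(x, subset, min_cm = 4, min_snps = 100)
  want <- oracle_runs(x, subset, min_cm = 4, min_snps = 100,
                      tolerate = TRUE)
  expect_equal(got[, names(want)], want, ignore_attr = TRUE)
  # all-runs collection mode agrees too
  got_all <- find_runs(x, subset, min_cm = 4, all_runs = TRUE,
                       min_snps_report = 3L)
  want_all <- oracle_runs(x, subset, min_cm = 4, min_snps = 100,
                          tolerate = TRUE, all_runs = TRUE,
                          min_snps_report = 3L)
  expect_equal(got_all[, names(want_all)], want_all, ignore_attr = TRUE)
})

test_that("run output is invariant under subset permutation and repeats", {
  x <- random_geno(10, 800, 20, seed = 31)
  a <- find_runs(x, c("I3", "I7", "I1", "I9"), min_cm = 1, min_snps = 10)
  b <- find_runs(x, c("I9", "I1", "I7", "I3"), min_cm = 1, min_snps = 10)
  expect_identical(a, b)
  expect_identical(a, find_runs(x, c("I3", "I7", "I1", "I9"),
                                min_cm = 1, min_snps = 10))
})

test_that("no-CH markers of a superset are no-CH for every sub-subset", {
  x <- random_geno(12, 600, 10, seed = 77)
  set.seed(8)
  for (rep in 1:10) {
    big <- sample(individuals(x), sample(4:8, 1))
    small <- sample(big, sample(2:(length(big) - 1L), 1))
    ch_big <- ch_status(x$geno[, big])
    ch_small <- ch_status(x$geno[, small])
    # conflict within the sub-subset implies conflict in the superset
    expect_false(any(ch_small & !ch_big))
  }
})

test_that("runs never cross chromosome boundaries", {
  cm <- seq(0, 10, length.out = 200)
  map <- data.frame(chrom = rep(c("1", "2"), each = 200),
                    id = paste0("m", 1:400),
                    bp = rep(as.integer(cm * 1e6) + 1:200, 2),
                    cm = rep(cm, 2))
  g <- matrix(1L, 400, 2, dimnames = list(NULL, c("A", "B")))
  x <- cch_genotypes(g, map)
  r <- find_runs(x, c("A", "B"), min_cm = 4, min_snps = 10)
  expect_equal(nrow(r), 2L)
  expect_equal(r$chromosome, c("1", "2"))
  r2 <- genome_scan(x, c("A", "B"), min_cm = 4, min_snps = 10)
  expect_identical(r, r2)
})

test_that("a CH marker in every window leaves no qualifying runs", {
  cm <- seq(0, 10, by = 0.1)
  x <- blank_geno(2, cm)
  x$geno[seq(1, 101, by = 5), 1] <- 0L
  x$geno[seq(1, 101, by = 5), 2] <- 2L
  r <- find_runs(x, c("I1", "I2"), min_cm = 4, min_snps = 10,
                 tolerate_single_ch = FALSE)
  expect_equal(nrow(r), 0L)
})

test_that("unknown subset members and missing cM positions are fatal", {
  x <- random_geno(4, 100, 5, seed = 2)
  expect_error(find_runs(x, c("I1", "nobody")), "nobody")
  expect_error(find_runs(x, "I1"), "at least two")
  x$map$cm <- NA_real_
  expect_error(find_runs(x, c("I1", "I2")), "attach_genetic_map")
})

test_that("sibling pairs carry long detectable runs", {
  # two sibs share >=1 haplotype over long stretches (expected scale tens
  # of cM), so a pair scan should find a qualifying run in most genomes
  ped <- pedigree(id = c("F", "M", "S1", "S2"),
                  father = c("0", "0", "F", "F"),
                  mother = c("0", "0", "M", "M"))
  hits <- 0L
  for (rep in 1:5) {
    map <- make_map(2, 3000, 100, seed = 400 + rep)
    gd <- gene_drop(ped, map, seed = 500 + rep)
    r <- find_runs(gd$genotypes, c("S1", "S2"), min_cm = 4, min_snps = 100)
    if (nrow(r) > 0L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
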