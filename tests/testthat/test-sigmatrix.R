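test_that("pairwise tests recover exact one-tailed P and directions", {
  # 12 patients, TC below P5 by >= 0.1 for all: one-signed exact P = 1/4096
  vals <- function(s) {
    m <- matrix(0.5, 12, 7)
    m[, 1] <- 0.3 + (1:12) / 100
    m[, 3] <- 0.5 + (1:12) / 90
    m
  }
  cm <- cohort_from_values(vals, coverage = 1000L)
  sm <- pairwise_region_tests(site_profile(cm, 1))
  expect_true(sm$sig["TC", "P5"])
  expect_equal(sm$dir["TC", "P5"], -1L)
  expect_equal(sm$p_low["TC", "P5"], 1 / 4096)
  expect_equal(sm$dir["P5", "TC"], 1L)

  # identical values in two regions -> all differences zero -> untestable
  vals2 <- function(s) {
    m <- matrix(0.5, 12, 7)
    m[, 1] <- m[, 2] <- 0.3 + (1:12) / 50
    m
  }
  cm2 <- cohort_from_values(vals2, coverage = 1000L)
  sm2 <- pairwise_region_tests(site_profile(cm2, 1))
  expect_false(sm2$sig["TC", "TE"])

  # matrices are symmetric, antisymmetric in direction, patient-order invariant
  set.seed(1)
  vals3 <- function(s) matrix(runif(84), 12, 7)
  cm3 <- cohort_from_values(vals3, coverage = 1000L)
  site <- site_profile(cm3, 1)
  sm3 <- pairwise_region_tests(site)
  sm3p <- pairwise_region_tests(site[sample(12), ])
  expect_identical(sm3$sig, sm3p$sig)
  expect_identical(sm3$dir, sm3p$dir)
  expect_equal(sm3$n_significant_pairs, sum(sm3$sig[upper.tri(sm3$sig)]))

  # independent recomputation of the count from the stored one-tailed Ps
  recount <- sum(pmin(sm3$p_low, sm3$p_high)[upper.tri(sm3$sig)] < 0.05,
                 na.rm = TRUE)
  expect_equal(sm3$n_significant_pairs, recount)

  # too few patients overall is an error
  expect_error(pairwise_region_tests(site[1:2, ]), "fewer than 3")
})

test_that("status vectors flatten consistently and feed cosine similarity", {
  m0 <- matrix(FALSE, 7, 7)
  expect_equal(status_vector(m0), rep(0L, 42))
  m1 <- m0; m1[1, 4] <- m1[4, 1] <- TRUE
  v1 <- status_vector(m1)
  expect_equal(sum(v1), 2)  # one pair lights both ordered cells
  expect_error(cosine_similarity(v1, rep(0, 42)), "zero")
  expect_equal(cosine_similarity(v1, v1), 1)
  m2 <- m0; m2[2, 5] <- m2[5, 2] <- TRUE
  expect_equal(cosine_similarity(v1, status_vector(m2)), 0)
  # 4 ones vs 2 ones sharing 2: 2 / sqrt(8)
  a <- c(rep(1, 4), rep(0, 38))
  b <- c(1, 1, rep(0, 40))
  expect_equal(cosine_similarity(a, b), 2 / sqrt(8))
})

test_that("neighbor proportions honour the closed 30 bp window", {
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    pos = c(100, 130, 100, 131, 500),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    bin = c(1, 1, 2, 2, 3))
  pr <- neighbor_significant_proportion(sites, window = 30)
  expect_equal(pr$proportion[pr$bin == 1], 1)  # 30 bp apart: inclusive
  expect_equal(pr$proportion[pr$bin == 2], 0)  # 31 bp apart: outside
  expect_equal(pr$proportion[pr$bin == 3], 0)  # lone site has no neighbour

  # brute-force pair scan agrees on random layouts
  set.seed(3)
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                    pos = sample.int(2000, 200),
                    significant = runif(200) < 0.4,
                    bin = sample(1:4, 200, TRUE))
  rnd <- rnd[!duplicated(rnd[, c("chrom", "pos")]), ]
  rnd <- rnd[order(rnd$chrom, rnd$pos), ]
  got <- neighbor_significant_proportion(rnd, window = 30)
  want <- sapply(seq_len(nrow(rnd)), function(i) {
    any(rnd$chrom == rnd$chrom[i] & rnd$significant &
          abs(rnd$pos - rnd$pos[i]) <= 30 & rnd$pos != rnd$pos[i])
  })
  for (b in sort(unique(rnd$bin))) {
    expect_equal(got$proportion[got$bin == b], mean(want[rnd$bin == b]))
  }
})

test_that("binning covers the fixed scheme, quantiles, EM and Fisher-Jenks", {
  # fixed-width study scheme: open bins below -0.025 and above 0.2
  v <- c(-0.03, -0.025, -0.01, 0.19, 0.2, 0.25)
  b <- bin_sites(v, "fixed_width")
  expect_equal(b[1], 1L)       # <= -0.025 start bin
  expect_equal(b[2], 1L)       # boundary belongs to the start bin
  expect_equal(b[6], 11L)      # > 0.2 end bin
  expect_equal(max(bin_sites(seq(-0.03, 0.25, 0.001), "fixed_width")), 11L)

  set.seed(2)
  x <- rnorm(100)
  q <- bin_sites(x, "quantile", k = 4)
  expect_equal(as.vector(table(q)), rep(25L, 4))

  g <- bin_sites(c(rnorm(60, 0, 0.3), rnorm(60, 5, 0.3)), "gmm_em", k = 2)
  expect_equal(as.vector(table(g)), c(60L, 60L))

  fj <- bin_sites(c(1, 1, 1, 10, 10, 10), "fisher_jenks", k = 2)
  expect_equal(fj, c(1L, 1L, 1L, 2L, 2L, 2L), ignore_attr = TRUE)
  expect_error(bin_sites(c(1, 1, 1), "fisher_jenks", k = 2), "distinct")
})

test_that("Fisher-Jenks DP attains the exhaustive-search optimum", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    x <- round(runif(n, 0, 100)) + runif(n) / 10  # near-ties included
    bin <- bin_sites(x, "fisher_jenks", k = k)
    expect_equal(attr(bin, "objective"), oracle_jenks_objective(x, k),
                 tolerance = 1e-10)
  }
})
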