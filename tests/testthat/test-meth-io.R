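test_that("coverage files parse, round-trip and validate", {
  f <- withr::local_tempfile(lines = c(
    "chr1\t100\t100\t75.0\t3\t1",
    "chr1\t50\t50\t0.0\t0\t20",
    "chr2\t10\t10\t100.0\t16\t0"))
  rec <- read_bismark_coverage(f)
  expect_equal(rec$pos, c(50, 100, 10))  # sorted within chromosome
  expect_equal(rec$meth_count[rec$pos == 100], 3)
  expect_equal(rec$unmeth_count[rec$pos == 100], 1)

  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(read_bismark_coverage(empty)), 0)

  bad <- withr::local_tempfile(lines = "chr1\t100\t100\t10.0\t9\t1")
  expect_warning(read_bismark_coverage(bad), "disagrees")

  # write-then-read identity through the simulator
  sim <- simulate_methylation_cohort(cohort_config(sites_per_pattern = 2,
                                                   seed = 4))
  dir <- withr::local_tempdir()
  layout <- write_bismark_cohort(sim, dir)
  s1 <- layout$sample[1]
  back <- read_bismark_coverage(file.path(dir, paste0(s1, ".cov")))
  orig <- sim[paste(sim$patient, sim$region, sep = "_") == s1, ]
  orig <- orig[order(orig$chrom, orig$pos), ]
  expect_equal(back$meth_count, orig$meth_count)
  expect_equal(back$unmeth_count, orig$unmeth_count)
})

test_that("assembly applies the strict 15x floor and keeps the site union", {
  mk <- function(pos, m, u) data.frame(chrom = "chr1", pos = pos,
                                       meth_count = m, unmeth_count = u)
  labs <- region_labels()
  layout <- data.frame(sample = paste0("s", 1:14),
                       patient = rep(c("A", "B"), each = 7),
                       region = rep(labs, 2))
  samples <- lapply(1:14, function(i) mk(c(100, 200), c(10, 7), c(5, 7)))
  names(samples) <- layout$sample
  # coverage 15 at site 100 (retained), 14 at site 200 (missing)
  cm <- assemble_cohort(samples, layout, min_coverage = 15)
  expect_equal(nrow(cm$meth), 2)
  expect_true(all(!is.na(cm$meth[1, ])))
  expect_true(all(is.na(cm$meth[2, ])))
  expect_equal(unname(cm$meth[1, 1]), 10 / 15)
  # coverage is kept even where methylation is masked
  expect_true(all(cm$coverage[2, ] == 14))

  # site absent from one patient's files is missing only there
  samples2 <- samples
  for (i in 1:7) samples2[[i]] <- mk(c(100, 200, 300), c(20, 20, 20), c(0, 0, 0))
  cm2 <- assemble_cohort(samples2, layout)
  i300 <- which(cm2$sites$pos == 300)
  expect_true(all(!is.na(cm2$meth[i300, cm2$samples$patient == "A"])))
  expect_true(all(is.na(cm2$meth[i300, cm2$samples$patient == "B"])))

  # order of the input samples does not matter
  perm <- sample(seq_len(nrow(layout)))
  cm3 <- assemble_cohort(samples[perm], layout[perm, ])
  expect_equal(cm3$meth, cm$meth)

  dup <- layout; dup$region[8] <- dup$region[1]; dup$patient[8] <- "A"
  expect_error(assemble_cohort(samples, dup), "duplicate")
  bad <- layout; bad$region[1] <- "XX"
  expect_error(assemble_cohort(samples, bad), "unknown region")
})

test_that("detection filter: fixed boundary and EM threshold", {
  set.seed(42)
  # synthetic detection counts: half low (N(20,2)), half high (N(80,2)) of 84
  counts <- c(round(rnorm(300, 20, 2)), round(rnorm(300, 80, 2)), 67, 68)
  sim <- simulate_methylation_cohort(cohort_config(sites_per_pattern = 1,
                                                   seed = 1))
  cm <- cohort_from_simulation(sim)
  # graft the synthetic counts onto a cohort-shaped matrix
  meth <- matrix(NA_real_, length(counts), 84,
                 dimnames = list(NULL, colnames(cm$meth)))
  for (i in seq_along(counts)) {
    meth[i, sample.int(84, min(84, max(0, counts[i])))] <- 0.5
  }
  fake <- cm
  fake$meth <- meth
  fake$coverage <- matrix(20L, nrow(meth), 84)
  fake$sites <- data.frame(chrom = "chr1", pos = seq_along(counts))

  fx <- detection_frequency_filter(fake, mode = "fixed", fixed_threshold = 68)
  expect_identical(fx$kept, rowSums(!is.na(meth)) >= 68)
  # boundary: detected in 67 dropped, 68 kept
  expect_false(fx$kept[which(fx$detection_count == 67)[1]])
  expect_true(fx$kept[which(fx$detection_count == 68)[1]])

  em <- detection_frequency_filter(fake, mode = "em")
  expect_gt(em$threshold, 40)
  expect_lt(em$threshold, 60)
  # EM threshold agrees with the brute-force posterior crossing of its fit
  support <- 0:84
  post <- methgrad:::gmm_posterior(em$mixture, support)[, 2]
  expect_equal(em$threshold, min(support[post >= 0.5]))

  # all sites detected everywhere: every threshold <= n keeps everything
  full <- fake
  full$meth[] <- 0.5
  expect_warning(fa <- detection_frequency_filter(full, mode = "em",
                                                  fixed_threshold = 84),
                 "degenerate")
  expect_true(all(fa$kept))
})

test_that("filtering is monotone in its thresholds", {
  set.seed(7)
  sim <- simulate_methylation_cohort(cohort_config(sites_per_pattern = 10,
                                                   missing_rate = 0.3,
                                                   seed = 8))
  for (th in c(40, 60, 80)) {
    cm <- cohort_from_simulation(sim)
    f_lo <- detection_frequency_filter(cm, "fixed", fixed_threshold = th)
    f_hi <- detection_frequency_filter(cm, "fixed", fixed_threshold = th + 5)
    expect_true(all(which(f_hi$kept) %in% which(f_lo$kept)))
  }
  cm15 <- cohort_from_simulation(sim, min_coverage = 15)
  cm25 <- cohort_from_simulation(sim, min_coverage = 25)
  expect_true(all(is.na(cm15$meth) | !is.na(cm15$meth)))
  expect_true(all(which(!is.na(cm25$meth)) %in% which(!is.na(cm15$meth))))
})
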