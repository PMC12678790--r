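mk_classified <- function(pos, class, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, class = class)
}

test_that("region merging honours gap, count and direction rules", {
  # gaps of 200: one region spanning all three sites
  r1 <- merge_changing_sites(mk_classified(c(100, 300, 500),
                                           rep("shallow_rise", 3)))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, 99)   # 0-based half-open over member span
  expect_equal(r1$end, 500)
  expect_equal(r1$category, "shallow_rise")

  # a 251 bp gap breaks the run; no set of 3 remains
  r2 <- merge_changing_sites(mk_classified(c(100, 351, 400),
                                           rep("steep_rise", 3)))
  expect_equal(nrow(r2), 0)
  # 250 exactly joins
  r3 <- merge_changing_sites(mk_classified(c(100, 350, 600),
                                           rep("steep_rise", 3)))
  expect_equal(nrow(r3), 1)

  # two same-direction sites never form a region
  expect_equal(nrow(merge_changing_sites(
    mk_classified(c(100, 200), rep("steep_rise", 2)))), 0)

  # direction change splits runs in direction-aware mode ...
  cls <- c("steep_rise", "steep_rise", "steep_rise",
           "steep_decline", "steep_decline", "steep_decline")
  r4 <- merge_changing_sites(mk_classified(seq(100, 600, 100), cls))
  expect_equal(nrow(r4), 2)
  expect_setequal(r4$category, c("steep_rise", "steep_decline"))
  # ... and is flagged bidirectional in the direction-agnostic mode
  r5 <- merge_changing_sites(mk_classified(seq(100, 600, 100), cls),
                             direction_aware = FALSE)
  expect_equal(r5$category, "discarded_bidirectional")

  # unordered sites are ignored entirely
  r6 <- merge_changing_sites(mk_classified(
    c(100, 150, 200, 250), c("steep_rise", "unordered", "steep_rise",
                             "steep_rise")))
  expect_equal(r6$n_sites, 3)
  expect_error(merge_changing_sites(mk_classified(c(300, 100, 200),
                                                  rep("steep_rise", 3))),
               "sorted")
})

test_that("merging agrees with the quadratic run-scan oracle", {
  set.seed(12)
  for (rep in 1:1000) {
    n <- sample(3:25, 1)
    pos <- sort(sample.int(3000, n))
    dir <- sample(c(1L, -1L), n, replace = TRUE)
    kind <- sample(c("steep", "shallow"), n, replace = TRUE)
    cls <- paste0(kind, ifelse(dir > 0, "_rise", "_decline"))
    got <- merge_changing_sites(mk_classified(pos, cls))
    want <- oracle_merge(pos, dir)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, `[[`, 0, "start") - 1)
      expect_equal(got$end, vapply(want, `[[`, 0, "end"))
      expect_equal(got$n_sites, vapply(want, function(w) unname(w["n"]), 0))
    }
  }
})

test_that("region categories follow the member composition", {
  expect_equal(categorize_region(rep("shallow_decline", 3)), "shallow_decline")
  expect_equal(categorize_region(c("steep_rise", "steep_rise", "shallow_rise")),
               "mixed_rise")
  expect_equal(categorize_region(c("steep_rise", "shallow_decline")),
               "discarded_bidirectional")
  expect_equal(categorize_region(rep("steep_decline", 5)), "steep_decline")
})

test_that("region methylation level is the member median per sample", {
  vals <- function(s) matrix(c(0.1, 0.2, 0.9)[((s - 1) %% 3) + 1], 12, 7)
  cm <- cohort_from_values(vals, n_sites = 3, coverage = 1000L)
  region <- merge_changing_sites(mk_classified(c(1000, 2000, 3000),
                                               rep("shallow_rise", 3)),
                                 max_gap = 1000)
  prof <- region_methylation_profile(region[1, ], cm)
  expect_equal(unname(prof[1]), 0.2, tolerance = 1e-3)
  # even member count after missingness: midpoint of the central pair
  cm2 <- cm
  cm2$meth[3, ] <- NA
  prof2 <- region_methylation_profile(region[1, ], cm2)
  expect_equal(unname(prof2[1]), 0.15, tolerance = 1e-3)
})

test_that("gene models derive strand-aware promoters from GTF", {
  gtf <- withr::local_tempfile(lines = c(
    'chr1\tsrc\tgene\t10001\t20000\t.\t+\t.\tgene_id "G1"; gene_name "GenA";',
    'chr1\tsrc\tgene\t10001\t20000\t.\t-\t.\tgene_id "G2"; gene_name "GenB";'),
    fileext = ".gtf")
  g <- load_gene_models(gtf)
  expect_equal(g$body_start, c(10000, 10000))
  expect_equal(g$body_end, c(20000, 20000))
  # + strand: promoter is the 2 kb upstream of the leftmost base
  expect_equal(g$prom_start[1], 8000)
  expect_equal(g$prom_end[1], 10000)
  # - strand: upstream means rightward of the gene end
  expect_equal(g$prom_start[2], 20000)
  expect_equal(g$prom_end[2], 22000)
  # both promoters abut their gene, on opposite sides
  expect_equal(g$prom_end[1], g$body_start[1])
  expect_equal(g$prom_start[2], g$body_end[2])

  gtf2 <- withr::local_tempfile(lines = c(
    'chr1\tsrc\tgene\t100\t200\t.\t.\t.\tgene_id "G3";'), fileext = ".gtf")
  expect_warning(g2 <- load_gene_models(gtf2), "strand")
  expect_equal(nrow(g2), 0)
})

test_that("regions map onto gene compartments by interval intersection", {
  gtf <- withr::local_tempfile(lines = c(
    'chr1\tsrc\tgene\t10001\t20000\t.\t+\t.\tgene_id "G1"; gene_name "GenA";'),
    fileext = ".gtf")
  genes <- load_gene_models(gtf)
  regions <- merge_changing_sites(mk_classified(
    c(9901, 9951, 10051,        # straddles promoter|TSS
      12001, 12051, 12101,      # inside the gene body
      3000100, 3000150, 3000200),  # far away
    rep("shallow_rise", 9)))
  hits <- map_regions_to_genes(regions, genes)
  h1 <- hits[hits$region_index == 1, ]
  expect_setequal(h1$compartment, c("gene_body", "promoter"))
  h2 <- hits[hits$region_index == 2, ]
  expect_equal(h2$compartment, "gene_body")
  expect_false(3 %in% hits$region_index)
  # chromosome naming is normalised with a warning
  regions_nochr <- regions
  regions_nochr$chrom <- "1"
  expect_warning(hits2 <- map_regions_to_genes(regions_nochr, genes), "chr")
  expect_equal(hits2$compartment, hits$compartment)
})

test_that("feature overlap proportions match a linear membership scan", {
  sets <- list(all_in = data.frame(chrom = "chr1", pos = 101:110),
               rnd = data.frame(chrom = "chr1",
                                pos = sort(sample.int(1000, 50))))
  track <- data.frame(chrom = "chr1", start = 100L, end = 110L)
  empty <- data.frame(chrom = character(), start = integer(), end = integer())
  pr <- feature_overlap_proportions(sets, list(t = track, none = empty))
  expect_equal(pr$proportion[pr$set == "all_in" & pr$track == "t"], 1)
  expect_equal(pr$proportion[pr$track == "none"], c(0, 0))
  # brute-force membership: position p inside 0-based half-open [start, end)
  # means start < p <= end in 1-based terms
  want <- mean(sets$rnd$pos > 100 & sets$rnd$pos <= 110)
  expect_equal(pr$proportion[pr$set == "rnd" & pr$track == "t"], want)
})
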