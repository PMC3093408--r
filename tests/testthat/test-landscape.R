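test_that("genome fraction reproduces the worked percentage and its bounds", {
  gi <- genome_index(c(chr1 = 2.5e9))
  # 3.7 Mbp of proviruses in a 2.5 Gbp genome -> 0.148%, ~0.15%
  chains <- data.frame(id = 1:2, chrom = "chr1", start = c(0, 1e7),
                       end = c(0 + 1.7e6, 1e7 + 2e6), strand = "+",
                       score = 400, genus = "gamma", stringsAsFactors = FALSE)
  frac <- genome_fraction(chain_table(chains), gi)
  expect_equal(frac, 100 * 3.7e6 / 2.5e9)
  expect_equal(round(frac, 2), 0.15)
  # no chains -> 0%; one chain covering a single-contig genome -> 100%
  expect_equal(genome_fraction(chains[0, ], gi), 0)
  gi1 <- genome_index(c(ctg = 5000))
  whole <- data.frame(id = 1, chrom = "ctg", start = 0, end = 5000,
                      strand = "+", score = 400, genus = "gamma")
  expect_equal(genome_fraction(whole, gi1), 100)
  # invariant under chromosome renaming and feature order
  gi2 <- genome_index(c(alpha = 2.5e9))
  chains2 <- chains[2:1, ]; chains2$chrom <- "alpha"
  expect_equal(genome_fraction(chains2, gi2), frac)
})

test_that("bin densities assign features by start and sum to the total", {
  gi <- genome_index(c(chr1 = 3.5e6, chr2 = 1e6))
  feats <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(1500000, 999999, 1000000, 10),
                      end = c(1500100, 1000100, 1000100, 200))
  bins <- bin_density(feats, gi, bin = 1e6)
  expect_equal(sum(bins$count), nrow(feats))
  expect_equal(bins$count[bins$chrom == "chr1" & bins$bin == 1], 2)
  expect_equal(bins$count[bins$chrom == "chr1" & bins$bin == 0], 1)
  expect_equal(nrow(bins[bins$chrom == "chr1", ]), 4)  # ceil(3.5e6/1e6)
  # matches a brute-force per-feature assignment on random fixtures
  set.seed(61)
  feats <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                      start = sample.int(9e5, 200))
  feats$end <- feats$start + 50
  bins <- bin_density(feats, gi, bin = 1e5)
  for (r in sample.int(nrow(bins), 20)) {
    expected <- sum(feats$chrom == bins$chrom[r] &
                      feats$start >= bins$bin_start[r] &
                      feats$start < bins$bin_start[r] + 1e5)
    expect_equal(bins$count[r], expected)
  }
  expect_equal(sum(bins$count), 200)
})

test_that("telomere distances report the closest feature to each end", {
  gi <- genome_index(c(chr1 = 100000, chr2 = 50000))
  feats <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(0, 40000, 20000),
                      end = c(500, 42000, 21000))
  td <- telomere_distances(feats, gi)
  expect_equal(td$start_distance[td$chrom == "chr1"], 0)  # telomeric
  expect_equal(td$end_distance[td$chrom == "chr1"], 100000 - 42000)
  # single mid-chromosome feature: distances sum to length - feature length
  row2 <- td[td$chrom == "chr2", ]
  expect_equal(row2$start_distance + row2$end_distance, 50000 - 1000)
  # chromosomes without features are absent
  expect_false("chr3" %in% td$chrom)
  expect_equal(nrow(telomere_distances(feats[0, ], gi)), 0)
  # feature flush with the chromosome end
  flush <- data.frame(chrom = "chr2", start = 49000, end = 50000)
  expect_equal(telomere_distances(flush, gi)$end_distance, 0)
})

test_that("region breakdown labels every basepair once, CDS > UTR > intron", {
  ann <- data.frame(
    chrom = "chr1",
    start = c(10000, 10000, 12000, 14000),
    end = c(20000, 12000, 13000, 16000),
    type = c("gene", "UTR", "CDS", "CDS"), stringsAsFactors = FALSE)
  erv <- function(s, e) data.frame(id = 1L, chrom = "chr1", start = s, end = e,
                                   strand = "+", score = 400, genus = "gamma")
  # fully intergenic
  rb <- region_breakdown(erv(30000, 31000), ann)
  expect_equal(rb$intergenic, 1000)
  expect_equal(rb$exonic + rb$utr + rb$intronic, 0)
  # fully inside an intron (between the CDS blocks)
  rb <- region_breakdown(erv(13000, 14000), ann)
  expect_equal(rb$intronic, 1000)
  # straddling UTR/CDS/intron/intergenic; counts sum to the ERV length
  rb <- region_breakdown(erv(11000, 22000), ann)
  expect_equal(rb$utr, 1000)          # [11000,12000)
  expect_equal(rb$exonic, 3000)       # [12000,13000) + [14000,16000)
  expect_equal(rb$intronic, 5000)     # [13000,14000) + [16000,20000)
  expect_equal(rb$intergenic, 2000)   # [20000,22000)
  expect_equal(rb$exonic + rb$utr + rb$intronic + rb$intergenic, 11000)
  # CDS takes precedence where annotations overlap
  ann2 <- rbind(ann, data.frame(chrom = "chr1", start = 14000, end = 16000,
                                type = "UTR"))
  rb2 <- region_breakdown(erv(14000, 16000), ann2)
  expect_equal(rb2$exonic, 2000)
  expect_equal(rb2$utr, 0)
})

test_that("breakdown sums match chain lengths on random fixtures", {
  set.seed(71)
  for (rep in 1:8) {
    n_feat <- sample(5:15, 1)
    s <- sample.int(80000, n_feat)
    ann <- data.frame(chrom = "chr1", start = s,
                      end = s + sample(500:8000, n_feat, TRUE),
                      type = sample(c("gene", "CDS", "UTR"), n_feat, TRUE),
                      stringsAsFactors = FALSE)
    es <- sample.int(70000, 5)
    chains <- data.frame(id = 1:5, chrom = "chr1", start = es,
                         end = es + sample(1000:9000, 5, TRUE), strand = "+",
                         score = 400, genus = "gamma",
                         stringsAsFactors = FALSE)
    rb <- region_breakdown(chains, ann)
    expect_equal(rb$exonic + rb$utr + rb$intronic + rb$intergenic,
                 chains$end - chains$start)
    expect_true(all(rb[, c("exonic", "utr", "intronic", "intergenic")] >= 0))
  }
})

test_that("count-covariate correlation matches the closed-form Pearson fit", {
  lens <- c(chr1 = 120, chr2 = 80, chr3 = 60, chr4 = 40, chr5 = 20)
  counts <- 2 * lens + 3                        # perfectly linear
  res <- suppressWarnings(correlate_counts(counts, lens))  # exact fit
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 2)
  expect_lt(res$p_value, 1e-10)
  set.seed(83)
  noisy <- counts + rnorm(5, sd = 10)
  res <- correlate_counts(noisy, lens)
  expect_equal(res$r_squared, unname(cor(noisy, lens)^2))
  ct <- cor.test(noisy, lens)
  expect_equal(res$p_value, ct$p.value)
  # outliers are excluded by name, never auto-detected
  spiked <- noisy; spiked["chr1"] <- 1e4
  res2 <- correlate_counts(spiked, lens, exclude = "chr1")
  expect_equal(res2$n, 4)
  expect_equal(res2$excluded_outliers, "chr1")
  expect_equal(res2$r_squared, unname(cor(noisy[-1], lens[-1])^2))
  expect_error(correlate_counts(counts[1:4], lens[1:4],
                                exclude = c("chr1", "chr2")), "3 chromosomes")
  # permuted covariate carries no signal on average
  r2 <- replicate(30, correlate_counts(
    setNames(sample(unname(noisy)), names(noisy)), lens)$r_squared)
  expect_lt(mean(r2), 0.4)
})
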