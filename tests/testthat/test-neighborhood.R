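tx_row <- function(gene, tid, start, end, strand = "+", chrom = "chr1") {
  data.frame(gene_id = gene, transcript_id = tid, chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

erv_row <- function(id, start, end, strand = "+", chrom = "chr1") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, score = 400, genus = "gamma",
             stringsAsFactors = FALSE)
}

test_that("composite models annex only transcripts that overlap and extend", {
  # overlapping pair: the longest ([400,900)) annexes [100,500) -> [100,900)
  tx <- rbind(tx_row("g", "t1", 100, 500), tx_row("g", "t2", 400, 900))
  m <- build_composite_models(tx)
  expect_equal(c(m$start, m$end), c(100, 900))
  # single transcript: the model is the transcript
  m <- build_composite_models(tx_row("g", "t1", 100, 500))
  expect_equal(c(m$start, m$end), c(100, 500))
  # non-overlapping alternative transcript is NOT annexed
  tx <- rbind(tx_row("g", "t1", 100, 500), tx_row("g", "t2", 700, 2000))
  m <- build_composite_models(tx)
  expect_equal(c(m$start, m$end), c(700, 2000))
  # chained annexation reaches transcripts connected through intermediates
  tx <- rbind(tx_row("g", "t1", 0, 300), tx_row("g", "t2", 200, 600),
              tx_row("g", "t3", 550, 2000), tx_row("g", "t4", 3000, 3100))
  m <- build_composite_models(tx)
  expect_equal(c(m$start, m$end), c(0, 2000))
  # both strands -> split into two models with a warning
  tx <- rbind(tx_row("g", "t1", 0, 300, "+"), tx_row("g", "t2", 100, 900, "-"))
  expect_warning(m <- build_composite_models(tx), "both strands")
  expect_equal(nrow(m), 2)
  expect_setequal(m$strand, c("+", "-"))
})

test_that("relative positions follow the ERV frame and collapse overlap to 0", {
  erv <- erv_row(1, 10000, 16000, "+")
  model <- function(s, e, strand = "+", chrom = "chr1")
    data.frame(gene_id = "g", chrom = chrom, strand = strand,
               start = s, end = e, stringsAsFactors = FALSE)
  expect_equal(erv_relative_position(erv, model(15000, 20000)), 0)
  expect_equal(erv_relative_position(erv, model(16000, 17000)), 1)
  expect_equal(erv_relative_position(erv, model(8000, 10000)), -1)
  expect_equal(erv_relative_position(erv, model(8000, 9000)), -1001)
  expect_true(is.na(erv_relative_position(erv, model(8000, 9000, chrom = "chr2"))))
  # minus-strand ERV: a model toward the chromosome start is downstream
  erv_m <- erv_row(1, 10000, 16000, "-")
  expect_equal(erv_relative_position(erv_m, model(8000, 9000)), 1001)
  expect_equal(erv_relative_position(erv_m, model(16000, 17000)), -1)
})

test_that("a single same-strand model yields unit sense counts at its offsets", {
  erv <- erv_row(1, 10000, 16000, "+")
  models <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                       start = 16009, end = 16019, stringsAsFactors = FALSE)
  prof <- neighborhood_profile(erv, models, window = 100)
  idx0 <- 101  # offset 0
  expect_equal(sum(prof$sense), 10)
  expect_equal(prof$sense[idx0 + (10:19)], rep(1, 10))  # offsets +10..+19
  expect_equal(sum(prof$antisense), 0)
  # no models at all
  prof0 <- neighborhood_profile(erv, models[0, ], window = 100)
  expect_equal(sum(prof0$sense) + sum(prof0$antisense), 0)
  # model entirely beyond the window contributes nothing
  far <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                    start = 16000 + 150, end = 16000 + 400,
                    stringsAsFactors = FALSE)
  expect_equal(sum(neighborhood_profile(erv, far, window = 100)$sense), 0)
})

test_that("profiles equal the quadratic per-basepair oracle", {
  set.seed(31)
  fx <- random_neighborhood_fixture(n_ervs = 10, n_models = 20)
  W <- 5000
  prof <- neighborhood_profile(fx$ervs, fx$models, window = W)
  oracle <- brute_profile(fx$ervs, fx$models, W)
  expect_equal(prof$sense, oracle$sense)
  expect_equal(prof$antisense, oracle$antisense)
})

test_that("count conservation and strand symmetry hold on random fixtures", {
  set.seed(41)
  for (rep in 1:12) {
    fx <- random_neighborhood_fixture()
    W <- 3000
    prof <- neighborhood_profile(fx$ervs, fx$models, window = W)
    # conservation: totals equal all model bp inside all ERV windows
    total_bp <- 0
    for (i in seq_len(nrow(fx$ervs))) for (j in seq_len(nrow(fx$models))) {
      lo <- max(fx$models$start[j], fx$ervs$start[i] - W)
      hi <- min(fx$models$end[j], fx$ervs$end[i] + W)
      total_bp <- total_bp + max(0, hi - lo)
    }
    expect_equal(sum(prof$sense) + sum(prof$antisense), total_bp)
    # flipping every strand keeps sense/antisense identity; the ERV frame
    # mirrors, so each array reverses around offset 0
    e2 <- fx$ervs; e2$strand <- flip_strand(e2$strand)
    m2 <- fx$models; m2$strand <- flip_strand(m2$strand)
    prof2 <- neighborhood_profile(e2, m2, window = W)
    expect_equal(prof2$sense, rev(prof$sense))
    expect_equal(prof2$antisense, rev(prof$antisense))
    # flipping only ERV strands swaps the arrays (in the mirrored frame)
    prof3 <- neighborhood_profile(e2, fx$models, window = W)
    expect_equal(prof3$sense, rev(prof$antisense))
    expect_equal(prof3$antisense, rev(prof$sense))
  }
})

test_that("over/under counts and the 1-df chi-square follow the closed form", {
  prof <- structure(list(window = 100, sense = rep(1, 201),
                         antisense = rep(1, 201), n_ervs = 1),
                    class = "neighborhood_profile")
  ou <- over_under(prof)
  expect_equal(c(ou$over, ou$under, ou$equal), c(0, 0, 201))
  expect_true(is.na(ou$chi2))
  # over = 150, under = 50 -> chi2 = 50
  prof$antisense[1:150] <- 2
  prof$sense[151:200] <- 2
  ou <- over_under(prof)
  expect_equal(c(ou$over, ou$under, ou$equal), c(150, 50, 1))
  expect_equal(ou$chi2, 50)
  expect_equal(ou$p_value, pchisq(50, 1, lower.tail = FALSE))
  # random profiles: chi2 agrees with stats::chisq.test
  set.seed(13)
  for (rep in 1:10) {
    s <- rpois(201, 3); a <- rpois(201, 3)
    prof$sense <- s; prof$antisense <- a
    ou <- over_under(prof)
    expect_equal(ou$over + ou$under + ou$equal, 201)
    if (ou$over + ou$under > 0)
      expect_equal(ou$chi2, unname(chisq.test(c(ou$over, ou$under),
                                              p = c(0.5, 0.5))$statistic))
  }
})

test_that("age-stratified profiles are additive and tolerate empty classes", {
  set.seed(53)
  fx <- random_neighborhood_fixture(n_ervs = 6, n_models = 10)
  W <- 3000
  dating <- data.frame(chain_id = fx$ervs$id,
                       age_class = c("young", "young", "middle", "old",
                                     "undatable", "young"))
  strat <- stratified_profiles(fx$ervs, fx$models, dating, window = W)
  expect_named(strat, c("young", "middle", "old"))
  datable <- fx$ervs[dating$age_class != "undatable", ]
  all_prof <- neighborhood_profile(datable, fx$models, window = W)
  expect_equal(strat$young$sense + strat$middle$sense + strat$old$sense,
               all_prof$sense)
  expect_equal(strat$young$antisense + strat$middle$antisense +
                 strat$old$antisense, all_prof$antisense)
  # all ERVs young -> young stratum reproduces the full profile
  dating$age_class <- "young"
  strat <- stratified_profiles(fx$ervs, fx$models, dating, window = W)
  full <- neighborhood_profile(fx$ervs, fx$models, window = W)
  expect_equal(strat$young$sense, full$sense)
  expect_equal(sum(strat$old$sense) + sum(strat$old$antisense), 0)
})

test_that("proximal genes respect the 5-kb flank boundary inclusively", {
  model <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      start = 50000, end = 60000, stringsAsFactors = FALSE)
  # ERV inside the model
  inside <- erv_row(1, 52000, 55000)
  out <- proximal_genes(inside, model)
  expect_equal(out$side, "contained")
  expect_equal(out$distance, 0)
  # upstream of the 5' end at 4999 / 5000 / 5001 bp
  at <- function(gap) erv_row(2, 50000 - gap - 3000, 50000 - gap)
  expect_equal(proximal_genes(at(4999), model)$side, "upstream")
  expect_equal(proximal_genes(at(5000), model)$distance, 5000)
  expect_equal(nrow(proximal_genes(at(5001), model)), 0)
  # downstream side and orientation on a minus-strand gene
  model_m <- model; model_m$strand <- "-"
  down <- erv_row(3, 45000, 47000)   # before start = after the 3' end of "-"
  out <- proximal_genes(down, model_m)
  expect_equal(out$side, "downstream")
  expect_equal(out$orientation, "antisense")
  expect_equal(nrow(proximal_genes(inside[0, ], model)), 0)
})
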