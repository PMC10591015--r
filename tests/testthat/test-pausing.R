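test_that("MAPQ filtering keeps records at or above the threshold", {
  aln <- reads_at(c(1000, 2000, 3000, 4000), mapq = c(0L, 29L, 30L, 42L))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sam)
  kept <- suppressMessages(read_alignments(sam, mapq_min = 30))
  expect_equal(length(kept), 2)
  expect_true(all(kept$mapq >= 30))

  # empty file: empty set, not an error
  empty <- reads_at(integer(0))
  sam0 <- tempfile(fileext = ".sam")
  write_sam(empty, sam0)
  expect_equal(length(suppressMessages(read_alignments(sam0))), 0)

  # BED without score: filter disabled with a warning
  bed <- tempfile(fileext = ".bed")
  writeLines("chrS1\t100\t150\tr1", bed)
  expect_warning(got <- read_alignments(bed), "MAPQ filter disabled")
  expect_equal(length(got), 1)
})

test_that("SAM and BED round-trips preserve the interval set", {
  gm <- generate_gene_models(3, 1e5, seed = 1)
  aln <- simulate_alignments(pausing_design(gm, true_tr = 2, depth = 2000, seed = 2))
  key <- function(g) sort(paste(GenomicRanges::seqnames(g), GenomicRanges::start(g),
                                GenomicRanges::end(g), g$mapq))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sam)
  expect_identical(key(suppressMessages(read_alignments(sam, 0))), key(aln))

  bed <- tempfile(fileext = ".bed")
  write_alignment_bed(aln, bed)
  expect_identical(key(suppressMessages(read_alignments(bed, 0))), key(aln))
})

test_that("RPKM coverage matches its formula and is depth-invariant", {
  one <- reads_at(1001, width = 50)
  trk <- coverage_track(one)
  v <- as.numeric(trk$cov$chrS1[1001:1050])
  expect_true(all(v == 1e9))          # 1 read, 1-bp bins: 1e9 / (1 * 1)
  expect_equal(as.numeric(trk$cov$chrS1[1000]), 0)

  # duplicating every read leaves the RPKM track unchanged
  dbl <- coverage_track(c(one, one))
  expect_identical(as.numeric(trk$cov$chrS1), as.numeric(dbl$cov$chrS1))

  expect_error(coverage_track(reads_at(integer(0))), "at least one")
})

test_that("per-base pileup equals a brute-force oracle on a 10-kb chromosome", {
  set.seed(7)
  starts <- sample(1:9950, 300, replace = TRUE)
  aln <- reads_at(starts, width = 50, chrom_len = 10000)
  raw <- coverage_track(aln, normalization = "raw")
  got <- as.numeric(raw$cov$chrS1)
  # oracle: position-by-position loop
  ref <- numeric(10000)
  for (s in starts) ref[s:(s + 49)] <- ref[s:(s + 49)] + 1
  expect_identical(got[1:10000], ref)
  # coverage conservation: total coverage = sum of read lengths
  expect_equal(sum(got), 300 * 50)
})

test_that("region counting matches hand arithmetic and a brute-force scan", {
  gene <- single_gene()
  tssr <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(5001, 5350))
  expect_equal(count_region(reads_at(integer(0)), tssr), 0)

  # 70 reads inside a 350-bp region, length-normalized -> 0.2
  aln70 <- reads_at(rep(seq(5001, 5300, length.out = 10), 7), width = 50)
  expect_equal(count_region(aln70, tssr, length_normalize = TRUE), 0.2)

  # random data vs interval scan
  set.seed(5)
  starts <- sample(1:19000, 500, replace = TRUE)
  aln <- reads_at(starts, width = 50)
  region <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(8000, 9000))
  ref <- sum(starts <= 9000 & (starts + 49) >= 8000)
  expect_equal(count_region(aln, region), ref)
})

test_that("traveling ratio reproduces the formula, the weak filter and statuses", {
  gene <- single_gene()    # TSS at 5001 (+ strand)
  # 70 reads in TSSR [5001, 5350], 300 in GBR [5351, 8350]
  tssr_reads <- reads_at(rep(seq(5001, 5300, length.out = 10), 7), width = 50)
  gbr_reads <- reads_at(rep(seq(5351, 8300, length.out = 30), 10), width = 50)
  tt <- traveling_ratio(gene, c(tssr_reads, gbr_reads))
  expect_equal(tt$tr, (70 / 350) / (300 / 3000), tolerance = 1e-12)  # = 2.0
  expect_equal(tt$status, "ok")

  # uniform coverage -> TR = 1
  tt_unif <- traveling_ratio(gene, uniform_reads())
  expect_equal(tt_unif$tr, 1.0, tolerance = 1e-12)

  # weak TSSR signal 0.0005 (input-normalized): 1 chip read vs 2000 input reads
  chip <- c(reads_at(5100, width = 50), gbr_reads)
  input <- c(reads_at(rep(seq(5001, 5300, length.out = 40), 50), width = 50),
             gbr_reads)
  ttw <- traveling_ratio(gene, chip, input = input)
  expect_equal(ttw$tssr_signal, (1 / 350) / (2000 / 350 + 1e-9), tolerance = 1e-6)
  expect_lt(ttw$tssr_signal, 0.001)
  expect_equal(ttw$status, "filtered_weak")
  expect_true(is.na(ttw$tr))

  # gene shorter than TSSR+GBR
  short <- single_gene(width = 2000)
  expect_equal(traveling_ratio(short, tssr_reads)$status, "too_short")
})

test_that("minus-strand genes give the same TR as mirrored plus-strand genes", {
  plus <- single_gene(strand = "+")
  minus <- single_gene(strand = "-")   # TSS at 11000 (= end)
  # mirror reads: x -> (5001 + 11000) - x - 49 so intervals map onto each other
  set.seed(9)
  starts <- sample(5001:8300, 400, replace = TRUE)
  aln_p <- reads_at(starts, width = 50)
  aln_m <- reads_at(16001 - starts - 49, width = 50)
  tp <- traveling_ratio(plus, aln_p)
  tm <- traveling_ratio(minus, aln_m)
  expect_equal(tp$tssr_signal, tm$tssr_signal)
  expect_equal(tp$tr, tm$tr)
})

test_that("planted traveling ratios are recovered within 10% at depth 1e5", {
  gm <- generate_gene_models(40, 2e6, seed = 11)
  for (tr_true in c(0.5, 2)) {
    aln <- simulate_alignments(pausing_design(gm, true_tr = tr_true,
                                              depth = 1e5, seed = 13))
    tt <- traveling_ratio(gm, aln)
    expect_lt(abs(median(tt$tr[tt$status == "ok"]) / tr_true - 1), 0.10)
  }
})

test_that("metagene geometry: flat under uniform coverage, zero without reads", {
  gene <- single_gene(chrom_len = 20000L, start = 5001L, width = 6000L)
  prof <- metagene_profile(uniform_reads(), gene)
  expect_length(prof, 1000 + 3000 + 1500)
  total <- 20000
  expect_equal(as.numeric(prof), rep(1e9 / total, 5500), tolerance = 1e-9)

  # no coverage anywhere near the gene -> zero vector
  far <- reads_at(19500, width = 10)
  prof0 <- metagene_profile(far, gene)
  expect_equal(as.numeric(prof0), rep(0, 5500))
})

test_that("metagene body rescaling equals hand interpolation on a step function", {
  # gene body 1000 bp: first half coverage 2, second half 0 (plus strand)
  gene <- single_gene(start = 5001L, width = 1000L)
  body_cov <- reads_at(5001:5500, width = 1L)
  body_cov <- c(body_cov, body_cov)  # pileup 2 over [5001, 5500]
  prof <- metagene_profile(body_cov, gene,
                           metagene_config(upstream = 100, downstream_of_tes = 100,
                                           body_target = 200))
  scale <- 1e9 / length(body_cov)
  ref_body <- approx(1:1000, c(rep(2, 500), rep(0, 500)) * scale,
                     xout = seq(1, 1000, length.out = 200))$y
  expect_equal(as.numeric(prof[101:300]), ref_body, tolerance = 1e-9)
  expect_equal(as.numeric(prof[1:100]), rep(0, 100))   # upstream empty
})

test_that("window signals are strand-symmetric and depth-invariant under RPKM", {
  plus <- single_gene(strand = "+")
  minus <- single_gene(strand = "-")
  u <- uniform_reads()
  wp <- window_signal(u, plus, c(-500, 500))
  wm <- window_signal(u, minus, c(-500, 500))
  expect_equal(wp$signal, wm$signal)

  # doubling depth leaves RPKM unchanged
  w2 <- window_signal(c(u, u), plus, c(-500, 500))
  expect_equal(wp$signal, w2$signal)

  # hand count: reads fully inside [tss-500, tss+500) of the plus gene
  aln <- reads_at(c(4400, 4600, 5400, 5600), width = 50)
  w <- window_signal(aln, plus, c(-500, 500))
  # window [4501, 5500]; reads starting 4600, 5400 inside; 4400+49 < 4501 out; 5600 out
  expect_equal(w$signal, 2 * 1e9 / (1000 * 4))

  expect_error(window_signal(u, plus, c(100, 100)), "positive width")
})
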