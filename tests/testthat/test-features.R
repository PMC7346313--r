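test_that("pair counting applies the m + 3v threshold", {
  m <- insert_size_model(300, 30)  # threshold 390
  aln <- make_aln(c("a", "b", "c"), flag = 99L, pos = c(1000L, 1100L, 1200L),
                  cigar = "100M", mpos = c(1280L, 1500L, 1510L),
                  isize = c(380L, 500L, 410L))
  cp <- count_pairs(aln, "chr1", 1200L, m)
  expect_equal(unname(cp["concord"]), 1L)
  expect_equal(unname(cp["discord"]), 2L)
  # empty window
  cp0 <- count_pairs(aln, "chr1", 999999L, m)
  expect_equal(unname(cp0), c(0L, 0L))
  # inter-chromosomal mate counts as discordant
  aln$mrnm[1] <- "chr9"
  cp2 <- count_pairs(aln, "chr1", 1200L, m)
  expect_equal(unname(cp2["discord"]), 3L)
})

test_that("pair counts conserve: concord + discord = qualifying pairs", {
  s <- small_sim()
  m <- s$model
  for (brk in s$cands$brk1[seq_len(min(5, nrow(s$cands)))]) {
    cp <- count_pairs(s$aln, s$cfg$chrom, brk, m)
    a <- s$aln
    same <- !is.na(a$mrnm) & (a$mrnm == "=" | a$mrnm == a$chrom)
    leftmost <- ifelse(same & !is.na(a$mpos), pmin(a$pos, a$mpos), a$pos)
    qual <- a$mapped & a$is_primary & a$first_in_pair & a$mate_mapped &
      a$chrom == s$cfg$chrom & leftmost >= brk - m$range &
      leftmost <= brk + m$range
    expect_equal(unname(cp["concord"] + cp["discord"]), sum(qual))
  }
})

test_that("pileup depth walks CIGARs correctly", {
  a1 <- make_aln("r", 0L, 10L, "4M")
  expect_equal(pileup_depth(a1, "chr1", 10, 13), rep(1L, 4))
  a2 <- make_aln("r", 0L, 10L, "2M2D2M")
  expect_equal(pileup_depth(a2, "chr1", 10, 15), c(1L, 1L, 0L, 0L, 1L, 1L))
  expect_equal(pileup_depth(a2, "chr1", 100, 104), rep(0L, 5))
  # clips and insertions consume no reference
  a3 <- make_aln("r", 0L, 10L, "5S3M2I3M")
  expect_equal(pileup_depth(a3, "chr1", 10, 15), c(1L, 1L, 1L, 1L, 1L, 1L))
})

test_that("pileup matches the brute-force oracle on random fixtures", {
  set.seed(23)
  ops <- c("M", "D", "I", "S")
  for (fixture in 1:100) {
    n <- sample(1:12, 1)
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(1:4, 1)
      op <- c(sample(ops, k, TRUE), "M")  # ensure at least one match op
      len <- sample(1:15, k + 1L, TRUE)
      flag <- sample(c(0L, 16L, 2048L, 256L), 1)
      make_aln(paste0("r", i), flag, sample(1:80, 1),
               paste0(paste0(len, op), collapse = ""))
    })
    aln <- do.call(rbind, rows)
    start <- sample(1:60, 1); end <- start + sample(5:40, 1)
    expect_equal(pileup_depth(aln, "chr1", start, end),
                 oracle_pileup(aln, "chr1", start, end),
                 info = paste("fixture", fixture))
    expect_equal(pileup_depth(aln, "chr1", start, end, primary_only = FALSE),
                 oracle_pileup(aln, "chr1", start, end, primary_only = FALSE))
  }
})

test_that("region summaries are means with sane degenerate behavior", {
  expect_equal(region_depth(c(0, 0, 10, 10)), 5.0)
  expect_equal(region_depth(c(3, 3, 3)), 3.0)
  expect_error(region_depth(integer(0)), "empty")
  # without supplementary records cov and depth coincide
  a1 <- make_aln("r", 0L, 10L, "4M")
  expect_equal(region_cov(a1, "chr1", 10, 13),
               region_depth(pileup_depth(a1, "chr1", 10, 13)))
  # a supplementary covering 2 of 4 positions adds 0.5
  a2 <- rbind(a1, make_aln("s", 2048L, 10L, "2M"))
  expect_equal(region_cov(a2, "chr1", 10, 13), 1.5)
  expect_equal(region_depth(pileup_depth(a2, "chr1", 10, 13)), 1.0)
})

test_that("cov is never below depth over simulated windows", {
  s <- small_sim()
  for (i in seq_len(min(5, nrow(s$cands)))) {
    b <- s$cands$brk1[i]
    d <- region_depth(pileup_depth(s$aln, s$cfg$chrom, b, b + 200L))
    cv <- region_cov(s$aln, s$cfg$chrom, b, b + 200L)
    expect_gte(cv, d)
  }
})

test_that("simulated gene bodies sit near the configured coverage", {
  s <- small_sim()
  g <- s$ds$genes
  ex <- s$ds$exons
  big <- ex[ex$end - ex$start + 1L >= 500L, ][1:5, ]
  for (i in seq_len(nrow(big))) {
    d <- region_depth(pileup_depth(s$aln, s$cfg$chrom, big$start[i],
                                   big$end[i]))
    expect_lt(abs(d - s$cfg$linear_coverage), 0.5 * s$cfg$linear_coverage + 3)
  }
})

test_that("breakpoint windows truncate at the chromosome start", {
  m <- insert_size_model(100, 10)  # range 130
  aln <- make_aln("r", 0L, 1L, "500M")
  cand <- data.frame(chrom = "chr1", brk1 = 50L, brk2 = 449L)
  v <- depth_cov_features(aln, cand, m, chrom_len = 600L)
  # W = 130; upstream of brk1 truncated to [1, 49], all covered
  expect_equal(unname(v["depth_brk1_Up"]), 1)
  expect_equal(unname(v["depth_brk1_Down"]), 1)
})

test_that("split reads are assigned by boundary and pattern", {
  fx <- micro_fixture()
  aln <- read_alignments(fx$sam)
  cand <- data.frame(chrom = "chrT", brk1 = 201L, brk2 = 400L)
  sr <- split_read_features(aln, cand)
  expect_equal(unname(sr), c(3L, 0L, 0L, 0L, 3L, 0L))
  # an SMS read with match spanning from brk1 counts on the left
  aln2 <- rbind(aln, make_aln("X1", 0L, 201L, "20S60M20S", chrom = "chrT",
                              seq = strrep("A", 100)))
  sr2 <- split_read_features(aln2, cand)
  expect_equal(unname(sr2["SMS_l"]), 1L)
})

test_that("GT-AG detection honors strand arrangement and tolerance", {
  fa <- tempfile(fileext = ".fa")
  base <- strrep("T", 60)
  # plus arrangement: AG at 19-20, GT at 41-42 (circle [21, 40])
  s <- base
  substr(s, 19, 20) <- "AG"; substr(s, 41, 42) <- "GT"
  writeLines(c(">c", s), fa)
  cand <- data.frame(chrom = "c", brk1 = 21L, brk2 = 40L)
  expect_equal(gtag_signal(fa, cand, tol = 0L)$signal, 1L)
  expect_equal(gtag_signal(fa, cand, tol = 0L)$strand, "+")
  # no signal
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">c", base), fa2)
  expect_equal(gtag_signal(fa2, cand, tol = 0L)$signal, 0L)
  # displaced by 2 bp: found only with tolerance
  fa3 <- tempfile(fileext = ".fa")
  s3 <- base
  substr(s3, 17, 18) <- "AG"; substr(s3, 43, 44) <- "GT"
  writeLines(c(">c", s3), fa3)
  expect_equal(gtag_signal(fa3, cand, tol = 0L)$signal, 0L)
  expect_equal(gtag_signal(fa3, cand, tol = 2L)$signal, 1L)
  # reverse-complement arrangement AC ... CT
  fa4 <- tempfile(fileext = ".fa")
  s4 <- base
  substr(s4, 19, 20) <- "AC"; substr(s4, 41, 42) <- "CT"
  writeLines(c(">c", s4), fa4)
  g4 <- gtag_signal(fa4, cand, tol = 0L)
  expect_equal(g4$signal, 1L)
  expect_equal(g4$strand, "-")
  # out-of-range reference -> 0 with warning
  cand2 <- data.frame(chrom = "c", brk1 = 2L, brk2 = 40L)
  expect_warning(g5 <- gtag_signal(fa, cand2, tol = 2L), "out of range")
  expect_equal(g5$signal, 0L)
})

test_that("junction support features are count and mean quality", {
  cand <- data.frame(chrom = "c", brk1 = 10L, brk2 = 400L, source = "pss",
                     sup_l_mapq = I(list(c(60L, 20L, 10L))),
                     sup_r_mapq = I(list(integer(0))))
  bs <- bsj_support_features(cand[1, ])
  expect_equal(unname(bs["Support_l"]), 3)
  expect_equal(unname(bs["Mapping_Quality_l"]), 30)
  expect_equal(unname(bs["Support_r"]), 0)
  expect_equal(unname(bs["Mapping_Quality_r"]), 0)
})

test_that("imported candidates get support recomputed from clipped reads", {
  fx <- micro_fixture()
  aln <- read_alignments(fx$sam)
  cand <- data.frame(chrom = "chrT", brk1 = 201L, brk2 = 400L,
                     source = "imported:x",
                     sup_l_mapq = I(list(integer(0))),
                     sup_r_mapq = I(list(integer(0))))
  bs <- bsj_support_features(cand[1, ], aln)
  expect_equal(unname(bs["Support_l"]), 3)
  expect_equal(unname(bs["Mapping_Quality_l"]), mean(c(50, 60, 20)))
  expect_equal(unname(bs["Support_r"]), 3)
  expect_equal(unname(bs["Mapping_Quality_r"]), mean(c(60, 40, 60)))
})

test_that("the documented single-circle fixture yields the hand-computed
          23-feature vector, stable under row shuffling", {
  fx <- micro_fixture()
  aln <- read_alignments(fx$sam)
  m <- insert_size_model(150, 20)
  cands <- collect_candidates(aln, m)
  expect_equal(nrow(cands), 1L)
  v <- extract_features(cands[1, ], aln, fx$fa, m, chrom_len = 600L)
  expected <- c(
    concord_brk1 = 5, concord_brk2 = 4, discord_brk1 = 1, discord_brk2 = 0,
    depth_brk1_Up = 300 / 200, depth_brk1_Down = 710 / 200,
    depth_brk2_Up = 704 / 200, depth_brk2_Down = 76 / 200,
    cov_brk1_Up = 350 / 200, cov_brk1_Down = 830 / 200,
    cov_brk2_Up = 824 / 200, cov_brk2_Down = 76 / 200,
    SM_l = 3, MS_l = 0, SMS_l = 0, SM_r = 0, MS_r = 3, SMS_r = 0,
    GTAG = 1, Support_l = 3, Support_r = 3,
    Mapping_Quality_l = 130 / 3, Mapping_Quality_r = 160 / 3)
  expect_equal(v, expected[FEATURE_NAMES])
  # order independence
  set.seed(1)
  shuf <- aln[sample(nrow(aln)), ]
  v2 <- extract_features(cands[1, ], shuf, fx$fa, m, chrom_len = 600L)
  expect_identical(v, v2)
  # determinism across repeated calls
  v3 <- extract_features(cands[1, ], aln, fx$fa, m, chrom_len = 600L)
  expect_identical(v, v3)
})

test_that("a candidate with no overlapping reads has zero count features", {
  fx <- micro_fixture()
  aln <- read_alignments(fx$sam)
  m <- insert_size_model(150, 20)
  cand <- data.frame(chrom = "chrT", brk1 = 550L, brk2 = 590L,
                     source = "imported:x",
                     sup_l_mapq = I(list(integer(0))),
                     sup_r_mapq = I(list(integer(0))))
  far <- aln[aln$pos > 10000, ]
  v <- extract_features(cand[1, ], far, fx$fa, m, chrom_len = 600L)
  counts <- v[c("concord_brk1", "discord_brk1", "SM_l", "MS_r",
                "Support_l", "Support_r", "depth_brk1_Up")]
  expect_true(all(counts == 0))
  expect_true(v["GTAG"] %in% c(0, 1))
})

test_that("feature tables round-trip through the TSV format", {
  fx <- micro_fixture()
  aln <- read_alignments(fx$sam)
  m <- insert_size_model(150, 20)
  cands <- collect_candidates(aln, m)
  ft <- feature_table(cands, aln, fx$fa, m, labels = 1L, chrom_len = 600L)
  expect_equal(colnames(ft),
               c("id", "chrom", "brk1", "brk2", FEATURE_NAMES, "label"))
  p <- tempfile(fileext = ".tsv")
  write_feature_table(ft, p)
  back <- read_feature_table(p)
  expect_equal(back$brk1, ft$brk1)
  expect_equal(as.numeric(back$Mapping_Quality_l),
               ft$Mapping_Quality_l, tolerance = 1e-9)
})
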