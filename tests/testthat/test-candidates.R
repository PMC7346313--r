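test_that("local similarity is best gap-free overlap identity", {
  expect_equal(local_similarity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(local_similarity("AAAA", "TTTT"), 0.0)
  expect_equal(local_similarity("ACGTAC", "ACGTTC"), 5 / 6)
  expect_equal(local_similarity("CGT", "ACGTACGT"), 1.0)  # contained
  expect_error(local_similarity("", "ACGT"), "empty")
})

test_that("local similarity agrees with a brute-force oracle", {
  oracle <- function(a, b) {
    if (nchar(a) > nchar(b)) { t <- a; a <- b; b <- t }
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    best <- 0
    for (off in 0:(length(cb) - length(ca))) {
      best <- max(best, sum(ca == cb[seq_along(ca) + off]))
    }
    best / length(ca)
  }
  set.seed(11)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1), TRUE),
               collapse = "")
    expect_equal(local_similarity(a, b), oracle(a, b), info = paste(a, b))
    expect_equal(local_similarity(a, b), local_similarity(b, a))
  }
})

test_that("PSS scan recovers the documented junction and gates noise", {
  fx <- micro_fixture()
  aln <- read_alignments(fx$sam)
  m <- insert_size_model(150, 20)
  pairs <- scan_pss(aln, m)
  expect_true(all(pairs$brk1 == 201L & pairs$brk2 == 400L))
  expect_true(all(pairs$similarity == 1.0))
  # the random-clip supplementary record never enters a pair
  s1 <- which(aln$qname == "S1")
  expect_false(any(pairs$up %in% s1 | pairs$down %in% s1))
})

test_that("candidates require mates inside the circle", {
  fx <- micro_fixture()
  aln <- read_alignments(fx$sam)
  m <- insert_size_model(150, 20)
  pairs <- scan_pss(aln, m)
  cands <- pair_to_candidate(pairs, aln, m)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$brk1, 201L)
  expect_equal(cands$brk2, 400L)
  expect_equal(cands$support_l, 3L)
  expect_equal(cands$support_r, 3L)
  # push one junction read's mate far outside: its pairs disappear
  aln2 <- aln
  aln2$mpos[aln2$qname == "J3"] <- 10000L
  c2 <- pair_to_candidate(scan_pss(aln2, m), aln2, m)
  expect_equal(c2$support_l, 2L)
  # unmapped mate fails the rule
  aln3 <- aln
  j <- aln3$qname == "J3"
  aln3$mate_mapped[j] <- FALSE
  c3 <- pair_to_candidate(scan_pss(aln3, m), aln3, m)
  expect_equal(c3$support_l, 2L)
})

test_that("merging unions support and takes the weighted-mode breakpoint", {
  mk <- function(b1, b2, nsup, ids) {
    data.frame(chrom = "chr1", brk1 = b1, brk2 = b2, strand = ".",
               support_l = nsup, support_r = nsup, source = "pss",
               sup_l_mapq = I(list(rep(60L, nsup))),
               sup_r_mapq = I(list(rep(60L, nsup))),
               sup_l_id = I(list(ids)), sup_r_id = I(list(ids)),
               stringsAsFactors = FALSE)
  }
  # exact duplicates -> one candidate, support unioned by read identity
  x <- rbind(mk(1000L, 1499L, 2L, c("a", "b")),
             mk(1000L, 1499L, 2L, c("b", "c")))
  m1 <- merge_candidates(x, tol = 2L)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$support_l, 3L)
  # support-weighted mode
  y <- rbind(mk(1000L, 1499L, 3L, c("a", "b", "c")),
             mk(1001L, 1499L, 1L, "d"))
  m2 <- merge_candidates(y, tol = 2L)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$brk1, 1000L)
  expect_equal(m2$brk2, 1499L)
  # beyond tolerance -> kept apart
  z <- rbind(mk(1000L, 1499L, 1L, "a"), mk(1000L, 1600L, 1L, "b"))
  expect_equal(nrow(merge_candidates(z, tol = 2L)), 2L)
})

test_that("merging is idempotent on random candidate sets", {
  set.seed(5)
  mk1 <- function(b1, b2, id) {
    data.frame(chrom = "chr1", brk1 = b1, brk2 = b2, strand = ".",
               support_l = 1L, support_r = 1L, source = "pss",
               sup_l_mapq = I(list(60L)), sup_r_mapq = I(list(60L)),
               sup_l_id = I(list(id)), sup_r_id = I(list(id)),
               stringsAsFactors = FALSE)
  }
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    x <- do.call(rbind, lapply(seq_len(n), function(i)
      mk1(sample(1000:1020, 1), sample(2000:2020, 1), paste0("r", i))))
    m1 <- merge_candidates(x, tol = 2L)
    m2 <- merge_candidates(m1, tol = 2L)
    expect_equal(m2[, c("chrom", "brk1", "brk2", "support_l", "support_r")],
                 m1[, c("chrom", "brk1", "brk2", "support_l", "support_r")])
  }
})

test_that("candidate import converts coordinate dialects", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend", "chr1\t999\t1499"), tsv)
  c0 <- import_candidates(tsv, "bed0")
  expect_equal(c0$brk1, 1000L)
  expect_equal(c0$brk2, 1499L)
  expect_match(c0$source, "^imported:")
  writeLines(c("# header", "chr1\t1000\t1499\t+\t5"), tsv)
  c1 <- import_candidates(tsv, "onebased")
  expect_equal(c1$brk1, 1000L)
  expect_equal(c1$brk2, 1499L)
  expect_equal(c1$strand, "+")
  writeLines("#only a header", tsv)
  expect_equal(nrow(import_candidates(tsv, "bed0")), 0L)
  writeLines(c("chr1\t10\t20", "garbage line"), tsv)
  expect_warning(c2 <- import_candidates(tsv, "bed0"), "skipped")
  expect_equal(nrow(c2), 1L)
})

test_that("collected candidates are ordered breakpoints with support", {
  s <- small_sim()
  expect_true(all(s$cands$brk1 < s$cands$brk2))
  expect_true(all(s$cands$support_l >= 1L))
  expect_true(all(s$cands$support_r >= 1L))
})

test_that("most simulated circles are recovered near their breakpoints", {
  s <- small_sim()
  circ <- s$ds$circles
  hit <- vapply(seq_len(nrow(circ)), function(j) {
    any(abs(s$cands$brk1 - circ$brk1[j]) <= 2L &
          abs(s$cands$brk2 - circ$brk2[j]) <= 2L)
  }, TRUE)
  expect_gte(mean(hit), 0.7)
})
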