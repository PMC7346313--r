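# Shared fixtures: a small simulated dataset reused across test files
# (built once per test run), and paths to the documented single-circle
# micro fixture.

.sim_cache <- new.env(parent = emptyenv())

# ~300 kb genome, 60 genes, 12 circles: big enough for recovery and
# parameter statistics, small enough to build in a couple of seconds.
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(genome_length = 3e5, n_genes = 60, seed = 7)
    ds <- simulate_dataset(cfg, file.path(tempdir(), "circjudge_small_sim"))
    aln <- read_alignments(ds$sam)
    model <- estimate_insert_size(aln)
    cands <- collect_candidates(aln, model)
    .sim_cache$small <- list(cfg = cfg, ds = ds, aln = aln,
                             model = model, cands = cands)
  }
  .sim_cache$small
}

micro_fixture <- function() {
  list(fa = system.file("extdata", "microcircle.fa", package = "circjudge"),
       sam = system.file("extdata", "microcircle.sam", package = "circjudge"))
}

# Minimal alignment data frame with the columns the feature/counting
# code consumes, for constructing in-memory fixtures without SAM files.
make_aln <- function(qname, flag, pos, cigar, chrom = "chr1", mapq = 60L,
                     mrnm = "=", mpos = NA_integer_, isize = NA_integer_,
                     seq = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    qname = rep_len(qname, n), flag = rep_len(as.integer(flag), n),
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    mapq = rep_len(as.integer(mapq), n), cigar = rep_len(cigar, n),
    strand = ifelse(bitwAnd(rep_len(as.integer(flag), n), 16L) > 0L, "-", "+"),
    mrnm = rep_len(mrnm, n), mpos = rep_len(as.integer(mpos), n),
    isize = rep_len(as.integer(isize), n), seq = rep_len(seq, n),
    stringsAsFactors = FALSE)
  fl <- df$flag
  df$mapped <- bitwAnd(fl, 4L) == 0L
  df$is_primary <- bitwAnd(fl, 256L) == 0L & bitwAnd(fl, 2048L) == 0L
  df$supplementary <- bitwAnd(fl, 2048L) > 0L
  df$proper <- bitwAnd(fl, 2L) > 0L
  df$first_in_pair <- bitwAnd(fl, 64L) > 0L
  df$mate_mapped <- bitwAnd(fl, 1L) > 0L & bitwAnd(fl, 8L) == 0L
  df$mate_reverse <- bitwAnd(fl, 32L) > 0L
  df
}

# Independent per-base pileup oracle: walk every read's CIGAR and
# increment every covered position. Mirrors the documented depth
# semantics but shares no code with pileup_depth().
oracle_pileup <- function(aln, chrom, start, end, primary_only = TRUE) {
  d <- integer(end - start + 1L)
  for (i in seq_len(nrow(aln))) {
    if (!aln$mapped[i] || aln$chrom[i] != chrom) next
    if (bitwAnd(aln$flag[i], 256L) > 0L) next
    if (primary_only && bitwAnd(aln$flag[i], 2048L) > 0L) next
    ops <- regmatches(aln$cigar[i], gregexpr("[0-9]+[MIDNSHP=X]",
                                             aln$cigar[i]))[[1]]
    p <- aln$pos[i]
    for (o in ops) {
      len <- as.integer(sub("[MIDNSHP=X]", "", o))
      op <- sub("[0-9]+", "", o)
      if (op %in% c("M", "=", "X")) {
        for (q in p:(p + len - 1L)) {
          if (q >= start && q <= end) d[q - start + 1L] <- d[q - start + 1L] + 1L
        }
        p <- p + len
      } else if (op %in% c("D", "N")) {
        p <- p + len
      }
    }
  }
  d
}
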