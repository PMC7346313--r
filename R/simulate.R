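# Truth-labelled paired-end RNA-seq simulator: random genome, spliced
# linear and circular transcripts, analytic clipped alignments for reads
# crossing back-spliced junctions, and decoy artifacts that mimic the
# error sources producing false candidates. Alignments are emitted
# directly as SAM (no external aligner): the back-spliced junction
# geometry fully determines where each read segment maps and how it is
# clipped.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' benchmarks: a 1 Mb genome carrying 200 multi-exon genes of which 20%
#' also express a circRNA over a contiguous exon subset, 100 bp
#' paired-end reads, 10x coverage on circular and linear transcripts,
#' inserts N(300, 30^2), and a 1% per-base substitution error rate.
#'
#' @param genome_length Genome size in bp.
#' @param n_genes Number of non-overlapping genes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length Range of exon lengths (bp).
#' @param intron_length Range of intron lengths (bp).
#' @param circ_fraction Fraction of genes that also emit a circRNA.
#' @param gtag_fraction Fraction of circles with canonical AG|...|GT
#'   splice dinucleotides planted at the genomic boundaries.
#' @param read_length Read length in bp (60-150 in the benchmarks).
#' @param circ_coverage,linear_coverage Fold coverage of circular and
#'   linear transcripts.
#' @param insert_mean,insert_sd Mean and sd of the fragment (insert)
#'   size in bp.
#' @param error_rate Per-base substitution error probability.
#' @param decoy_rate Decoy artifact events per Mb at 10x linear
#'   coverage; the realized count scales with `linear_coverage/10`
#'   because mapping artifacts are produced by reads.
#' @param min_segment Shortest read segment emitted as its own (clipped)
#'   alignment record; shorter segments remain soft clips only,
#'   mirroring a local aligner's minimum seed length.
#' @param chrom Name of the single simulated chromosome.
#' @param seed Integer seed; the full output (SAM bytes, truth tables)
#'   is a pure function of the configuration including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, n_genes = 200,
                       exons_per_gene = c(2L, 4L),
                       exon_length = c(300L, 1200L),
                       intron_length = c(100L, 600L),
                       circ_fraction = 0.2, gtag_fraction = 0.9,
                       read_length = 100L,
                       circ_coverage = 10, linear_coverage = 10,
                       insert_mean = 300, insert_sd = 30,
                       error_rate = 0.01, decoy_rate = 60,
                       min_segment = 19L, chrom = "chrS", seed = 1L) {
  stopifnot(read_length < insert_mean,
            circ_coverage >= 0, linear_coverage >= 0,
            genome_length > 0, all(exon_length > 0),
            error_rate >= 0, error_rate < 1)
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              circ_fraction = circ_fraction,
              gtag_fraction = gtag_fraction,
              read_length = as.integer(read_length),
              circ_coverage = circ_coverage,
              linear_coverage = linear_coverage,
              insert_mean = insert_mean, insert_sd = insert_sd,
              error_rate = error_rate, decoy_rate = decoy_rate,
              min_segment = as.integer(min_segment),
              chrom = chrom, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Seed sub-streams: each generator stage uses its own derived seed so
# stages stay reproducible independently of each other.
derive_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 7919 + tag * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

#' Generate a random genome sequence
#'
#' I.i.d. uniform A/C/G/T sequence, deterministic for a given config
#' seed. If `path` is given the sequence is written as 60-column wrapped
#' FASTA and indexed.
#'
#' @param config A [sim_config()].
#' @param path Optional FASTA output path.
#' @return The genome as a single character string (invisibly the same
#'   string that was written).
#' @export
generate_genome <- function(config, path = NULL) {
  seq <- with_seed(derive_seed(config$seed, 1L), {
    paste(sample(BASES, config$genome_length, replace = TRUE),
          collapse = "")
  })
  if (!is.null(path)) write_genome_fasta(seq, config$chrom, path)
  seq
}

write_genome_fasta <- function(seq, chrom, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- chrom
  Biostrings::writeXStringSet(x, path, width = 60L)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Define gene models and circRNA selections on a genome
#'
#' Lays out non-overlapping multi-exon genes left to right, then picks
#' `circ_fraction` of them to additionally emit a circRNA spanning a
#' contiguous subset of the host gene's exons (so circle and host share
#' exons). For `gtag_fraction` of circles the canonical splice
#' dinucleotides are planted in the genome: AG immediately upstream of
#' the left breakpoint and GT immediately downstream of the right one.
#'
#' @param config A [sim_config()].
#' @param genome Genome string from [generate_genome()].
#' @return A list with elements `genome` (the genome string, with
#'   planted splice signals), `genes`, `exons` and `circles` data
#'   frames. Circle coordinates `brk1`/`brk2` are the genomic first and
#'   last bases of the circle (1-based, inclusive).
#' @export
define_transcriptome <- function(config, genome) {
  with_seed(derive_seed(config$seed, 2L), {
    glen <- config$genome_length
    n <- config$n_genes
    genes <- vector("list", n)
    exons <- vector("list", n)
    cursor <- 1L
    for (g in seq_len(n)) {
      gap <- sample(100:800, 1L)
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                       replace = TRUE)
      in_len <- if (n_ex > 1L)
        sample(config$intron_length[1]:config$intron_length[2], n_ex - 1L,
               replace = TRUE) else integer(0)
      span <- sum(ex_len) + sum(in_len)
      start <- cursor + gap
      if (start + span - 1L > glen - 10L) {
        stop(sprintf(
          "genome too small: placed %d of %d genes in %d bp", g - 1L, n,
          glen), call. = FALSE)
      }
      ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len - 1L
      genes[[g]] <- data.frame(gene_id = sprintf("G%03d", g),
                               start = start, end = start + span - 1L,
                               strand = "+", n_exons = n_ex,
                               stringsAsFactors = FALSE)
      exons[[g]] <- data.frame(gene_id = sprintf("G%03d", g),
                               exon = seq_len(n_ex),
                               start = as.integer(ex_start),
                               end = as.integer(ex_end),
                               stringsAsFactors = FALSE)
      cursor <- start + span - 1L
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)

    n_circ <- floor(config$circ_fraction * n)
    circ_genes <- if (n_circ > 0L) sort(sample(n, n_circ)) else integer(0)
    circles <- NULL
    if (n_circ > 0L) {
      rows <- lapply(seq_along(circ_genes), function(k) {
        g <- circ_genes[k]
        ex <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
        i <- sample(nrow(ex), 1L)
        j <- if (i < nrow(ex)) sample(i:nrow(ex), 1L) else i
        data.frame(circ_id = sprintf("C%03d", k),
                   gene_id = genes$gene_id[g],
                   chrom = config$chrom,
                   brk1 = ex$start[i], brk2 = ex$end[j],
                   exon_from = i, exon_to = j,
                   strand = "+",
                   length = sum(ex$end[i:j] - ex$start[i:j] + 1L),
                   gtag = FALSE, stringsAsFactors = FALSE)
      })
      circles <- do.call(rbind, rows)
      plant <- stats::runif(n_circ) < config$gtag_fraction
      circles$gtag <- plant
      for (k in which(plant)) {
        b1 <- circles$brk1[k]; b2 <- circles$brk2[k]
        if (b1 >= 3L && b2 + 2L <= config$genome_length) {
          substr(genome, b1 - 2L, b1 - 1L) <- "AG"
          substr(genome, b2 + 1L, b2 + 2L) <- "GT"
        } else circles$gtag[k] <- FALSE
      }
    } else {
      circles <- data.frame(circ_id = character(0), gene_id = character(0),
                            chrom = character(0), brk1 = integer(0),
                            brk2 = integer(0), exon_from = integer(0),
                            exon_to = integer(0), strand = character(0),
                            length = integer(0), gtag = logical(0),
                            stringsAsFactors = FALSE)
    }
    list(genome = genome, genes = genes, exons = exons, circles = circles)
  })
}

# ---- transcript -> genome segment mapping ---------------------------------

# Map a transcript-coordinate interval [a, a+len-1] onto genomic
# segments. `ts` are transcript-coordinate starts of the blocks, `gs`
# their genomic starts, `bl` their lengths; `L` the transcript length.
# For circular transcripts positions wrap modulo L. Returns a matrix
# with columns qstart, gstart, len (qstart relative to the interval).
map_tx_interval <- function(a, len, ts, gs, bl, L, circular) {
  out <- matrix(0L, nrow = 0L, ncol = 3L)
  done <- 0L
  while (done < len) {
    p <- a + done
    p0 <- if (circular) ((p - 1L) %% L) + 1L else p
    chunk <- min(len - done, L - p0 + 1L)
    # split this chunk at block boundaries
    e <- findInterval(p0, ts)
    while (chunk > 0L) {
      block_left <- ts[e] + bl[e] - p0
      take <- min(chunk, block_left)
      out <- rbind(out, c(done + 1L, gs[e] + (p0 - ts[e]), take))
      done <- done + take
      chunk <- chunk - take
      p0 <- p0 + take
      e <- e + 1L
    }
  }
  colnames(out) <- c("qstart", "gstart", "len")
  out
}

# Segments for many reads of one transcript. a: vector of interval
# starts (transcript coords, may exceed L for circular), rl: read
# length. Returns a list(read = idx, qstart, gstart, len) of parallel
# vectors.
tx_segments_batch <- function(a, rl, ts, gs, bl, L, circular) {
  n <- length(a)
  if (n == 0L) {
    return(list(read = integer(0), qstart = integer(0),
                gstart = integer(0), len = integer(0)))
  }
  a0 <- if (circular) ((a - 1L) %% L) + 1L else a
  no_wrap <- a0 + rl - 1L <= L
  e1 <- findInterval(a0, ts)
  e2 <- findInterval(pmin(a0 + rl - 1L, L), ts)
  simple <- no_wrap & e1 == e2
  read <- qstart <- gstart <- len <- vector("list", 1L + sum(!simple))
  idx_simple <- which(simple)
  read[[1]] <- idx_simple
  qstart[[1]] <- rep(1L, length(idx_simple))
  gstart[[1]] <- gs[e1[idx_simple]] + (a0[idx_simple] - ts[e1[idx_simple]])
  len[[1]] <- rep(rl, length(idx_simple))
  k <- 1L
  for (i in which(!simple)) {
    m <- map_tx_interval(a[i], rl, ts, gs, bl, L, circular)
    k <- k + 1L
    read[[k]] <- rep(i, nrow(m))
    qstart[[k]] <- m[, "qstart"]
    gstart[[k]] <- m[, "gstart"]
    len[[k]] <- m[, "len"]
  }
  list(read = unlist(read), qstart = as.integer(unlist(qstart)),
       gstart = as.integer(unlist(gstart)), len = as.integer(unlist(len)))
}

# ---- read simulation -------------------------------------------------------

#' Simulate paired-end reads as analytic alignments
#'
#' Draws fragments from every linear transcript (at `linear_coverage`)
#' and from the circularized sequence of every circle (at
#' `circ_coverage`, with wrap-around across the back-spliced junction).
#' The expected pair count per transcript is `L * coverage / (2 *
#' read_length)` (Poisson-realized). Reads crossing a splice or
#' back-spliced junction are emitted as soft-clipped alignments: the
#' longest segment is the primary record and other segments of at least
#' `min_segment` bp become supplementary records, which reproduces the
#' SM / MS / SMS CIGAR patterns at circle boundaries.
#'
#' @param config A [sim_config()].
#' @param txome Output of [define_transcriptome()].
#' @return A list with `records` (SAM-field data frame, unsorted) and
#'   `reads` (truth table: read name -> origin transcript).
#' @export
simulate_reads <- function(config, txome) {
  with_seed(derive_seed(config$seed, 3L), {
    rl <- config$read_length
    m <- config$insert_mean; v <- config$insert_sd
    units <- list()
    for (g in seq_len(nrow(txome$genes))) {
      gid <- txome$genes$gene_id[g]
      ex <- txome$exons[txome$exons$gene_id == gid, , drop = FALSE]
      units[[length(units) + 1L]] <- list(
        id = gid, circular = FALSE, coverage = config$linear_coverage,
        gstarts = ex$start, lens = ex$end - ex$start + 1L)
    }
    if (nrow(txome$circles) > 0L) {
      for (k in seq_len(nrow(txome$circles))) {
        ci <- txome$circles[k, ]
        ex <- txome$exons[txome$exons$gene_id == ci$gene_id, , drop = FALSE]
        ex <- ex[ci$exon_from:ci$exon_to, , drop = FALSE]
        units[[length(units) + 1L]] <- list(
          id = ci$circ_id, circular = TRUE, coverage = config$circ_coverage,
          gstarts = ex$start, lens = ex$end - ex$start + 1L)
      }
    }

    res <- lapply(units, function(u) {
      L <- sum(u$lens)
      if (L < rl || u$coverage <= 0) return(NULL)
      n <- stats::rpois(1L, L * u$coverage / (2 * rl))
      if (n == 0L) return(NULL)
      ts <- c(1L, cumsum(u$lens)[-length(u$lens)] + 1L)
      txseq <- paste(substring(txome$genome, u$gstarts,
                               u$gstarts + u$lens - 1L), collapse = "")
      maxfrag <- ceiling(m + 5 * v)
      frag <- pmax(round(stats::rnorm(n, m, v)), rl)
      frag <- pmin(frag, maxfrag)
      if (!u$circular) frag <- pmin(frag, L)
      s <- if (u$circular) floor(stats::runif(n) * L) + 1L
           else floor(stats::runif(n) * (L - frag + 1)) + 1L
      s <- as.integer(s); frag <- as.integer(frag)
      copies <- max(2L, ceiling((max(frag) + L) / L) + 1L)
      ext <- if (u$circular) strrep(txseq, copies) else txseq
      a1 <- s; a2 <- s + frag - rl
      seq1 <- substring(ext, a1, a1 + rl - 1L)
      seq2 <- substring(ext, a2, a2 + rl - 1L)
      seg1 <- tx_segments_batch(a1, rl, ts, u$gstarts, u$lens, L, u$circular)
      seg2 <- tx_segments_batch(a2, rl, ts, u$gstarts, u$lens, L, u$circular)
      qn <- sprintf("%s_%06d", u$id, seq_len(n))
      list(qname = qn, seq1 = seq1, seq2 = seq2, frag = frag,
           seg1 = seg1, seg2 = seg2, origin = rep(u$id, n))
    })
    res <- Filter(Negate(is.null), res)
    if (length(res) == 0L) {
      return(list(records = empty_records(), reads = data.frame(
        qname = character(0), origin = character(0))))
    }

    qname <- unlist(lapply(res, `[[`, "qname"))
    seq1 <- unlist(lapply(res, `[[`, "seq1"))
    seq2 <- unlist(lapply(res, `[[`, "seq2"))
    origin <- unlist(lapply(res, `[[`, "origin"))
    frag <- unlist(lapply(res, `[[`, "frag"))
    # concatenate the per-transcript segment tables, shifting read ids
    offs <- cumsum(c(0L, vapply(res, function(r) length(r$qname), 1L)))
    gather <- function(field) {
      list(read = unlist(lapply(seq_along(res), function(i)
             res[[i]][[field]]$read + offs[i])),
           qstart = unlist(lapply(res, function(r) r[[field]]$qstart)),
           gstart = unlist(lapply(res, function(r) r[[field]]$gstart)),
           len = unlist(lapply(res, function(r) r[[field]]$len)))
    }
    s1 <- gather("seg1"); s2 <- gather("seg2")

    seq1 <- add_errors(seq1, config$error_rate)
    seq2 <- add_errors(seq2, config$error_rate)

    rec1 <- emit_mate_records(qname, seq1, s1, rl, config, first = TRUE)
    rec2 <- emit_mate_records(qname, seq2, s2, rl, config, first = FALSE)
    records <- finalize_pairs(rec1, rec2, qname, frag, config)
    list(records = records,
         reads = data.frame(qname = qname, origin = origin,
                            stringsAsFactors = FALSE))
  })
}

# Per-base substitution errors, vectorized over a character vector of
# equal-length reads.
add_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  rl <- nchar(seqs[1])
  total <- length(seqs) * rl
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  at <- sample.int(total, n_err)
  ri <- ((at - 1L) %/% rl) + 1L
  pp <- ((at - 1L) %% rl) + 1L
  shift <- sample.int(3L, n_err, replace = TRUE)
  # repeated-substitution reads are handled in passes
  while (length(ri) > 0L) {
    firsts <- !duplicated(ri)
    i <- ri[firsts]; p <- pp[firsts]; sh <- shift[firsts]
    orig <- substr(substring(seqs[i], p, p), 1L, 1L)
    code <- (match(orig, BASES) - 1L + sh) %% 4L + 1L
    repl <- BASES[ifelse(is.na(code), 1L, code)]
    str <- seqs[i]
    substr(str, p, p) <- repl
    seqs[i] <- str
    ri <- ri[!firsts]; pp <- pp[!firsts]; shift <- shift[!firsts]
  }
  seqs
}

# Build alignment records for one mate of every pair: choose primary
# (longest) segment, keep supplementary segments >= min_segment, derive
# soft-clip CIGARs. Returns a data frame, one row per emitted record.
emit_mate_records <- function(qname, seqs, segs, rl, config, first) {
  ord <- order(segs$read, -segs$len, segs$qstart)
  read <- segs$read[ord]
  primary <- !duplicated(read)
  keep <- primary | segs$len[ord] >= config$min_segment
  read <- read[keep]
  qstart <- segs$qstart[ord][keep]
  gstart <- segs$gstart[ord][keep]
  len <- segs$len[ord][keep]
  primary <- primary[keep]
  lclip <- qstart - 1L
  rclip <- rl - (qstart + len - 1L)
  cigar <- paste0(ifelse(lclip > 0L, paste0(lclip, "S"), ""),
                  len, "M",
                  ifelse(rclip > 0L, paste0(rclip, "S"), ""))
  data.frame(read = read, qname = qname[read], pos = gstart,
             end = gstart + len - 1L, cigar = cigar, primary = primary,
             seq = seqs[read], first = first, stringsAsFactors = FALSE)
}

# Combine both mates' records: flags, mate position, TLEN, MAPQ.
finalize_pairs <- function(rec1, rec2, qname, frag, config) {
  n <- length(qname)
  p1 <- rec1[rec1$primary, ]; p1 <- p1[order(p1$read), ]
  p2 <- rec2[rec2$primary, ]; p2 <- p2[order(p2$read), ]
  stopifnot(nrow(p1) == n, nrow(p2) == n)
  left <- pmin(p1$pos, p2$pos)
  right <- pmax(p1$end, p2$end)
  span <- right - left + 1L
  nseg1 <- tabulate(rec1$read, n); nseg2 <- tabulate(rec2$read, n)
  # proper = contiguous fragment: both mates in one block and the
  # genomic span equals the fragment (no intron or wrap in between)
  proper <- nseg1 == 1L & nseg2 == 1L & span == frag
  build <- function(rec, mate_p, first) {
    # flags: paired; read1 forward/mate reverse, read2 reverse
    flag <- 1L + (if (first) 32L + 64L else 16L + 128L) +
      2L * proper[rec$read] + 2048L * (!rec$primary)
    tlen <- ifelse(p1$pos[rec$read] <= p2$pos[rec$read],
                   if (first) span[rec$read] else -span[rec$read],
                   if (first) -span[rec$read] else span[rec$read])
    data.frame(qname = rec$qname, flag = flag, pos = rec$pos,
               mapq = 60L, cigar = rec$cigar, mrnm = "=",
               mpos = mate_p[rec$read], isize = as.integer(tlen),
               seq = rec$seq, stringsAsFactors = FALSE)
  }
  out <- rbind(build(rec1, p2$pos, TRUE), build(rec2, p1$pos, FALSE))
  out$chrom <- config$chrom
  out
}

empty_records <- function() {
  data.frame(qname = character(0), flag = integer(0), pos = integer(0),
             mapq = integer(0), cigar = character(0), mrnm = character(0),
             mpos = integer(0), isize = integer(0), seq = character(0),
             chrom = character(0), stringsAsFactors = FALSE)
}

# ---- decoy artifacts -------------------------------------------------------

#' Inject decoy artifacts into a simulated read set
#'
#' Adds the alignment artifacts that produce false candidate circRNAs in
#' real data (ambiguous mapping, repeats, chimeric fragments), tagged as
#' decoys in the truth table. Three constructions are used:
#' (a) randomly clipped linear reads whose clip content is random
#' sequence, (b) copied-repeat read pairs that reproduce the
#' paired-similar-sequence geometry of a back-spliced junction at a
#' locus with no circle (clip content copied from the partner flank,
#' low mapping quality, mates placed inside the fake circle), and
#' (c) low-MAPQ chimeric pairs with grossly inflated template lengths.
#' Event counts scale with `decoy_rate` per Mb and with
#' `linear_coverage / 10`.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_reads()] (list with `records`,
#'   `reads`).
#' @param genome Genome string (post splice-signal planting).
#' @return `sim` with decoy records appended and decoy origins added to
#'   the truth table.
#' @export
inject_decoys <- function(config, sim, genome) {
  if (config$decoy_rate <= 0) return(sim)
  with_seed(derive_seed(config$seed, 4L), {
    rl <- config$read_length
    glen <- config$genome_length
    scale <- (config$genome_length / 1e6) *
      max(config$linear_coverage, 1) / 10
    n_b <- stats::rpois(1L, 0.5 * config$decoy_rate * scale)
    n_a <- stats::rpois(1L, 0.3 * config$decoy_rate * scale)
    n_c <- stats::rpois(1L, 0.2 * config$decoy_rate * scale)
    recs <- list(); truth <- list()
    add <- function(rec, origin) {
      recs[[length(recs) + 1L]] <<- rec
      truth[[length(truth) + 1L]] <<- origin
    }
    refseq <- function(s, e) substr(genome, s, e)
    rand_seq <- function(n) paste(sample(BASES, n, TRUE), collapse = "")

    # (b) PSS-mimicking repeat pairs: SM record at b1 with clip copied
    # from the b2 flank, MS record at b2 with clip copied from the b1
    # flank, mates placed inside [b1, b2]; low MAPQ throughout.
    for (i in seq_len(n_b)) {
      span <- sample(250:2500, 1L)
      b1 <- sample.int(glen - span - 2L * rl - 10L, 1L) + rl
      b2 <- b1 + span - 1L
      id <- sprintf("DB%04d", i)
      k <- sample(1:2, 1L)
      for (j in seq_len(k)) {
        x <- sample(20:min(60L, rl - 25L), 1L)
        mq <- sample(0:25, 1L)
        up_seq <- paste0(refseq(b2 - x + 1L, b2),
                         refseq(b1, b1 + (rl - x) - 1L))
        mp_up <- b1 + sample.int(max(span - rl, 1L), 1L) - 1L
        qup <- sprintf("%s_u%d", id, j)
        add(data.frame(
          qname = c(qup, qup),
          flag = c(97L, 145L),
          pos = c(b1, mp_up), mapq = c(mq, sample(10:40, 1L)),
          cigar = c(paste0(x, "S", rl - x, "M"), paste0(rl, "M")),
          mrnm = "=", mpos = c(mp_up, b1),
          isize = c(mp_up + rl - b1, -(mp_up + rl - b1)),
          seq = c(up_seq, refseq(mp_up, mp_up + rl - 1L)),
          chrom = config$chrom, stringsAsFactors = FALSE), id)
        z <- sample(20:min(60L, rl - 25L), 1L)
        dn_pos <- b2 - (rl - z) + 1L
        dn_seq <- paste0(refseq(dn_pos, b2), refseq(b1, b1 + z - 1L))
        mp_dn <- b1 + sample.int(max(span - rl, 1L), 1L) - 1L
        qdn <- sprintf("%s_d%d", id, j)
        add(data.frame(
          qname = c(qdn, qdn),
          flag = c(97L, 145L),
          pos = c(dn_pos, mp_dn), mapq = c(sample(0:25, 1L), sample(10:40, 1L)),
          cigar = c(paste0(rl - z, "M", z, "S"), paste0(rl, "M")),
          mrnm = "=", mpos = c(mp_dn, dn_pos),
          isize = c(-(b2 - mp_dn + 1L), b2 - mp_dn + 1L),
          seq = c(dn_seq, refseq(mp_dn, mp_dn + rl - 1L)),
          chrom = config$chrom, stringsAsFactors = FALSE), id)
      }
    }

    # (a) randomly clipped reads: clip content is random sequence, so
    # the pair-similarity gate should reject them.
    for (i in seq_len(n_a)) {
      id <- sprintf("DA%04d", i)
      x <- sample(20:min(60L, rl - 25L), 1L)
      p <- sample.int(glen - 2L * rl - 400L, 1L) + rl
      left <- sample(c(TRUE, FALSE), 1L)
      cig <- if (left) paste0(x, "S", rl - x, "M")
             else paste0(rl - x, "M", x, "S")
      body <- if (left) refseq(p, p + (rl - x) - 1L)
              else refseq(p, p + (rl - x) - 1L)
      sq <- if (left) paste0(rand_seq(x), body) else paste0(body, rand_seq(x))
      mp <- p + sample(150:350, 1L)
      add(data.frame(
        qname = c(id, id), flag = c(97L, 145L),
        pos = c(p, mp), mapq = c(sample(20:60, 1L), 60L),
        cigar = c(cig, paste0(rl, "M")),
        mrnm = "=", mpos = c(mp, p),
        isize = c(mp + rl - p, -(mp + rl - p)),
        seq = c(sq, refseq(mp, mp + rl - 1L)),
        chrom = config$chrom, stringsAsFactors = FALSE), id)
    }

    # (c) chimeric pairs: mates far apart, low MAPQ.
    for (i in seq_len(n_c)) {
      id <- sprintf("DC%04d", i)
      p <- sample.int(glen - 2L * rl - 10L, 1L)
      mp <- sample.int(glen - rl - 1L, 1L)
      tl <- max(p, mp) + rl - min(p, mp)
      add(data.frame(
        qname = c(id, id), flag = c(65L, 129L),
        pos = c(p, mp), mapq = c(sample(0:10, 1L), sample(0:10, 1L)),
        cigar = paste0(rl, "M"),
        mrnm = "=", mpos = c(mp, p),
        isize = c(ifelse(p <= mp, tl, -tl), ifelse(p <= mp, -tl, tl)),
        seq = c(refseq(p, p + rl - 1L), refseq(mp, mp + rl - 1L)),
        chrom = config$chrom, stringsAsFactors = FALSE), id)
    }

    if (length(recs) > 0L) {
      sim$records <- rbind(sim$records, do.call(rbind, recs))
      dq <- do.call(rbind, lapply(seq_along(recs), function(i)
        data.frame(qname = unique(recs[[i]]$qname),
                   origin = paste0("decoy:", truth[[i]]),
                   stringsAsFactors = FALSE)))
      sim$reads <- rbind(sim$reads, dq[!duplicated(dq$qname), ])
    }
    sim
  })
}

# ---- SAM output ------------------------------------------------------------

#' Write simulated records as a coordinate-sorted SAM file
#'
#' @param records Record data frame (as produced by [simulate_reads()]).
#' @param chrom Chromosome name for the `@SQ` header.
#' @param chrom_len Chromosome length.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, chrom, chrom_len, path) {
  ord <- order(records$pos, records$qname, records$flag)
  r <- records[ord, , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_len)),
              "@PG\tID:circjudge\tPN:circjudge")
  qual <- strrep("I", nchar(r$seq))
  lines <- paste(r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
                 r$mrnm, r$mpos, r$isize, r$seq, qual, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

# ---- dataset orchestration -------------------------------------------------

#' Simulate a complete truth-labelled dataset
#'
#' Runs genome generation, transcriptome definition, read simulation and
#' decoy injection, and writes the outputs to `dir`: `genome.fa` (+
#' `.fai`), `reads.sam` (coordinate-sorted), `truth_circles.tsv`,
#' `truth_reads.tsv` and a `config.json` echo for reproducibility.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list with the paths (`fasta`, `sam`, `circles_tsv`,
#'   `reads_tsv`), the in-memory `records`, `circles` and `reads`
#'   tables, and the `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("sim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  txome <- define_transcriptome(config, genome)
  sim <- simulate_reads(config, txome)
  sim <- inject_decoys(config, sim, txome$genome)
  fasta <- file.path(dir, "genome.fa")
  write_genome_fasta(txome$genome, config$chrom, fasta)
  sam <- file.path(dir, "reads.sam")
  write_sam(sim$records, config$chrom, config$genome_length, sam)
  circles_tsv <- file.path(dir, "truth_circles.tsv")
  utils::write.table(txome$circles, circles_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reads_tsv <- file.path(dir, "truth_reads.tsv")
  utils::write.table(sim$reads, reads_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  list(fasta = fasta, sam = sam, circles_tsv = circles_tsv,
       reads_tsv = reads_tsv, records = sim$records,
       circles = txome$circles, reads = sim$reads,
       genes = txome$genes, exons = txome$exons, config = config,
       dir = dir)
}

#' Label candidates against simulation truth
#'
#' A candidate is labelled 1 when a true circle on the same chromosome
#' has both breakpoints within `tol` bp of the candidate's; otherwise 0.
#'
#' @param cands Candidate data frame (`chrom`, `brk1`, `brk2`).
#' @param circles Truth circle table (from [simulate_dataset()]).
#' @param tol Breakpoint tolerance in bp.
#' @return Integer vector of 0/1 labels, one per candidate.
#' @export
label_candidates <- function(cands, circles, tol = 2L) {
  if (nrow(cands) == 0L) return(integer(0))
  vapply(seq_len(nrow(cands)), function(i) {
    hit <- circles$chrom == cands$chrom[i] &
      abs(circles$brk1 - cands$brk1[i]) <= tol &
      abs(circles$brk2 - cands$brk2[i]) <= tol
    as.integer(any(hit))
  }, 1L)
}
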