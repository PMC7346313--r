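# Candidate circRNA detection from paired-similar-sequence (PSS)
# signals: an upstream clip-then-match (SM) read whose match starts at
# the putative left breakpoint, a downstream match-then-clip (MS) read
# whose match ends at the putative right breakpoint, and clipped
# portions that are locally similar to the partner read's matched flank
# — the alignment fingerprint of a back-spliced junction.

#' Gap-free local similarity of two sequences
#'
#' Identity of the best gap-free placement of the shorter sequence
#' within the longer, as a fraction of the shorter length. Symmetric in
#' its arguments; 1.0 means the shorter is an exact substring of the
#' longer.
#'
#' @param a,b Non-empty character strings (same alphabet).
#' @return A fraction in `[0, 1]`.
#' @examples
#' local_similarity("ACGTAC", "ACGTTC")  # 5/6
#' @export
local_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("local_similarity: empty input", call. = FALSE)
  }
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  if (length(ai) > length(bi)) { tmp <- ai; ai <- bi; bi <- tmp }
  ns <- length(ai); nl <- length(bi)
  best <- 0L
  for (off in 0:(nl - ns)) {
    hits <- sum(ai == bi[(off + 1L):(off + ns)])
    if (hits > best) best <- hits
    if (best == ns) break
  }
  best / ns
}

#' Scan alignments for paired-similar-sequence junction signals
#'
#' Pairs every upstream SM/SMS record (match starting at a putative
#' left breakpoint `brk1`) with every downstream MS/SMS record (match
#' ending at a putative right breakpoint `brk2 > brk1`) on the same
#' chromosome, and keeps pairs whose clipped portions are locally
#' similar to the partner's matched flank: the upstream clip must match
#' the suffix of the downstream read's aligned block (the sequence just
#' inside `brk2`) and vice versa. Records lacking a stored sequence
#' (hard-clipped) cannot be compared and are skipped.
#'
#' @param aln Alignment data frame from [read_alignments()].
#' @param model An [insert_size_model()] (reserved for geometry checks
#'   in [pair_to_candidate()]; the scan itself only needs clip
#'   geometry).
#' @param min_clip Minimum clip length treated as breakpoint evidence.
#' @param sim_threshold Minimum similarity for a PSS pair (default
#'   0.90, tolerating roughly one sequencing error per 10 bp).
#' @param min_span,max_span Allowed `brk2 - brk1 + 1` span range.
#' @return A data frame of read-level PSS pairs: `chrom`, `brk1`,
#'   `brk2`, `up` and `down` (row indices into `aln`), `similarity`.
#' @export
scan_pss <- function(aln, model, min_clip = 19L, sim_threshold = 0.90,
                     min_span = 100L, max_span = 50000L) {
  aln <- annotate_patterns(aln, min_clip = min_clip)
  ok <- aln$mapped & aln$pattern != "OTHER"
  up <- which(ok & aln$pattern %in% c("SM", "SMS") & aln$soft_left >= min_clip &
                !is.na(aln$seq))
  dn <- which(ok & aln$pattern %in% c("MS", "SMS") & aln$soft_right >= min_clip &
                !is.na(aln$seq))
  empty <- data.frame(chrom = character(0), brk1 = integer(0),
                      brk2 = integer(0), up = integer(0), down = integer(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (length(up) == 0L || length(dn) == 0L) return(empty)

  # exact k-mer seeds for a cheap position-pair gate: for a genuine
  # back-spliced junction the upstream read's clip and the downstream
  # read's aligned block both end at brk2, and the downstream clip and
  # upstream block both start at brk1, so their terminal k-mers agree
  # (up to sequencing error; the gate only needs one error-free seed
  # among the supporting reads).
  k <- 10L
  u_clip_end <- substr(aln$seq[up], aln$soft_left[up] - k + 1L,
                       aln$soft_left[up])
  u_block_start <- substr(aln$seq[up], aln$soft_left[up] + 1L,
                          aln$soft_left[up] + k)
  d_block_end <- substr(aln$seq[dn], aln$soft_left[dn] + aln$q_span[dn] - k + 1L,
                        aln$soft_left[dn] + aln$q_span[dn])
  d_clip_start <- substr(aln$seq[dn], aln$soft_left[dn] + aln$q_span[dn] + 1L,
                         aln$soft_left[dn] + aln$q_span[dn] + k)

  up_key <- paste(aln$chrom[up], aln$match_start[up])
  dn_key <- paste(aln$chrom[dn], aln$match_end[dn])
  up_pos <- split(seq_along(up), up_key)
  dn_pos <- split(seq_along(dn), dn_key)
  pos_tab <- function(keys) {
    data.frame(key = keys, chrom = sub(" .*", "", keys),
               pos = as.integer(sub(".* ", "", keys)),
               stringsAsFactors = FALSE)
  }
  up_tab <- pos_tab(names(up_pos))
  dn_tab <- pos_tab(names(dn_pos))

  out <- list()
  for (ci in unique(up_tab$chrom)) {
    u <- up_tab[up_tab$chrom == ci, , drop = FALSE]
    d <- dn_tab[dn_tab$chrom == ci, , drop = FALSE]
    if (nrow(d) == 0L) next
    for (iu in seq_len(nrow(u))) {
      b1 <- u$pos[iu]
      sel_d <- which(d$pos >= b1 + min_span - 1L & d$pos <= b1 + max_span - 1L)
      if (length(sel_d) == 0L) next
      ui_loc <- up_pos[[u$key[iu]]]
      for (id in sel_d) {
        b2 <- d$pos[id]
        di_loc <- dn_pos[[d$key[id]]]
        gate <- any(u_clip_end[ui_loc] %in% d_block_end[di_loc]) ||
          any(d_clip_start[di_loc] %in% u_block_start[ui_loc])
        if (!gate) next
        for (ui in ui_loc) {
          for (di in di_loc) {
            s <- pss_similarity(aln, up[ui], dn[di])
            if (!is.na(s) && s >= sim_threshold) {
              out[[length(out) + 1L]] <- c(up[ui], dn[di], b1, b2, s)
            }
          }
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  data.frame(chrom = aln$chrom[m[, 1]], brk1 = as.integer(m[, 3]),
             brk2 = as.integer(m[, 4]), up = as.integer(m[, 1]),
             down = as.integer(m[, 2]), similarity = m[, 5],
             stringsAsFactors = FALSE)
}

# Similarity of one up/down record pair: compare the up read's left
# clip with the suffix of the down read's aligned block, and the down
# read's right clip with the prefix of the up read's aligned block.
# Returns the minimum of the comparable directions (NA if neither can
# be compared over at least min_overlap bases).
pss_similarity <- function(aln, ui, di, min_overlap = 10L) {
  sims <- c()
  u_seq <- aln$seq[ui]; d_seq <- aln$seq[di]
  u_clip <- aln$soft_left[ui]; d_clip <- aln$soft_right[di]
  u_m <- aln$q_span[ui]; d_m <- aln$q_span[di]
  if (!is.na(u_seq) && !is.na(d_seq)) {
    k <- min(u_clip, d_m)
    if (k >= min_overlap) {
      a <- substr(u_seq, u_clip - k + 1L, u_clip)
      b <- substr(d_seq, aln$soft_left[di] + d_m - k + 1L,
                  aln$soft_left[di] + d_m)
      sims <- c(sims, local_similarity(a, b))
    }
    k2 <- min(d_clip, u_m)
    if (k2 >= min_overlap) {
      a <- substr(d_seq, aln$soft_left[di] + d_m + 1L,
                  aln$soft_left[di] + d_m + k2)
      b <- substr(u_seq, u_clip + 1L, u_clip + k2)
      sims <- c(sims, local_similarity(a, b))
    }
  }
  if (length(sims) == 0L) return(NA_real_)
  min(sims)
}

#' Turn PSS pairs into candidate circRNAs
#'
#' A pair is promoted to a candidate `[brk1, brk2]` only when (a) the
#' two records' strands agree, (b) each junction read's mate maps to
#' the same chromosome within `[brk1, brk2]` (all reads of a circular
#' fragment stay inside the circle), and (c) the implied span is at
#' least `min_span` and at most `max_span` bp. Qualifying pairs are
#' grouped by breakpoint pair into candidates with per-side support
#' sets.
#'
#' @param pairs Output of [scan_pss()].
#' @param aln The alignment data frame the pair indices refer to.
#' @param model An [insert_size_model()] (span sanity bound).
#' @param min_span,max_span Allowed circle length range.
#' @return A candidate data frame: `chrom`, `brk1`, `brk2`, `strand`,
#'   `support_l`, `support_r`, `source`, plus list columns
#'   `sup_l_mapq`, `sup_r_mapq`, `sup_l_id`, `sup_r_id`.
#' @export
pair_to_candidate <- function(pairs, aln, model, min_span = 100L,
                              max_span = 50000L) {
  if (nrow(pairs) == 0L) return(empty_candidates())
  ok <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$up[i]; d <- pairs$down[i]
    b1 <- pairs$brk1[i]; b2 <- pairs$brk2[i]
    span <- b2 - b1 + 1L
    if (span < min_span || span > max_span) next
    if (aln$strand[u] != aln$strand[d]) next
    mate_in <- function(r) {
      !is.na(aln$mpos[r]) && aln$mate_mapped[r] &&
        (is.na(aln$mrnm[r]) || aln$mrnm[r] %in% c("=", aln$chrom[r])) &&
        aln$mpos[r] >= b1 && aln$mpos[r] <= b2
    }
    ok[i] <- mate_in(u) && mate_in(d)
  }
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_candidates())
  key <- paste(pairs$chrom, pairs$brk1, pairs$brk2)
  rows <- lapply(split(seq_len(nrow(pairs)), key), function(ii) {
    ups <- unique(pairs$up[ii]); dns <- unique(pairs$down[ii])
    data.frame(chrom = pairs$chrom[ii[1]],
               brk1 = pairs$brk1[ii[1]], brk2 = pairs$brk2[ii[1]],
               strand = ".",
               support_l = length(ups), support_r = length(dns),
               source = "pss",
               sup_l_mapq = I(list(aln$mapq[ups])),
               sup_r_mapq = I(list(aln$mapq[dns])),
               sup_l_id = I(list(paste0(aln$qname[ups], "/", aln$pos[ups]))),
               sup_r_id = I(list(paste0(aln$qname[dns], "/", aln$pos[dns]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$brk1, out$brk2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(chrom = character(0), brk1 = integer(0), brk2 = integer(0),
             strand = character(0), support_l = integer(0),
             support_r = integer(0), source = character(0),
             sup_l_mapq = I(list()), sup_r_mapq = I(list()),
             sup_l_id = I(list()), sup_r_id = I(list()),
             stringsAsFactors = FALSE)
}

#' Merge near-duplicate candidates
#'
#' Candidates on the same chromosome whose left and right breakpoints
#' each differ by at most `tol` bp are merged (single-linkage
#' components). The merged breakpoints are the support-weighted modes
#' of the member breakpoints (ties broken towards the smaller
#' coordinate) and support sets are unioned with read-identity
#' de-duplication. Idempotent: merging a merged set changes nothing.
#'
#' @param cands Candidate data frame.
#' @param tol Breakpoint tolerance in bp.
#' @return Merged candidate data frame sorted by (chrom, brk1, brk2).
#' @export
merge_candidates <- function(cands, tol = 2L) {
  if (nrow(cands) <= 1L) return(cands)
  out <- list()
  for (ci in unique(cands$chrom)) {
    x <- cands[cands$chrom == ci, , drop = FALSE]
    n <- nrow(x)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (abs(x$brk1[i] - x$brk1[j]) <= tol &&
          abs(x$brk2[i] - x$brk2[j]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    comp <- vapply(seq_len(n), find, 1L)
    for (cc in unique(comp)) {
      ii <- which(comp == cc)
      w <- x$support_l[ii] + x$support_r[ii]
      out[[length(out) + 1L]] <- merge_group(x[ii, , drop = FALSE], w)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$brk1, res$brk2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

weighted_mode <- function(vals, w) {
  agg <- tapply(w, vals, sum)
  best <- names(agg)[agg == max(agg)]
  as.integer(min(as.integer(best)))
}

merge_group <- function(x, w) {
  if (nrow(x) == 1L) return(x)
  union_side <- function(ids, mapqs) {
    id <- unlist(ids); mq <- unlist(mapqs)
    keep <- !duplicated(id)
    list(id = id[keep], mapq = mq[keep])
  }
  l <- union_side(x$sup_l_id, x$sup_l_mapq)
  r <- union_side(x$sup_r_id, x$sup_r_mapq)
  strand <- setdiff(unique(x$strand), ".")
  data.frame(chrom = x$chrom[1],
             brk1 = weighted_mode(x$brk1, pmax(w, 1L)),
             brk2 = weighted_mode(x$brk2, pmax(w, 1L)),
             strand = if (length(strand) == 1L) strand else ".",
             support_l = length(l$id), support_r = length(r$id),
             source = paste(sort(unique(x$source)), collapse = "+"),
             sup_l_mapq = I(list(l$mapq)), sup_r_mapq = I(list(r$mapq)),
             sup_l_id = I(list(l$id)), sup_r_id = I(list(r$id)),
             stringsAsFactors = FALSE)
}

#' Collect candidate circRNAs from alignments
#'
#' Convenience wrapper: [scan_pss()] then [pair_to_candidate()] then
#' [merge_candidates()].
#'
#' @inheritParams scan_pss
#' @inheritParams merge_candidates
#' @param min_span,max_span Allowed circle length range in bp.
#' @return Candidate data frame (see [pair_to_candidate()]).
#' @export
collect_candidates <- function(aln, model, min_clip = 19L,
                               sim_threshold = 0.90, min_span = 100L,
                               max_span = 50000L, tol = 2L) {
  pairs <- scan_pss(aln, model, min_clip = min_clip,
                    sim_threshold = sim_threshold,
                    min_span = min_span, max_span = max_span)
  cands <- pair_to_candidate(pairs, aln, model, min_span = min_span,
                             max_span = max_span)
  merge_candidates(cands, tol = tol)
}

#' Import candidates from an external detector's table
#'
#' Reads a BED-like TSV with at least chrom/start/end columns.
#' `dialect = "bed0"` converts 0-based half-open coordinates
#' (`brk1 = start + 1`, `brk2 = end`); `dialect = "onebased"` takes the
#' columns as 1-based inclusive breakpoints. Lines starting with `#`
#' are ignored; unparsable lines are skipped with a warning.
#'
#' @param path TSV path.
#' @param dialect `"bed0"` or `"onebased"`.
#' @param source Label recorded in the `source` column
#'   (`"imported:<source>"`).
#' @return Candidate data frame with empty support sets.
#' @export
import_candidates <- function(path, dialect = c("bed0", "onebased"),
                              source = "external") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_candidates())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) {
    length(p) >= 3L && !is.na(suppressWarnings(as.integer(p[2]))) &&
      !is.na(suppressWarnings(as.integer(p[3])))
  }, TRUE)
  if (any(!keep)) {
    warning(sum(!keep), " unparsable candidate line(s) skipped")
  }
  parts <- parts[keep]
  if (length(parts) == 0L) return(empty_candidates())
  chrom <- vapply(parts, `[`, "", 1L)
  start <- as.integer(vapply(parts, `[`, "", 2L))
  end <- as.integer(vapply(parts, `[`, "", 3L))
  strand <- vapply(parts, function(p)
    if (length(p) >= 4L && p[4] %in% c("+", "-")) p[4] else ".", "")
  brk1 <- if (dialect == "bed0") start + 1L else start
  brk2 <- end
  n <- length(chrom)
  data.frame(chrom = chrom, brk1 = brk1, brk2 = brk2, strand = strand,
             support_l = 0L, support_r = 0L,
             source = paste0("imported:", source),
             sup_l_mapq = I(rep(list(integer(0)), n)),
             sup_r_mapq = I(rep(list(integer(0)), n)),
             sup_l_id = I(rep(list(character(0)), n)),
             sup_r_id = I(rep(list(character(0)), n)),
             stringsAsFactors = FALSE)
}

#' Write candidates to the package's TSV format
#'
#' Columns: chrom, brk1, brk2, strand, support_l, support_r, source
#' (1-based inclusive coordinates, `#`-prefixed header).
#'
#' @param cands Candidate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(cands, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#chrom\tbrk1\tbrk2\tstrand\tsupport_l\tsupport_r",
                    "\tsource"), con)
  if (nrow(cands) > 0L) {
    writeLines(paste(cands$chrom, cands$brk1, cands$brk2, cands$strand,
                     cands$support_l, cands$support_r, cands$source,
                     sep = "\t"), con)
  }
  invisible(path)
}
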