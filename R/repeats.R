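# repeat-pair (HSP) discovery within a genome, and ingestion of
# precomputed BLAST outfmt-6 tables
#
# find_repeats() is a self-contained seed-and-extend local aligner with
# Karlin-Altschul E-values. It mimics default blastn-style scoring
# (+1/-2, gap open 5, gap extend 2) but exact parity with NCBI BLAST is
# not promised; analyses that must reproduce a published BLAST table
# bit-for-bit should ingest the real output via parse_hsp_table().

#' Find repeat pairs (HSPs) within a genome
#'
#' Aligns the genome against itself (all chromosome pairs including self,
#' both strands) by exact-seed ungapped extension followed by banded gapped
#' refinement. Chromosomes are treated as circular: each sequence is
#' scanned doubled and hits are de-duplicated modulo the chromosome
#' length, so repeats spanning the origin are found. Trivial self-hits and
#' mirror duplicates (A-B vs B-A) are removed; HSPs contained in a longer
#' overlapping HSP are dropped.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector
#' @param min_word exact seed length
#' @param evalue_cutoff maximum Karlin-Altschul E-value (database size =
#'   total genome length)
#' @param min_length minimum alignment length to report
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   as positive numbers)
#' @param xdrop ungapped extension X-drop
#' @param min_ungapped minimum ungapped seed-extension score kept for
#'   gapped refinement
#' @param top_k keep at most this many repeat pairs (best E-value first)
#' @return a tibble with one row per repeat pair: `repeat_id`, `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`, `orientation`
#'   (direct/inverted), `identity`, `aln_length`, `mismatches`,
#'   `gap_opens`, `score`, `evalue`, `inter_molecular`. Coordinates are
#'   1-based inclusive on the plus strand; an interval with `end < start`
#'   wraps through the origin.
#' @export
find_repeats <- function(genome, min_word = 7, evalue_cutoff = 1e-6,
                         min_length = 50, match = 1, mismatch = 2,
                         gap_open = 5, gap_extend = 2, xdrop = 20,
                         min_ungapped = 18, top_k = Inf) {
  genome <- as_genome(genome)
  if (length(genome) == 0) abort("genome is empty")
  min_word <- check_count(min_word, "min_word")
  if (min_word > 12) abort("`min_word` must be <= 12")
  ids <- names(genome)
  lens <- chromosome_lengths(genome)
  total_len <- sum(as.numeric(lens))
  lambda <- karlin_lambda(match, mismatch)
  K <- 0.33  # Karlin-Altschul K for uniform base composition (documented constant)

  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq(i, length(ids))) {
      qi <- as.character(genome[[i]]); sj <- as.character(genome[[j]])
      qd <- paste0(qi, qi); sd <- paste0(sj, sj)
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") sd else dna_revcomp(sd)
        hits <- cpp_find_hsps(qd, subj, min_word, match, mismatch,
                              gap_open, gap_extend, xdrop, min_ungapped,
                              same_chrom = (i == j && strand == "+"),
                              period = lens[[i]],
                              max_chain_gap = 100L, band_pad = 100L)
        if (nrow(hits) == 0) next
        h <- as_tibble(hits)
        if (strand == "-") {
          L2 <- 2L * lens[[j]]
          ss <- L2 - h$send + 1L; se <- L2 - h$sstart + 1L
          h$sstart <- ss; h$send <- se
        }
        q1 <- normalize_circular(h$qstart, h$qend, lens[[i]])
        s1 <- normalize_circular(h$sstart, h$send, lens[[j]])
        rows[[length(rows) + 1]] <- tibble(
          chrom1 = ids[i], start1 = q1$start, end1 = q1$end,
          chrom2 = ids[j], start2 = s1$start, end2 = s1$end,
          orientation = if (strand == "+") "direct" else "inverted",
          identity = h$identity, aln_length = h$length,
          mismatches = h$mismatches, gap_opens = h$gap_opens,
          score = h$score,
          evalue = K * as.numeric(lens[[i]]) * total_len * exp(-lambda * h$score),
          span_q = pmin(h$qend - h$qstart + 1L, lens[[i]]),
          qlen = lens[[i]], slen = lens[[j]])
      }
    }
  }
  if (length(rows) == 0) return(empty_repeat_table())
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out,
                       .data$aln_length <= pmin(.data$qlen, .data$slen),
                       .data$evalue <= evalue_cutoff,
                       .data$aln_length >= min_length)
  out <- dplyr::select(out, -"span_q")
  # drop trivial self-alignments that survived refinement
  out <- dplyr::filter(out, !(.data$chrom1 == .data$chrom2 &
                                .data$orientation == "direct" &
                                .data$start1 == .data$start2 &
                                .data$end1 == .data$end2))
  # mirror collapse: copy1 is the positionally smaller locus
  swap <- out$chrom1 == out$chrom2 & out$start2 < out$start1
  if (any(swap)) {
    tmp <- out[swap, c("start1", "end1")]
    out[swap, c("start1", "end1")] <- out[swap, c("start2", "end2")]
    out[swap, c("start2", "end2")] <- tmp
  }
  out <- dplyr::distinct(out, .data$chrom1, .data$start1, .data$end1,
                         .data$chrom2, .data$start2, .data$end2,
                         .data$orientation, .keep_all = TRUE)
  out <- drop_contained_hsps(out)
  out <- dplyr::select(out, -"qlen", -"slen")
  out <- dplyr::arrange(out, .data$evalue, dplyr::desc(.data$aln_length),
                        .data$chrom1, .data$start1)
  if (is.finite(top_k)) out <- head(out, top_k)
  out$repeat_id <- sprintf("r%02d", seq_len(nrow(out)))
  out$inter_molecular <- out$chrom1 != out$chrom2
  dplyr::select(out, "repeat_id", dplyr::everything())
}

# positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1 for uniform base
# frequencies and a match/mismatch scoring scheme
karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(-l * mismatch) - 1
  uniroot(f, c(1e-4, 10), tol = 1e-10)$root
}

# map an interval found on a doubled circular sequence back onto the
# single circle; `end < start` in the result marks an origin-wrapping hit
normalize_circular <- function(start, end, L) {
  len <- end - start
  s <- ((start - 1L) %% L) + 1L
  e <- s + len
  wrapped <- e > L
  e[wrapped] <- e[wrapped] - L
  list(start = as.integer(s), end = as.integer(e))
}

# remove HSPs whose copy1 and copy2 intervals are both contained in a
# longer HSP of the same chromosome pair and orientation
drop_contained_hsps <- function(tbl) {
  if (nrow(tbl) < 2) return(tbl)
  keep <- rep(TRUE, nrow(tbl))
  ord <- order(-tbl$aln_length)
  for (a in seq_along(ord)) {
    ia <- ord[a]
    if (!keep[ia]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      ib <- ord[b]
      if (!keep[ib]) next
      if (tbl$chrom1[ia] != tbl$chrom1[ib] || tbl$chrom2[ia] != tbl$chrom2[ib] ||
          tbl$orientation[ia] != tbl$orientation[ib]) next
      direct_in <- interval_contains(tbl$start1[ia], tbl$end1[ia], tbl$start1[ib],
                                     tbl$end1[ib], tbl$qlen[ia]) &&
        interval_contains(tbl$start2[ia], tbl$end2[ia], tbl$start2[ib],
                          tbl$end2[ib], tbl$slen[ia])
      # a fragment may also sit inside the container with the two copies'
      # roles swapped (both copies of a repeat share the same sequence)
      mirror_in <- tbl$chrom1[ia] == tbl$chrom2[ia] &&
        interval_contains(tbl$start1[ia], tbl$end1[ia], tbl$start2[ib],
                          tbl$end2[ib], tbl$qlen[ia]) &&
        interval_contains(tbl$start2[ia], tbl$end2[ia], tbl$start1[ib],
                          tbl$end1[ib], tbl$slen[ia])
      if (direct_in || mirror_in) keep[ib] <- FALSE
    }
  }
  tbl[keep, ]
}

# does [s1,e1] contain [s2,e2] on a circle of length L?
# `end < start` marks an origin-wrapping interval
interval_contains <- function(s1, e1, s2, e2, L) {
  b1 <- if (e1 < s1) e1 + L else e1
  b2 <- if (e2 < s2) e2 + L else e2
  for (shift in c(0, L)) {
    if (s2 + shift >= s1 && b2 + shift <= b1) return(TRUE)
  }
  FALSE
}

empty_repeat_table <- function() {
  tibble(repeat_id = character(), chrom1 = character(), start1 = integer(),
         end1 = integer(), chrom2 = character(), start2 = integer(),
         end2 = integer(), orientation = character(), identity = numeric(),
         aln_length = integer(), mismatches = integer(), gap_opens = integer(),
         score = integer(), evalue = numeric(), inter_molecular = logical())
}

#' Parse a BLAST tabular (outfmt 6) HSP table into repeat pairs
#'
#' Expects the standard 12-column tab-separated layout `qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' [bitscore]` with no header. A subject interval given with
#' `sstart > send` denotes an inverted repeat and is normalised to
#' `(min, max)` with `orientation = "inverted"`.
#'
#' @param path path to a tab-separated HSP table
#' @return a repeat-pair tibble in the same layout as [find_repeats()]
#' @export
parse_hsp_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("HSP table not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty HSP table: %s", path))
  rows <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      abort(sprintf("malformed HSP row at line %d: expected >= 11 tab-separated fields, got %d",
                    ln, length(f)))
    num <- suppressWarnings(as.numeric(gsub(",", "", f[3:11])))
    if (anyNA(num))
      abort(sprintf("malformed HSP row at line %d: non-numeric field", ln))
    inverted <- num[7] > num[8]
    rows[[ln]] <- tibble(
      chrom1 = f[1],
      start1 = as.integer(min(num[5], num[6])),
      end1 = as.integer(max(num[5], num[6])),
      chrom2 = f[2],
      start2 = as.integer(min(num[7], num[8])),
      end2 = as.integer(max(num[7], num[8])),
      orientation = if (inverted) "inverted" else "direct",
      identity = num[1],
      aln_length = as.integer(num[2]),
      mismatches = as.integer(num[3]),
      gap_opens = as.integer(num[4]),
      score = if (length(f) >= 12) suppressWarnings(as.integer(f[12])) else NA_integer_,
      evalue = num[9])
  }
  out <- dplyr::bind_rows(rows)
  out$repeat_id <- sprintf("r%02d", seq_len(nrow(out)))
  out$inter_molecular <- out$chrom1 != out$chrom2
  dplyr::select(out, "repeat_id", dplyr::everything())
}

#' Write a repeat-pair table as TSV
#'
#' @param repeats repeat-pair tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_repeat_table <- function(repeats, path) write_tsv_report(repeats, path)

#' Repeat copies as BED intervals
#'
#' One BED line per repeat copy (two per pair), named
#' `<repeat_id>/1` and `<repeat_id>/2`.
#'
#' @param repeats repeat-pair tibble
#' @return tibble with `chrom`, `start`, `end`, `name`, `strand`
#' @export
repeat_bed <- function(repeats) {
  dplyr::bind_rows(
    tibble(chrom = repeats$chrom1, start = repeats$start1, end = repeats$end1,
           name = paste0(repeats$repeat_id, "/1"), strand = "+"),
    tibble(chrom = repeats$chrom2, start = repeats$start2, end = repeats$end2,
           name = paste0(repeats$repeat_id, "/2"),
           strand = ifelse(repeats$orientation == "inverted", "-", "+")))
}
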