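# four junction conformations around a repeat pair
#
# C1 and C2 are the junctions present in the assembly (the two major
# conformations); C3 and C4 are built by switching the flanking sequences
# and are present only if recombination at the repeat occurs. All four are
# expressed on the frame of copy1's plus strand: for an inverted repeat,
# copy2's context is first rewritten in the reverse-complement frame so
# both copies read the repeat body on the same strand, and the same
# flank-switch rule then applies.

#' Build the four junction conformations around one repeat
#'
#' For a direct repeat with copies `R1`, `R2` and flanks `U` (upstream) /
#' `D` (downstream): `C1 = U1 R1 D1`, `C2 = U2 R2 D2`, `C3 = U1 R1 D2`,
#' `C4 = U2 R2 D1`. When the two copies differ (identity < 100) the
#' recombinant conformations carry the repeat body of the copy that
#' contributes the upstream flank, which keeps read classification
#' insensitive to the repeat interior. Flanks wrap the circular origin
#' when needed; the flank is clipped (with a recorded warning) only when
#' a chromosome is shorter than the requested window.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector
#' @param repeat_pair one repeat: a single-row tibble from
#'   [find_repeats()] / [parse_hsp_table()], or a list with fields
#'   `repeat_id`, `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`,
#'   `orientation`
#' @param flank flank length in bp on each side of the repeat body
#' @param max_span repeats whose body exceeds this record a warning on
#'   the result (spanning reads become rare for very long repeats)
#' @return a `junction_set`: list with `repeat_id`, `flank` (effective),
#'   `sequences` (named C1..C4), `body_length` (named, per conformation),
#'   `roles` (C1/C2 = Mac, C3/C4 = Mic) and `warnings`
#' @export
build_conformations <- function(genome, repeat_pair, flank = 500,
                                max_span = 5000) {
  genome <- as_genome(genome)
  rp <- if (is.data.frame(repeat_pair)) as.list(repeat_pair[1, , drop = FALSE])
        else as.list(repeat_pair)
  flank <- check_count(flank, "flank")
  lens <- chromosome_lengths(genome)
  for (f in c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "orientation"))
    if (is.null(rp[[f]])) abort(sprintf("repeat_pair is missing field '%s'", f))
  for (k in 1:2) {
    ch <- rp[[paste0("chrom", k)]]
    if (!ch %in% names(lens)) abort(sprintf("chromosome '%s' not in genome", ch))
  }
  warnings <- character()

  body_len <- function(s, e, L) if (e >= s) e - s + 1L else L - s + 1L + e
  L1 <- lens[[rp$chrom1]]; L2 <- lens[[rp$chrom2]]
  b1 <- body_len(rp$start1, rp$end1, L1)
  b2 <- body_len(rp$start2, rp$end2, L2)
  eff_flank <- min(flank, (L1 - b1) %/% 2L, (L2 - b2) %/% 2L)
  if (eff_flank < 1) abort("chromosome too short to place any flank around the repeat")
  if (eff_flank < flank) {
    warnings <- c(warnings, sprintf(
      "flank clipped from %d to %d bp: chromosome shorter than requested window",
      flank, eff_flank))
  }
  if (max(b1, b2) > max_span) {
    warnings <- c(warnings, sprintf(
      "repeat body (%d bp) exceeds max_span (%d bp); spanning support will be sparse",
      max(b1, b2), max_span))
  }

  wrap <- function(pos, L) ((pos - 1L) %% L) + 1L
  get <- function(chrom, s, e) {
    L <- lens[[chrom]]
    extract_circular(genome, chrom, wrap(s, L), wrap(e, L))
  }
  # copy1 context, plus strand
  R1 <- get(rp$chrom1, rp$start1, rp$end1)
  U1 <- get(rp$chrom1, rp$start1 - eff_flank, rp$start1 - 1L)
  D1 <- get(rp$chrom1, rp$end1 + 1L, rp$end1 + eff_flank)
  if (identical(rp$orientation, "direct")) {
    R2 <- get(rp$chrom2, rp$start2, rp$end2)
    U2 <- get(rp$chrom2, rp$start2 - eff_flank, rp$start2 - 1L)
    D2 <- get(rp$chrom2, rp$end2 + 1L, rp$end2 + eff_flank)
  } else {
    # rewrite copy2 in the reverse-complement frame so the body reads as R
    R2 <- dna_revcomp(get(rp$chrom2, rp$start2, rp$end2))
    U2 <- dna_revcomp(get(rp$chrom2, rp$end2 + 1L, rp$end2 + eff_flank))
    D2 <- dna_revcomp(get(rp$chrom2, rp$start2 - eff_flank, rp$start2 - 1L))
  }
  # same-conformation window overlap makes junction support ambiguous
  if (rp$chrom1 == rp$chrom2) {
    gap_12 <- (rp$start2 - rp$end1 - 1L) %% L1
    gap_21 <- (rp$start1 - rp$end2 - 1L) %% L1
    if (min(gap_12, gap_21) < 2L * eff_flank) {
      warnings <- c(warnings,
                    "flank windows of the two copies overlap; junction support is ambiguous")
    }
  }
  seqs <- c(C1 = paste0(U1, R1, D1), C2 = paste0(U2, R2, D2),
            C3 = paste0(U1, R1, D2), C4 = paste0(U2, R2, D1))
  structure(list(
    repeat_id = rp$repeat_id %||% "r01",
    flank = eff_flank,
    requested_flank = flank,
    sequences = seqs,
    body_length = c(C1 = b1, C2 = b2, C3 = b1, C4 = b2),
    roles = c(C1 = "Mac", C2 = "Mac", C3 = "Mic", C4 = "Mic"),
    orientation = rp$orientation,
    warnings = warnings
  ), class = "junction_set")
}

#' @export
print.junction_set <- function(x, ...) {
  cat(sprintf("junction set for %s (%s repeat), flank %d bp\n",
              x$repeat_id, x$orientation, x$flank))
  for (ci in names(x$sequences))
    cat(sprintf("  %s [%s] %d bp\n", ci, x$roles[[ci]], nchar(x$sequences[[ci]])))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tidy a junction set into a tibble
#'
#' @param x a `junction_set`
#' @param ... unused
#' @return tibble with one row per conformation
#' @export
tidy.junction_set <- function(x, ...) {
  tibble(repeat_id = x$repeat_id,
         conformation = names(x$sequences),
         role = unname(x$roles[names(x$sequences)]),
         body_length = unname(x$body_length[names(x$sequences)]),
         flank = x$flank,
         length = nchar(unname(x$sequences)),
         sequence = unname(x$sequences))
}

#' Write a junction set as a 4-record FASTA
#'
#' Headers follow `<repeat_id>|C1|Mac` ... `<repeat_id>|C4|Mic`, ready for
#' any external read mapper.
#'
#' @param junctions a `junction_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_conformations_fasta <- function(junctions, path) {
  seqs <- junctions$sequences
  names(seqs) <- sprintf("%s|%s|%s", junctions$repeat_id, names(seqs),
                         junctions$roles[names(seqs)])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy
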