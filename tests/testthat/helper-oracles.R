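# shared fixtures and independent oracles
#
# The oracles deliberately use different machinery than the package:
# Biostrings::pairwiseAlignment for read classification, plain string
# enumeration for SSRs, and explicit sequence surgery for recombination.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_fasta_lines <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

# exhaustive read classification oracle: full (unbanded, unseeded)
# overlap alignment of every conformation against the read, both strands,
# scored like the implementation (match +1, mismatch -2, gap -2 linear)
oracle_classify <- function(read, junctions, min_anchor = 100,
                            max_divergence = 0.15) {
  confs <- junctions$sequences
  flank <- junctions$flank
  body <- junctions$body_length
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  best_per_conf <- list()
  for (ci in names(confs)) {
    cands <- list()
    for (s in c(read, mitorecomb::dna_revcomp(read))) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = confs[[ci]], subject = s, type = "overlap",
        substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
      pstr <- as.character(Biostrings::alignedPattern(pa))
      sstr <- as.character(Biostrings::alignedSubject(pa))
      cols <- nchar(pstr)
      if (cols == 0) next
      gapcols <- sum(strsplit(pstr, "")[[1]] == "-") +
        sum(strsplit(sstr, "")[[1]] == "-")
      mism <- Biostrings::nmismatch(pa)
      a_start <- Biostrings::start(Biostrings::pattern(pa))
      a_end <- Biostrings::end(Biostrings::pattern(pa))
      covered <- a_start <= flank - min_anchor + 1 &&
        a_end >= flank + body[[ci]] + min_anchor
      div <- (mism + gapcols) / cols
      cands[[length(cands) + 1]] <- list(score = Biostrings::score(pa),
                                         covered = covered, div = div)
    }
    if (length(cands) == 0) next
    sc <- vapply(cands, `[[`, numeric(1), "score")
    cov <- vapply(cands, `[[`, logical(1), "covered")
    ord <- order(-cov, -sc)
    best_per_conf[[ci]] <- cands[[ord[1]]]
  }
  span <- Filter(function(x) x$covered && x$div <= max_divergence &&
                   x$score > 0, best_per_conf)
  if (length(span) == 0) return("unspanning")
  sc <- vapply(span, `[[`, numeric(1), "score")
  if (sum(sc == max(sc)) > 1) return("ambiguous")
  names(span)[which.max(sc)]
}

# brute-force SSR oracle: enumerate every start and unit length, extend
# perfect copies, keep maximal primitive runs above threshold, then apply
# the documented overlap-resolution rule (longer run wins, ties to the
# smaller unit)
oracle_ssrs <- function(seq, thresholds = mitorecomb::ssr_thresholds()) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  cand <- list()
  for (u in 1:6) {
    for (i in seq_len(n - u * thresholds[u] + 1)) {
      unit <- substr(seq, i, i + u - 1)
      if (grepl("N", unit, fixed = TRUE)) next
      # maximality on the left: previous unit must differ
      if (i > u && substr(seq, i - u, i - 1) == unit) next
      copies <- 1L
      while (i + (copies + 1) * u - 1 <= n &&
             substr(seq, i + copies * u, i + (copies + 1) * u - 1) == unit)
        copies <- copies + 1L
      if (copies < thresholds[u]) next
      # primitive unit only (otherwise reported at the shorter period)
      primitive <- TRUE
      for (p in seq_len(u - 1)) {
        if (u %% p == 0 && strrep(substr(unit, 1, p), u / p) == unit) {
          primitive <- FALSE; break
        }
      }
      if (!primitive) next
      cand[[length(cand) + 1]] <- data.frame(
        unit_length = u, copies = copies, start = i, end = i + u * copies - 1)
    }
  }
  if (length(cand) == 0)
    return(data.frame(unit_length = integer(), copies = integer(),
                      start = integer(), end = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$unit_length * cand$copies), cand$unit_length,
                     cand$start), ]
  keep <- rep(FALSE, nrow(cand))
  acc <- data.frame(start = integer(), end = integer())
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= acc$end & cand$end[i] >= acc$start)) {
      keep[i] <- TRUE
      acc <- rbind(acc, cand[i, c("start", "end")])
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# are two circular sequences the same circle (either strand)?
same_circle <- function(x, y) {
  if (nchar(x) != nchar(y)) return(FALSE)
  grepl(y, paste0(x, x), fixed = TRUE) ||
    grepl(mitorecomb::dna_revcomp(y), paste0(x, x), fixed = TRUE)
}

# explicit sequence surgery for the three recombination outcomes, on raw
# strings (copies must not wrap; copy1 before copy2 for intra cases)
surgery_split <- function(S, s1, s2) {
  # direct intra: two circles, each beginning at one repeat copy
  c(mitorecomb::extract_circular(S, start = s1, end = if (s2 == 1) nchar(S) else s2 - 1),
    mitorecomb::extract_circular(S, start = s2, end = if (s1 == 1) nchar(S) else s1 - 1))
}

surgery_invert <- function(S, e1, s2) {
  # inverted intra: the run strictly between the copies flips
  L <- nchar(S)
  mid <- if (s2 > e1 + 1) mitorecomb::dna_revcomp(substr(S, e1 + 1, s2 - 1)) else ""
  paste0(substr(S, 1, e1), mid, substr(S, s2, L))
}

surgery_fuse <- function(S1, s1, S2, s2) {
  # inter direct: one circle running copy1, rest of circle 1, copy2, rest
  # of circle 2
  a <- mitorecomb::extract_circular(S1, start = s1, end = if (s1 == 1) nchar(S1) else s1 - 1)
  b <- mitorecomb::extract_circular(S2, start = s2, end = if (s2 == 1) nchar(S2) else s2 - 1)
  paste0(a, b)
}

# maximal exact extension of a planted duplication: how far the two
# copies stay identical when walked outward (gives the true repeat length
# including coincidental boundary matches)
exact_extension <- function(g1, s1, e1, g2, s2, e2) {
  L1 <- nchar(g1); L2 <- nchar(g2)
  a <- e1; b <- e2
  while (substr(g1, (a %% L1) + 1, (a %% L1) + 1) ==
         substr(g2, (b %% L2) + 1, (b %% L2) + 1)) { a <- a + 1; b <- b + 1 }
  sa <- s1 - 1; sb <- s2 - 1
  while (sa >= 1 && sb >= 1 && substr(g1, sa, sa) == substr(g2, sb, sb)) {
    sa <- sa - 1; sb <- sb - 1
  }
  (a - (sa + 1) + 1)
}

# printed spanning-read count table used across tests (eleven repeats:
# major/minor junction reads and the printed body length)
printed_support_counts <- function() {
  tibble::tibble(
    repeat_id = sprintf("r%02d", 1:11),
    mac1 = c(70, 31, 28, 24, 65, 46, 30, 33, 41, 15, 61),
    mac2 = c(46, 28, 22, 17, 60, 59, 37, 29, 48, 10, 65),
    mic1 = c(5, 5, 5, 1, 2, 6, 3, 11, 9, 15, 0),
    mic2 = c(3, 11, 3, 1, 1, 5, 2, 3, 3, 12, 1),
    aln_length = c(127L, 682L, 369L, 192L, 87L, 144L, 136L, 74L, 59L,
                   5835L, 116L),
    frequency_printed = c(6.45, 21.33, 13.79, 4.65, 2.34, 9.48, 6.94,
                          18.42, 11.88, 51.92, 0.79))
}

# printed repeat-copy coordinates on the two assembly chromosomes
printed_repeat_coords <- function() {
  tibble::tibble(
    repeat_id = sprintf("r%02d", 1:9),
    chrom1 = "MC1",
    start1 = c(328831L, 279954L, 223308L, 232877L, 185367L, 191145L,
               175216L, 300772L, 311788L),
    end1 = c(328915L, 280635L, 223676L, 233068L, 185453L, 191287L,
             175351L, 300845L, 311846L),
    chrom2 = c("MC2", rep("MC1", 8)),
    start2 = c(85115L, 234787L, 27145L, 78659L, 1433L, 141672L, 209471L,
               19641L, 252783L),
    end2 = c(85199L, 235468L, 27513L, 78846L, 1519L, 141814L, 209605L,
             19714L, 252840L),
    orientation = c("direct", "inverted", "inverted", "direct", "direct",
                    "direct", "inverted", "direct", "direct"))
}

chrom_lengths_assembly <- c(MC1 = 328915, MC2 = 85199)
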