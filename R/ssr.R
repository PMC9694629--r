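# MISA-style microsatellite (SSR) scanning
#
# Maximal perfect tandem runs of a 1-6 bp unit, with per-unit-length
# minimum copy numbers. Unlike MISA, compound-SSR merging across short
# interruptions is off by default; a merge distance can be supplied.
# Chromosomes are scanned in their linear frame (MISA parity); a run is
# never extended through the circular origin.

#' Per-unit-length minimum copy numbers for SSR calling
#'
#' Defaults are 10 copies for mononucleotide units, 5 for di-, 4 for tri-
#' and 3 for tetra-, penta- and hexanucleotide units.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum copy numbers (all >= 2)
#' @return integer vector of length 6 (unit lengths 1..6)
#' @export
ssr_thresholds <- function(mono = 10, di = 5, tri = 4, tetra = 3, penta = 3,
                           hexa = 3) {
  thr <- c(mono, di, tri, tetra, penta, hexa)
  if (any(thr < 2)) abort("all SSR copy thresholds must be >= 2")
  as.integer(thr)
}

#' Scan a genome for simple sequence repeats
#'
#' Reports maximal perfect tandem runs of a 1-6 bp unit meeting the copy
#' thresholds. A run whose unit is itself a tandem of a shorter unit is
#' reported once, at the shortest unit length. Overlapping candidate calls
#' are resolved in favour of the longer run, with ties going to the
#' smaller unit; records of the same unit length never overlap. The
#' reported motif is the lexicographically smallest rotation of the unit
#' on the scanned strand (no strand collapsing).
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector
#' @param thresholds integer vector from [ssr_thresholds()]
#' @param compound_max_dist if positive, SSRs on the same chromosome
#'   within this many bases of each other share a `compound_id` (MISA-like
#'   compound annotation; 100 bp is the conventional choice). Default off.
#' @return tibble with `chrom`, `motif`, `unit_length`, `copies`,
#'   `start`, `end` (1-based inclusive; `end - start + 1 ==
#'   unit_length * copies`)
#' @export
scan_ssrs <- function(genome, thresholds = ssr_thresholds(),
                      compound_max_dist = 0) {
  genome <- as_genome(genome)
  if (length(genome) == 0) abort("genome is empty")
  stopifnot(length(thresholds) == 6)
  cand <- purrr::map_dfr(names(genome), function(cid) {
    ssr_candidates(as.character(genome[[cid]]), cid, thresholds)
  })
  if (nrow(cand) == 0) return(empty_ssr_table(compound_max_dist))
  out <- resolve_ssr_overlaps(cand)
  out <- dplyr::arrange(out, match(.data$chrom, names(genome)), .data$start)
  if (compound_max_dist > 0) {
    out <- out |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(compound_id = cumsum(
        c(TRUE, .data$start[-1] - .data$end[-dplyr::n()] - 1 > compound_max_dist))) |>
      dplyr::ungroup() |>
      dplyr::mutate(compound_id = paste0(.data$chrom, ".", .data$compound_id))
  }
  out
}

ssr_candidates <- function(seq, cid, thresholds) {
  n <- nchar(seq)
  r <- charToRaw(seq)
  isN <- r == charToRaw("N")
  rows <- list()
  for (u in 1:6) {
    if (n < u * thresholds[u]) next
    eq <- r[seq_len(n - u)] == r[(u + 1):n] &
      !isN[seq_len(n - u)] & !isN[(u + 1):n]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & rl$lengths >= (thresholds[u] - 1L) * u)
    for (h in hit) {
      i <- starts[h]
      copies <- (rl$lengths[h] + u) %/% u
      if (copies < thresholds[u]) next
      motif <- substr(seq, i, i + u - 1L)
      if (min_period(motif) < u) next  # reported at the shorter unit instead
      rows[[length(rows) + 1]] <- tibble(
        chrom = cid, motif = canonical_rotation(motif),
        unit_length = u, copies = as.integer(copies),
        start = as.integer(i), end = as.integer(i + u * copies - 1L))
    }
  }
  if (length(rows) == 0) return(empty_ssr_table(0)) else dplyr::bind_rows(rows)
}

# smallest p such that the motif is (unit of length p) repeated; p must
# divide the motif length for a perfect tandem
min_period <- function(motif) {
  u <- nchar(motif)
  for (p in seq_len(u - 1)) {
    if (u %% p != 0) next
    if (strrep(substr(motif, 1, p), u %/% p) == motif) return(p)
  }
  u
}

canonical_rotation <- function(motif) {
  u <- nchar(motif)
  doubled <- paste0(motif, motif)
  min(vapply(seq_len(u), function(i) substr(doubled, i, i + u - 1L), character(1)))
}

# longer run wins; ties to the smaller unit; greedy acceptance
resolve_ssr_overlaps <- function(cand) {
  cand <- dplyr::arrange(cand, dplyr::desc(.data$unit_length * .data$copies),
                         .data$unit_length, .data$chrom, .data$start)
  keep <- logical(nrow(cand))
  acc <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    prev <- acc[[ch]]
    ok <- TRUE
    if (!is.null(prev)) {
      ok <- !any(cand$start[i] <= prev$end & cand$end[i] >= prev$start)
    }
    if (ok) {
      keep[i] <- TRUE
      acc[[ch]] <- rbind(prev, data.frame(start = cand$start[i], end = cand$end[i]))
    }
  }
  cand[keep, ]
}

empty_ssr_table <- function(compound) {
  t <- tibble(chrom = character(), motif = character(), unit_length = integer(),
              copies = integer(), start = integer(), end = integer())
  if (compound > 0) t$compound_id <- character()
  t
}

#' SSR records as BED intervals
#'
#' @param ssrs tibble from [scan_ssrs()]
#' @return tibble suitable for [write_bed()]
#' @export
ssr_bed <- function(ssrs) {
  tibble(chrom = ssrs$chrom, start = ssrs$start, end = ssrs$end,
         name = sprintf("(%s)%d", ssrs$motif, ssrs$copies))
}
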