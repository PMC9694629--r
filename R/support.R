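# classify long reads as spanning support for one of the four junction
# conformations, tally support counts and compute the recombination
# frequency statistic
#
# A read supports a conformation when its alignment covers the full
# repeat body plus at least `min_anchor` bases of BOTH flanks, with edit
# divergence (mismatch + gap columns over aligned columns) at most
# `max_divergence`. The aligner is a seed-located banded overlap
# alignment (match +1, mismatch -2, gap -2, linear); both read strands
# are tried. The best-scoring spanning candidate wins; equal best scores
# give `ambiguous`; no spanning candidate gives `unspanning`.

#' Read long reads from FASTA or FASTQ
#'
#' Format is detected from the first non-empty character (`>` FASTA,
#' `@` FASTQ). Qualities are ignored.
#'
#' @param path input path
#' @return tibble with `read_id` and `seq`
#' @export
read_long_reads <- function(path) {
  if (!file.exists(path)) abort(sprintf("reads file not found: %s", path))
  first <- substr(trimws(readLines(path, n = 1L)), 1, 1)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read_id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Classify reads against a junction set
#'
#' @param reads a tibble with `read_id` and `seq`, a (named) character
#'   vector, or a [Biostrings::DNAStringSet]
#' @param junctions a `junction_set` from [build_conformations()]
#' @param min_anchor minimum flank coverage (bp) on each side of the
#'   repeat body for a read to count as spanning
#' @param max_divergence maximum edit divergence over the aligned span
#' @param seed_k k-mer length used to locate each conformation in a read
#' @return tibble with `read_id`, `label` (C1/C2/C3/C4/ambiguous/
#'   unspanning), `score` and `divergence` of the winning alignment (NA
#'   when unspanning)
#' @export
classify_reads <- function(reads, junctions, min_anchor = 100,
                           max_divergence = 0.15, seed_k = 13) {
  reads <- as_read_table(reads)
  stopifnot(inherits(junctions, "junction_set"))
  min_anchor <- check_count(min_anchor, "min_anchor")
  max_divergence <- check_fraction(max_divergence, "max_divergence")
  if (min_anchor > junctions$flank)
    abort(sprintf("min_anchor (%d) exceeds the junction flank (%d)",
                  min_anchor, junctions$flank))
  confs <- junctions$sequences
  flank <- junctions$flank
  body <- junctions$body_length[names(confs)]
  band <- as.integer(max(48, ceiling(0.3 * max_divergence * max(nchar(confs))) + 20))
  res <- cpp_classify_batch(
    reads$seq, unname(confs),
    astart_max = rep(as.integer(flank - min_anchor + 1L), length(confs)),
    aend_min = as.integer(flank + body + min_anchor),
    k = as.integer(seed_k), band_w = band, min_seeds = 2L,
    match = 1L, mismatch = 2L, gap = 2L)
  spanning <- res$aligned == 1L & res$covered == 1L &
    !is.na(res$divergence) & res$divergence <= max_divergence
  decide <- function(i) {
    cand <- which(spanning[i, ])
    if (length(cand) == 0)
      return(list(label = "unspanning", score = NA_real_, divergence = NA_real_))
    sc <- res$score[i, cand]
    top <- cand[which.max(sc)]
    if (sum(sc == max(sc)) > 1)
      return(list(label = "ambiguous", score = max(sc),
                  divergence = res$divergence[i, top]))
    list(label = names(confs)[top], score = max(sc),
         divergence = res$divergence[i, top])
  }
  dec <- lapply(seq_len(nrow(reads)), decide)
  tibble(read_id = reads$read_id,
         label = vapply(dec, `[[`, character(1), "label"),
         score = vapply(dec, `[[`, numeric(1), "score"),
         divergence = vapply(dec, `[[`, numeric(1), "divergence"))
}

#' @rdname classify_reads
#' @param read a single DNA string
#' @export
classify_read <- function(read, junctions, min_anchor = 100,
                          max_divergence = 0.15, seed_k = 13) {
  classify_reads(c(read1 = read), junctions, min_anchor = min_anchor,
                 max_divergence = max_divergence, seed_k = seed_k)$label
}

as_read_table <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    return(tibble(read_id = as.character(reads$read_id),
                  seq = as.character(reads$seq)))
  }
  if (methods::is(reads, "DNAStringSet")) {
    return(tibble(read_id = names(reads) %||% paste0("read", seq_along(reads)),
                  seq = unname(as.character(reads))))
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% paste0("read", seq_along(reads))
    return(tibble(read_id = ids, seq = unname(reads)))
  }
  abort("`reads` must be a tibble, character vector or DNAStringSet")
}

#' Tally spanning-read support for the four conformations
#'
#' @inheritParams classify_reads
#' @param ... passed to [classify_reads()]
#' @return one-row tibble: `repeat_id`, `mac1`, `mac2`, `mic1`, `mic2`,
#'   `ambiguous`, `unspanning`
#' @export
count_support <- function(reads, junctions, ...) {
  labels <- classify_reads(reads, junctions, ...)$label
  tibble(repeat_id = junctions$repeat_id,
         mac1 = sum(labels == "C1"), mac2 = sum(labels == "C2"),
         mic1 = sum(labels == "C3"), mic2 = sum(labels == "C4"),
         ambiguous = sum(labels == "ambiguous"),
         unspanning = sum(labels == "unspanning"))
}

#' Recombination frequency from conformation support counts
#'
#' The statistic is `100 * (mic1 + mic2) / (mac1 + mac2 + mic1 + mic2)`,
#' i.e. minor-conformation spanning reads over all confidently assigned
#' spanning reads (ambiguous reads are excluded from the denominator),
#' rounded half-up to two decimals. A zero denominator yields `NA` with a
#' warning.
#'
#' Given a data frame with columns `mac1`, `mac2`, `mic1`, `mic2`, the
#' frequencies are appended as a `frequency` column; given four numbers,
#' the frequency is returned directly.
#'
#' @param counts a data frame of support counts, or `mac1` as a number
#' @param mac2,mic1,mic2 counts when `counts` is a number
#' @return the input tibble with a `frequency` column, or a numeric
#'   percentage
#' @export
#' @examples
#' recombination_frequency(70, 46, 5, 3)   # 6.45
#' recombination_frequency(31, 28, 5, 11)  # 21.33
recombination_frequency <- function(counts, mac2 = NULL, mic1 = NULL,
                                    mic2 = NULL) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("mac1", "mac2", "mic1", "mic2") %in% names(counts)))
    counts$frequency <- recombination_frequency(counts$mac1, counts$mac2,
                                                counts$mic1, counts$mic2)
    return(counts)
  }
  mac1 <- counts
  denom <- mac1 + mac2 + mic1 + mic2
  if (any(denom == 0)) warn("zero spanning-read denominator: frequency is NA")
  ifelse(denom > 0, round_half_up(100 * (mic1 + mic2) / denom, 2), NA_real_)
}

#' Flag repeats whose support indicates active recombination
#'
#' A repeat is called active when both minor junctions have at least
#' `min_each_mic` supporting reads, the minor junctions together have at
#' least `min_total_mic` reads, and the repeat body is no longer than
#' `max_repeat_span` (very long repeats cannot be spanned reliably, so
#' their support is not trusted). The thresholds are a stated heuristic.
#'
#' @param records data frame with columns `mic1`, `mic2` and `aln_length`
#' @param min_each_mic minimum reads on each minor junction
#' @param min_total_mic minimum total minor-junction reads
#' @param max_repeat_span maximum repeat body length (bp)
#' @return `records` with a logical `active` column
#' @export
call_active_repeats <- function(records, min_each_mic = 1, min_total_mic = 2,
                                max_repeat_span = 5000) {
  stopifnot(all(c("mic1", "mic2", "aln_length") %in% names(records)))
  records$active <- records$mic1 >= min_each_mic &
    records$mic2 >= min_each_mic &
    (records$mic1 + records$mic2) >= min_total_mic &
    records$aln_length <= max_repeat_span
  records
}
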