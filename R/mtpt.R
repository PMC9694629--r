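# mitochondrial plastid DNA (MTPT) detection: plastid-derived fragments
# in the mitogenome, reciprocal-best filtered, merged, summarised and
# grouped into plastome gene clusters

#' Find plastid-derived fragments (MTPTs) in a mitogenome
#'
#' Runs the same seed-and-extend homology engine as [find_repeats()]
#' with the plastome as query and the mitogenome as subject (both
#' strands, circular). Hits shorter than `min_length` are ignored.
#' Reciprocal-best filtering keeps a hit only when its mitochondrial and
#' plastid intervals are each other's best-scoring partners; overlapping
#' mito-side hits that extend the same plastid region colinearly are
#' merged (within `merge_tol` bp).
#'
#' @param mitogenome,plastome genomes ([Biostrings::DNAStringSet] or
#'   named character)
#' @param evalue_cutoff,word_size homology search parameters
#' @param min_length minimum hit length in bp (shorter hits are ignored)
#' @param merge_tol gap/overlap tolerance (bp) when merging colinear hits
#' @param id_prefix prefix for the `mtpt_id` labels
#' @inheritParams find_repeats
#' @return tibble with `mtpt_id`, `mito_chrom`, `mito_start`, `mito_end`,
#'   `plastid_chrom`, `plastid_start`, `plastid_end`, `strand`,
#'   `identity`, `aln_length`, `score`, `evalue`
#' @export
find_mtpt <- function(mitogenome, plastome, evalue_cutoff = 1e-6,
                      word_size = 7, min_length = 100, merge_tol = 10,
                      match = 1, mismatch = 2, gap_open = 5, gap_extend = 2,
                      id_prefix = "mtpt") {
  mitogenome <- as_genome(mitogenome); plastome <- as_genome(plastome)
  lens_m <- chromosome_lengths(mitogenome)
  lens_p <- chromosome_lengths(plastome)
  lambda <- karlin_lambda(match, mismatch)
  K <- 0.33
  total_n <- sum(as.numeric(lens_m))
  rows <- list()
  for (pc in names(plastome)) {
    qd <- paste0(as.character(plastome[[pc]]), as.character(plastome[[pc]]))
    for (mc in names(mitogenome)) {
      sj <- as.character(mitogenome[[mc]])
      sd <- paste0(sj, sj)
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") sd else dna_revcomp(sd)
        hits <- cpp_find_hsps(qd, subj, as.integer(word_size), match, mismatch,
                              gap_open, gap_extend, 20L, 18L,
                              same_chrom = FALSE, period = 0L,
                              max_chain_gap = 100L, band_pad = 100L)
        if (nrow(hits) == 0) next
        h <- as_tibble(hits)
        if (strand == "-") {
          L2 <- 2L * lens_m[[mc]]
          ss <- L2 - h$send + 1L; se <- L2 - h$sstart + 1L
          h$sstart <- ss; h$send <- se
        }
        p1 <- normalize_circular(h$qstart, h$qend, lens_p[[pc]])
        m1 <- normalize_circular(h$sstart, h$send, lens_m[[mc]])
        rows[[length(rows) + 1]] <- tibble(
          mito_chrom = mc, mito_start = m1$start, mito_end = m1$end,
          plastid_chrom = pc, plastid_start = p1$start, plastid_end = p1$end,
          strand = strand, identity = h$identity, aln_length = h$length,
          score = h$score,
          evalue = K * as.numeric(lens_p[[pc]]) * total_n * exp(-lambda * h$score))
      }
    }
  }
  if (length(rows) == 0) return(empty_mtpt_table())
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out, .data$evalue <= evalue_cutoff,
                       .data$aln_length >= min_length,
                       .data$mito_end >= .data$mito_start,
                       .data$plastid_end >= .data$plastid_start)
  out <- dplyr::distinct(out, .data$mito_chrom, .data$mito_start,
                         .data$mito_end, .data$plastid_chrom,
                         .data$plastid_start, .data$plastid_end,
                         .data$strand, .keep_all = TRUE)
  if (nrow(out) == 0) return(empty_mtpt_table())
  out <- reciprocal_best(out)
  out <- merge_colinear_mtpt(out, merge_tol)
  out <- dplyr::arrange(out, match(.data$mito_chrom, names(mitogenome)),
                        .data$mito_start)
  out$mtpt_id <- sprintf("%s-%03d", id_prefix, seq_len(nrow(out)))
  dplyr::select(out, "mtpt_id", dplyr::everything())
}

# keep a hit iff it is the best-scoring hit among those overlapping its
# mito interval AND among those overlapping its plastid interval
reciprocal_best <- function(hits) {
  n <- nrow(hits)
  keep <- rep(TRUE, n)
  mito_ov <- function(i, j) hits$mito_chrom[i] == hits$mito_chrom[j] &&
    hits$mito_start[i] <= hits$mito_end[j] && hits$mito_end[i] >= hits$mito_start[j]
  pl_ov <- function(i, j) hits$plastid_chrom[i] == hits$plastid_chrom[j] &&
    hits$plastid_start[i] <= hits$plastid_end[j] &&
    hits$plastid_end[i] >= hits$plastid_start[j]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || hits$score[j] <= hits$score[i]) next
      if (mito_ov(i, j) || pl_ov(i, j)) { keep[i] <- FALSE; break }
    }
  }
  hits[keep, ]
}

merge_colinear_mtpt <- function(hits, tol) {
  hits <- dplyr::arrange(hits, .data$mito_chrom, .data$mito_start)
  out <- list()
  cur <- NULL
  flush <- function(cur, out) { out[[length(out) + 1]] <- cur; out }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (!is.null(cur) &&
        h$mito_chrom == cur$mito_chrom &&
        h$plastid_chrom == cur$plastid_chrom &&
        h$strand == cur$strand &&
        h$mito_start <= cur$mito_end + tol + 1) {
      mito_gap <- h$mito_start - cur$mito_end - 1
      pl_gap <- if (h$strand == "+") h$plastid_start - cur$plastid_end - 1
                else cur$plastid_start - h$plastid_end - 1
      if (abs(pl_gap - mito_gap) <= 2 * tol && pl_gap > -(cur$aln_length)) {
        w <- cur$aln_length + h$aln_length
        cur$identity <- (cur$identity * cur$aln_length + h$identity * h$aln_length) / w
        cur$mito_end <- max(cur$mito_end, h$mito_end)
        cur$plastid_start <- min(cur$plastid_start, h$plastid_start)
        cur$plastid_end <- max(cur$plastid_end, h$plastid_end)
        cur$aln_length <- cur$mito_end - cur$mito_start + 1
        cur$score <- cur$score + h$score
        cur$evalue <- min(cur$evalue, h$evalue)
        next
      }
    }
    if (!is.null(cur)) out <- flush(cur, out)
    cur <- h
  }
  if (!is.null(cur)) out <- flush(cur, out)
  dplyr::bind_rows(out)
}

empty_mtpt_table <- function() {
  tibble(mtpt_id = character(), mito_chrom = character(),
         mito_start = integer(), mito_end = integer(),
         plastid_chrom = character(), plastid_start = integer(),
         plastid_end = integer(), strand = character(),
         identity = numeric(), aln_length = integer(), score = integer(),
         evalue = numeric())
}

#' Summarise the MTPT footprint
#'
#' The total footprint is the non-redundant union of the mito-side
#' intervals (overlapping records never double-count bases). Percentages
#' are rounded half-up to two decimals.
#'
#' @param records tibble from [find_mtpt()]
#' @param mito_len total mitogenome length (bp)
#' @param plastid_len plastome length (bp)
#' @return one-row tibble: `n`, `total_bp`, `pct_of_mito`,
#'   `pct_of_plastome`
#' @export
#' @examples
#' # the worked numbers: 12,583 bp over a 414,114 bp mitogenome and a
#' # 151,394 bp plastome
#' rec <- tibble::tibble(mito_chrom = "MC1", mito_start = 1, mito_end = 12583)
#' summarize_mtpt(rec, mito_len = 328915 + 85199, plastid_len = 151394)
summarize_mtpt <- function(records, mito_len, plastid_len) {
  stopifnot(mito_len > 0, plastid_len > 0)
  total <- 0L
  if (nrow(records) > 0) {
    by_chrom <- split(records, records$mito_chrom)
    total <- sum(vapply(by_chrom, function(x) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = x$mito_start, end = x$mito_end))))
    }, numeric(1)))
  }
  tibble(n = nrow(records), total_bp = as.integer(total),
         pct_of_mito = round_half_up(100 * total / mito_len, 2),
         pct_of_plastome = round_half_up(100 * total / plastid_len, 2))
}

#' Read a plastome gene annotation
#'
#' Accepts a GFF3 file (gene features; requires the rtracklayer package)
#' or a data frame with columns `gene`, `start`, `end` and optionally
#' `chrom`, `strand`.
#'
#' @param x path to a GFF3 file or a data frame
#' @return tibble with `chrom`, `gene`, `start`, `end`, `strand`
#' @export
read_plastome_annotation <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene", "start", "end") %in% names(x)))
    return(tibble(chrom = if ("chrom" %in% names(x)) as.character(x$chrom) else NA_character_,
                  gene = as.character(x$gene),
                  start = as.integer(x$start), end = as.integer(x$end),
                  strand = if ("strand" %in% names(x)) as.character(x$strand) else "+"))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("reading GFF3 annotations requires the rtracklayer package")
  df <- as.data.frame(rtracklayer::import(x))
  df <- df[df$type == "gene", , drop = FALSE]
  nm <- df$Name %||% df$gene %||% df$ID
  tibble(chrom = as.character(df$seqnames), gene = as.character(nm),
         start = as.integer(df$start), end = as.integer(df$end),
         strand = as.character(df$strand))
}

#' Group MTPT records into plastome gene clusters
#'
#' For each MTPT, plastome genes fully contained in its plastid interval
#' are listed as `full`; genes partially overlapped are flagged
#' `partial`. Genes in a cluster are contiguous along the plastome by
#' construction (they are the consecutive genes overlapped by one
#' interval).
#'
#' @param records tibble from [find_mtpt()]
#' @param annotation gene table from [read_plastome_annotation()]
#' @return tibble with `mtpt_id`, `gene`, `status`, `gene_start`,
#'   `gene_end`; MTPTs in intergenic regions contribute no rows
#' @export
group_gene_clusters <- function(records, annotation) {
  annotation <- read_plastome_annotation(annotation)
  if (nrow(records) > 0 && !all(is.na(annotation$chrom))) {
    if (!any(annotation$chrom %in% records$plastid_chrom))
      abort("annotation chromosome ids do not match the plastome ids in the MTPT records")
  }
  annotation <- dplyr::arrange(annotation, .data$start)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    a <- annotation
    if (!all(is.na(a$chrom))) a <- a[is.na(a$chrom) | a$chrom == r$plastid_chrom, ]
    ov <- a$start <= r$plastid_end & a$end >= r$plastid_start
    if (!any(ov)) return(tibble())
    a <- a[ov, ]
    tibble(mtpt_id = r$mtpt_id, gene = a$gene,
           status = ifelse(a$start >= r$plastid_start & a$end <= r$plastid_end,
                           "full", "partial"),
           gene_start = a$start, gene_end = a$end)
  })
}

#' MTPT mito-side footprints as BED
#' @param records tibble from [find_mtpt()]
#' @return tibble suitable for [write_bed()]
#' @export
mtpt_bed <- function(records) {
  tibble(chrom = records$mito_chrom, start = records$mito_start,
         end = records$mito_end, name = records$mtpt_id,
         strand = records$strand)
}

#' Mito-plastid link table for circular plots
#' @param records tibble from [find_mtpt()]
#' @return tibble pairing each mito interval with its plastid interval
#' @export
mtpt_links <- function(records) {
  dplyr::select(records, "mtpt_id", "mito_chrom", "mito_start", "mito_end",
                "plastid_chrom", "plastid_start", "plastid_end", "strand",
                "identity")
}
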