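# end-to-end orchestration: repeats -> conformations -> read support ->
# topology -> SSR -> MTPT, with a report bundle on disk

#' Run the full recombination-analysis pipeline
#'
#' Stages: (1) repeat discovery (or ingestion of a precomputed HSP
#' table), (2) junction-conformation FASTAs per repeat, (3) read
#' classification into the per-repeat support/frequency report, (4)
#' conformation-space enumeration (JSON + FASTA), (5) SSR scan, (6) MTPT
#' detection when a plastome is supplied, (7) a run log with package
#' version, parameters and seed. Stages lacking their inputs are skipped
#' with a notice; a failing stage aborts with a stage-tagged message,
#' retaining the outputs already written.
#'
#' When `counts_table` is supplied (a data frame or TSV with `mac1`,
#' `mac2`, `mic1`, `mic2` and optionally `aln_length`), read mapping is
#' skipped and the frequency/active columns are computed directly from
#' those counts.
#'
#' @param genome genome FASTA path or genome object
#' @param reads long-read FASTA/FASTQ path or read tibble (optional)
#' @param hsp_table optional precomputed BLAST outfmt-6 table path
#' @param plastome optional plastome FASTA path or genome object
#' @param plastome_annotation optional gene annotation (GFF3 path or
#'   data frame) for MTPT gene clusters
#' @param counts_table optional precomputed support counts (path or data
#'   frame); activates counts-only mode
#' @param out_dir output directory (created if missing)
#' @param flank junction flank length (bp)
#' @param min_anchor,max_divergence read-classification parameters
#' @param ssr_thresholds SSR copy thresholds ([ssr_thresholds()])
#' @param max_repeat_span active-repeat span threshold (bp)
#' @param evalue_cutoff,min_repeat_length repeat-search parameters
#' @param seed seed recorded in the log (stages here are deterministic;
#'   the seed matters when simulation steps are composed around the
#'   pipeline)
#' @return invisibly, a list of result tibbles and output paths
#' @export
run_pipeline <- function(genome, reads = NULL, hsp_table = NULL,
                         plastome = NULL, plastome_annotation = NULL,
                         counts_table = NULL,
                         out_dir = "mitorecomb-out", flank = 500,
                         min_anchor = 100, max_divergence = 0.15,
                         ssr_thresholds = mitorecomb::ssr_thresholds(),
                         max_repeat_span = 5000,
                         evalue_cutoff = 1e-6, min_repeat_length = 50,
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("mitorecomb %s | %s\n",
              as.character(utils::packageVersion("mitorecomb")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = logf)
  log_line("seed=%d flank=%d min_anchor=%d max_divergence=%.3f", seed, flank,
           min_anchor, max_divergence)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  results <- list(paths = list())

  if (!is.null(counts_table)) {
    counts <- stage("counts-only", {
      if (is.character(counts_table))
        counts_table <- read.table(counts_table, sep = "\t", header = TRUE)
      as_tibble(counts_table)
    })
    freq <- recombination_frequency(counts)
    if ("aln_length" %in% names(freq))
      freq <- call_active_repeats(freq, max_repeat_span = max_repeat_span)
    p <- file.path(out_dir, "support_frequency.tsv")
    write_tsv_report(freq, p)
    log_line("counts-only mode: %d rows", nrow(freq))
    results$support <- freq
    results$paths$support <- p
    return(invisible(results))
  }

  gen <- stage("genome", {
    if (is.character(genome) && length(genome) == 1 && file.exists(genome))
      read_genome_fasta(genome) else as_genome(genome)
  })
  log_line("genome: %d chromosome(s), %s bp",
           length(gen), format(sum(Biostrings::width(gen)), big.mark = ","))

  repeats <- stage("repeats", {
    if (!is.null(hsp_table)) parse_hsp_table(hsp_table)
    else find_repeats(gen, evalue_cutoff = evalue_cutoff,
                      min_length = min_repeat_length)
  })
  p <- file.path(out_dir, "repeats.tsv")
  write_repeat_table(repeats, p)
  write_bed(repeat_bed(repeats), file.path(out_dir, "repeats.bed"))
  log_line("repeats: %d pair(s)", nrow(repeats))
  results$repeats <- repeats
  results$paths$repeats <- p

  junction_sets <- stage("conformations", {
    js <- lapply(seq_len(nrow(repeats)), function(i)
      build_conformations(gen, repeats[i, ], flank = flank,
                          max_span = max_repeat_span))
    for (j in js)
      write_conformations_fasta(j, file.path(out_dir, paste0(
        "conformations_", j$repeat_id, ".fasta")))
    js
  })
  log_line("conformations: %d junction set(s)", length(junction_sets))
  results$junctions <- junction_sets

  if (!is.null(reads)) {
    support <- stage("support", {
      rtab <- if (is.character(reads)) read_long_reads(reads) else as_read_table(reads)
      dplyr::bind_rows(lapply(junction_sets, function(j)
        count_support(rtab, j, min_anchor = min_anchor,
                      max_divergence = max_divergence)))
    })
    support <- dplyr::left_join(
      support, dplyr::select(repeats, "repeat_id", "aln_length"),
      by = "repeat_id")
    support <- recombination_frequency(support)
    support <- call_active_repeats(support, max_repeat_span = max_repeat_span)
    p <- file.path(out_dir, "support_frequency.tsv")
    write_tsv_report(support, p)
    log_line("support: %d repeat(s), %d active", nrow(support),
             sum(support$active))
    results$support <- support
    results$paths$support <- p
  } else {
    log_line("support: skipped (no reads supplied)")
    message("stage support skipped: no reads supplied")
    results$support <- NULL
  }

  topo <- stage("topology", {
    active_ids <- if (!is.null(results$support))
      results$support$repeat_id[results$support$active] else repeats$repeat_id
    usable <- repeats[repeats$repeat_id %in% active_ids &
                        repeats$end1 >= repeats$start1 &
                        repeats$end2 >= repeats$start2, ]
    mac <- genome_to_molecules(gen, usable)
    mics <- enumerate_conformation_space(mac, usable$repeat_id)
    names(mics) <- usable$repeat_id
    for (rid in names(mics))
      export_molecules(mics[[rid]], gen,
                       fasta_path = file.path(out_dir, paste0("conformation_space_", rid, ".fasta")),
                       json_path = file.path(out_dir, paste0("conformation_space_", rid, ".json")))
    list(mac = mac, mics = mics)
  })
  log_line("topology: %d minor conformation set(s)", length(topo$mics))
  results$topology <- topo

  ssrs <- stage("ssr", scan_ssrs(gen, thresholds = ssr_thresholds))
  write_tsv_report(ssrs, file.path(out_dir, "ssr.tsv"))
  write_bed(ssr_bed(ssrs), file.path(out_dir, "ssr.bed"))
  log_line("ssr: %d record(s)", nrow(ssrs))
  results$ssr <- ssrs

  if (!is.null(plastome)) {
    mtpt <- stage("mtpt", {
      pla <- if (is.character(plastome) && file.exists(plastome[1]))
        read_genome_fasta(plastome) else as_genome(plastome)
      rec <- find_mtpt(gen, pla)
      summ <- summarize_mtpt(rec, sum(Biostrings::width(gen)),
                             sum(Biostrings::width(pla)))
      clusters <- if (!is.null(plastome_annotation))
        group_gene_clusters(rec, plastome_annotation) else NULL
      list(records = rec, summary = summ, clusters = clusters)
    })
    write_tsv_report(mtpt$records, file.path(out_dir, "mtpt.tsv"))
    write_bed(mtpt_bed(mtpt$records), file.path(out_dir, "mtpt.bed"))
    write_tsv_report(mtpt$summary, file.path(out_dir, "mtpt_summary.tsv"))
    if (!is.null(mtpt$clusters))
      write_tsv_report(mtpt$clusters, file.path(out_dir, "mtpt_gene_clusters.tsv"))
    log_line("mtpt: %d record(s), %d bp", nrow(mtpt$records),
             mtpt$summary$total_bp)
    results$mtpt <- mtpt
  } else {
    log_line("mtpt: skipped (no plastome supplied)")
  }

  invisible(results)
}
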