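# synthetic genomes, conformation mixtures and noisy long reads with
# known truth
#
# The generator emulates the kind of data the pipeline targets: a small
# multipartite circular genome (default two chromosomes at 44.5% GC,
# matching typical plant-mitogenome composition), planted direct or
# inverted repeat pairs, plastid-derived insertions copied from a
# companion simulated plastome, and PacBio-like long reads (lognormal
# lengths, ~10% error dominated by indels). A single master seed derives
# all per-stage generators by fixed offsets, so identical configurations
# give byte-identical outputs.

#' Simulation configuration
#'
#' @param seed master seed; all stage seeds derive from it
#' @param chrom_lengths circular chromosome lengths in bp
#' @param gc background GC content
#' @param repeats tibble of repeats to plant: `length` (bp), `identity`
#'   (percent), `orientation` ("direct"/"inverted"), `inter` (logical:
#'   copies on two chromosomes)
#' @param mtpt_lengths lengths (bp) of plastome segments to insert into
#'   the mitogenome
#' @param plastome_length length of the companion simulated plastome
#' @param minor_fraction mixture weight of the minor conformation
#' @param n_reads number of reads for [simulate_reads()]
#' @param read_meanlog,read_sdlog lognormal read-length parameters
#' @param read_min,read_max read-length truncation bounds (bp)
#' @param error_rate total per-base error rate
#' @param error_mix relative weights of substitution/insertion/deletion
#'   errors (PacBio-like 1:5:4 by default)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(MC1 = 50000, MC2 = 15000),
                       gc = 0.445,
                       repeats = tibble(length = 300, identity = 100,
                                        orientation = "direct", inter = FALSE),
                       mtpt_lengths = integer(),
                       plastome_length = 30000,
                       minor_fraction = 0.10,
                       n_reads = 500,
                       read_meanlog = log(9000), read_sdlog = 0.5,
                       read_min = 1000, read_max = 40000,
                       error_rate = 0.10,
                       error_mix = c(sub = 1, ins = 5, del = 4)) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  minor_fraction <- check_fraction(minor_fraction, "minor_fraction")
  error_rate <- check_fraction(error_rate, "error_rate")
  structure(list(seed = seed, chrom_lengths = chrom_lengths, gc = gc,
                 repeats = repeats, mtpt_lengths = as.integer(mtpt_lengths),
                 plastome_length = plastome_length,
                 minor_fraction = minor_fraction, n_reads = n_reads,
                 read_meanlog = read_meanlog, read_sdlog = read_sdlog,
                 read_min = read_min, read_max = read_max,
                 error_rate = error_rate,
                 error_mix = error_mix / sum(error_mix)),
            class = "sim_config")
}

random_circle <- function(L, gc) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute bases at n distinct positions (never to the original base)
mutate_substitutions <- function(seq, n) {
  if (n == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(nchar(seq), n)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(bases, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted repeats and MTPT insertions
#'
#' Background residues are i.i.d. at the configured GC. Each repeat is
#' planted by copying a random source locus to a random non-overlapping
#' target locus (reverse-complemented for inverted repeats) and mutating
#' the copy with substitutions to hit the target identity. MTPTs are
#' planted by overwriting mitogenome loci with segments of a companion
#' simulated plastome. Chromosomes must be at least 10 times as long as
#' the largest planted feature.
#'
#' @param config a [sim_config()]
#' @return list with `genome` (DNAStringSet), `plastome` (or NULL),
#'   `truth` (list of `repeats` and `mtpts` tibbles) and `config`
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  feats <- c(config$repeats$length, config$mtpt_lengths, 0)
  if (max(feats) * 10 > min(config$chrom_lengths))
    abort("chromosome lengths must be at least 10x the largest planted feature")
  set.seed(derive_seed(config$seed, 1L))
  chroms <- vapply(config$chrom_lengths, random_circle, character(1),
                   gc = config$gc)
  occupied <- lapply(chroms, function(x) IRanges::IRanges())
  claim <- function(chrom_i, len, margin = 25L) {
    # a free interval of `len` bp with `margin` clearance, or NA
    L <- nchar(chroms[[chrom_i]])
    for (try in 1:200) {
      s <- sample.int(L - len - margin, 1) + margin %/% 2L
      cand <- IRanges::IRanges(s - margin, s + len - 1L + margin)
      if (length(IRanges::findOverlaps(cand, occupied[[chrom_i]])) == 0) {
        occupied[[chrom_i]] <<- c(occupied[[chrom_i]],
                                  IRanges::IRanges(s, s + len - 1L))
        return(s)
      }
    }
    abort("could not place a planted feature without overlap; shorten or enlarge")
  }
  rep_truth <- list()
  reps <- config$repeats
  if (!is.null(reps) && nrow(reps) > 0) {
    for (k in seq_len(nrow(reps))) {
      len <- as.integer(reps$length[k])
      inter <- isTRUE(reps$inter[k])
      c1 <- 1L
      c2 <- if (inter) 2L else 1L
      if (inter && length(chroms) < 2) abort("inter-molecular repeat needs >= 2 chromosomes")
      s1 <- claim(c1, len)
      body <- substr(chroms[[c1]], s1, s1 + len - 1L)
      nmut <- max(0L, round((1 - reps$identity[k] / 100) * len))
      placed <- mutate_substitutions(body, nmut)
      inverted <- identical(reps$orientation[k], "inverted")
      if (inverted) placed <- dna_revcomp(placed)
      s2 <- claim(c2, len)
      substr(chroms[[c2]], s2, s2 + len - 1L) <- placed
      # order copies by position so the truth table matches find_repeats
      ch1 <- names(chroms)[c1]; ch2 <- names(chroms)[c2]
      a <- list(chrom = ch1, start = s1, end = s1 + len - 1L)
      b <- list(chrom = ch2, start = s2, end = s2 + len - 1L)
      if (ch1 == ch2 && b$start < a$start) { tmp <- a; a <- b; b <- tmp }
      rep_truth[[k]] <- tibble(
        repeat_id = sprintf("r%02d", k),
        chrom1 = a$chrom, start1 = a$start, end1 = a$end,
        chrom2 = b$chrom, start2 = b$start, end2 = b$end,
        orientation = reps$orientation[k],
        identity = 100 * (len - nmut) / len,
        aln_length = len,
        inter_molecular = inter)
    }
  }
  plastome <- NULL
  mtpt_truth <- list()
  if (length(config$mtpt_lengths) > 0) {
    plastome <- random_circle(config$plastome_length, config$gc)
    taken_p <- IRanges::IRanges()
    claim_plastid <- function(len, margin = 25L) {
      for (try in 1:200) {
        ps <- sample.int(config$plastome_length - len - margin, 1)
        cand <- IRanges::IRanges(ps - margin, ps + len - 1L + margin)
        if (length(IRanges::findOverlaps(cand, taken_p)) == 0) {
          taken_p <<- c(taken_p, IRanges::IRanges(ps, ps + len - 1L))
          return(ps)
        }
      }
      abort("could not place a plastid source segment without overlap")
    }
    for (k in seq_along(config$mtpt_lengths)) {
      len <- config$mtpt_lengths[k]
      ps <- claim_plastid(len)
      seg <- substr(plastome, ps, ps + len - 1L)
      ms <- claim(1L, len)
      substr(chroms[[1L]], ms, ms + len - 1L) <- seg
      mtpt_truth[[k]] <- tibble(
        mtpt_id = sprintf("mtpt-%03d", k),
        mito_chrom = names(chroms)[1], mito_start = ms, mito_end = ms + len - 1L,
        plastid_chrom = "plastome", plastid_start = ps, plastid_end = ps + len - 1L,
        length = len)
    }
  }
  list(genome = as_genome(chroms),
       plastome = if (is.null(plastome)) NULL else as_genome(c(plastome = plastome)),
       truth = list(repeats = dplyr::bind_rows(rep_truth),
                    mtpts = dplyr::bind_rows(mtpt_truth)),
       config = config)
}

#' Simulate noisy long reads from a mixture of circular molecules
#'
#' Reads start uniformly on a molecule drawn by the mixture weights, on a
#' random strand, with lognormal lengths truncated to the configured
#' bounds (and to the molecule length); errors are injected at the
#' configured rate and substitution/insertion/deletion mix.
#'
#' @param molecules named character vector (or DNAStringSet) of circular
#'   molecule sequences
#' @param weights mixture weights, summing to 1 (recycled uniform if NULL)
#' @param config a [sim_config()]
#' @param n number of reads
#' @param seed_offset stage offset added to the master seed
#' @return list with `reads` (tibble `read_id`, `seq`) and `truth`
#'   (tibble `read_id`, `molecule`, `start`, `strand`, `length`)
#' @export
simulate_reads <- function(molecules, weights = NULL, config = sim_config(),
                           n = config$n_reads, seed_offset = 2L) {
  if (methods::is(molecules, "DNAStringSet"))
    molecules <- setNames(as.character(molecules), names(molecules))
  if (is.null(weights)) weights <- rep(1 / length(molecules), length(molecules))
  if (abs(sum(weights) - 1) > 1e-8) abort("mixture weights must sum to 1")
  set.seed(derive_seed(config$seed, seed_offset))
  mix <- config$error_mix * config$error_rate
  mol_names <- names(molecules)
  out_seq <- character(n); truth <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sample(mol_names, 1, prob = weights)
    L <- nchar(molecules[[m]])
    len <- draw_read_length(config, L)
    s <- sample.int(L, 1)
    e <- ((s + len - 2L) %% L) + 1L
    raw <- extract_circular(molecules[[m]], start = s, end = e)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") raw <- dna_revcomp(raw)
    out_seq[i] <- if (config$error_rate > 0)
      cpp_inject_errors(raw, mix[["sub"]], mix[["ins"]], mix[["del"]]) else raw
    truth[[i]] <- tibble(read_id = sprintf("read%05d", i), molecule = m,
                         start = s, strand = strand, length = len)
  }
  truth <- dplyr::bind_rows(truth)
  list(reads = tibble(read_id = truth$read_id, seq = out_seq), truth = truth)
}

draw_read_length <- function(config, L) {
  for (try in 1:100) {
    len <- round(rlnorm(1, config$read_meanlog, config$read_sdlog))
    if (len >= config$read_min && len <= config$read_max) return(min(len, L))
  }
  min(config$read_min, L)
}

#' Simulate spanning reads over a repeat's junctions at a known minor
#' fraction
#'
#' Draws reads guaranteed to span one of the four junctions of
#' `repeat_pair`: the two major junctions (on the assembly molecules,
#' weight `1 - p` split evenly) and the two minor junctions (on the
#' recombined molecules, weight `p` split evenly). Used to study
#' recovery of a planted minor fraction without wasting reads that never
#' touch the junction region.
#'
#' @param sim output of [simulate_genome()] (genome plus truth)
#' @param repeat_pair one row of the truth repeat table
#' @param p planted minor fraction
#' @param n number of spanning reads
#' @param span_margin bases of flank each read must cover on both sides
#'   of the repeat body
#' @param seed_offset stage offset added to the master seed
#' @return list with `reads`, `truth` (true junction C1..C4 per read)
#' @export
simulate_junction_reads <- function(sim, repeat_pair, p, n,
                                    span_margin = 150, seed_offset = 3L) {
  config <- sim$config
  p <- check_fraction(p, "p")
  mac <- genome_to_molecules(sim$genome, repeat_pair)
  mic <- recombine(mac, repeat_pair$repeat_id[1])
  mac_seqs <- vapply(names(mac$molecules), function(nm)
    realize_sequence(mac, sim$genome, nm), character(1))
  mic_seqs <- vapply(names(mic$molecules), function(nm)
    realize_sequence(mic, sim$genome, nm), character(1))
  # junction positions: each repeat marker's span within its realized molecule
  junction_of <- function(mols, seqs, copy) {
    for (nm in names(mols$molecules)) {
      m <- mols$molecules[[nm]]
      off <- cumsum(c(0, m$length))
      i <- which(m$type == "repeat" & grepl(paste0("/", copy, "$"), m$id))
      if (length(i) == 1)
        return(list(mol = nm, seq = seqs[[nm]], start = off[i] + 1L,
                    end = off[i] + m$length[i]))
    }
    abort("junction not found")
  }
  # after the exchange, the copy-1 marker sits in copy-2's upstream context
  # for a direct repeat (C4) but keeps its own upstream flank when the
  # repeat is inverted (C3)
  inverted <- identical(repeat_pair$orientation[1], "inverted")
  juncs <- list(C1 = junction_of(mac, mac_seqs, 1),
                C2 = junction_of(mac, mac_seqs, 2),
                C3 = junction_of(mic, mic_seqs, if (inverted) 1 else 2),
                C4 = junction_of(mic, mic_seqs, if (inverted) 2 else 1))
  set.seed(derive_seed(config$seed, seed_offset))
  mix <- config$error_mix * config$error_rate
  probs <- c((1 - p) / 2, (1 - p) / 2, p / 2, p / 2)
  lab <- sample(names(juncs), n, replace = TRUE, prob = probs)
  # vectorised draw: lognormal lengths truncated to the configured bounds,
  # then clamped so every read covers its junction plus the margins
  lens <- round(rlnorm(n, config$read_meanlog, config$read_sdlog))
  for (it in 1:50) {
    bad <- lens < config$read_min | lens > config$read_max
    if (!any(bad)) break
    lens[bad] <- round(rlnorm(sum(bad), config$read_meanlog, config$read_sdlog))
  }
  lens[lens < config$read_min | lens > config$read_max] <- config$read_min
  jL <- vapply(juncs, function(j) nchar(j$seq), numeric(1))[lab]
  jstart <- vapply(juncs, `[[`, numeric(1), "start")[lab]
  jend <- vapply(juncs, `[[`, numeric(1), "end")[lab]
  need <- (jend - jstart + 1) + 2 * span_margin
  lens <- pmin(pmax(lens, pmin(need + 200, jL)), jL)
  lo <- jend + span_margin - lens + 1
  hi <- pmax(jstart - span_margin, lo)
  s <- lo + floor(runif(n) * (hi - lo + 1))
  s <- ((s - 1) %% jL) + 1
  doubled <- vapply(juncs, function(j) paste0(j$seq, j$seq), character(1))
  raw <- unname(substring(doubled[lab], s, s + lens - 1))
  flip <- runif(n) < 0.5
  if (any(flip)) raw[flip] <- dna_revcomp(raw[flip])
  out_seq <- if (config$error_rate > 0) {
    vapply(raw, cpp_inject_errors, character(1), sub_rate = mix[["sub"]],
           ins_rate = mix[["ins"]], del_rate = mix[["del"]],
           USE.NAMES = FALSE)
  } else raw
  ids <- sprintf("sread%05d", seq_len(n))
  list(reads = tibble(read_id = ids, seq = out_seq),
       truth = tibble(read_id = ids, conformation = lab))
}

#' Write reads as FASTQ (uniform placeholder qualities)
#'
#' @param reads tibble with `read_id`, `seq`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_reads_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$read_id[i]), reads$seq[i], "+",
                 strrep("I", nchar(reads$seq[i]))), con)
  }
  invisible(path)
}

#' Compare estimated recombination frequencies against planted truth
#'
#' For each repeat, compares the estimated frequency with the planted
#' minor fraction: absolute error, and whether the truth lies inside the
#' Clopper-Pearson 95% interval of the estimate.
#'
#' @param truth tibble with `repeat_id` and `minor_fraction`
#' @param records support-count tibble with `repeat_id`, `mac1`, `mac2`,
#'   `mic1`, `mic2`
#' @param read_labels optional tibble with per-read `truth` and `label`
#'   columns, to add a misclassification rate
#' @return a `recovery_eval` tibble: `repeat_id`, `minor_fraction`,
#'   `estimate`, `ci_lo`, `ci_hi`, `abs_error`, `covered`
#' @export
evaluate_recovery <- function(truth, records, read_labels = NULL) {
  stopifnot(all(c("repeat_id", "minor_fraction") %in% names(truth)))
  missing <- setdiff(truth$repeat_id, records$repeat_id)
  if (length(missing) > 0)
    abort(sprintf("no support record for repeat(s): %s",
                  paste(missing, collapse = ", ")))
  out <- dplyr::inner_join(truth, records, by = "repeat_id")
  res <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
    x <- out$mic1[i] + out$mic2[i]
    nn <- x + out$mac1[i] + out$mac2[i]
    ci <- if (nn > 0) stats::binom.test(x, nn)$conf.int else c(NA_real_, NA_real_)
    est <- if (nn > 0) x / nn else NA_real_
    tibble(repeat_id = out$repeat_id[i],
           minor_fraction = out$minor_fraction[i],
           estimate = est, ci_lo = ci[1], ci_hi = ci[2],
           abs_error = abs(est - out$minor_fraction[i]),
           covered = !is.na(est) & out$minor_fraction[i] >= ci[1] &
             out$minor_fraction[i] <= ci[2])
  })
  if (!is.null(read_labels)) {
    ok <- read_labels$label %in% c("C1", "C2", "C3", "C4")
    attr(res, "misclassification_rate") <-
      mean(read_labels$label[ok] != read_labels$truth[ok])
  }
  class(res) <- c("recovery_eval", class(res))
  res
}

#' One-row summary of a recovery evaluation
#'
#' @param x a `recovery_eval` from [evaluate_recovery()]
#' @param ... unused
#' @return tibble with coverage rate, mean absolute error and repeat count
#' @export
glance.recovery_eval <- function(x, ...) {
  tibble(n_repeats = nrow(x),
         ci_coverage = mean(x$covered, na.rm = TRUE),
         mean_abs_error = mean(x$abs_error, na.rm = TRUE),
         misclassification_rate = attr(x, "misclassification_rate") %||% NA_real_)
}

#' @importFrom generics glance
#' @export
generics::glance
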