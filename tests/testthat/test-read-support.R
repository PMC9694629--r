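# read classification against the four junction conformations and the
# recombination-frequency statistic

support_fixture <- function(seed = 51, orientation = "direct", error = 0.10,
                            n = 120, p = 0.25, flank = 300) {
  cfg <- sim_config(seed = seed, chrom_lengths = c(MC1 = 15000),
                    repeats = tibble::tibble(length = 200, identity = 100,
                                             orientation = orientation,
                                             inter = FALSE),
                    read_meanlog = log(2200), read_sdlog = 0.25,
                    read_min = 1400, read_max = 6000,
                    error_rate = error)
  sim <- simulate_genome(cfg)
  rp <- sim$truth$repeats[1, ]
  js <- build_conformations(sim$genome, rp, flank = flank)
  jr <- simulate_junction_reads(sim, rp, p = p, n = n, span_margin = 150)
  list(sim = sim, rp = rp, js = js, reads = jr$reads, truth = jr$truth)
}

test_that("an error-free conformation sequence classifies as itself", {
  toy <- support_fixture(seed = 52, error = 0, n = 1)
  js <- toy$js
  for (ci in c("C1", "C2", "C3", "C4"))
    expect_equal(classify_read(js$sequences[[ci]], js), ci)
  # and on the opposite strand
  expect_equal(classify_read(dna_revcomp(js$sequences[["C3"]]), js), "C3")
})

test_that("a bare repeat body without flank anchors is unspanning", {
  toy <- support_fixture(seed = 53, error = 0, n = 1)
  body <- substr(toy$js$sequences[["C1"]], toy$js$flank + 1,
                 toy$js$flank + toy$js$body_length[["C1"]])
  expect_equal(classify_read(body, toy$js), "unspanning")
  # unrelated sequence is unspanning too
  set.seed(1)
  expect_equal(classify_read(random_dna(800), toy$js), "unspanning")
})

test_that("labels match simulation truth on error-free junction reads", {
  toy <- support_fixture(seed = 54, error = 0, n = 80)
  got <- classify_reads(toy$reads, toy$js)
  expect_equal(got$label, toy$truth$conformation)
})

test_that("at 10% read error the truth is recovered up to a small remainder", {
  toy <- support_fixture(seed = 55, error = 0.10, n = 120)
  got <- classify_reads(toy$reads, toy$js)
  assigned <- got$label %in% c("C1", "C2", "C3", "C4")
  expect_gte(mean(assigned), 0.95)
  agree <- got$label[assigned] == toy$truth$conformation[assigned]
  # reads spanning both Mac (or both Mic) junctions may legitimately be
  # credited to the sister conformation; Mac/Mic class is what matters
  mic_true <- toy$truth$conformation[assigned] %in% c("C3", "C4")
  mic_got <- got$label[assigned] %in% c("C3", "C4")
  expect_equal(mic_got, mic_true)
  expect_gte(mean(agree), 0.95)
})

test_that("support counting tallies forced mixtures and degenerate inputs", {
  toy <- support_fixture(seed = 56, error = 0, n = 1)
  js <- toy$js
  reads <- c(replicate(7, js$sequences[["C1"]]), replicate(3, js$sequences[["C4"]]))
  names(reads) <- paste0("rd", 1:10)
  cnt <- count_support(reads, js)
  expect_equal(cnt$mac1, 7L)
  expect_equal(cnt$mic2, 3L)
  expect_equal(cnt$mac2 + cnt$mic1 + cnt$ambiguous + cnt$unspanning, 0L)
  empty <- count_support(tibble::tibble(read_id = character(),
                                        seq = character()), js)
  expect_equal(unlist(empty[, c("mac1", "mac2", "mic1", "mic2")]),
               c(mac1 = 0L, mac2 = 0L, mic1 = 0L, mic2 = 0L))
})

test_that("a synthetic minor fraction is recovered within binomial noise", {
  toy <- support_fixture(seed = 57, error = 0.10, n = 500, p = 0.10)
  cnt <- count_support(toy$reads, toy$js)
  mic <- cnt$mic1 + cnt$mic2
  tot <- mic + cnt$mac1 + cnt$mac2
  # within 3 sigma of binomial(tot, 0.10)
  expect_lt(abs(mic - 0.10 * tot), 3 * sqrt(tot * 0.10 * 0.90) + 1)
})

test_that("the frequency statistic reproduces printed worked examples", {
  expect_equal(recombination_frequency(70, 46, 5, 3), 6.45)
  expect_equal(recombination_frequency(31, 28, 5, 11), 21.33)
  expect_equal(recombination_frequency(10, 10, 0, 0), 0)
  expect_warning(out <- recombination_frequency(0, 0, 0, 0), "zero")
  expect_true(is.na(out))
})

test_that("frequency is invariant under swapping the major and the minor pair", {
  set.seed(58)
  for (i in 1:20) {
    v <- sample(0:60, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    expect_equal(recombination_frequency(v[1], v[2], v[3], v[4]),
                 recombination_frequency(v[2], v[1], v[4], v[3]))
  }
})

test_that("raising the anchor requirement never creates spanning reads", {
  toy <- support_fixture(seed = 59, error = 0.10, n = 60)
  a1 <- classify_reads(toy$reads, toy$js, min_anchor = 80)
  a2 <- classify_reads(toy$reads, toy$js, min_anchor = 180)
  newly_spanning <- a1$label == "unspanning" & a2$label != "unspanning"
  expect_false(any(newly_spanning))
})

test_that("active repeats are called from minor support and repeat span", {
  counts <- printed_support_counts()
  called <- call_active_repeats(counts)
  expect_false(called$active[called$repeat_id == "r11"])  # mic1 = 0
  expect_true(called$active[called$repeat_id == "r04"])   # 1 + 1 minor reads
  expect_false(called$active[called$repeat_id == "r10"])  # 5,835 bp > span cap
  expect_equal(called$repeat_id[called$active], sprintf("r%02d", 1:9))
})

test_that("FASTQ and FASTA read input are equivalent (qualities ignored)", {
  toy <- support_fixture(seed = 60, error = 0, n = 6)
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(toy$reads, fq)
  rtab <- read_long_reads(fq)
  expect_equal(rtab$seq, toy$reads$seq)
  fa <- tempfile(fileext = ".fasta")
  write_fasta_lines(setNames(toy$reads$seq, toy$reads$read_id), fa)
  expect_equal(read_long_reads(fa)$seq, toy$reads$seq)
})
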