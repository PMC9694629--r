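test_that("identical configurations give byte-identical genomes and reads", {
  cfg <- sim_config(seed = 91, chrom_lengths = c(A = 8000), n_reads = 30,
                    read_meanlog = log(1500), read_min = 1000, read_max = 4000)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$repeats, b$truth$repeats)
  ra <- simulate_reads(a$genome, config = cfg)
  rb <- simulate_reads(b$genome, config = cfg)
  expect_identical(ra$reads$seq, rb$reads$seq)
  # a different master seed changes the output
  c2 <- simulate_genome(sim_config(seed = 92, chrom_lengths = c(A = 8000)))
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))
})

test_that("background composition hits the configured GC within 1%", {
  cfg <- sim_config(seed = 93, chrom_lengths = c(A = 100000),
                    repeats = tibble::tibble(length = integer(),
                                             identity = numeric(),
                                             orientation = character(),
                                             inter = logical()),
                    gc = 0.445)
  sim <- simulate_genome(cfg)
  s <- as.character(sim$genome[[1]])
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.445), 0.01)
})

test_that("planted truth describes exactly what was planted", {
  cfg <- sim_config(seed = 94, chrom_lengths = c(A = 20000),
                    repeats = tibble::tibble(length = 87, identity = 100,
                                             orientation = "direct",
                                             inter = FALSE))
  sim <- simulate_genome(cfg)
  tr <- sim$truth$repeats
  expect_equal(nrow(tr), 1)
  expect_equal(tr$identity, 100)
  g <- as.character(sim$genome[[1]])
  expect_equal(substr(g, tr$start1, tr$end1), substr(g, tr$start2, tr$end2))
  # identity < 100 plants the stated number of substitutions
  cfg2 <- sim_config(seed = 95, chrom_lengths = c(A = 20000),
                     repeats = tibble::tibble(length = 200, identity = 95,
                                              orientation = "direct",
                                              inter = FALSE))
  sim2 <- simulate_genome(cfg2)
  t2 <- sim2$truth$repeats
  g2 <- as.character(sim2$genome[[1]])
  d <- mapply(function(a, b) a != b,
              strsplit(substr(g2, t2$start1, t2$end1), "")[[1]],
              strsplit(substr(g2, t2$start2, t2$end2), "")[[1]])
  expect_equal(sum(d), 10)  # 5% of 200
})

test_that("chromosomes must dwarf the largest planted feature", {
  cfg <- sim_config(seed = 96, chrom_lengths = c(A = 2000),
                    repeats = tibble::tibble(length = 300, identity = 100,
                                             orientation = "direct",
                                             inter = FALSE))
  expect_error(simulate_genome(cfg), "10x")
})

test_that("error-free reads are exact wrap-aware substrings of their molecule", {
  cfg <- sim_config(seed = 97, chrom_lengths = c(A = 6000), n_reads = 40,
                    read_meanlog = log(1500), read_sdlog = 0.3,
                    read_min = 800, read_max = 4000, error_rate = 0)
  sim <- simulate_genome(cfg)
  rr <- simulate_reads(sim$genome, config = cfg)
  doubled <- vapply(as.character(sim$genome), function(s) paste0(s, s),
                    character(1))
  for (i in seq_len(nrow(rr$reads))) {
    s <- rr$reads$seq[i]
    mol <- doubled[[rr$truth$molecule[i]]]
    expect_true(grepl(s, mol, fixed = TRUE) ||
                  grepl(dna_revcomp(s), mol, fixed = TRUE))
  }
})

test_that("mixture weights control molecule provenance binomially", {
  cfg <- sim_config(seed = 98, chrom_lengths = c(A = 6000, B = 6000),
                    repeats = tibble::tibble(length = integer(),
                                             identity = numeric(),
                                             orientation = character(),
                                             inter = logical()),
                    n_reads = 2000, read_meanlog = log(1200),
                    read_min = 800, read_max = 3000, error_rate = 0)
  sim <- simulate_genome(cfg)
  rr <- simulate_reads(sim$genome, weights = c(0.9, 0.1), config = cfg)
  frac_b <- mean(rr$truth$molecule == "B")
  expect_lt(abs(frac_b - 0.10), 3 * sqrt(0.1 * 0.9 / 2000))
})

test_that("read lengths respect the truncation bounds", {
  cfg <- sim_config(seed = 99, chrom_lengths = c(A = 60000), n_reads = 200,
                    repeats = tibble::tibble(length = integer(),
                                             identity = numeric(),
                                             orientation = character(),
                                             inter = logical()),
                    read_min = 2000, read_max = 10000)
  sim <- simulate_genome(cfg)
  rr <- simulate_reads(sim$genome, config = cfg)
  expect_true(all(rr$truth$length >= 2000 & rr$truth$length <= 10000))
})

test_that("recovery evaluation flags coverage and errors of the estimate", {
  truth <- tibble::tibble(repeat_id = "r01", minor_fraction = 0)
  rec0 <- tibble::tibble(repeat_id = "r01", mac1 = 200L, mac2 = 190L,
                         mic1 = 0L, mic2 = 0L, aln_length = 300L)
  ev <- evaluate_recovery(truth, rec0)
  expect_equal(ev$estimate, 0)
  expect_true(ev$covered)
  expect_false(call_active_repeats(rec0)$active)
  # symmetric mixture: the estimate is unbiased at the centre
  truth5 <- tibble::tibble(repeat_id = "r01", minor_fraction = 0.5)
  rec5 <- tibble::tibble(repeat_id = "r01", mac1 = 250L, mac2 = 240L,
                         mic1 = 255L, mic2 = 245L)
  ev5 <- evaluate_recovery(truth5, rec5)
  expect_true(ev5$covered)
  expect_lt(ev5$abs_error, 0.05)
  g <- glance(ev5)
  expect_equal(g$ci_coverage, 1)
  expect_error(evaluate_recovery(tibble::tibble(repeat_id = "rX",
                                                minor_fraction = 0.1), rec5),
               "rX")
})
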