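make_repeat_genome <- function(seed, L = 8000, len = 200,
                               orientation = "direct", identity = 100,
                               inter = FALSE) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = if (inter) c(A = L, B = ceiling(L / 2))
                                    else c(A = L),
                    repeats = tibble::tibble(length = len, identity = identity,
                                             orientation = orientation,
                                             inter = inter))
  simulate_genome(cfg)
}

test_that("a planted exact duplication is recovered as one direct repeat pair", {
  sim <- make_repeat_genome(31, len = 200)
  found <- find_repeats(sim$genome)
  expect_equal(nrow(found), 1)
  expect_equal(found$orientation, "direct")
  expect_equal(found$identity, 100)
  tr <- sim$truth$repeats
  # seed extension may legitimately include boundary bases that happen to
  # match; compare against the maximal exact extension of the planted pair
  g <- as.character(sim$genome[[1]])
  true_len <- exact_extension(g, tr$start1, tr$end1, g, tr$start2, tr$end2)
  expect_equal(found$aln_length, true_len)
  expect_lte(found$start1, tr$start1)
  expect_gte(found$end1, tr$end1)
})

test_that("a planted reverse-complemented copy is reported as inverted", {
  sim <- make_repeat_genome(32, len = 300, orientation = "inverted")
  found <- find_repeats(sim$genome)
  expect_equal(nrow(found), 1)
  expect_equal(found$orientation, "inverted")
  expect_gte(found$aln_length, 300)
  expect_false(found$inter_molecular)
})

test_that("an 87 bp exact direct pair in a 5 kb genome matches its planted profile", {
  cfg <- sim_config(seed = 33, chrom_lengths = c(A = 5000),
                    repeats = tibble::tibble(length = 87, identity = 100,
                                             orientation = "direct",
                                             inter = FALSE))
  sim <- simulate_genome(cfg)
  found <- find_repeats(sim$genome)
  expect_equal(nrow(found), 1)
  expect_equal(found$identity, 100)
  expect_equal(found$mismatches, 0)
  expect_equal(found$gap_opens, 0)
  tr <- sim$truth$repeats
  g <- as.character(sim$genome[[1]])
  expect_equal(found$aln_length,
               exact_extension(g, tr$start1, tr$end1, g, tr$start2, tr$end2))
})

test_that("inter-molecular repeats carry the flag and both chromosome ids", {
  sim <- make_repeat_genome(34, L = 8000, len = 150, inter = TRUE)
  found <- find_repeats(sim$genome)
  expect_equal(nrow(found), 1)
  expect_true(found$inter_molecular)
  expect_setequal(c(found$chrom1, found$chrom2), c("A", "B"))
})

test_that("repeat discovery is invariant under chromosome rotation", {
  sim <- make_repeat_genome(35, L = 6000, len = 250)
  g <- as.character(sim$genome[[1]])
  base <- find_repeats(sim$genome)
  profile <- function(x) x[order(x$aln_length), c("orientation", "aln_length", "identity")]
  for (off in c(1500, 4200)) {
    rot <- paste0(substr(g, off + 1, nchar(g)), substr(g, 1, off))
    fr <- find_repeats(as_genome(c(A = rot)))
    expect_equal(profile(fr), profile(base))
  }
  # including a rotation that places the repeat across the origin
  tr <- sim$truth$repeats
  off <- tr$start1 + 100  # copy1 now wraps
  rot <- paste0(substr(g, off + 1, nchar(g)), substr(g, 1, off))
  fr <- find_repeats(as_genome(c(A = rot)))
  expect_equal(profile(fr), profile(base))
})

test_that("reported repeats realign at the reported loci with at least the reported identity", {
  sim <- make_repeat_genome(36, L = 9000, len = 400, identity = 94)
  found <- find_repeats(sim$genome)
  expect_equal(nrow(found), 1)
  g <- sim$genome
  s1 <- extract_circular(g, found$chrom1, found$start1, found$end1)
  s2 <- extract_circular(g, found$chrom2, found$start2, found$end2)
  if (found$orientation == "inverted") s2 <- dna_revcomp(s2)
  pa <- Biostrings::pairwiseAlignment(s1, s2, type = "global")
  oracle_ident <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  expect_gte(oracle_ident, found$identity - 0.5)
  expect_equal(found$identity, 94, tolerance = 0.02)
})

test_that("mirror duplicates are collapsed and copy1 is the smaller locus", {
  sim <- make_repeat_genome(37, len = 220)
  found <- find_repeats(sim$genome)
  expect_equal(nrow(found), 1)
  expect_lte(found$start1, found$start2)
})

test_that("outfmt-6 tables parse with orientation from subject coordinates", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("MC1", "MC1", "99.853", "682", "1", "0", "279954", "280635",
            "235468", "234787", "0", "1255"), collapse = "\t"),
    paste(c("MC1", "MC1", "100", "87", "0", "0", "185367", "185453",
            "1433", "1519", "2.72e-38", "161"), collapse = "\t"),
    paste(c("MC1", "MC2", "100", "127", "1", "1", "328831", "328915",
            "85115", "85199", "3.51e-37", "230"), collapse = "\t")), tf)
  tab <- parse_hsp_table(tf)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$orientation, c("inverted", "direct", "direct"))
  expect_equal(tab$aln_length[1], 682L)
  expect_equal(tab$start2[1], 234787L)  # normalised to (min, max)
  expect_equal(tab$inter_molecular, c(FALSE, FALSE, TRUE))
})

test_that("malformed HSP rows fail with the line number", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("a", "b", "90", "100", "1", "0", "1", "100", "1",
                       "100", "0"), collapse = "\t"),
               "too\tfew\tfields"), tf)
  expect_error(parse_hsp_table(tf), "line 2")
})
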