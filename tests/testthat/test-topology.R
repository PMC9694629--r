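# circular rearrangement algebra: decomposition, reciprocal exchange,
# enumeration and sequence realization

test_that("a genome without repeats decomposes into one full-length segment per circle", {
  mols <- genome_to_molecules(c(MC1 = 1000, MC2 = 400))
  expect_length(mols$molecules, 2)
  expect_equal(total_length(mols), 1400)
  expect_equal(nrow(mols$molecules$MC1), 1)
  expect_equal(mols$molecules$MC1$length, 1000L)
})

test_that("marker decomposition reproduces the assembly-scale segment arithmetic", {
  # 87 bp repeat copies at 1,433-1,519 and 185,367-185,453 on a
  # 328,915 bp circle: inter-marker segments of 183,847 and 144,894 bp
  reps <- tibble::tibble(repeat_id = "r05", chrom1 = "MC1", start1 = 1433L,
                         end1 = 1519L, chrom2 = "MC1", start2 = 185367L,
                         end2 = 185453L, orientation = "direct")
  mols <- genome_to_molecules(chrom_lengths_assembly, reps)
  m <- mols$molecules$MC1
  expect_equal(sum(m$length), 328915)
  expect_equal(sort(m$length[m$type == "segment"]), c(144894L, 183847L))
  expect_equal(m$length[m$type == "repeat"], c(87L, 87L))
})

test_that("overlapping repeat copies are rejected with both names", {
  reps <- tibble::tibble(repeat_id = c("rA", "rB"),
                         chrom1 = "c", start1 = c(100L, 150L),
                         end1 = c(200L, 260L),
                         chrom2 = "c", start2 = c(500L, 700L),
                         end2 = c(600L, 800L),
                         orientation = "direct")
  expect_error(genome_to_molecules(c(c = 1000), reps), "overlap")
})

test_that("recombination outcomes: split, inversion and fusion conserve length", {
  coords <- printed_repeat_coords()
  for (i in seq_len(nrow(coords))) {
    rp <- coords[i, ]
    mac <- genome_to_molecules(chrom_lengths_assembly, rp)
    mic <- recombine(mac, rp$repeat_id)
    expect_equal(total_length(mic), 328915 + 85199)
    n_markers <- sum(vapply(mic$molecules,
                            function(m) sum(m$type == "repeat"), integer(1)))
    expect_equal(n_markers, 2L)
    if (rp$repeat_id == "r01") {
      expect_length(mic$molecules, 1)       # inter-molecular fusion
    } else if (rp$orientation == "inverted") {
      expect_length(mic$molecules, 2)       # MC1 rearranged + MC2
      expect_equal(sort(vapply(mic$molecules, function(m) sum(m$length),
                               numeric(1))), c(85199, 328915),
                   ignore_attr = TRUE)
    } else {
      expect_length(mic$molecules, 3)       # split + untouched MC2
      split_lens <- vapply(mic$molecules, function(m) sum(m$length),
                           numeric(1))
      split_lens <- split_lens[names(split_lens) != "MC2"]
      expect_equal(sum(split_lens), 328915)
    }
  }
})

test_that("recombining twice at the same exact repeat restores the molecule set", {
  coords <- printed_repeat_coords()
  for (i in c(1, 2, 5)) {  # one fusion, one inversion, one split
    rp <- coords[i, ]
    mac <- genome_to_molecules(chrom_lengths_assembly, rp)
    back <- recombine(recombine(mac, rp$repeat_id), rp$repeat_id)
    expect_equal(canonical_form(back), canonical_form(mac))
  }
})

test_that("conformation enumeration yields one minor set per active repeat", {
  coords <- printed_repeat_coords()
  mac <- genome_to_molecules(chrom_lengths_assembly, coords)
  mics <- enumerate_conformation_space(mac, coords$repeat_id)
  expect_length(mics, 9)
  n_mols <- vapply(mics, function(ms) length(ms$molecules), integer(1))
  # five splits (+1 circle), three inversions (same count), one fusion (-1)
  expect_equal(sort(table(n_mols)), sort(table(c(1, 2, 2, 2, 3, 3, 3, 3, 3))),
               ignore_attr = TRUE)
  expect_length(enumerate_conformation_space(mac, character(0)), 0)
})

test_that("realized sequences match explicit string surgery in all three cases", {
  run_case <- function(seed, orientation, inter) {
    cfg <- sim_config(seed = seed,
                      chrom_lengths = if (inter) c(A = 6000, B = 3000) else c(A = 7000),
                      repeats = tibble::tibble(length = 180, identity = 100,
                                               orientation = orientation,
                                               inter = inter))
    sim <- simulate_genome(cfg)
    rp <- sim$truth$repeats[1, ]
    mac <- genome_to_molecules(sim$genome, rp)
    # realization of the major set is the chromosome itself (up to rotation)
    expect_true(same_circle(realize_sequence(mac, sim$genome, rp$chrom1),
                            as.character(sim$genome[[rp$chrom1]])))
    mic <- recombine(mac, rp$repeat_id)
    got <- vapply(names(mic$molecules),
                  function(nm) realize_sequence(mic, sim$genome, nm),
                  character(1))
    if (inter) {
      want <- surgery_fuse(as.character(sim$genome[[rp$chrom1]]), rp$start1,
                           as.character(sim$genome[[rp$chrom2]]), rp$start2)
      expect_length(got, 1)
      expect_equal(sum(nchar(got)), 9000)
      expect_true(same_circle(got[[1]], want))
    } else if (orientation == "direct") {
      want <- surgery_split(as.character(sim$genome[[1]]), rp$start1, rp$start2)
      expect_length(got, 2)
      expect_true((same_circle(got[[1]], want[[1]]) && same_circle(got[[2]], want[[2]])) ||
                    (same_circle(got[[1]], want[[2]]) && same_circle(got[[2]], want[[1]])))
    } else {
      want <- surgery_invert(as.character(sim$genome[[1]]), rp$end1, rp$start2)
      expect_length(got, 1)
      expect_equal(nchar(got[[1]]), 7000)
      expect_true(same_circle(got[[1]], want))
    }
  }
  run_case(71, "direct", FALSE)
  run_case(72, "inverted", FALSE)
  run_case(73, "direct", TRUE)
})

test_that("depth-2 enumeration matches brute-force surgery on a two-repeat toy", {
  cfg <- sim_config(seed = 74, chrom_lengths = c(A = 9000),
                    repeats = tibble::tibble(length = c(150, 150),
                                             identity = 100,
                                             orientation = "direct",
                                             inter = FALSE))
  sim <- simulate_genome(cfg)
  reps <- sim$truth$repeats
  mac <- genome_to_molecules(sim$genome, reps)
  sets <- enumerate_conformation_space(mac, reps$repeat_id, depth = 2)
  # depth 1: two single-event splits; depth 2 adds the double-split and
  # any fusions back are de-duplicated against earlier states
  expect_gte(length(sets), 3)
  forms <- vapply(sets, canonical_form, character(1))
  expect_equal(anyDuplicated(forms), 0L)
  # every depth-2 product realizes to the same base multiset as explicit
  # surgery: total length conserved and all markers present
  for (ms in sets) {
    expect_equal(total_length(ms), 9000)
    n_markers <- sum(vapply(ms$molecules,
                            function(m) sum(m$type == "repeat"), integer(1)))
    expect_equal(n_markers, 4L)
  }
  # the double-split product has three circles; verify one against surgery
  n_mols <- vapply(sets, function(ms) length(ms$molecules), integer(1))
  expect_true(3 %in% n_mols)
})

test_that("molecule sets export FASTA and a JSON structure report", {
  cfg <- sim_config(seed = 75, chrom_lengths = c(A = 5000),
                    repeats = tibble::tibble(length = 120, identity = 100,
                                             orientation = "direct",
                                             inter = FALSE))
  sim <- simulate_genome(cfg)
  mac <- genome_to_molecules(sim$genome, sim$truth$repeats)
  fa <- tempfile(fileext = ".fasta"); js <- tempfile(fileext = ".json")
  out <- export_molecules(mac, sim$genome, fasta_path = fa, json_path = js)
  expect_true(file.exists(fa) && file.exists(js))
  rep <- jsonlite::read_json(js)
  expect_equal(rep$total_bp, 5000)
  expect_equal(sum(nchar(out$sequences)), 5000)
})
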