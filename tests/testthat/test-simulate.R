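test_that("genome construction records the planted truth and is deterministic", {
  set.seed(100)
  spec <- planted_array_spec(rnd_dna(28), c(32, 30, 35), genome_offset = 500)
  g1 <- make_genomes(1, 0, 5000, list(spec), seed = 7)
  expect_equal(nrow(g1$truth), 3)
  expect_equal(nchar(g1$genomes$residues), 5000)
  expect_equal(g1$truth$sequence,
               substring(g1$genomes$residues,
                         g1$truth$start + 1, g1$truth$end))
  g2 <- make_genomes(1, 0, 5000, list(spec), seed = 7)
  expect_identical(g1, g2)

  g3 <- make_genomes(0, 5, 2000, list(), seed = 3)
  expect_equal(nrow(g3$truth), 0)
  expect_equal(nrow(g3$genomes), 5)

  bad <- planted_array_spec(rnd_dna(28), c(32, 30), genome_offset = 4900)
  expect_error(make_genomes(1, 0, 5000, list(bad), seed = 1), "exceeds")
  two <- list(list(planted_array_spec(rnd_dna(28), c(30, 30), 100),
                   planted_array_spec(rnd_dna(28), c(30, 30), 150)))
  expect_error(make_genomes(1, 0, 5000, two, seed = 1), "overlap")
})

test_that("error-free reads are exact genome substrings; sd 0 fixes lengths", {
  set.seed(101)
  gen <- make_genomes(1, 1, 4000,
                      list(planted_array_spec(rnd_dna(28), c(30, 32), 900)),
                      seed = 11)
  reads <- simulate_reads(gen$genomes,
                          read_sim_params(n_reads = 60, read_length_sd = 0,
                                          read_length_mean = 300, seed = 5))
  expect_true(all(nchar(reads$residues) == 300))
  for (i in seq_len(nrow(reads))) {
    d <- strsplit(reads$description[i], ":")[[1]]
    span <- as.integer(strsplit(d[2], "-")[[1]])
    origin <- substring(gen$genomes$residues[gen$genomes$id == d[1]],
                        span[1] + 1, span[2])
    if (d[3] == "-") origin <- reverse_complement(origin)
    expect_identical(reads$residues[i], origin)
  }
})

test_that("the substitution ramp yields the expected mean error rate", {
  set.seed(102)
  gen <- make_genomes(0, 1, 20000, list(), seed = 13)
  p1 <- 0.02
  reads <- simulate_reads(gen$genomes,
                          read_sim_params(n_reads = 1500, p0 = 0, p1 = p1,
                                          read_length_sd = 0,
                                          read_length_mean = 400, seed = 9))
  nerr <- 0; nbase <- 0
  for (i in seq_len(nrow(reads))) {
    d <- strsplit(reads$description[i], ":")[[1]]
    span <- as.integer(strsplit(d[2], "-")[[1]])
    origin <- substring(gen$genomes$residues, span[1] + 1, span[2])
    if (d[3] == "-") origin <- reverse_complement(origin)
    nerr <- nerr + sum(strsplit(reads$residues[i], "")[[1]] !=
                         strsplit(origin, "")[[1]])
    nbase <- nbase + nchar(origin)
  }
  # mean of the linear 0 -> p1 ramp is p1/2
  expect_equal(nerr / nbase, p1 / 2, tolerance = 0.1)
})

test_that("paired mode emits fragment-end mates at the stated insert", {
  set.seed(103)
  gen <- make_genomes(0, 1, 5000, list(), seed = 17)
  reads <- simulate_reads(gen$genomes,
                          read_sim_params(n_reads = 10, paired = TRUE,
                                          insert = 300,
                                          read_length_mean = 150, seed = 3))
  expect_equal(nrow(reads), 20)
  expect_true(all(nchar(reads$residues) == 150))
  r1 <- reads[seq(1, 20, 2), ]; r2 <- reads[seq(2, 20, 2), ]
  for (i in 1:10) {
    d <- strsplit(r1$description[i], ":")[[1]]
    span <- as.integer(strsplit(d[2], "-")[[1]])
    expect_equal(span[2] - span[1], 300)
    frag <- substring(gen$genomes$residues, span[1] + 1, span[2])
    if (d[3] == "-") frag <- reverse_complement(frag)
    expect_identical(r1$residues[i], substr(frag, 1, 150))
    expect_identical(r2$residues[i],
                     reverse_complement(substr(frag, 151, 300)))
  }
})

test_that("identity matching honors the strand rule and the threshold", {
  set.seed(104)
  known <- seq_records(replicate(5, rnd_dna(32)), id = paste0("k", 1:5))
  # exact strings match at 1.0
  m <- cluster_at_identity(known, known, 1.0)
  expect_true(all(m$matched))
  # reverse complements match at 1.0
  rc <- known; rc$residues <- reverse_complement(rc$residues)
  expect_true(all(cluster_at_identity(rc, known, 1.0)$matched))
  # one mismatch over 32 nt: 31/32 = 0.969
  mut <- known[1, ]
  substr(mut$residues, 16, 16) <-
    setdiff(c("A", "C", "G", "T"), substr(mut$residues, 16, 16))[1]
  expect_false(cluster_at_identity(mut, known, 1.0)$matched)
  expect_true(cluster_at_identity(mut, known, 0.96)$matched[1])
})

test_that("evaluation counts tp/fp/fn under the 100%-identity rule", {
  set.seed(105)
  truth <- seq_records(replicate(8, rnd_dna(32)), id = paste0("t", 1:8))
  self <- evaluate_predictions(truth, truth)
  expect_equal(self$sensitivity, 1.0)
  expect_equal(self$precision, 1.0)

  half <- evaluate_predictions(truth[1:4, ], truth)
  expect_equal(half$sensitivity, 0.5)
  expect_equal(half$precision, 1.0)

  noisy <- rbind(truth, seq_records(replicate(2, rnd_dna(32)),
                                    id = c("d1", "d2")))
  dec <- evaluate_predictions(noisy, truth)
  expect_equal(dec$sensitivity, 1.0)
  expect_equal(dec$precision, 0.8)

  none <- evaluate_predictions(truth[0, ], truth)
  expect_true(is.na(none$precision))
  expect_equal(none$sensitivity, 0.0)
})

test_that("read errors degrade read-level detection monotonically", {
  set.seed(106)
  spec <- planted_array_spec(rnd_dna(28), c(32, 30, 34), genome_offset = 2400)
  gen <- make_genomes(1, 0, 5000, list(spec), seed = 23)
  repeat_db <- fixture_repeat_db(planted = spec$repeat_seq)
  cas_db <- fixture_cas_db()
  truth <- truth_records(gen$truth)
  score <- function(p1) {
    reads <- simulate_reads(gen$genomes,
                            read_sim_params(n_reads = 250, p0 = 0, p1 = p1,
                                            read_length_mean = 450,
                                            read_length_sd = 0, seed = 31))
    ev <- validate_all(reads, cas_db, repeat_db)
    sp <- extract_bona_fide_spacers(ev, "liberal")
    evaluate_predictions(sp, truth)
  }
  r0 <- score(0); r2 <- score(0.02); r8 <- score(0.08)
  expect_equal(r0$sensitivity, 1.0)
  expect_equal(r0$precision, 1.0)
  expect_true(r0$sensitivity >= r2$sensitivity)
  expect_true(r2$sensitivity >= r8$sensitivity || r2$precision >= r8$precision)
  expect_true(r8$sensitivity < 1.0 || r8$precision < 1.0)
})
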