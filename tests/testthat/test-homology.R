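nt_mat <- function(match, mismatch) {
  m <- matrix(mismatch, 4, 4); diag(m) <- match; m
}

test_that("lambda solves the Karlin sum condition", {
  # +1/-1 uniform DNA: 0.25*x + 0.75/x = 1 with x = e^lambda -> x = 3
  lam <- solve_lambda(nt_mat(1, -1), rep(0.25, 4))
  expect_equal(lam, log(3), tolerance = 1e-9)

  # +1/-2 uniform DNA vs an independent bisection oracle
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lo <- 1e-9; hi <- 5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(solve_lambda(nt_mat(1, -2), rep(0.25, 4)), (lo + hi) / 2,
               tolerance = 1e-9)

  # non-negative expected score has no positive root
  expect_error(solve_lambda(nt_mat(1, 0), rep(0.25, 4)), "lambda")
})

test_that("ungapped nucleotide statistics agree with published reference values", {
  # the +1/-2 ungapped parameters are tabulated for the standard tool:
  # lambda 1.33271, K 0.620857
  s <- nt_scheme(match = 1, mismatch = -2)
  expect_equal(s$lambda, 1.33271, tolerance = 2e-4)
  expect_equal(s$K, 0.620857, tolerance = 0.02)
})

test_that("E-values fall and bit scores rise with raw score, linearly in n", {
  s <- nt_scheme()
  raw <- 10:40
  ev <- evalue(raw, 30, 1e6, s)
  expect_true(all(diff(ev) < 0))
  expect_true(all(diff(bit_score(raw, s)) > 0))
  expect_equal(evalue(25, 30, 2e6, s) / evalue(25, 30, 1e6, s), 2)
})

test_that("doubling the database doubles every HSP's E-value exactly", {
  set.seed(31)
  contig <- rnd_dna(400)
  q <- seq_records(substr(contig, 100, 135), id = "q")
  db1 <- build_search_db(seq_records(contig, id = "c1"), 7)
  db2 <- build_search_db(seq_records(c(contig, rnd_dna(400)),
                                     id = c("c1", "c2")), 7)
  h1 <- search_nt(q, db1, e_max = 10)
  h2 <- search_nt(q, db2, e_max = 10)
  h2 <- h2[h2$subject_id == "c1", ]
  expect_equal(h2$raw_score, h1$raw_score)
  expect_equal(h2$evalue, 2 * h1$evalue)
})

test_that("an exact substring match is recovered in full", {
  set.seed(32)
  contig <- rnd_dna(300)
  q <- seq_records(substr(contig, 51, 80), id = "sp")  # 30 nt
  db <- build_search_db(seq_records(contig, id = "c"), 7)
  h <- search_nt(q, db, e_max = 10)
  top <- h[1, ]
  expect_equal(top$identities, 30L)
  expect_equal(top$mismatches, 0L)
  expect_equal(top$gap_openings, 0L)
  expect_equal(top$s_start, 50L)
  expect_equal(top$s_end, 80L)
  expect_equal(top$strand_or_frame, "+")
})

test_that("no shared word and short queries give empty results, not errors", {
  db <- build_search_db(seq_records(strrep("AC", 100), id = "c"), 7)
  h <- search_nt(seq_records(strrep("GT", 20), id = "q"), db, e_max = 10)
  # GTGT... is the revcomp of ACAC...: hits only on the minus strand
  expect_true(all(h$strand_or_frame == "-"))
  h2 <- search_nt(seq_records("GGGGGGGGGGGGGGGGGGGG", id = "q"), db, e_max = 10)
  expect_equal(nrow(h2), 0)
  h3 <- search_nt(seq_records("ACGT", id = "q"), db, word_size = 7, e_max = 10)
  expect_equal(nrow(h3), 0)  # word longer than the query
})

test_that("seeded nucleotide search equals the Smith-Waterman oracle", {
  set.seed(33)
  for (i in 1:60) {
    qlen <- sample(30:60, 1)
    q <- rnd_dna(qlen)
    sub <- q
    # two substitutions spaced > word size apart keep an exact 7-word
    p1 <- 10; p2 <- min(qlen - 2, 10 + 15)
    for (p in c(p1, p2))
      substr(sub, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(q, p, p)), 1)
    if (i %% 3 == 0) # occasionally add a gap
      sub <- paste0(substr(sub, 1, 20), "A", substr(sub, 21, nchar(sub)))
    subject <- paste0(rnd_dna(40), sub, rnd_dna(40))
    db <- build_search_db(seq_records(subject, id = "s"), 7)
    h <- search_nt(seq_records(q, id = "q"), db, e_max = 1e6)
    expect_gt(nrow(h), 0)
    expect_equal(max(h$raw_score), sw_oracle_nt(q, subject))
  }
})

test_that("translated search finds protein-level matches in the right frame", {
  set.seed(34)
  prot <- rnd_protein(40)
  db <- build_search_db(seq_records(prot, id = "p1", kind = "protein"),
                        4, "protein")
  # back-translate to a frame-0 query (one codon per aa; pick any codon)
  gc <- Biostrings::GENETIC_CODE
  codon_of <- vapply(strsplit(prot, "")[[1]],
                     function(a) names(gc)[gc == a][1], character(1))
  qdna <- paste(codon_of, collapse = "")
  h <- search_translated(seq_records(qdna, id = "q"), db, e_max = 1e-6)
  expect_gt(nrow(h), 0)
  expect_equal(h$identities[1], 40L)
  expect_equal(h$strand_or_frame[1], "+1")

  # the reverse-complemented query matches on a minus frame
  hr <- search_translated(seq_records(reverse_complement(qdna), id = "qr"),
                          db, e_max = 1e-6)
  expect_gt(nrow(hr), 0)
  expect_equal(hr$strand_or_frame[1], "-1")

  # a stop-riddled query finds nothing at a stringent cutoff
  stopq <- paste(rep("TAA", 60), collapse = "")
  expect_equal(nrow(search_translated(seq_records(stopq, id = "sq"), db,
                                      e_max = 1e-12)), 0)
})

test_that("translated search scores equal the protein Smith-Waterman oracle", {
  set.seed(35)
  for (i in 1:10) {
    prot <- rnd_protein(60)
    mut <- prot
    for (p in c(15, 40))
      substr(mut, p, p) <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                          substr(prot, p, p)), 1)
    subject <- paste0(rnd_protein(20), mut, rnd_protein(20))
    db <- build_search_db(seq_records(subject, id = "s", kind = "protein"),
                          4, "protein")
    h <- search_translated(seq_records(prot, id = "q", kind = "protein"), db,
                           e_max = 1e6, query_is_protein = TRUE)
    expect_gt(nrow(h), 0)
    expect_equal(max(h$raw_score), sw_oracle_aa(prot, subject))
  }
})

test_that("results are independent of record insertion order", {
  set.seed(36)
  recs <- seq_records(replicate(6, rnd_dna(200)), id = paste0("c", 1:6))
  q <- seq_records(substr(recs$residues[3], 40, 75), id = "q")
  h1 <- search_nt(q, build_search_db(recs, 7), e_max = 10)
  h2 <- search_nt(q, build_search_db(recs[sample(1:6), ], 7), e_max = 10)
  expect_equal(h1, h2)
})

test_that("hit tables are written in the 12-column layout", {
  set.seed(37)
  contig <- rnd_dna(200)
  db <- build_search_db(seq_records(contig, id = "c"), 7)
  h <- search_nt(seq_records(substr(contig, 20, 55), id = "q"), db, e_max = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(h, f)
  tab <- read.delim(f, header = FALSE)
  expect_equal(ncol(tab), 12)
  expect_equal(tab$V1[1], "q")
})
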