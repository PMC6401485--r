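test_that("virome sequences carrying arrays are removed before matching", {
  set.seed(81)
  fx <- planted_record(rnd_dna(28), c(30, 30, 31), flank = 400, id = "v1")
  virome <- rbind(fx$record,
                  seq_records(replicate(9, rnd_dna(800)),
                              id = paste0("v", 2:10)))
  out <- suppressWarnings(remove_array_bearing_sequences(
    virome, fixture_cas_db(), fixture_repeat_db(planted = fx$repeat_seq)))
  expect_equal(nrow(out), 9)
  expect_equal(attr(out, "dropped"), "v1")
  # idempotent: a second pass changes nothing
  out2 <- suppressWarnings(remove_array_bearing_sequences(
    out, fixture_cas_db(), fixture_repeat_db(planted = fx$repeat_seq)))
  expect_equal(out2$id, out$id)
  # array-free input passes through unchanged
  clean <- seq_records(replicate(3, rnd_dna(500)), id = paste0("c", 1:3))
  kept <- suppressWarnings(remove_array_bearing_sequences(clean))
  expect_equal(kept$id, clean$id)
})

test_that("an all-array virome empties with a warning", {
  set.seed(82)
  reps <- replicate(2, rnd_dna(28))
  virome <- rbind(planted_record(reps[1], c(30, 30, 31), 300, id = "a1")$record,
                  planted_record(reps[2], c(33, 34, 33), 300, id = "a2")$record)
  expect_warning(
    out <- remove_array_bearing_sequences(
      virome, fixture_cas_db(), fixture_repeat_db(planted = reps)),
    "every virome sequence")
  expect_equal(nrow(out), 0)
})

test_that("spacer matching keeps one best HSP per contig", {
  set.seed(83)
  spacer <- rnd_dna(32)
  # contig carries the spacer twice; a second contig shares no 7-mer
  contig1 <- paste0(rnd_dna(200), spacer, rnd_dna(100), spacer, rnd_dna(200))
  contig2 <- strrep("AC", 200)
  db <- build_search_db(seq_records(c(contig1, contig2),
                                    id = c("c1", "c2")), 7)
  h <- match_spacers(seq_records(spacer, id = "sp1"), db)
  expect_equal(nrow(h), 1)
  expect_equal(h$subject_id, "c1")
  expect_equal(h$mismatches, 0L)
  # a mismatched spacer is retained iff its E-value clears the cutoff
  sp2 <- spacer
  substr(sp2, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(sp2, 10, 10))[1]
  substr(sp2, 22, 22) <- setdiff(c("A", "C", "G", "T"), substr(sp2, 22, 22))[1]
  h2 <- match_spacers(seq_records(sp2, id = "sp2"), db)
  expect_equal(nrow(h2), 1)
  expect_lte(h2$evalue, 0.1)
  expect_equal(h2$raw_score, sw_oracle_nt(sp2, contig1))
  # no shared word at all
  h3 <- match_spacers(seq_records(strrep("GGGGA", 7), id = "sp3"), db)
  expect_equal(nrow(h3), 0)
})

test_that("ORF calling finds maximal ATG..stop frames on both strands", {
  set.seed(84)
  inner <- paste(vapply(1:31, function(i)
    sample(c("GCT", "GAA", "TGG", "CTT", "AAA"), 1), character(1)),
    collapse = "")                       # 31 codons, no ATG/stops
  orf <- paste0("ATG", inner, "TAA")     # protein: M + 31 aa = 32 aa
  contig <- seq_records(paste0("CCCCC", orf, "CCCCC"), id = "k1")
  o <- call_orfs(contig, min_aa = 30)
  expect_equal(nrow(o), 1)
  expect_equal(o$start, 5L)
  expect_equal(o$end, 5L + nchar(orf))
  expect_equal(o$strand, "+")
  expect_equal(nchar(o$protein), 32)
  expect_equal(substr(o$protein, 1, 1), "M")
  expect_equal((o$end - o$start) %% 3, 0)

  # the same ORF on the minus strand, forward coordinates preserved
  rc <- seq_records(reverse_complement(contig$residues), id = "k2")
  o2 <- call_orfs(rc, min_aa = 30)
  expect_equal(nrow(o2), 1)
  expect_equal(o2$strand, "-")
  expect_equal(o2$protein, o$protein)
  expect_equal(o2$start, nchar(rc$residues) - o$end)

  # nothing to call in poly-N
  expect_equal(nrow(call_orfs(seq_records(strrep("N", 300), id = "n"))), 0)
})

test_that("matches are assigned to overlapping, spanning, or no ORFs", {
  orfs <- data.frame(
    orf_id = c("c|orf1", "c|orf2"), contig_id = "c",
    start = c(100L, 250L), end = c(250L, 400L), strand = "+",
    protein = "M", stringsAsFactors = FALSE)
  hsp <- function(s0, s1) {
    h <- cascr:::.empty_hsps()
    h[1, ] <- list("sp", "c", "+", 0L, 32L, s0, s1, 32L, 60, 1e-12,
                   32L, 0L, 0L, 32L)
    h
  }
  inside <- assign_matches(hsp(120L, 152L), orfs)
  expect_equal(inside$n_orfs, 1)
  expect_false(inside$spans_two_orfs)
  straddle <- assign_matches(hsp(240L, 272L), orfs)
  expect_equal(straddle$n_orfs, 2)
  expect_true(straddle$spans_two_orfs)
  outside <- assign_matches(hsp(450L, 482L), orfs)
  expect_equal(outside$n_orfs, 0)
  expect_equal(outside$orf_ids, "")
  expect_false(outside$spans_two_orfs)
})

test_that("degree histograms satisfy the handshake identity", {
  mk <- function(spacer, orfs) data.frame(
    spacer_id = spacer, contig_id = "c", evalue = 1e-5, bit_score = 30,
    mismatches = 0L, gap_openings = 0L, s_start = 0L, s_end = 30L,
    orf_ids = paste(orfs, collapse = ","), n_orfs = length(orfs),
    spans_two_orfs = FALSE, stringsAsFactors = FALSE)
  one <- degree_distributions(mk("s1", c("o1", "o2", "o3")))
  expect_equal(as.integer(one$spacer_degree["3"]), 1)
  expect_equal(as.integer(one$orf_degree["1"]), 3)

  empty <- degree_distributions(mk("s1", character(0)))
  expect_equal(length(empty$spacer_degree), 0)

  set.seed(85)
  m <- do.call(rbind, lapply(1:40, function(i)
    mk(paste0("s", sample(1:12, 1)),
       paste0("o", sample(1:15, sample(1:4, 1))))))
  dd <- degree_distributions(m)
  edges_from_spacers <- sum(as.integer(names(dd$spacer_degree)) *
                              as.integer(dd$spacer_degree))
  edges_from_orfs <- sum(as.integer(names(dd$orf_degree)) *
                           as.integer(dd$orf_degree))
  expect_equal(edges_from_spacers, edges_from_orfs)
})

test_that("great-circle distances follow the haversine on the mean Earth radius", {
  site <- function(lat, lon) list(lat = lat, lon = lon)
  expect_equal(great_circle_km(site(12, 34), site(12, 34)), 0)
  expect_equal(great_circle_km(site(0, 0), site(0, 180)), pi * 6371.0088,
               tolerance = 0.1 / 20015)
  expect_equal(great_circle_km(site(0, 0), site(90, 0)), pi / 2 * 6371.0088,
               tolerance = 0.1 / 10007)
  a <- site(42.3, -71.1); b <- site(-33.9, 151.2)
  expect_equal(great_circle_km(a, b), great_circle_km(b, a))
  expect_lte(great_circle_km(a, b), pi * 6371.0088)
  expect_error(great_circle_km(site(91, 0), site(0, 0)), "out of range")
})

test_that("the end-to-end target workflow links spacers to virome ORFs", {
  set.seed(86)
  # a virome contig whose single long ORF contains a planted protospacer
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[!gc %in% c("*", "M")]
  body <- paste(sample(sense, 120, replace = TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")
  contig <- seq_records(paste0(rnd_dna(150), orf, rnd_dna(150)), id = "vc1")
  proto_start <- 150 + 33                       # inside the ORF
  spacer <- substr(contig$residues, proto_start + 1, proto_start + 34)
  hs <- match_spacers(seq_records(spacer, id = "g1|array1|spacer1"),
                      build_search_db(contig, 7))
  expect_equal(nrow(hs), 1)
  orfs <- call_orfs(contig)
  expect_gte(nrow(orfs), 1)
  am <- assign_matches(hs, orfs)
  expect_equal(am$n_orfs, 1)
  expect_true(grepl("orf", am$orf_ids))
})
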