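# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

rnd_protein <- function(n) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# A record carrying one planted array: flank + (repeat spacer)*n + repeat
# + flank. Returns the record plus the planted pieces and coordinates.
planted_record <- function(repeat_seq, spacer_lengths, flank = 1000,
                           id = "g1") {
  spacers <- vapply(spacer_lengths, rnd_dna, character(1))
  left <- rnd_dna(flank); right <- rnd_dna(flank)
  # keep planted boundaries unambiguous, as make_genomes guarantees
  spacers <- cascr:::.sharpen_boundaries(
    spacers, substr(left, flank, flank), substr(right, 1, 1))
  parts <- repeat_seq
  for (s in spacers) parts <- c(parts, s, repeat_seq)
  ins <- paste(parts, collapse = "")
  res <- paste0(left, ins, right)
  list(record = seq_records(res, id = id),
       repeat_seq = repeat_seq, spacers = spacers,
       start = flank, end = flank + nchar(ins))
}

# Small known-repeat database containing `planted` plus random entries.
fixture_repeat_db <- function(planted = character(0), n_random = 15,
                              word_size = 4L) {
  extra <- vapply(sample(24:36, n_random, replace = TRUE), rnd_dna,
                  character(1))
  rec <- seq_records(c(planted, extra),
                     id = sprintf("repeat%02d", seq_len(length(planted) + n_random)))
  build_search_db(rec, word_size, "dna")
}

fixture_cas_db <- function(n = 5, word_size = 4L) {
  rec <- seq_records(vapply(sample(150:200, n, replace = TRUE), rnd_protein,
                            character(1)),
                     id = sprintf("cas%d", seq_len(n)), kind = "protein")
  build_search_db(rec, word_size, "protein")
}

# Independent full Smith-Waterman oracle via Biostrings, same scoring
# convention as the package (gap of length L costs open + L*extend).
sw_oracle_nt <- function(q, s, match = 1, mismatch = -2,
                         gap_open = 2, gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend))
}

sw_oracle_aa <- function(q, s, gap_open = 11, gap_extend = 1) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend))
}

# a crispr_array built directly (for unit tests of validation arithmetic)
toy_array <- function(spacer_lengths, repeat_len = 28, seq_id = "t1") {
  rep_seq <- rnd_dna(repeat_len)
  spacers <- vapply(spacer_lengths, rnd_dna, character(1))
  starts_r <- integer(0); starts_s <- integer(0)
  pos <- 0L
  for (i in seq_along(spacers)) {
    starts_r <- c(starts_r, pos); pos <- pos + repeat_len
    starts_s <- c(starts_s, pos); pos <- pos + spacer_lengths[i]
  }
  starts_r <- c(starts_r, pos)
  structure(list(seq_id = seq_id, start = 0L, end = pos + repeat_len,
                 repeats = data.frame(start = starts_r,
                                      residues = rep(rep_seq, length(starts_r)),
                                      stringsAsFactors = FALSE),
                 spacers = data.frame(start = starts_s, residues = spacers,
                                      stringsAsFactors = FALSE),
                 consensus_repeat = rep_seq),
            class = "crispr_array")
}
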