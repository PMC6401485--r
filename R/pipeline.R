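## End-to-end convenience wrappers: the detect-and-validate pipeline the
## command-line tool exposes, and the synthetic benchmark that scores the
## pipeline against a planted truth.

#' Run detection plus validation over a FASTA file
#'
#' Detects candidate arrays in every input sequence, validates them
#' against the supplied Cas-protein and known-repeat databases, and
#' writes the array reports (GFF3 + TSV), the validation report, and the
#' bona fide spacers (FASTA) for the chosen mode into `out_dir`.
#'
#' @param in_fasta input sequences (reads or contigs), FASTA.
#' @param out_dir output directory (created if needed).
#' @param mode `"liberal"` or `"conservative"`.
#' @param cas_db_fasta FASTA of known Cas proteins (optional).
#' @param repeat_db_fasta FASTA of known CRISPR repeats (optional).
#' @param params [detection_params()].
#' @param thresholds [validation_thresholds()].
#' @return the list of `validation_evidence`, invisibly.
#' @export
casc_run <- function(in_fasta, out_dir, mode = c("liberal", "conservative"),
                     cas_db_fasta = NULL, repeat_db_fasta = NULL,
                     params = detection_params(),
                     thresholds = validation_thresholds()) {
  mode <- match.arg(mode)
  records <- read_fasta(in_fasta)
  cas_db <- if (!is.null(cas_db_fasta))
    build_search_db(read_fasta(cas_db_fasta, kind = "protein"), 4L, "protein")
  repeat_db <- if (!is.null(repeat_db_fasta))
    build_search_db(read_fasta(repeat_db_fasta), thresholds$repeat_word_size, "dna")
  ev <- validate_all(records, cas_db, repeat_db, params, thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- lapply(ev, function(e) e$array)
  write_array_tsv(arrays, file.path(out_dir, "arrays.tsv"))
  write_array_gff3(arrays, file.path(out_dir, "arrays.gff3"))
  write_validation_report(ev, file.path(out_dir, "validation.tsv"))
  spacers <- extract_bona_fide_spacers(ev, mode)
  if (nrow(spacers))
    write_fasta(spacers, file.path(out_dir, "spacers.fasta"))
  invisible(ev)
}

#' Synthetic benchmark fixture
#'
#' The scaled-down benchmark metagenome: 10 genomes of 100 kb (5 carrying
#' one planted CRISPR array each, 5 carrying tandem-repeat decoy loci),
#' a 20-entry known-repeat database containing the 5 planted repeats,
#' and a 5-protein toy Cas database. Error-free contig mode: the genomes
#' themselves stand in for assembled contigs.
#'
#' @param seed RNG seed; the whole fixture is deterministic in it.
#' @param genome_len genome length (bp).
#' @return list: genomes, truth, repeat_db, cas_db (record data.frames).
#' @export
benchmark_fixture <- function(seed = 1L, genome_len = 100000L) {
  set.seed(seed)
  rep_len <- c(28L, 30L, 26L, 32L, 29L)
  n_spacers <- c(3L, 4L, 5L, 3L, 4L)
  planted_repeats <- vapply(rep_len, .random_dna, character(1))
  specs <- lapply(1:5, function(g)
    planted_array_spec(planted_repeats[g],
                       sample(26:45, n_spacers[g], replace = TRUE),
                       genome_offset = sample(2000:(genome_len - 2000L), 1)))
  decoy_units <- vapply(c(24L, 28L, 30L, 26L, 22L), .random_dna, character(1))
  decoy_n <- c(6L, 5L, 7L, 6L, 8L)
  decoy_gap <- c(0L, 0L, 10L, 0L, 5L)
  decoys <- lapply(1:5, function(g)
    decoy_spec(decoy_units[g], decoy_n[g],
               genome_offset = sample(2000:(genome_len - 2000L), 1),
               gap = decoy_gap[g]))
  extra_repeats <- vapply(sample(24:36, 15, replace = TRUE),
                          .random_dna, character(1))
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  cas <- vapply(sample(150:200, 5), function(n)
    paste(sample(aa20, n, replace = TRUE), collapse = ""), character(1))
  gen <- make_genomes(5, 5, genome_len, specs,
                      seed = seed + 1L, decoys = decoys)
  list(genomes = gen$genomes, truth = gen$truth,
       repeat_db = seq_records(c(planted_repeats, extra_repeats),
                               id = sprintf("known_repeat%02d", 1:20)),
       cas_db = seq_records(cas, id = sprintf("cas_protein%d", 1:5),
                            kind = "protein"))
}

#' Run the planted-truth benchmark
#'
#' Generates the [benchmark_fixture()], runs detection plus validation,
#' extracts the spacers bona fide under `mode`, and scores them against
#' the planted truth under the 100%-identity rule.
#' @inheritParams benchmark_fixture
#' @param mode validation mode for spacer extraction.
#' @return list: eval (tp/fp/fn/sensitivity/precision), n_predicted,
#'   n_truth, evidence.
#' @export
run_benchmark <- function(seed = 1L, genome_len = 100000L, mode = "liberal") {
  fix <- benchmark_fixture(seed, genome_len)
  cas_db <- build_search_db(fix$cas_db, 4L, "protein")
  repeat_db <- build_search_db(fix$repeat_db, 4L, "dna")
  ev <- validate_all(fix$genomes, cas_db, repeat_db)
  spacers <- extract_bona_fide_spacers(ev, mode)
  res <- evaluate_predictions(spacers, truth_records(fix$truth))
  list(eval = res, n_predicted = nrow(spacers), n_truth = nrow(fix$truth),
       evidence = ev)
}
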