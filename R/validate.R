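## Validation of candidate arrays. A candidate is deemed bona fide when
## (i) the sequence carrying it has a translated-search hit to a known
## Cas protein, (ii) its consensus repeat has a nucleotide hit to a known
## repeat (either orientation), or (iii) its spacer lengths are tightly
## regular. Conservative mode requires (i) or (ii); liberal mode accepts
## (iii) as well, so the conservative spacer set is always nested inside
## the liberal one.

#' Validation thresholds
#'
#' Defaults: Cas translated-search E <= 1e-12; known-repeat nucleotide
#' search E <= 1e-5 at word size 4; spacer-length standard deviation
#' <= 2 bp.
#' @param cas_e_max E-value cutoff for the Cas-protein condition (i).
#' @param repeat_e_max E-value cutoff for the known-repeat condition (ii).
#' @param repeat_word_size seed word size for condition (ii).
#' @param spacer_sd_max spacer-length SD bound (bp) for condition (iii).
#' @export
validation_thresholds <- function(cas_e_max = 1e-12, repeat_e_max = 1e-5,
                                  repeat_word_size = 4L, spacer_sd_max = 2.0) {
  stopifnot(cas_e_max > 0, repeat_e_max > 0, repeat_word_size >= 2,
            spacer_sd_max > 0)
  list(cas_e_max = cas_e_max, repeat_e_max = repeat_e_max,
       repeat_word_size = as.integer(repeat_word_size),
       spacer_sd_max = spacer_sd_max)
}

#' Population standard deviation of spacer lengths in an array
#'
#' Divides by n (not n-1); a single-spacer array has SD 0 by definition
#' and is flagged downstream so users can filter such arrays.
#' @param array a `crispr_array`.
#' @return SD in bp.
#' @export
spacer_length_sd <- function(array) {
  len <- nchar(array$spacers$residues)
  if (!length(len)) stop("array has no spacers")
  sqrt(mean((len - mean(len))^2))
}

#' Validate one candidate array
#'
#' Evaluates the three conditions and both mode verdicts. Condition (i)
#' searches the entire source sequence (not a window around the array)
#' against the Cas database; condition (ii) searches the consensus repeat
#' against the repeat database (the search covers both orientations); an
#' empty database evaluates its condition as false with a warning.
#'
#' @param array a `crispr_array` detected on `source`.
#' @param source the single-row record the array was detected on.
#' @param cas_db protein [build_search_db()] of known Cas proteins, or NULL.
#' @param repeat_db DNA [build_search_db()] of known repeats, or NULL.
#' @param thresholds [validation_thresholds()].
#' @param cas_hits optional precomputed translated-search HSPs for
#'   `source` against `cas_db` (one search serves all arrays on a record).
#' @return a `validation_evidence` list: array, cas_hit, repeat_hit
#'   (best HSP rows or NULL), spacer_sd, single_spacer flag,
#'   bona_fide_liberal, bona_fide_conservative.
#' @export
validate_array <- function(array, source, cas_db = NULL, repeat_db = NULL,
                           thresholds = validation_thresholds(),
                           cas_hits = NULL) {
  stopifnot(inherits(array, "crispr_array"))
  if (is.null(cas_hits)) {
    cas_hits <- if (is.null(cas_db) || !nrow(cas_db$records)) {
      warning("empty Cas database: condition (i) evaluated as false")
      .empty_hsps()
    } else {
      search_translated(source, cas_db, e_max = thresholds$cas_e_max)
    }
  }
  cas_hit <- if (nrow(cas_hits)) cas_hits[1, , drop = FALSE] else NULL

  repeat_hit <- NULL
  if (is.null(repeat_db) || !nrow(repeat_db$records)) {
    warning("empty repeat database: condition (ii) evaluated as false")
  } else {
    q <- seq_records(array$consensus_repeat, id = "consensus")
    rh <- search_nt(q, repeat_db, word_size = thresholds$repeat_word_size,
                    e_max = thresholds$repeat_e_max)
    if (nrow(rh)) repeat_hit <- rh[1, , drop = FALSE]
  }

  sd <- spacer_length_sd(array)
  cons <- !is.null(cas_hit) || !is.null(repeat_hit)
  lib <- cons || sd <= thresholds$spacer_sd_max
  structure(list(array = array, cas_hit = cas_hit, repeat_hit = repeat_hit,
                 spacer_sd = sd,
                 single_spacer = nrow(array$spacers) == 1L,
                 bona_fide_conservative = cons,
                 bona_fide_liberal = lib),
            class = "validation_evidence")
}

#' Validate all arrays detected on a set of records
#'
#' Runs [find_arrays()] per record and [validate_array()] per array; the
#' Cas search over each source record is computed once and shared by its
#' arrays.
#' @param records sequence record data.frame.
#' @inheritParams validate_array
#' @inheritParams find_arrays
#' @return list of `validation_evidence`.
#' @export
validate_all <- function(records, cas_db = NULL, repeat_db = NULL,
                         params = detection_params(),
                         thresholds = validation_thresholds()) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    arrays <- find_arrays(rec, params)
    if (!length(arrays)) next
    cas_hits <- if (is.null(cas_db) || !nrow(cas_db$records)) NULL else
      search_translated(rec, cas_db, e_max = thresholds$cas_e_max)
    for (a in arrays) {
      ev <- if (is.null(cas_hits))
        validate_array(a, rec, cas_db, repeat_db, thresholds)
      else
        validate_array(a, rec, cas_db, repeat_db, thresholds, cas_hits = cas_hits)
      out[[length(out) + 1L]] <- ev
    }
  }
  out
}

#' Spacers of bona fide arrays
#'
#' Returns the spacers of arrays whose verdict under the chosen mode is
#' true, as sequence records with ids `{seq_id}|array{i}|spacer{j}`
#' (array index i in coordinate order per source sequence), in stable
#' order.
#' @param evidence list of `validation_evidence` (see [validate_all()]).
#' @param mode `"liberal"` or `"conservative"`.
#' @export
extract_bona_fide_spacers <- function(evidence, mode = c("liberal", "conservative")) {
  mode <- match.arg(mode)
  field <- if (mode == "liberal") "bona_fide_liberal" else "bona_fide_conservative"
  # array index is per source sequence, over all detected arrays
  seq_ids <- vapply(evidence, function(e) e$array$seq_id, character(1))
  idx <- stats::ave(seq_along(evidence), seq_ids, FUN = seq_along)
  out <- list()
  for (k in seq_along(evidence)) {
    e <- evidence[[k]]
    if (!isTRUE(e[[field]])) next
    sp <- e$array$spacers
    if (!nrow(sp)) next
    out[[length(out) + 1L]] <- data.frame(
      id = sprintf("%s|array%d|spacer%d", e$array$seq_id, idx[k], seq_len(nrow(sp))),
      description = "", residues = sp$residues, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id = character(0), description = character(0),
                      residues = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positional nucleotide counts of a repeat set
#'
#' Builds a 4 x L position frequency matrix over repeats brought to the
#' modal length L (longer repeats are truncated, shorter ones dropped),
#' optionally on the reverse complement, plus the per-column information
#' content `2 + sum_b f_b log2 f_b` in bits (N bases are ignored in the
#' counts).
#' @param repeats character vector of repeat sequences.
#' @param orientation `"forward"` or `"revcomp"`.
#' @return a `repeat_pfm` list: orientation, counts (4 x L), n_repeats,
#'   info_content (length-L vector of bits).
#' @export
repeat_pfm <- function(repeats, orientation = c("forward", "revcomp")) {
  orientation <- match.arg(orientation)
  if (!length(repeats)) stop("no repeats supplied")
  if (orientation == "revcomp") repeats <- reverse_complement(repeats)
  len <- nchar(repeats)
  Ltab <- table(len)
  L <- as.integer(names(Ltab))[which.max(Ltab)]
  repeats <- substr(repeats[len >= L], 1, L)
  m <- do.call(rbind, strsplit(repeats, ""))
  counts <- vapply(seq_len(L), function(j)
    table(factor(m[, j], levels = c("A", "C", "G", "T"))), integer(4))
  rownames(counts) <- c("A", "C", "G", "T")
  info <- apply(counts, 2, function(cn) {
    n <- sum(cn)
    if (n == 0) return(0)
    f <- cn / n
    2 + sum(ifelse(f > 0, f * log2(f), 0))
  })
  structure(list(orientation = orientation, counts = counts,
                 n_repeats = length(repeats), info_content = info),
            class = "repeat_pfm")
}

#' Write the per-array validation report
#'
#' TSV columns: seq_id, array, n_repeats, n_spacers, spacer_sd,
#' cas_hit_evalue, repeat_hit_evalue, single_spacer, liberal,
#' conservative.
#' @inheritParams extract_bona_fide_spacers
#' @param path output file.
#' @export
write_validation_report <- function(evidence, path) {
  seq_ids <- vapply(evidence, function(e) e$array$seq_id, character(1))
  idx <- if (length(evidence))
    stats::ave(seq_along(evidence), seq_ids, FUN = seq_along) else integer(0)
  tab <- data.frame(
    seq_id = seq_ids, array = idx,
    n_repeats = vapply(evidence, function(e) nrow(e$array$repeats), integer(1)),
    n_spacers = vapply(evidence, function(e) nrow(e$array$spacers), integer(1)),
    spacer_sd = vapply(evidence, function(e) e$spacer_sd, numeric(1)),
    cas_hit_evalue = vapply(evidence, function(e)
      if (is.null(e$cas_hit)) NA_real_ else e$cas_hit$evalue, numeric(1)),
    repeat_hit_evalue = vapply(evidence, function(e)
      if (is.null(e$repeat_hit)) NA_real_ else e$repeat_hit$evalue, numeric(1)),
    single_spacer = vapply(evidence, function(e) e$single_spacer, logical(1)),
    liberal = vapply(evidence, function(e) e$bona_fide_liberal, logical(1)),
    conservative = vapply(evidence, function(e) e$bona_fide_conservative, logical(1)),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
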