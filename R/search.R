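## Seeded local-alignment search (word seeding + windowed Smith-Waterman
## extension) with Karlin-Altschul E-values, replacing the external BLAST
## binaries the legacy pipeline shells out to. Nucleotide mode searches
## both query strands; translated mode searches all six query frames
## against a protein database. Results are deterministic and independent
## of record insertion order.

.encode_seq <- function(seq, alphabet) {
  lut <- integer(127)
  lut[vapply(alphabet, utf8ToInt, integer(1))] <- seq_along(alphabet)
  v <- lut[utf8ToInt(seq)]
  if (any(v == 0L)) stop("residue outside scheme alphabet")
  v
}

.seq_words <- function(seq, w) {
  L <- nchar(seq)
  if (L < w) return(character(0))
  substring(seq, 1:(L - w + 1), w:L)
}

#' Build a word-indexed search database
#'
#' Every word occurrence of length `word_size` in every record is indexed.
#'
#' @param records sequence record data.frame (see [seq_records()]).
#' @param word_size exact-match seed length (>= 2).
#' @param kind `"dna"` or `"protein"`.
#' @return a `search_db` list: records, total_length, word_size, index.
#' @export
build_search_db <- function(records, word_size, kind = "dna") {
  stopifnot(word_size >= 2)
  validate_records(records, kind)
  idx <- new.env(parent = emptyenv(), size = 4096L)
  for (i in seq_len(nrow(records))) {
    words <- .seq_words(records$residues[i], word_size)
    if (!length(words)) next
    byw <- split(seq_along(words) - 1L, words)   # 0-based offsets
    for (w in names(byw)) {
      hit <- cbind(rec = i, off = byw[[w]])
      idx[[w]] <- if (is.null(idx[[w]])) hit else rbind(idx[[w]], hit)
    }
  }
  structure(list(records = records,
                 total_length = sum(nchar(records$residues)),
                 word_size = as.integer(word_size), kind = kind, index = idx),
            class = "search_db")
}

.empty_hsps <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             strand_or_frame = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             raw_score = integer(0), bit_score = numeric(0),
             evalue = numeric(0), identities = integer(0),
             mismatches = integer(0), gap_openings = integer(0),
             align_len = integer(0), stringsAsFactors = FALSE)
}

# Seed, cluster by (subject, diagonal), extend with windowed SW, and
# dedupe overlapping alignments keeping the highest raw score.
# qseq is the already-oriented query string; coordinates are on qseq.
.seed_extend <- function(qseq, db, scheme, max_extension, band) {
  w <- db$word_size
  words <- .seq_words(qseq, w)
  if (!length(words)) return(NULL)
  found <- mget(words, envir = db$index, ifnotfound = list(NULL))
  rows <- list()
  for (qi in seq_along(found)) {
    h <- found[[qi]]
    if (is.null(h)) next
    rows[[length(rows) + 1L]] <- cbind(qpos = qi - 1L, h)
  }
  if (!length(rows)) return(NULL)
  seeds <- do.call(rbind, rows)
  diag <- seeds[, "qpos"] - seeds[, "off"]
  grp <- paste(seeds[, "rec"], diag)
  qenc <- .encode_seq(qseq, scheme$alphabet)
  qlen <- length(qenc)
  enc_cache <- vector("list", nrow(db$records))
  out <- list()
  for (g in sort(unique(grp))) {
    sel <- which(grp == g)
    qp <- sort(seeds[sel, "qpos"])
    rec <- seeds[sel[1], "rec"]
    dg <- diag[sel[1]]
    # merge seeds on the same diagonal within 2*word_size into clusters
    brk <- c(TRUE, diff(qp) > 2L * w)
    cl <- cumsum(brk)
    if (is.null(enc_cache[[rec]]))
      enc_cache[[rec]] <- .encode_seq(db$records$residues[rec], scheme$alphabet)
    senc <- enc_cache[[rec]]
    slen <- length(senc)
    for (ci in unique(cl)) {
      qlo <- min(qp[cl == ci]); qhi <- max(qp[cl == ci]) + w
      qw0 <- max(0L, qlo - max_extension)
      qw1 <- min(qlen, qhi + max_extension)
      sw0 <- max(0L, qw0 - dg - band)
      sw1 <- min(slen, qw1 - dg + band)
      if (sw1 <= sw0) next
      r <- .sw_align_int(qenc[(qw0 + 1):qw1], senc[(sw0 + 1):sw1],
                         scheme$matrix, scheme$gap_open, scheme$gap_extend)
      if (r$score <= 0) next
      out[[length(out) + 1L]] <- data.frame(
        rec = rec, q_start = qw0 + r$q_start, q_end = qw0 + r$q_end,
        s_start = sw0 + r$s_start, s_end = sw0 + r$s_end,
        raw_score = r$score, identities = r$identities,
        mismatches = r$mismatches, gap_openings = r$gap_openings,
        align_len = r$align_len, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  h <- do.call(rbind, out)
  # dedupe: within a subject keep the best-scoring of mutually overlapping HSPs
  h <- h[order(-h$raw_score, h$rec, h$q_start, h$s_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i < nrow(h)) {
      j <- (i + 1):nrow(h)
      ov <- keep[j] & h$rec[j] == h$rec[i] &
        h$q_start[j] < h$q_end[i] & h$q_end[j] > h$q_start[i] &
        h$s_start[j] < h$s_end[i] & h$s_end[j] > h$s_start[i]
      keep[j][ov] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

.finish_hsps <- function(h, query_id, db, m, e_max, scheme) {
  if (is.null(h) || !nrow(h)) return(.empty_hsps())
  h$query_id <- query_id
  h$subject_id <- db$records$id[h$rec]
  h$bit_score <- bit_score(h$raw_score, scheme)
  h$evalue <- evalue(h$raw_score, m, db$total_length, scheme)
  h <- h[h$evalue <= e_max, , drop = FALSE]
  h <- h[order(h$evalue, h$subject_id, h$s_start, h$q_start), , drop = FALSE]
  rownames(h) <- NULL
  h[, names(.empty_hsps())]
}

#' Nucleotide search of a query against a word-indexed database
#'
#' Both query strands are searched. Every exact shared word seeds a
#' windowed Smith-Waterman extension around the seed diagonal; overlapping
#' alignments on the same subject keep the highest score; only HSPs with
#' `evalue <= e_max` are returned, sorted by ascending E-value then
#' subject id. Query coordinates are always reported on the forward
#' strand of the query; `strand_or_frame` records which strand matched.
#'
#' @param query a single-row sequence record data.frame (or an id +
#'   residues pair built with [seq_records()]).
#' @param db a `"dna"` [build_search_db()] database.
#' @param word_size seed word length; if it differs from the database's,
#'   the database is re-indexed transparently.
#' @param e_max E-value cutoff.
#' @param scheme scoring scheme, default [nt_scheme()].
#' @param max_extension cap, in residues, on how far the Smith-Waterman
#'   window extends beyond the seed cluster.
#' @return HSP data.frame (possibly empty): query_id, subject_id,
#'   strand_or_frame, q/s start/end (0-based half-open), raw_score,
#'   bit_score, evalue, identities, mismatches, gap_openings, align_len.
#' @export
search_nt <- function(query, db, word_size = db$word_size, e_max = 10,
                      scheme = nt_scheme(), max_extension = 400L) {
  stopifnot(inherits(db, "search_db"), db$kind == "dna", nrow(query) == 1)
  if (word_size != db$word_size)
    db <- build_search_db(db$records, word_size, "dna")
  band <- 10L + max(0L, (word_size * max(scheme$matrix)) %/% scheme$gap_extend)
  qseq <- query$residues
  qlen <- nchar(qseq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") qseq else reverse_complement(qseq)
    h <- .seed_extend(s, db, scheme, as.integer(max_extension), band)
    if (is.null(h) || !nrow(h)) next
    if (strand == "-") {
      qs <- qlen - h$q_end; qe <- qlen - h$q_start
      h$q_start <- qs; h$q_end <- qe
    }
    h$strand_or_frame <- strand
    res[[strand]] <- h
  }
  h <- if (length(res)) do.call(rbind, res) else NULL
  .finish_hsps(h, query$id, db, qlen, e_max, scheme)
}

#' Translated search of a DNA query against a protein database
#'
#' The query is translated in all six frames (or taken as-is when
#' `query_is_protein`); each frame is seeded and extended with a protein
#' substitution matrix. `strand_or_frame` records the frame as
#' `"+1".."-3"` (or `"+1"` for a protein query); query coordinates are
#' amino-acid positions within that frame's translation. The E-value uses
#' the total translated query length.
#'
#' @inheritParams search_nt
#' @param protein_db a `"protein"` [build_search_db()] database.
#' @param query_is_protein set when the query is already a protein.
#' @export
search_translated <- function(query, protein_db, e_max = 1e-12,
                              scheme = protein_scheme(),
                              query_is_protein = FALSE,
                              max_extension = 400L) {
  stopifnot(inherits(protein_db, "search_db"), protein_db$kind == "protein",
            nrow(query) == 1)
  frames <- if (query_is_protein) {
    setNames(list(query$residues), "+1")
  } else {
    fr <- list()
    for (strand in c("+", "-")) for (off in 0:2) {
      p <- translate_dna(query$residues, off, strand)
      if (nzchar(p)) fr[[paste0(strand, off + 1)]] <- p
    }
    fr
  }
  if (!length(frames)) return(.empty_hsps())
  m <- sum(nchar(unlist(frames)))
  band <- 10L + max(0L, (protein_db$word_size * max(scheme$matrix)) %/%
                      scheme$gap_extend)
  res <- list()
  for (fr in names(frames)) {
    h <- .seed_extend(frames[[fr]], protein_db, scheme,
                      as.integer(max_extension), band)
    if (is.null(h) || !nrow(h)) next
    h$strand_or_frame <- fr
    res[[fr]] <- h
  }
  h <- if (length(res)) do.call(rbind, res) else NULL
  .finish_hsps(h, query$id, protein_db, m, e_max, scheme)
}

#' Write HSPs in the classic 12-column tabular hit layout
#'
#' Columns: query, subject, percent identity, alignment length,
#' mismatches, gap openings, q_start, q_end, s_start, s_end (1-based,
#' inclusive), E-value, bit score.
#'
#' @param hsps HSP data.frame from [search_nt()]/[search_translated()].
#' @param path output file.
#' @export
write_hit_table <- function(hsps, path) {
  tab <- data.frame(
    query = hsps$query_id, subject = hsps$subject_id,
    pident = round(100 * hsps$identities / pmax(hsps$align_len, 1), 2),
    length = hsps$align_len, mismatches = hsps$mismatches,
    gapopen = hsps$gap_openings,
    qstart = hsps$q_start + 1L, qend = hsps$q_end,
    sstart = hsps$s_start + 1L, send = hsps$s_end,
    evalue = signif(hsps$evalue, 3), bitscore = round(hsps$bit_score, 1),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
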