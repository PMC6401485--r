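#' Sequence records
#'
#' Sequence sets are plain data frames with columns `id`, `description`,
#' and `residues`. Helpers here read and write them as FASTA/FASTQ (via
#' Biostrings) and provide the elementary sequence operations the rest of
#' the pipeline uses. DNA residues are restricted to the 5-letter alphabet
#' A, C, G, T, N; other IUPAC degeneracy codes are rejected at ingest
#' because the array detector and the aligner assume 5 letters.
#'
#' @param residues character vector of sequences.
#' @param id character vector of unique ids (defaults to `seq1..seqN`).
#' @param description free-text descriptions (default empty).
#' @param kind `"dna"` or `"protein"`; controls alphabet validation.
#' @return data.frame with columns `id`, `description`, `residues`.
#' @export
seq_records <- function(residues, id = NULL, description = "", kind = "dna") {
  if (is.null(id)) id <- paste0("seq", seq_along(residues))
  stopifnot(length(id) == length(residues))
  residues <- toupper(as.character(residues))
  rec <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description), length(residues)),
                    residues = residues, stringsAsFactors = FALSE)
  validate_records(rec, kind)
  rec
}

validate_records <- function(rec, kind = "dna") {
  if (anyDuplicated(rec$id))
    stop("duplicate sequence ids: ", paste(rec$id[duplicated(rec$id)][1]))
  for (i in seq_len(nrow(rec))) {
    if (is.na(rec$id[i]) || !nzchar(rec$id[i]))
      stop("record ", i, ": empty id")
    if (!nzchar(rec$residues[i]))
      stop("record ", i, " ('", rec$id[i], "'): empty sequence body")
    bad <- if (kind == "dna") grepl("[^ACGTN]", rec$residues[i])
           else grepl("[^A-Z*]", rec$residues[i])
    if (bad)
      stop("record ", i, " ('", rec$id[i], "'): residues outside the ",
           kind, " alphabet")
  }
  invisible(rec)
}

#' Read a FASTA file
#'
#' One record per header, order preserved, wrapped lines concatenated,
#' residues folded to upper case. An empty sequence body or empty header
#' is a format error naming the offending record.
#'
#' @param path FASTA file.
#' @inheritParams seq_records
#' @return data.frame of sequence records.
#' @export
read_fasta <- function(path, kind = "dna") {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  parse_stringset(x, kind)
}

parse_stringset <- function(x, kind) {
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  rec <- data.frame(id = id, description = desc,
                    residues = toupper(as.character(x)),
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  validate_records(rec, kind)
}

#' Write sequence records as FASTA
#' @param rec record data.frame (see [seq_records()]).
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(rec, path, width = 70) {
  x <- Biostrings::BStringSet(rec$residues)
  names(x) <- ifelse(nzchar(rec$description),
                     paste(rec$id, rec$description), rec$id)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file (sequences only; qualities kept as strings)
#' @inheritParams read_fasta
#' @export
read_fastq <- function(path, kind = "dna") {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  rec <- parse_stringset(x, kind)
  q <- S4Vectors::mcols(x)$qualities
  rec$quality <- if (is.null(q)) NA_character_ else as.character(q)
  rec
}

#' Write records as FASTQ
#' @inheritParams write_fasta
#' @export
write_fastq <- function(rec, path) {
  qual <- rec$quality
  if (is.null(qual)) qual <- strrep("I", nchar(rec$residues))
  lines <- as.vector(rbind(paste0("@", rec$id), rec$residues, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Vectorized; N is self-complementary. Non-DNA characters are an error.
#' @param seq DNA string(s) over A,C,G,T,N.
#' @return reverse-complemented string(s).
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) stop("non-DNA character in sequence")
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a DNA string in a given frame and strand
#'
#' Standard genetic code; stops rendered `*`; the trailing partial codon is
#' dropped. For the minus strand the sequence is reverse-complemented
#' first and the frame offset applies to the reverse complement.
#'
#' @param seq DNA string.
#' @param frame 0, 1 or 2 (offset into the strand).
#' @param strand `"+"` or `"-"`.
#' @return protein string (possibly empty if fewer than 3 nt remain).
#' @export
translate_dna <- function(seq, frame = 0, strand = "+") {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  s <- toupper(seq)
  if (strand == "-") s <- reverse_complement(s)
  s <- substr(s, frame + 1, nchar(s))
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  s <- substr(s, 1, n)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' GC content of a DNA string
#'
#' Fraction (G+C)/(A+C+G+T); N is excluded from the denominator. An
#' all-N (or empty) sequence is an error.
#' @param seq DNA string.
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("non-DNA character in sequence")
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  acgt <- n - nchar(gsub("[ACGT]", "", seq))
  if (acgt == 0) stop("GC content undefined: no unambiguous bases")
  gc / acgt
}

#' Read mapped-read spans from a SAM file
#'
#' Only the information the pipeline needs is consumed: `@SQ` header lines
#' (reference lengths) and, for mapped primary records, the reference span
#' derived from the CIGAR (M/=/X/D consume reference; I/S do not; aligned
#' bases are the M/=/X total). Unmapped, secondary, and supplementary
#' records are skipped.
#'
#' @param path SAM file.
#' @return data.frame with columns `read_id`, `ref_id`, `ref_start`
#'   (0-based), `ref_end` (exclusive), `aligned_bases`; reference lengths
#'   attached as the `ref_lengths` attribute.
#' @export
read_sam_mappings <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    ref_lengths <- setNames(ln, sn)
  }
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L ||
        bitwAnd(flag, 2048L) != 0L) next
    cig <- f[6]
    if (cig == "*") next
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    ref_consumed <- sum(len[op %in% c("M", "=", "X", "D", "N")])
    aligned <- sum(len[op %in% c("M", "=", "X")])
    start0 <- as.integer(f[4]) - 1L
    out[[length(out) + 1L]] <- data.frame(
      read_id = f[1], ref_id = f[3], ref_start = start0,
      ref_end = start0 + ref_consumed, aligned_bases = aligned,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), ref_id = character(0),
               ref_start = integer(0), ref_end = integer(0),
               aligned_bases = integer(0), stringsAsFactors = FALSE)
  attr(res, "ref_lengths") <- ref_lengths
  res
}

#' Read a per-interval coverage table
#'
#' Alternative to SAM input: a TSV with columns `ref_id`, `start`, `end`,
#' `mean_depth` (0-based half-open intervals).
#' @param path TSV file.
#' @export
read_coverage_tsv <- function(path) {
  cov <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref_id", "start", "end", "mean_depth")
  if (!all(need %in% names(cov)))
    stop("coverage table must have columns: ", paste(need, collapse = ", "))
  cov
}

#' Mean read depth over an interval
#'
#' Mean, over positions in `[start, end)`, of the number of read mappings
#' covering each position.
#'
#' @param mappings data.frame from [read_sam_mappings()].
#' @param ref_id reference sequence id.
#' @param start,end 0-based half-open interval.
#' @param ref_lengths optional named vector of reference lengths; defaults
#'   to the attribute carried by `mappings`. Used to validate `ref_id`.
#' @return mean depth (float, >= 0).
#' @export
interval_depth <- function(mappings, ref_id, start, end,
                           ref_lengths = attr(mappings, "ref_lengths")) {
  stopifnot(start < end, start >= 0)
  known <- if (length(ref_lengths)) names(ref_lengths) else unique(mappings$ref_id)
  if (!ref_id %in% known) stop("unknown reference: ", ref_id)
  if (length(ref_lengths) && end > ref_lengths[[ref_id]])
    stop("interval beyond reference length")
  m <- mappings[mappings$ref_id == ref_id, , drop = FALSE]
  if (!nrow(m)) return(0)
  ov <- pmin(m$ref_end, end) - pmax(m$ref_start, start)
  sum(pmax(ov, 0)) / (end - start)
}

#' Mean depth of an interval from a coverage table
#'
#' Length-weighted mean of `mean_depth` over the parts of `[start, end)`
#' covered by table rows; uncovered positions count as depth 0.
#' @param cov data.frame from [read_coverage_tsv()].
#' @inheritParams interval_depth
#' @export
interval_depth_from_table <- function(cov, ref_id, start, end) {
  stopifnot(start < end)
  if (!ref_id %in% cov$ref_id) stop("unknown reference: ", ref_id)
  m <- cov[cov$ref_id == ref_id, , drop = FALSE]
  ov <- pmax(pmin(m$end, end) - pmax(m$start, start), 0)
  sum(ov * m$mean_depth) / (end - start)
}
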