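## Spacer-to-virome protospacer analysis: drop virome sequences that
## themselves carry arrays, match spacers permissively at the nucleotide
## level, call ORFs only on matched contigs (the workflow order keeps the
## spanning-spacer signal visible), assign matches to overlapping ORFs,
## and summarize the bipartite spacer/ORF network and the geography of
## the links.

#' Remove virome sequences that carry CRISPR arrays
#'
#' Runs detection plus liberal validation on every virome record and
#' drops any record with at least one liberal-bona-fide array, so that
#' spacer matches to other arrays are not mistaken for protospacers.
#' @param virome sequence record data.frame.
#' @inheritParams validate_all
#' @return surviving records, with the dropped ids attached as the
#'   `dropped` attribute.
#' @export
remove_array_bearing_sequences <- function(virome, cas_db = NULL,
                                           repeat_db = NULL,
                                           params = detection_params(),
                                           thresholds = validation_thresholds()) {
  drop <- logical(nrow(virome))
  for (i in seq_len(nrow(virome))) {
    rec <- virome[i, , drop = FALSE]
    ev <- suppressWarnings(
      validate_all(rec, cas_db, repeat_db, params, thresholds))
    drop[i] <- any(vapply(ev, function(e) e$bona_fide_liberal, logical(1)))
  }
  if (all(drop)) warning("every virome sequence carries an array")
  out <- virome[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- virome$id[drop]
  out
}

#' Match spacers against a virome database
#'
#' Permissive nucleotide search (defaults: word size 7, E <= 0.1, both
#' strands); per (spacer, contig) pair only the best-E-value HSP is kept
#' so one spacer is never double-counted against a contig.
#' @param spacers spacer records (e.g. from [extract_bona_fide_spacers()]).
#' @param virome_db DNA [build_search_db()] built from the filtered virome.
#' @param e_max E-value cutoff.
#' @param word_size seed word size.
#' @export
match_spacers <- function(spacers, virome_db, e_max = 0.1, word_size = 7L) {
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    h <- search_nt(spacers[i, , drop = FALSE], virome_db,
                   word_size = word_size, e_max = e_max)
    if (!nrow(h)) next
    # best E-value per subject contig
    h <- h[order(h$evalue, h$s_start), , drop = FALSE]
    out[[length(out) + 1L]] <- h[!duplicated(h$subject_id), , drop = FALSE]
  }
  if (!length(out)) return(.empty_hsps())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call open reading frames on a contig
#'
#' Transparent ATG-to-stop caller: all maximal ATG..stop frames on both
#' strands with a protein of at least `min_aa` residues, reported in
#' forward-strand coordinates sorted by start; overlaps are allowed.
#' ORFs running off the contig end without a stop are not reported.
#' @param contig single-row DNA record.
#' @param min_aa minimum protein length (aa).
#' @return data.frame: orf_id, contig_id, start, end (0-based half-open,
#'   forward strand, stop codon included), strand, protein.
#' @export
call_orfs <- function(contig, min_aa = 30L) {
  stopifnot(nrow(contig) == 1)
  seq <- toupper(contig$residues)
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (off in 0:2) {
      prot <- translate_dna(s, off, "+")
      if (!nzchar(prot)) next
      aa <- strsplit(prot, "")[[1]]
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)          # codon index after each stop
      seg_stop <- c(stops, NA_integer_)       # NA: runs off the end, skip
      for (k in seq_along(seg_start)) {
        if (is.na(seg_stop[k])) next
        seg <- aa[seg_start[k]:seg_stop[k]]
        m <- which(seg == "M")[1]
        if (is.na(m)) next
        first <- seg_start[k] + m - 1L        # codon index of the ATG
        plen <- seg_stop[k] - first           # aa count, stop excluded
        if (plen < min_aa) next
        nt0 <- off + (first - 1L) * 3L        # 0-based on strand s
        nt1 <- off + seg_stop[k] * 3L         # stop codon included
        if (strand == "+") { a <- nt0; b <- nt1 } else { a <- L - nt1; b <- L - nt0 }
        out[[length(out) + 1L]] <- data.frame(
          contig_id = contig$id, start = a, end = b, strand = strand,
          protein = paste(seg[m:(length(seg) - 1)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  res$orf_id <- sprintf("%s|orf%d", contig$id, seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("orf_id", "contig_id", "start", "end", "strand", "protein")]
}

#' Assign spacer matches to overlapping ORFs
#'
#' Each HSP is assigned to every ORF whose interval overlaps the subject
#' interval by at least 1 nt. A match overlapping two adjacent ORFs is
#' flagged as spanning; a match overlapping none is recorded as
#' intergenic with no ORF ids.
#' @param hsps HSPs from [match_spacers()].
#' @param orfs ORF data.frame from [call_orfs()] covering every matched
#'   contig (rbind over contigs).
#' @return data.frame: spacer_id, contig_id, evalue, bit_score,
#'   mismatches, gap_openings, s_start, s_end, orf_ids (comma-joined,
#'   may be empty), n_orfs, spans_two_orfs.
#' @export
assign_matches <- function(hsps, orfs) {
  out <- vector("list", nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    h <- hsps[i, ]
    o <- orfs[orfs$contig_id == h$subject_id, , drop = FALSE]
    ov <- o[o$start < h$s_end & o$end > h$s_start, , drop = FALSE]
    spans <- FALSE
    if (nrow(ov) == 2) {
      # adjacent: consecutive in the per-contig start ordering
      ord <- order(o$start, o$end, o$strand)
      pos <- match(ov$orf_id, o$orf_id[ord])
      spans <- abs(diff(sort(pos))) == 1
    }
    out[[i]] <- data.frame(
      spacer_id = h$query_id, contig_id = h$subject_id,
      evalue = h$evalue, bit_score = h$bit_score,
      mismatches = h$mismatches, gap_openings = h$gap_openings,
      s_start = h$s_start, s_end = h$s_end,
      orf_ids = paste(ov$orf_id, collapse = ","),
      n_orfs = nrow(ov), spans_two_orfs = spans,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(spacer_id = character(0), contig_id = character(0),
                      evalue = numeric(0), bit_score = numeric(0),
                      mismatches = integer(0), gap_openings = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      orf_ids = character(0), n_orfs = integer(0),
                      spans_two_orfs = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Degree histograms of the spacer/ORF match network
#'
#' Spacer degree = number of distinct ORFs a spacer matches; ORF degree =
#' number of distinct spacers matching an ORF. Histograms cover degrees
#' >= 1 and satisfy the handshake identity (both sides count the same
#' edge set).
#' @param matches data.frame from [assign_matches()].
#' @return list of two tables: `spacer_degree`, `orf_degree`.
#' @export
degree_distributions <- function(matches) {
  edges <- unique(do.call(rbind, lapply(seq_len(nrow(matches)), function(i) {
    ids <- strsplit(matches$orf_ids[i], ",", fixed = TRUE)[[1]]
    ids <- ids[nzchar(ids)]
    if (!length(ids)) return(NULL)
    data.frame(spacer = matches$spacer_id[i], orf = ids,
               stringsAsFactors = FALSE)
  })))
  if (is.null(edges) || !nrow(edges))
    return(list(spacer_degree = table(integer(0)),
                orf_degree = table(integer(0))))
  list(spacer_degree = table(table(edges$spacer)),
       orf_degree = table(table(edges$orf)))
}

#' Great-circle distance between two sampling sites
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#' @param a,b lists or data.frame rows with `lat` (degrees, -90..90) and
#'   `lon` (degrees, -180..180).
#' @return kilometers.
#' @export
great_circle_km <- function(a, b) {
  chk <- function(s) {
    if (abs(s$lat) > 90 || abs(s$lon) > 180)
      stop("coordinates out of range")
  }
  chk(a); chk(b)
  geosphere::distHaversine(c(a$lon, a$lat), c(b$lon, b$lat),
                           r = 6371.0088e3) / 1000
}

#' Write the spacer-target match table
#'
#' TSV mirroring the match network edges, with great-circle distance when
#' both sites are known.
#' @param matches data.frame from [assign_matches()].
#' @param path output file.
#' @param spacer_sites,contig_sites optional data.frames (`sample_id`,
#'   `lat`, `lon`) plus a `sample_of` named vector mapping spacer/contig
#'   ids to sample ids.
#' @param sample_of named character vector: sequence id -> sample id.
#' @export
write_match_table <- function(matches, path, spacer_sites = NULL,
                              contig_sites = NULL, sample_of = NULL) {
  tab <- matches
  tab$distance_km <- NA_real_
  if (!is.null(spacer_sites) && !is.null(contig_sites) && !is.null(sample_of)) {
    for (i in seq_len(nrow(tab))) {
      sa <- sample_of[[tab$spacer_id[i]]]
      sb <- sample_of[[tab$contig_id[i]]]
      if (is.null(sa) || is.null(sb)) next
      A <- spacer_sites[spacer_sites$sample_id == sa, ]
      B <- contig_sites[contig_sites$sample_id == sb, ]
      if (nrow(A) && nrow(B))
        tab$distance_km[i] <- great_circle_km(A[1, ], B[1, ])
    }
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
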