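## Synthetic-data generator and planted-truth evaluation. Genomes are
## uniform-random DNA with repeat-spacer arrays (and tandem-repeat
## decoys) inserted at recorded offsets; reads follow a normal length
## model with a linearly 3'-increasing substitution ramp; predictions
## are scored against the planted truth with the 100%-identity rule
## (a prediction matching a planted spacer or its reverse complement).

#' Specification of one planted array
#' @param repeat_seq repeat sequence (length within detector bounds).
#' @param spacer_lengths spacer lengths; the array has
#'   `length(spacer_lengths) + 1` repeat units.
#' @param genome_offset 0-based insertion offset.
#' @export
planted_array_spec <- function(repeat_seq, spacer_lengths, genome_offset) {
  list(repeat_seq = toupper(repeat_seq),
       spacer_lengths = as.integer(spacer_lengths),
       n_units = length(spacer_lengths) + 1L,
       genome_offset = as.integer(genome_offset))
}

#' Specification of one tandem-repeat decoy locus
#' @param unit repeated unit sequence.
#' @param n_units copy number.
#' @param gap gap between copies (0 = perfect tandem).
#' @inheritParams planted_array_spec
#' @export
decoy_spec <- function(unit, n_units, genome_offset, gap = 0L) {
  list(unit = toupper(unit), n_units = as.integer(n_units),
       gap = as.integer(gap), genome_offset = as.integer(genome_offset))
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

#' Generate genomes with planted arrays and decoys
#'
#' Uniform-random background DNA; arrays (alternating planted repeat and
#' fresh random spacers of the specified lengths) and tandem-repeat
#' decoys are spliced in at their recorded offsets. The truth table
#' lists every planted spacer with its genome, locus, and sequence.
#' Identical seeds give byte-identical output.
#'
#' Planted boundaries are guaranteed unambiguous: the columns
#' immediately flanking the repeat instances (the bases just before and
#' just after each unit) are never perfectly conserved across instances
#' (one spacer base is resampled when chance would make them so), so the
#' planted repeat/spacer boundaries are the ones any consensus-based
#' detector should recover and the truth table is well defined.
#'
#' @param n_with_arrays,n_without genome counts.
#' @param genome_len genome length (bp).
#' @param specs list of length `n_with_arrays`; element g is one
#'   [planted_array_spec()] (or a list of them) for genome g.
#' @param seed RNG seed.
#' @param decoys list of length `n_without`; element g is one
#'   [decoy_spec()] (or a list of them, or NULL) for array-free genome g.
#' @return list: `genomes` (record data.frame), `truth` (data.frame:
#'   genome, array, spacer, start, end, sequence).
#' @export
make_genomes <- function(n_with_arrays, n_without, genome_len, specs,
                         seed = 1L, decoys = NULL) {
  stopifnot(length(specs) == n_with_arrays)
  set.seed(seed)
  genomes <- character(n_with_arrays + n_without)
  ids <- sprintf("genome%02d", seq_len(n_with_arrays + n_without))
  truth <- list()
  as_list <- function(x) if (is.null(x)) list() else
    if (!is.null(x$genome_offset)) list(x) else x

  for (g in seq_len(n_with_arrays)) {
    seq <- .random_dna(genome_len)
    arr_specs <- as_list(specs[[g]])
    iv <- do.call(rbind, lapply(arr_specs, function(s) {
      len <- s$n_units * nchar(s$repeat_seq) + sum(s$spacer_lengths)
      c(s$genome_offset, s$genome_offset + len)
    }))
    if (any(iv[, 2] > genome_len)) stop("planted array exceeds genome length")
    if (nrow(iv) > 1) {
      o <- order(iv[, 1])
      if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
        stop("planted arrays overlap")
    }
    for (ai in seq_along(arr_specs)) {
      s <- arr_specs[[ai]]
      spacers <- vapply(s$spacer_lengths, .random_dna, character(1))
      ins_len <- s$n_units * nchar(s$repeat_seq) + sum(s$spacer_lengths)
      left_flank <- substr(seq, s$genome_offset, s$genome_offset)
      right_flank <- substr(seq, s$genome_offset + ins_len + 1,
                            s$genome_offset + ins_len + 1)
      spacers <- .sharpen_boundaries(spacers, left_flank, right_flank)
      parts <- character(0)
      for (u in seq_len(s$n_units)) {
        parts <- c(parts, s$repeat_seq)
        if (u < s$n_units) parts <- c(parts, spacers[u])
      }
      ins <- paste(parts, collapse = "")
      seq <- paste0(substr(seq, 1, s$genome_offset),
                    ins,
                    substr(seq, s$genome_offset + nchar(ins) + 1, genome_len))
      pos <- s$genome_offset
      rl <- nchar(s$repeat_seq)
      for (u in seq_along(spacers)) {
        sp_start <- pos + u * rl + sum(s$spacer_lengths[seq_len(u - 1)])
        truth[[length(truth) + 1L]] <- data.frame(
          genome = ids[g], array = ai, spacer = u,
          start = sp_start, end = sp_start + s$spacer_lengths[u],
          sequence = spacers[u], stringsAsFactors = FALSE)
      }
    }
    genomes[g] <- seq
  }
  for (g in seq_len(n_without)) {
    seq <- .random_dna(genome_len)
    dk <- if (is.null(decoys)) list() else as_list(decoys[[g]])
    for (s in dk) {
      gapseq <- if (s$gap > 0) .random_dna(s$gap) else ""
      ins <- paste(rep(c(s$unit, gapseq), s$n_units)[seq_len(2 * s$n_units - 1)],
                   collapse = "")
      if (s$genome_offset + nchar(ins) > genome_len)
        stop("decoy exceeds genome length")
      seq <- paste0(substr(seq, 1, s$genome_offset),
                    ins,
                    substr(seq, s$genome_offset + nchar(ins) + 1, genome_len))
    }
    genomes[n_with_arrays + g] <- seq
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome = character(0), array = integer(0), spacer = integer(0),
               start = integer(0), end = integer(0), sequence = character(0),
               stringsAsFactors = FALSE)
  list(genomes = seq_records(genomes, id = ids), truth = truth)
}

#' Read-simulation parameters
#'
#' Lengths are normal (truncated to `[50, genome length]`); substitution
#' probability rises linearly from `p0` at the read start to `p1` at the
#' read end (a simple stand-in for pyrosequencing-style 3' error
#' accrual); indels are not modelled.
#' @param n_reads reads (or read pairs) to generate.
#' @param read_length_mean,read_length_sd bp.
#' @param paired emit mate pairs at `insert` fragment length.
#' @param insert fragment length for paired mode (bp).
#' @param p0,p1 substitution probabilities at read start/end
#'   (`0 <= p0 <= p1 < 0.1`).
#' @param seed RNG seed.
#' @export
read_sim_params <- function(n_reads = 20000L, read_length_mean = 450,
                            read_length_sd = 50, paired = FALSE,
                            insert = 300L, p0 = 0, p1 = 0, seed = 1L) {
  stopifnot(p0 >= 0, p1 >= p0, p1 < 0.1)
  list(n_reads = as.integer(n_reads), read_length_mean = read_length_mean,
       read_length_sd = read_length_sd, paired = paired,
       insert = as.integer(insert), p0 = p0, p1 = p1, seed = as.integer(seed))
}

# resample one spacer base if a column flanking the repeat instances
# would be perfectly conserved by chance (see make_genomes docs)
.sharpen_boundaries <- function(spacers, left_flank, right_flank) {
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  lastc <- substring(spacers, nchar(spacers), nchar(spacers))
  if (length(unique(c(left_flank, lastc))) == 1)
    substr(spacers[1], nchar(spacers[1]), nchar(spacers[1])) <- other(lastc[1])
  firstc <- substring(spacers, 1, 1)
  if (length(unique(c(firstc, right_flank))) == 1)
    substr(spacers[1], 1, 1) <- other(firstc[1])
  spacers
}

.mutate_read <- function(seq, p0, p1) {
  if (p1 <= 0) return(seq)
  n <- nchar(seq)
  t <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  p <- p0 + (p1 - p0) * t
  hit <- which(runif(n) < p)
  if (!length(hit)) return(seq)
  b <- strsplit(seq, "")[[1]]
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

#' Simulate shotgun reads from a genome set
#'
#' Read starts are uniform over the genomes proportional to length;
#' strands are random; paired mode emits both fragment ends with the
#' mate reverse-complemented.
#' @param genomes record data.frame (e.g. from [make_genomes()]).
#' @param params [read_sim_params()].
#' @return record data.frame with `quality` column (FASTQ-ready;
#'   constant qualities), origin recorded in `description` as
#'   `genome:start-end:strand`.
#' @export
simulate_reads <- function(genomes, params = read_sim_params()) {
  stopifnot(nrow(genomes) > 0)
  set.seed(params$seed)
  glen <- nchar(genomes$residues)
  out_id <- character(0); out_seq <- character(0); out_desc <- character(0)
  for (r in seq_len(params$n_reads)) {
    g <- sample.int(nrow(genomes), 1, prob = glen)
    L <- nchar(genomes$residues[g])
    flen <- if (params$paired) params$insert else {
      max(50L, min(L, round(rnorm(1, params$read_length_mean,
                                  params$read_length_sd))))
    }
    flen <- min(flen, L)
    start <- sample.int(L - flen + 1L, 1) - 1L     # 0-based
    frag <- substr(genomes$residues[g], start + 1, start + flen)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") frag <- reverse_complement(frag)
    desc <- sprintf("%s:%d-%d:%s", genomes$id[g], start, start + flen, strand)
    if (params$paired) {
      rl <- max(50L, min(flen, round(params$read_length_mean)))
      r1 <- .mutate_read(substr(frag, 1, rl), params$p0, params$p1)
      r2 <- .mutate_read(reverse_complement(
        substr(frag, flen - rl + 1, flen)), params$p0, params$p1)
      out_id <- c(out_id, sprintf("read%06d/1", r), sprintf("read%06d/2", r))
      out_seq <- c(out_seq, r1, r2)
      out_desc <- c(out_desc, desc, desc)
    } else {
      out_id <- c(out_id, sprintf("read%06d", r))
      out_seq <- c(out_seq, .mutate_read(frag, params$p0, params$p1))
      out_desc <- c(out_desc, desc)
    }
  }
  rec <- seq_records(out_seq, id = out_id, description = out_desc)
  rec$quality <- strrep("I", nchar(rec$residues))
  rec
}

.pair_identity <- function(a, b) {
  # identity over the shorter sequence, best of both strands
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global-local")
  idf <- Biostrings::nmatch(pa) / nchar(a)
  pa2 <- Biostrings::pairwiseAlignment(reverse_complement(a), b,
                                       type = "global-local")
  max(idf, Biostrings::nmatch(pa2) / nchar(a))
}

#' Match predicted spacers to known spacers at an identity threshold
#'
#' At identity 1.0 a prediction matches a known spacer iff the strings
#' are equal or reverse complements. Below 1.0, greedy length-sorted
#' clustering: sequences join the first existing cluster whose
#' representative they match at global identity >= `identity` over the
#' shorter sequence (either strand), else found a new cluster; a
#' prediction is matched iff its cluster contains a known spacer.
#' @param predicted,known record data.frames (`id`, `residues`).
#' @param identity fraction in (0, 1].
#' @return data.frame: predicted_id, matched (logical), known_id (first
#'   known in the cluster, NA if none).
#' @export
cluster_at_identity <- function(predicted, known, identity = 1.0) {
  stopifnot(identity > 0, identity <= 1)
  if (!nrow(predicted))
    return(data.frame(predicted_id = character(0), matched = logical(0),
                      known_id = character(0), stringsAsFactors = FALSE))
  res <- data.frame(predicted_id = predicted$id, matched = FALSE,
                    known_id = NA_character_, stringsAsFactors = FALSE)
  if (identity == 1) {
    lut <- c(setNames(known$id, known$residues),
             setNames(known$id, reverse_complement(known$residues)))
    lut <- lut[!duplicated(names(lut))]
    hit <- lut[predicted$residues]
    res$matched <- !is.na(hit)
    res$known_id <- unname(hit)
    return(res)
  }
  pool <- rbind(data.frame(id = known$id, residues = known$residues,
                           known = TRUE, stringsAsFactors = FALSE),
                data.frame(id = predicted$id, residues = predicted$residues,
                           known = FALSE, stringsAsFactors = FALSE))
  pool <- pool[order(-nchar(pool$residues), pool$id), , drop = FALSE]
  rep_seq <- character(0); members <- list()
  for (i in seq_len(nrow(pool))) {
    placed <- FALSE
    for (cl in seq_along(rep_seq)) {
      if (.pair_identity(pool$residues[i], rep_seq[cl]) >= identity) {
        members[[cl]] <- rbind(members[[cl]], pool[i, ])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_seq <- c(rep_seq, pool$residues[i])
      members[[length(rep_seq)]] <- pool[i, , drop = FALSE]
    }
  }
  for (cl in seq_along(members)) {
    kn <- members[[cl]]$id[members[[cl]]$known]
    if (!length(kn)) next
    pd <- members[[cl]]$id[!members[[cl]]$known]
    sel <- res$predicted_id %in% pd
    res$matched[sel] <- TRUE
    res$known_id[sel] <- kn[1]
  }
  res
}

#' Sensitivity and precision against a planted truth
#'
#' `tp` = predictions matched to truth, `fp` = unmatched predictions,
#' `fn` = truth spacers no prediction matched; sensitivity =
#' tp/(tp+fn), precision = tp/(tp+fp) (NA-flagged when the denominator
#' is 0, e.g. precision of an empty prediction set).
#' @param predicted predicted spacer records.
#' @param truth known spacer records (`id`, `residues`), e.g. built from
#'   the [make_genomes()] truth table.
#' @param identity matching threshold, default the 100%-identity rule.
#' @return list: tp, fp, fn, sensitivity, precision.
#' @export
evaluate_predictions <- function(predicted, truth, identity = 1.0) {
  stopifnot(nrow(truth) > 0)
  m <- cluster_at_identity(predicted, truth, identity)
  tp <- sum(m$matched)
  fp <- sum(!m$matched)
  matched_known <- unique(m$known_id[m$matched])
  fn <- sum(!truth$id %in% matched_known)
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Truth table as spacer records
#' @param truth truth data.frame from [make_genomes()].
#' @export
truth_records <- function(truth) {
  data.frame(id = sprintf("%s|array%d|spacer%d",
                          truth$genome, truth$array, truth$spacer),
             description = "", residues = truth$sequence,
             stringsAsFactors = FALSE)
}
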