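## CRT-style detection of candidate repeat-spacer arrays: an exact-match
## word scan proposes anchor sets whose spacing fits a repeat+spacer
## period, anchors are extended column-by-column under a consensus
## threshold, boundaries are polished and trimmed to the length bounds,
## and surviving candidates are reported as arrays. Validation of the
## candidates (Cas/repeat homology, spacer-length regularity) lives in
## the companion validation functions.

#' Detection parameters
#'
#' Defaults follow the reference repeat-finder's internal settings:
#' an 8-nt exact search window, at least 3 repeat units, repeat lengths
#' 19-38 nt, spacer lengths 19-48 nt, and a 0.75 per-column consensus
#' threshold during extension. `min_instance_identity` is the overall
#' identity each repeat instance must keep against the consensus.
#'
#' @param search_window exact-match seed word length (2..repeat_len_min).
#' @param min_repeats minimum number of repeat units (>= 2).
#' @param repeat_len_min,repeat_len_max repeat length bounds (nt).
#' @param spacer_len_min,spacer_len_max spacer length bounds (nt).
#' @param column_consensus_min fraction of instances that must agree with
#'   the column consensus for extension to continue.
#' @param min_instance_identity minimum overall instance-vs-consensus identity.
#' @param max_spacer_identity maximum pairwise identity allowed between
#'   spacers of one array; candidates with near-identical "spacers" are
#'   tandem repeats, not CRISPR arrays, and are discarded.
#' @export
detection_params <- function(search_window = 8L, min_repeats = 3L,
                             repeat_len_min = 19L, repeat_len_max = 38L,
                             spacer_len_min = 19L, spacer_len_max = 48L,
                             column_consensus_min = 0.75,
                             min_instance_identity = 0.9,
                             max_spacer_identity = 0.8) {
  p <- list(search_window = as.integer(search_window),
            min_repeats = as.integer(min_repeats),
            repeat_len_min = as.integer(repeat_len_min),
            repeat_len_max = as.integer(repeat_len_max),
            spacer_len_min = as.integer(spacer_len_min),
            spacer_len_max = as.integer(spacer_len_max),
            column_consensus_min = column_consensus_min,
            min_instance_identity = min_instance_identity,
            max_spacer_identity = max_spacer_identity)
  stopifnot(p$search_window >= 2, p$search_window <= p$repeat_len_min,
            p$min_repeats >= 2,
            p$repeat_len_min <= p$repeat_len_max,
            p$spacer_len_min <= p$spacer_len_max,
            p$column_consensus_min > 0, p$column_consensus_min <= 1)
  p
}

#' Per-column majority consensus of equal-length repeats
#'
#' Ties are broken by fixed base order A < C < G < T (N sorts last).
#' @param repeats character vector of equal-length DNA strings.
#' @return consensus string.
#' @export
consensus_repeat <- function(repeats) {
  stopifnot(length(repeats) >= 1)
  L <- unique(nchar(repeats))
  if (length(L) != 1) stop("internal invariant error: unequal repeat lengths")
  m <- do.call(rbind, strsplit(repeats, ""))
  paste(apply(m, 2, .column_consensus), collapse = "")
}

.base_order <- c("A", "C", "G", "T", "N")

.column_consensus <- function(col) {
  tab <- table(factor(col, levels = .base_order))
  .base_order[which.max(tab)]   # which.max takes the first max: A<C<G<T
}

.column_agreement <- function(col) {
  tab <- table(factor(col, levels = .base_order))
  max(tab) / length(col)
}

# bases of each anchor at a given column offset (1-based genome string)
.col_at <- function(seq, anchors, offset) {
  substring(seq, anchors + offset + 1L, anchors + offset + 1L)
}

#' Find candidate CRISPR arrays in one sequence
#'
#' Scans with an exact-match word of `search_window` nt; a seed is a run
#' of >= `min_repeats` occurrences of the same word whose successive gaps
#' lie within `[spacer_len_min + repeat_len_min, spacer_len_max +
#' repeat_len_max]`. Seeds are extended left and right column-by-column
#' while at least `column_consensus_min` of the instances agree with the
#' column consensus, boundary columns are then trimmed back to perfect
#' conservation and to the length bounds, and candidates violating any
#' array invariant are discarded. Non-overlapping arrays are reported in
#' coordinate order (on overlap, the candidate with more repeats, then
#' the longer, then the leftmost wins).
#'
#' @param record single-row sequence record data.frame (DNA; N runs are
#'   permitted but never inside a reported repeat).
#' @param params [detection_params()].
#' @return list of `crispr_array` objects: `seq_id`, `start`, `end`
#'   (0-based half-open), `repeats` and `spacers` data.frames
#'   (`start`, `residues`), and `consensus_repeat`.
#' @export
find_arrays <- function(record, params = detection_params()) {
  stopifnot(nrow(record) == 1)
  seq <- toupper(record$residues)
  L <- nchar(seq)
  k <- params$search_window
  if (L < k * params$min_repeats) return(list())
  gmin <- params$spacer_len_min + params$repeat_len_min
  gmax <- params$spacer_len_max + params$repeat_len_max

  words <- substring(seq, 1:(L - k + 1), k:L)
  ok <- !grepl("N", words, fixed = TRUE)
  pos <- which(ok) - 1L                      # 0-based word starts
  occ <- split(pos, words[ok])
  occ <- occ[lengths(occ) >= params$min_repeats]

  cands <- list()
  for (w in sort(names(occ))) {
    p <- sort(occ[[w]])
    d <- diff(p)
    inr <- d >= gmin & d <= gmax
    # maximal runs of in-range gaps with >= min_repeats anchors
    r <- rle(inr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= params$min_repeats - 1L)) {
      anchors <- p[starts[ri]:(ends[ri] + 1L)]
      a <- .build_candidate(seq, L, anchors, k, params)
      if (!is.null(a)) cands[[length(cands) + 1L]] <- a
    }
  }
  if (!length(cands)) return(list())
  # the same array is rebuilt from every seed word inside its repeat:
  # dedupe structurally before the (alignment-based) tandem check
  key <- vapply(cands, function(a)
    paste(a$start, a$end, nrow(a$repeats)), character(1))
  cands <- cands[!duplicated(key)]
  cands <- Filter(function(a)
    !.spacers_tandem_like(a$spacers$residues, params$max_spacer_identity),
    cands)
  if (!length(cands)) return(list())
  .resolve_overlaps(cands, record$id)
}

# Extend, polish, trim, and check one anchor set; NULL if it fails.
.build_candidate <- function(seq, L, anchors, k, params) {
  m <- length(anchors)
  d <- diff(anchors)
  maxlen <- min(d) - 1L                     # repeats must not touch
  a <- 0L; b <- k                           # repeat = [anchor+a, anchor+b)
  # extend left
  while (b - a < maxlen && anchors[1] + a - 1L >= 0L) {
    col <- .col_at(seq, anchors, a - 1L)
    if (.column_agreement(col) < params$column_consensus_min) break
    a <- a - 1L
  }
  # extend right
  while (b - a < maxlen && anchors[m] + b + 1L <= L) {
    col <- .col_at(seq, anchors, b)
    if (.column_agreement(col) < params$column_consensus_min) break
    b <- b + 1L
  }
  # units clipped by the sequence ends have unknowable extent (reads often
  # cut inside a flanking repeat): drop them rather than guess boundaries
  clip_lo <- anchors[1] + a == 0L
  clip_hi <- anchors[m] + b == L
  if (clip_lo || clip_hi) {
    keep <- seq_len(m)
    if (clip_lo) keep <- keep[-1]
    if (clip_hi && length(keep)) keep <- keep[-length(keep)]
    if (length(keep) < params$min_repeats) return(NULL)
    return(.build_candidate(seq, L, anchors[keep], k, params))
  }
  # boundary polish: terminal columns must be perfectly conserved
  while (b - a > 0L && .column_agreement(.col_at(seq, anchors, a)) < 1) a <- a + 1L
  while (b - a > 0L && .column_agreement(.col_at(seq, anchors, b - 1L)) < 1) b <- b - 1L
  # trim to the feasible repeat-length range
  lmin <- max(params$repeat_len_min, max(d) - params$spacer_len_max)
  lmax <- min(params$repeat_len_max, min(d) - params$spacer_len_min)
  if (lmin > lmax || b - a < lmin) return(NULL)
  while (b - a > lmax) {
    la <- .column_agreement(.col_at(seq, anchors, a))
    ra <- .column_agreement(.col_at(seq, anchors, b - 1L))
    if (la < ra) a <- a + 1L else b <- b - 1L
  }
  reps <- substring(seq, anchors + a + 1L, anchors + b)
  if (any(grepl("N", reps, fixed = TRUE))) return(NULL)
  cons <- consensus_repeat(reps)
  ident <- vapply(strsplit(reps, ""), function(r)
    mean(r == strsplit(cons, "")[[1]]), numeric(1))
  if (any(ident < params$min_instance_identity)) {
    # truncated flanking units at the array ends may be dropped; interior
    # disagreement invalidates the candidate
    bad <- which(ident < params$min_instance_identity)
    if (any(bad > 1 & bad < m)) return(NULL)
    keep <- ident >= params$min_instance_identity
    if (sum(keep) < params$min_repeats) return(NULL)
    return(.build_candidate(seq, L, anchors[keep], k, params))
  }
  sp_start <- anchors[-m] + b
  sp_end <- anchors[-1] + a
  spacers <- substring(seq, sp_start + 1L, sp_end)
  if (any(nchar(spacers) < params$spacer_len_min) ||
      any(nchar(spacers) > params$spacer_len_max)) return(NULL)
  structure(list(
    seq_id = NA_character_,
    start = anchors[1] + a, end = anchors[m] + b,
    repeats = data.frame(start = anchors + a, residues = reps,
                         stringsAsFactors = FALSE),
    spacers = data.frame(start = sp_start, residues = spacers,
                         stringsAsFactors = FALSE),
    consensus_repeat = cons), class = "crispr_array")
}

# true CRISPR spacers are mutually dissimilar; near-identical spacers
# mean the candidate is a tandem repeat with a conserved "gap"
.spacers_tandem_like <- function(spacers, max_identity) {
  n <- length(spacers)
  if (n < 2) return(FALSE)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (spacers[i] == spacers[j]) return(TRUE)
    if (.pair_identity(spacers[i], spacers[j]) > max_identity) return(TRUE)
  }
  FALSE
}

.resolve_overlaps <- function(cands, seq_id) {
  nrep <- vapply(cands, function(x) nrow(x$repeats), integer(1))
  len <- vapply(cands, function(x) x$end - x$start, integer(1))
  st <- vapply(cands, function(x) x$start, integer(1))
  en <- vapply(cands, function(x) x$end, integer(1))
  ord <- order(-nrep, -len, st)
  keep <- integer(0)
  for (i in ord) {
    if (!any(st[keep] < en[i] & en[keep] > st[i])) keep <- c(keep, i)
  }
  keep <- keep[order(st[keep])]
  out <- cands[keep]
  for (i in seq_along(out)) out[[i]]$seq_id <- seq_id
  out
}

#' Find arrays across a set of records
#' @param records sequence record data.frame.
#' @inheritParams find_arrays
#' @return flat list of `crispr_array` objects, in record then
#'   coordinate order.
#' @export
find_arrays_all <- function(records, params = detection_params()) {
  out <- list()
  for (i in seq_len(nrow(records)))
    out <- c(out, find_arrays(records[i, , drop = FALSE], params))
  out
}

#' Check the structural invariants of a detected array
#'
#' Errors if alternation, ordering, length bounds, or the coordinate
#' conventions are violated; returns the array invisibly otherwise.
#' @param array a `crispr_array`.
#' @param params the [detection_params()] the array was called with.
#' @export
check_crispr_array <- function(array, params = detection_params()) {
  r <- array$repeats; s <- array$spacers
  stopifnot(nrow(r) == nrow(s) + 1,
            array$start == r$start[1],
            array$end == r$start[nrow(r)] + nchar(r$residues[nrow(r)]),
            all(nchar(r$residues) >= params$repeat_len_min),
            all(nchar(r$residues) <= params$repeat_len_max),
            all(nchar(s$residues) >= params$spacer_len_min),
            all(nchar(s$residues) <= params$spacer_len_max),
            !any(grepl("N", r$residues, fixed = TRUE)))
  rend <- r$start + nchar(r$residues)
  send <- s$start + nchar(s$residues)
  stopifnot(all(s$start == rend[-nrow(r)]),    # spacer begins where repeat ends
            all(send == r$start[-1]))          # and ends at the next repeat
  invisible(array)
}
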