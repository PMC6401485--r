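## Functional annotation of virome ORFs by cumulative bit score, and
## actual-vs-expected enrichment of annotations among spacer-matched
## ORFs. An ORF is assigned the function whose hits sum to the highest
## bit score; the expected count of an annotation among n matched ORFs
## is n times its frequency across ALL database ORFs (including the
## "no hits" class), so expected counts conserve n.

#' Annotate one ORF from its protein-database hits
#'
#' Hits are grouped by (normalized) function label; the label with the
#' highest cumulative bit score wins; ties go to the label with more
#' hits, then the lexicographically smaller label. No hits is a valid
#' outcome, labelled `"no hits"`.
#' @param hits data.frame with columns `annotation` (function label) and
#'   `bit_score`, already filtered to `evalue <= e_max`.
#' @param e_max cutoff the hits are expected to honor (hits with an
#'   `evalue` column are filtered defensively).
#' @param keyword_map optional label normalization map (see
#'   [normalize_label()]).
#' @return list: annotation, cumulative_bit_score, n_hits.
#' @export
annotate_orf <- function(hits, e_max = 1e-3, keyword_map = NULL) {
  if (!is.null(hits) && nrow(hits) && "evalue" %in% names(hits))
    hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (is.null(hits) || !nrow(hits))
    return(list(annotation = "no hits", cumulative_bit_score = 0, n_hits = 0L))
  lab <- hits$annotation
  if (!is.null(keyword_map)) lab <- normalize_label(lab, keyword_map)
  bits <- tapply(hits$bit_score, lab, sum)
  n <- tapply(rep(1L, nrow(hits)), lab, sum)
  labs <- sort(names(bits))                      # lexicographic tie floor
  bits <- bits[labs]; n <- n[labs]
  best <- order(-bits, -n, labs)[1]
  list(annotation = labs[best],
       cumulative_bit_score = unname(bits[best]),
       n_hits = as.integer(n[best]))
}

#' Normalize a free-text function label to a reporting category
#'
#' First case-insensitive pattern match in the ordered keyword map wins;
#' unmatched labels pass through verbatim (they are collapsed under
#' "Other annotations" at reporting time).
#' @param raw_function character vector of database function labels.
#' @param keyword_map data.frame with columns `pattern` (regular
#'   expression, matched case-insensitively, in order) and `category`.
#' @export
normalize_label <- function(raw_function, keyword_map = default_keyword_map()) {
  out <- raw_function
  done <- rep(FALSE, length(out))
  for (i in seq_len(nrow(keyword_map))) {
    hit <- !done & grepl(keyword_map$pattern[i], raw_function,
                         ignore.case = TRUE, perl = TRUE)
    out[hit] <- keyword_map$category[i]
    done <- done | hit
  }
  out
}

#' Default keyword map for the 15 reporting categories
#'
#' Ordered so that specific categories (terminase, capsid, tail fiber,
#' ...) fire before the generic "Phage protein" catch-all. The grouping
#' of free-text database functions into categories is a reporting choice
#' of this package and is fully overridable via the `keyword_map`
#' arguments.
#' @export
default_keyword_map <- function() {
  path <- system.file("extdata", "annotation_keyword_map.tsv",
                      package = "cascr", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Background annotation frequencies over all database ORFs
#'
#' @param annotations character vector of annotations for EVERY database
#'   ORF, `"no hits"` included, produced by the same [annotate_orf()]
#'   pipeline as the matched set.
#' @return a `background` list: freq (named frequencies summing to 1),
#'   total_orfs.
#' @export
annotation_background <- function(annotations) {
  stopifnot(length(annotations) > 0)
  tab <- table(annotations)
  freq <- setNames(as.numeric(tab) / sum(tab), names(tab))
  structure(list(freq = freq, total_orfs = sum(tab)), class = "background")
}

#' Expected annotation counts among n matched ORFs
#'
#' `expected_a = n_matched * freq_a` for every annotation in the
#' background; the expected counts sum to `n_matched`.
#' @param background from [annotation_background()].
#' @param n_matched number of spacer-matched ORFs.
#' @export
expected_counts <- function(background, n_matched) {
  stopifnot(inherits(background, "background"), n_matched >= 0)
  n_matched * background$freq
}

#' Fold change of an annotation (actual / expected)
#'
#' Reported values are rounded half-away-from-zero to 1 decimal;
#' `expected = 0` with `actual > 0` is flagged infinite; both zero is
#' undefined (NA).
#' @param actual observed count.
#' @param expected expected count (>= 0).
#' @param digits reporting precision (decimal places).
#' @return list: value (full precision), reported (rounded; Inf or NA in
#'   the degenerate cases).
#' @export
fold_change <- function(actual, expected, digits = 1) {
  stopifnot(expected >= 0)
  if (expected == 0)
    return(list(value = if (actual > 0) Inf else NA_real_,
                reported = if (actual > 0) Inf else NA_real_))
  v <- actual / expected
  # round half away from zero at the reporting precision
  rep <- sign(v) * floor(abs(v) * 10^digits + 0.5) / 10^digits
  list(value = v, reported = rep)
}

#' Actual-vs-expected enrichment table
#'
#' One row per annotation with actual > 0 plus "no hits", sorted by
#' actual count descending; annotations below `top` (by actual count)
#' can be collapsed into "Other annotations" (their expected counts are
#' summed; "no hits" is never collapsed).
#' @param annotations annotations of the spacer-matched ORFs.
#' @param background from [annotation_background()] over ALL database ORFs.
#' @param top keep this many leading rows before collapsing, NULL for all.
#' @return data.frame: annotation, actual, expected, fold_change
#'   (full precision), fold_reported (1 decimal).
#' @export
enrichment_table <- function(annotations, background, top = NULL) {
  if (!length(annotations))
    return(data.frame(annotation = character(0), actual = integer(0),
                      expected = numeric(0), fold_change = numeric(0),
                      fold_reported = numeric(0), stringsAsFactors = FALSE))
  n <- length(annotations)
  exp_all <- expected_counts(background, n)
  act <- table(annotations)
  labs <- union(names(act)[as.integer(act) > 0], "no hits")
  tab <- data.frame(annotation = labs,
                    actual = as.integer(ifelse(labs %in% names(act),
                                               act[labs], 0L)),
                    expected = as.numeric(ifelse(labs %in% names(exp_all),
                                                 exp_all[labs], 0)),
                    stringsAsFactors = FALSE)
  ord <- order(-tab$actual, tab$annotation)
  tab <- tab[ord, , drop = FALSE]
  if (!is.null(top)) {
    main <- tab$annotation == "no hits" | seq_len(nrow(tab)) <= top
    if (any(!main)) {
      other <- data.frame(
        annotation = sprintf("Other annotations (%d)", sum(!main)),
        actual = sum(tab$actual[!main]),
        expected = sum(tab$expected[!main]), stringsAsFactors = FALSE)
      tab <- rbind(tab[main & tab$annotation != "no hits", , drop = FALSE],
                   other,
                   tab[tab$annotation == "no hits", , drop = FALSE])
    }
  }
  fc <- lapply(seq_len(nrow(tab)),
               function(i) fold_change(tab$actual[i], tab$expected[i]))
  tab$fold_change <- vapply(fc, `[[`, numeric(1), "value")
  tab$fold_reported <- vapply(fc, `[[`, numeric(1), "reported")
  rownames(tab) <- NULL
  tab
}
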