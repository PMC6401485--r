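## Plain-text exporters for detected arrays.

#' Arrays as a TSV table
#' @param arrays list of `crispr_array` objects (see [find_arrays_all()]).
#' @param path output file.
#' @export
write_array_tsv <- function(arrays, path) {
  seq_ids <- vapply(arrays, function(a) a$seq_id, character(1))
  idx <- if (length(arrays))
    stats::ave(seq_along(arrays), seq_ids, FUN = seq_along) else integer(0)
  tab <- data.frame(
    seq_id = seq_ids, array = idx,
    start = vapply(arrays, function(a) a$start, integer(1)),
    end = vapply(arrays, function(a) a$end, integer(1)),
    n_repeats = vapply(arrays, function(a) nrow(a$repeats), integer(1)),
    n_spacers = vapply(arrays, function(a) nrow(a$spacers), integer(1)),
    consensus_repeat = vapply(arrays, function(a) a$consensus_repeat,
                              character(1)),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Arrays as GFF3 (one repeat_region per array with repeat/spacer children)
#' @inheritParams write_array_tsv
#' @export
write_array_gff3 <- function(arrays, path) {
  lines <- "##gff-version 3"
  seq_ids <- vapply(arrays, function(a) a$seq_id, character(1))
  idx <- if (length(arrays))
    stats::ave(seq_along(arrays), seq_ids, FUN = seq_along) else integer(0)
  for (k in seq_along(arrays)) {
    a <- arrays[[k]]
    aid <- sprintf("%s|array%d", a$seq_id, idx[k])
    gff <- function(type, s, e, id, parent = NULL) {
      attrs <- paste0("ID=", id,
                      if (!is.null(parent)) paste0(";Parent=", parent) else "")
      sprintf("%s\tcascr\t%s\t%d\t%d\t.\t.\t.\t%s",
              a$seq_id, type, s + 1L, e, attrs)   # GFF is 1-based inclusive
    }
    lines <- c(lines, gff("repeat_region", a$start, a$end, aid))
    for (j in seq_len(nrow(a$repeats)))
      lines <- c(lines, gff("direct_repeat", a$repeats$start[j],
                            a$repeats$start[j] + nchar(a$repeats$residues[j]),
                            sprintf("%s|repeat%d", aid, j), aid))
    for (j in seq_len(nrow(a$spacers)))
      lines <- c(lines, gff("spacer", a$spacers$start[j],
                            a$spacers$start[j] + nchar(a$spacers$residues[j]),
                            sprintf("%s|spacer%d", aid, j), aid))
  }
  writeLines(lines, path)
  invisible(path)
}
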