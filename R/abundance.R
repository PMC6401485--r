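## Sequencing-effort-normalized spacer abundance. Read-level surveys
## report spacers per Mbp of raw reads; contig-level surveys report
## cumulative spacer read coverage per Gbp of mapped read bases, where
## "cumulative spacer coverage" is the sum over spacers of their mean
## per-base read depth (a proxy for spacer copy number).

#' Spacers per megabase pair of sequenced reads
#' @param n_spacers spacer count.
#' @param total_read_bases total bases sequenced (> 0).
#' @export
spacers_per_mbp <- function(n_spacers, total_read_bases) {
  if (any(total_read_bases <= 0)) stop("total_read_bases must be positive")
  n_spacers / (total_read_bases / 1e6)
}

#' Normalized spacer abundance (coverage per mapped Gbp)
#'
#' Sum of per-spacer mean depths divided by mapped read gigabases.
#' @param spacer_depths per-spacer mean read depths (see
#'   [interval_depth()]).
#' @param mapped_read_bases mapped read bases (> 0).
#' @export
normalized_spacer_abundance <- function(spacer_depths, mapped_read_bases) {
  if (mapped_read_bases <= 0) stop("mapped_read_bases must be positive")
  sum(spacer_depths) / (mapped_read_bases / 1e9)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; p from the t transform with n-2 degrees of
#' freedom (no multiple-testing correction).
#' @param x,y numeric vectors, equal length >= 3, each with nonzero
#'   variance.
#' @return list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-sample spacer abundance statistics
#'
#' Assembles the per-sample summary used by the survey analyses. Exactly
#' one of the two normalizations is populated per row: read-level samples
#' get spacers/Mbp; contig-level samples (those with mapped bases and
#' spacer depths) get coverage/Gbp.
#'
#' @param samples data.frame with columns `sample_id`, `total_read_bases`
#'   and optionally `lat`, `lon`, `depth_m`, `mapped_read_bases`.
#' @param n_spacers named (by sample_id) spacer counts.
#' @param spacer_depths optional named list (by sample_id) of per-spacer
#'   mean depth vectors, for contig-level normalization.
#' @param mean_gc optional named mean contig GC per sample.
#' @return data.frame of per-sample statistics including `nsa`.
#' @export
sample_stats <- function(samples, n_spacers, spacer_depths = NULL,
                         mean_gc = NULL) {
  out <- samples
  out$n_spacers <- as.integer(n_spacers[out$sample_id])
  out$spacers_per_mbp <- spacers_per_mbp(out$n_spacers, out$total_read_bases)
  out$cumulative_spacer_coverage <- NA_real_
  out$nsa <- NA_real_
  if (!is.null(spacer_depths) && "mapped_read_bases" %in% names(out)) {
    for (i in seq_len(nrow(out))) {
      d <- spacer_depths[[out$sample_id[i]]]
      if (is.null(d)) next
      out$cumulative_spacer_coverage[i] <- sum(d)
      out$nsa[i] <- normalized_spacer_abundance(d, out$mapped_read_bases[i])
    }
  }
  if (!is.null(mean_gc)) out$mean_gc <- as.numeric(mean_gc[out$sample_id])
  out
}
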