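## Karlin-Altschul score statistics for the seeded local-alignment search.
## Raw scores come from integer substitution matrices; lambda and K turn
## them into bit scores and E-values:
##   bit = (lambda*raw - ln K) / ln 2,   E = K*m*n*exp(-lambda*raw).
## Gapped searches reuse the ungapped lambda/K (documented approximation;
## adequate for thresholding at the loose cutoffs this pipeline uses).

.scheme_cache <- new.env(parent = emptyenv())

#' Solve for the Karlin-Altschul lambda
#'
#' The unique positive root of `sum_ij p_i p_j exp(lambda * s_ij) = 1`.
#' Requires a negative expected pair score and a positive maximum score.
#'
#' @param smat integer substitution matrix (residues x residues).
#' @param background residue background frequencies (sums to 1), one per
#'   row/column of `smat`.
#' @param tol relative tolerance of the root.
#' @return positive real lambda.
#' @export
solve_lambda <- function(smat, background, tol = 1e-9) {
  stopifnot(nrow(smat) == ncol(smat), length(background) == nrow(smat))
  p2 <- outer(background, background)
  es <- sum(p2 * smat)
  if (es >= 0 || max(smat) <= 0)
    stop("no positive lambda: expected pair score must be negative ",
         "and the maximum score positive")
  f <- function(l) sum(p2 * exp(l * smat)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-12, hi), tol = tol * max(1, hi))$root
}

# gcd of the integer lattice spanned by the score values
.score_gcd <- function(v) {
  v <- unique(abs(as.integer(v)))
  v <- v[v > 0]
  g <- v[1]
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  for (x in v[-1]) g <- gcd2(g, x)
  g
}

#' Karlin-Altschul K for an ungapped integer scoring scheme
#'
#' Lattice-case series
#' `K = lambda*delta*exp(-2*sigma) / (H*(1-exp(-lambda*delta)))` with
#' `sigma = sum_k (1/k) [ P(S_k >= 0) + E(exp(lambda*S_k); S_k < 0) ]`,
#' where `S_k` is the k-step random walk of pair scores and `delta` the
#' lattice span. The series is truncated when terms fall below `tol`.
#'
#' @inheritParams solve_lambda
#' @param lambda value from [solve_lambda()].
#' @param tol series truncation threshold.
#' @return positive real K.
#' @export
karlin_K <- function(smat, background, lambda, tol = 1e-9) {
  p2 <- outer(background, background)
  val <- as.vector(smat)
  pr <- as.vector(p2)
  d1 <- tapply(pr, val, sum)              # single-step score distribution
  sup <- as.integer(names(d1)); d1 <- as.numeric(d1)
  q <- pr * exp(lambda * val)
  H <- lambda * sum(q * val)
  delta <- .score_gcd(sup)

  conv <- function(sa, pa, sb, pb) {
    v <- as.vector(outer(sa, sb, "+"))
    w <- as.vector(outer(pa, pb))
    agg <- tapply(w, v, sum)
    keep <- agg > 1e-300
    list(s = as.integer(names(agg))[keep], p = as.numeric(agg)[keep])
  }
  sk <- sup; pk <- d1
  sigma <- 0
  for (k in 1:500) {
    neg <- sk < 0
    term <- (sum(pk[!neg]) + sum(pk[neg] * exp(lambda * sk[neg]))) / k
    sigma <- sigma + term
    if (term < tol) break
    nx <- conv(sk, pk, sup, d1)
    sk <- nx$s; pk <- nx$p
  }
  lambda * delta * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
}

#' Nucleotide scoring scheme
#'
#' Integer match/mismatch scores with affine gaps (a gap of length L costs
#' `gap_open + L*gap_extend`). Lambda and K are solved for the ungapped
#' scheme on the A/C/G/T alphabet under the given background; N scores as
#' a mismatch against everything but never contributes to statistics.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open,gap_extend affine gap costs (> 0).
#' @param background A/C/G/T background frequencies.
#' @return a `scoring_scheme` list: alphabet, matrix, gap costs, lambda, K.
#' @export
nt_scheme <- function(match = 1L, mismatch = -2L, gap_open = 2L,
                      gap_extend = 1L, background = rep(0.25, 4)) {
  key <- paste("nt", match, mismatch, gap_open, gap_extend,
               paste(background, collapse = ","))
  if (!is.null(.scheme_cache[[key]])) return(.scheme_cache[[key]])
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(as.integer(mismatch), 5, 5, dimnames = list(ab, ab))
  diag(m) <- as.integer(match)
  m["N", ] <- as.integer(mismatch); m[, "N"] <- as.integer(mismatch)
  core <- m[1:4, 1:4]
  lambda <- solve_lambda(core, background)
  K <- karlin_K(core, background, lambda)
  sch <- structure(list(alphabet = ab, matrix = m, gap_open = as.integer(gap_open),
                        gap_extend = as.integer(gap_extend), lambda = lambda,
                        K = K, type = "dna"),
                   class = "scoring_scheme")
  .scheme_cache[[key]] <- sch
  sch
}

#' Protein scoring scheme (BLOSUM62)
#'
#' BLOSUM62 substitution scores with affine gaps; lambda and K solved on
#' the 20 standard amino acids under a uniform background.
#' @inheritParams nt_scheme
#' @export
protein_scheme <- function(gap_open = 11L, gap_extend = 1L) {
  key <- paste("aa", gap_open, gap_extend)
  if (!is.null(.scheme_cache[[key]])) return(.scheme_cache[[key]])
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ab <- c(aa20, "B", "Z", "X", "*")
  m <- B[ab, ab]
  core <- m[aa20, aa20]
  bg <- rep(1 / 20, 20)
  lambda <- solve_lambda(core, bg)
  K <- karlin_K(core, bg, lambda)
  sch <- structure(list(alphabet = ab, matrix = m, gap_open = as.integer(gap_open),
                        gap_extend = as.integer(gap_extend), lambda = lambda,
                        K = K, type = "protein"),
                   class = "scoring_scheme")
  .scheme_cache[[key]] <- sch
  sch
}

#' Bit score of a raw alignment score
#' @param raw_score integer raw score.
#' @param scheme a [nt_scheme()] / [protein_scheme()] scoring scheme.
#' @export
bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' E-value of a raw alignment score
#' @inheritParams bit_score
#' @param m query length (residues).
#' @param n database total length (residues).
#' @export
evalue <- function(raw_score, m, n, scheme) {
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}
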