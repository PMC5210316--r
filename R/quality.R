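#' Convert a Phred quality score to an error probability
#'
#' The Phred score q of a base call encodes its error probability
#' \eqn{e = 10^{-q/10}}; q = 30 means one miscall in a thousand.
#'
#' @param q Integer (or numeric) vector of Phred scores, all \eqn{\ge 0}.
#' @return Numeric vector of error probabilities in (0, 1].
#' @examples
#' phredToError(c(0, 20, 30))  # 1, 0.01, 0.001
#' @export
phredToError <- function(q) {
  if (any(!is.finite(q)) || any(q < 0)) {
    stop("Phred scores must be finite and >= 0")
  }
  10^(-q / 10)
}

#' Quality-derived pseudocount vector for one replicate
#'
#' Each retained base call contributes mass to the three base channels it
#' did \emph{not} call: a fixed noise term \code{epsilon} (sequencing
#' independent errors) plus one third of its own error probability
#' \eqn{e/3} (the miscall probability is assumed uniform over the three
#' uncalled bases). The called channel receives nothing. The total added
#' mass over all channels is \eqn{3 n \epsilon + \sum_l e_l}.
#'
#' @param bases Character vector of called bases (\code{"A","C","G","T"}),
#'   one per call.
#' @param quals Integer vector of Phred scores, parallel to \code{bases}.
#' @param epsilon Fixed per-call noise term; default 0.01.
#' @return Named numeric 4-vector (A, C, G, T) of pseudocount mass.
#' @examples
#' pseudocountVector("A", 20)  # (0, 0.0133..., 0.0133..., 0.0133...)
#' @export
pseudocountVector <- function(bases, quals, epsilon = 0.01) {
  stopifnot(length(bases) == length(quals))
  if (length(bases) == 0L) {
    return(setNames(numeric(4L), BASES))
  }
  if (!all(bases %in% BASES)) stop("bases must be A, C, G or T")
  e <- phredToError(quals)
  n <- length(bases)
  eTot <- sum(e)
  cnt <- vapply(BASES, function(b) sum(bases == b), numeric(1))
  eByChan <- vapply(BASES, function(b) sum(e[bases == b]), numeric(1))
  # each call adds (epsilon + e/3) to its 3 uncalled channels
  epsilon * (n - cnt) + (eTot - eByChan) / 3
}

#' Pseudocount-adjust a replicate's base-count vector
#'
#' Produces the real-valued adjusted count vector
#' \eqn{\tilde{x} = x + x_P} that feeds the Dirichlet-Multinomial
#' likelihood: the integer counts plus the quality-derived pseudocount of
#' [pseudocountVector()]. With coverage \eqn{\ge 1} and \code{epsilon > 0}
#' every channel of the result is strictly positive, which keeps all Gamma
#' evaluations downstream finite.
#'
#' @param rec A replicate record (list with \code{counts} and \code{quals}
#'   as stored in a \linkS4class{SiteTallySet}).
#' @param epsilon Fixed noise term; default 0.01.
#' @return Named numeric 4-vector of adjusted counts.
#' @export
adjustCounts <- function(rec, epsilon = 0.01) {
  counts <- rec$counts
  quals <- rec$quals
  bases <- rep(BASES, times = vapply(quals, length, integer(1)))
  xp <- pseudocountVector(bases, unlist(quals, use.names = FALSE), epsilon)
  counts + xp
}

## Adjusted-count matrix (replicates x 4) for a list of replicate records.
.adjustedMatrix <- function(recs, epsilon = 0.01) {
  t(vapply(recs, adjustCounts, numeric(4L), epsilon = epsilon))
}
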