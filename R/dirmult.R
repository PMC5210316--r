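#' Dirichlet-Multinomial log-density for real-valued count vectors
#'
#' Log of the Dirichlet-Multinomial (multivariate Pólya) probability of a
#' base-count vector under concentration \eqn{\alpha}, with every factorial
#' generalized through the Gamma function so pseudocount-adjusted,
#' real-valued counts are admissible:
#' \deqn{\log \frac{\Gamma(n+1)\,\Gamma(\alpha_0)}{\Gamma(n+\alpha_0)}
#'   \prod_k \frac{\Gamma(x_k+\alpha_k)}{\Gamma(x_k+1)\Gamma(\alpha_k)},}
#' with \eqn{n = \sum_k x_k} and \eqn{\alpha_0 = \sum_k \alpha_k}. All
#' evaluations are in log space, so the result stays finite at high
#' coverage.
#'
#' @param x Non-negative numeric 4-vector of (adjusted) counts, or a matrix
#'   with 4 columns (one row per replicate).
#' @param alpha Strictly positive numeric 4-vector, or a
#'   \linkS4class{ConcentrationFit}.
#' @return Numeric log-density (vector of length \code{nrow(x)} for matrix
#'   input).
#' @examples
#' exp(logDirMult(c(2, 0, 0, 0), c(1, 1, 1, 1)))  # 1/10
#' @export
logDirMult <- function(x, alpha) {
  if (is(alpha, "ConcentrationFit")) alpha <- concentration(alpha)
  if (length(alpha) != 4L || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("'alpha' must be a strictly positive 4-vector")
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 4L || any(x < 0)) {
    stop("'x' must be non-negative with 4 channels")
  }
  n <- rowSums(x)
  a0 <- sum(alpha)
  lgamma(n + 1) + lgamma(a0) - lgamma(n + a0) +
    rowSums(lgamma(sweep(x, 2L, alpha, "+"))) -
    rowSums(lgamma(x + 1)) - sum(lgamma(alpha))
}

## Method-of-moments starting point for the fixed-point iteration.
## Uses population (1/N) variances so the start -- like the fixed-point
## map itself -- is invariant under duplicating the replicate set; the
## pooled fit of two identical samples then reproduces the separate fits
## exactly and the likelihood-ratio score of identical samples is 0.
.momStart <- function(X) {
  n <- rowSums(X)
  P <- X / n
  m <- colMeans(P)
  a0 <- mean(n) # single-replicate fallback: multinomial-like scale
  if (nrow(X) >= 2L) {
    v <- colMeans(P * P) - m * m
    ok <- v > 1e-12 & m > 1e-6 & m < 1 - 1e-6
    if (any(ok)) {
      est <- stats::median(m[ok] * (1 - m[ok]) / v[ok] - 1)
      if (is.finite(est) && est > 0) a0 <- est
    }
  }
  m <- pmax(m, 1e-6)
  m <- m / sum(m)
  pmax(m * a0, 1e-6)
}

#' Maximum-likelihood fit of the Dirichlet-Multinomial concentration
#'
#' Estimates the concentration vector \eqn{\alpha} maximizing
#' \eqn{\sum_i \log \mathrm{DirMult}(\tilde{x}_i, \alpha)} over the
#' replicates of one sample, by a Minka-style fixed-point iteration with a
#' method-of-moments start. The fixed-point update is a
#' minorize-maximize step, so the log-likelihood trajectory is
#' non-decreasing; if an update ever fails to improve (numerically
#' degenerate input) the fit falls back to bounded quasi-Newton on
#' \eqn{\log \alpha}. Channels with essentially no mass are floored at
#' 1e-6 to keep the parameter domain open.
#'
#' With a single replicate the likelihood supremum lies at
#' \eqn{\alpha_0 \to \infty} (the multinomial limit) and is not attained;
#' the iteration then runs to its cap and returns the (perfectly usable)
#' final iterate with \code{converged = FALSE}.
#'
#' @param X Matrix of adjusted counts, replicates in rows, 4 channels in
#'   columns; or a list of replicate records (adjusted with
#'   \code{epsilon}).
#' @param epsilon Pseudocount noise term used when \code{X} is a list of
#'   raw records.
#' @param maxIterations Iteration cap (default 100).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param start Optional starting \eqn{\alpha} (positive 4-vector);
#'   defaults to the method-of-moments estimate.
#' @return A \linkS4class{ConcentrationFit}.
#' @examples
#' X <- rbind(c(10.1, 1.1, 0.1, 0.1), c(9.2, 2.1, 0.2, 0.1))
#' fitAlpha(X)
#' @export
fitAlpha <- function(X, epsilon = 0.01, maxIterations = 100L, tol = 1e-6,
                     start = NULL) {
  if (is.list(X) && !is.matrix(X)) X <- .adjustedMatrix(X, epsilon)
  if (!is.matrix(X) || ncol(X) != 4L) stop("'X' must have 4 columns")
  if (nrow(X) < 1L) stop("need at least one replicate")
  if (any(rowSums(X) <= 0)) stop("every replicate needs positive total mass")

  alpha <- if (is.null(start)) .momStart(X) else pmax(start, 1e-6)
  N <- nrow(X)
  n <- rowSums(X)
  tX <- t(X) # 4 x N; channel-wise recycling of alpha is then direct
  # alpha-independent part of the log-likelihood
  llConst <- sum(lgamma(n + 1)) - sum(lgamma(X + 1))
  llOf <- function(a) {
    a0 <- sum(a)
    llConst + N * lgamma(a0) - sum(lgamma(n + a0)) +
      sum(lgamma(tX + a)) - N * sum(lgamma(a))
  }
  ll <- llOf(alpha)
  trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < maxIterations) {
    it <- it + 1L
    a0 <- sum(alpha)
    num <- rowSums(digamma(tX + alpha)) - N * digamma(alpha)
    den <- sum(digamma(n + a0)) - N * digamma(a0)
    alphaNew <- pmax(alpha * num / den, 1e-6)
    if (any(!is.finite(alphaNew))) break
    llNew <- llOf(alphaNew)
    if (!is.finite(llNew) || llNew < ll - 1e-8) break
    delta <- abs(llNew - ll) / (abs(ll) + 1e-12)
    alpha <- alphaNew
    ll <- llNew
    trace <- c(trace, ll)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  if (!converged && it < maxIterations) {
    # fixed point stalled before the cap: polish on log(alpha)
    opt <- stats::optim(log(alpha),
                        fn = function(la) -llOf(exp(la)),
                        method = "L-BFGS-B",
                        lower = log(1e-6), upper = log(1e9))
    llOpt <- -opt$value
    if (is.finite(llOpt) && llOpt > ll) {
      alpha <- pmax(exp(opt$par), 1e-6)
      ll <- llOf(alpha)
      trace <- c(trace, ll)
    }
    converged <- TRUE
  }

  new("ConcentrationFit", alpha = setNames(alpha, BASES), logLik = ll,
      converged = converged, iterations = it, trace = trace)
}

#' Sample replicate count vectors from a Dirichlet-Multinomial
#'
#' Hierarchical sampler: per replicate draws a base-probability vector
#' \eqn{p \sim \mathrm{Dirichlet}(\alpha)} and then counts
#' \eqn{x \sim \mathrm{Multinomial}(n, p)}.
#'
#' @param alpha Positive numeric 4-vector or \linkS4class{ConcentrationFit}.
#' @param n Total count per replicate (coverage).
#' @param N Number of replicates.
#' @param seed Optional integer seed for reproducibility (scoped locally;
#'   the caller's RNG state is restored).
#' @return Integer matrix, \code{N} rows by 4 columns (A, C, G, T).
#' @export
sampleDirMult <- function(alpha, n, N = 1L, seed = NULL) {
  if (is(alpha, "ConcentrationFit")) alpha <- concentration(alpha)
  stopifnot(length(alpha) == 4L, all(alpha > 0), n >= 0, N >= 1)
  if (!is.null(seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
  }
  out <- matrix(0L, nrow = N, ncol = 4L, dimnames = list(NULL, BASES))
  if (n == 0L) return(out)
  for (i in seq_len(N)) {
    g <- stats::rgamma(4L, shape = alpha, rate = 1)
    if (sum(g) <= 0) g <- alpha # degenerate underflow guard
    out[i, ] <- as.integer(stats::rmultinom(1L, size = n, prob = g / sum(g)))
  }
  out
}
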