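# Convergence diagnostics for MCMC draws.
#
# Implements the rank-normalised split-chain R-hat and the bulk/tail
# effective sample size of Vehtari, Gelman, Simpson, Carpenter & Buerkner
# (2021), which are the de-facto standard diagnostics reported for
# Bayesian behavioural model fits.  Draws are an iterations x chains
# matrix throughout.

split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalise <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(x) {
  m <- ncol(x); n <- nrow(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, var))
  B <- n * var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat convergence diagnostic
#'
#' Rank-normalised split R-hat: the maximum of the diagnostic on the
#' rank-normalised draws and on their folded (median-absolute-deviation)
#' transform, each computed on half-split chains.  Values at or below
#' 1.01 indicate convergence.
#'
#' @param x Iterations x chains matrix of draws of one parameter.
#' @return Scalar R-hat.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  xs <- split_chains(x)
  bulk <- rhat_basic(rank_normalise(xs))
  folded <- rhat_basic(rank_normalise(abs(xs - median(xs))))
  max(bulk, folded)
}

ess_basic <- function(x) {
  m <- ncol(x); n <- nrow(x)
  if (n < 4 || sd(x) == 0) return(NA_real_)
  acov <- apply(x, 2, function(v) {
    v <- v - mean(v)
    if (sum(v^2) == 0) return(numeric(n))
    L <- 2^ceiling(log2(2 * n))
    f <- fft(c(v, rep(0, L - n)))
    ac <- Re(fft(f * Conj(f), inverse = TRUE))[1:n] / L
    ac / ac[1] * sum(v^2) / n
  })
  mean_acov <- rowMeans(acov)
  W <- mean(apply(x, 2, var))
  var_plus <- W * (n - 1) / n + (if (m > 1) var(colMeans(x)) else 0)
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer initial monotone positive sequence over paired sums
  tau <- -1
  t <- 0
  prev_pair <- Inf
  repeat {
    if (t + 1 >= n) break
    pair <- rho[t + 1] + if (t + 2 <= n) rho[t + 2] else 0
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  tau <- max(tau, 1 / log10(n * m + 1))
  min(n * m / tau, n * m * log10(n * m))
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalised split chains; measures sampling efficiency
#' in the bulk of the posterior.
#'
#' @inheritParams rhat
#' @return Scalar ESS.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  ess_basic(rank_normalise(split_chains(x)))
}

#' Tail effective sample size
#'
#' Minimum ESS of the 5\% and 95\% quantile-exceedance indicators;
#' measures efficiency in the distribution tails, which drive interval
#' estimates.
#'
#' @inheritParams rhat
#' @return Scalar ESS.
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  xs <- split_chains(x)
  q <- quantile(xs, c(0.05, 0.95), names = FALSE)
  e1 <- ess_basic(rank_normalise(matrix(as.numeric(xs <= q[1]), nrow(xs))))
  e2 <- ess_basic(rank_normalise(matrix(as.numeric(xs <= q[2]), nrow(xs))))
  min(e1, e2, na.rm = TRUE)
}

#' Highest density interval of a sample
#'
#' Shortest interval containing \code{prob} of the draws.
#'
#' @param x Numeric draws.
#' @param prob Interval mass (default 0.94, i.e. the 3\%-97\% HDI).
#' @return Length-2 vector (lower, upper).
#' @export
hdi <- function(x, prob = 0.94) {
  x <- sort(as.vector(x))
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  w <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' Posterior summary with convergence diagnostics
#'
#' Per-parameter table in the layout standard for MCMC reports: posterior
#' mean and sd, 3\%/97\% HDI bounds, Monte-Carlo standard errors of the
#' mean and sd, bulk and tail ESS, and split R-hat.
#'
#' @param draws Iterations x chains x parameters array, or a list of
#'   iterations x chains matrices.
#' @return A data frame, one row per parameter.
#' @export
posterior_summary_table <- function(draws) {
  if (is.array(draws) && length(dim(draws)) == 3) {
    nm <- dimnames(draws)[[3]]
    draws <- lapply(seq_len(dim(draws)[3]), function(j) draws[, , j])
    names(draws) <- nm
  }
  rows <- lapply(names(draws), function(nm) {
    x <- as.matrix(draws[[nm]])
    v <- as.vector(x)
    eb <- ess_bulk(x); et <- ess_tail(x)
    h <- hdi(v)
    data.frame(parameter = nm, mean = mean(v), sd = sd(v),
               hdi_3 = h[1], hdi_97 = h[2],
               mcse_mean = sd(v) / sqrt(eb),
               mcse_sd = sd(v) / sqrt(2 * (eb - 1)),
               ess_bulk = eb, ess_tail = et,
               r_hat = rhat(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
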