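#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws after
#' splitting each chain in half, taking the maximum of the bulk statistic
#' and the same statistic on folded (median-absolute) draws, so that both
#' location and scale non-stationarity are detected.
#'
#' @param draws A matrix of posterior draws, iterations x chains.
#' @return A single R-hat value.
#' @export
rhat_rank <- function(draws) {
  draws <- as.matrix(draws)
  max(split_rhat(rank_normalize(draws)),
      split_rhat(rank_normalize(abs(draws - median(draws)))))
}

rank_normalize <- function(draws) {
  s <- length(draws)
  z <- qnorm((rank(draws) - 3 / 8) / (s + 1 / 4))
  matrix(z, nrow = nrow(draws), ncol = ncol(draws))
}

split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  b <- half * var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Bulk effective sample size across chains
#'
#' @param draws A matrix of posterior draws, iterations x chains.
#' @return Effective sample size (sum over chains of the autocorrelation-
#'   adjusted size of the rank-normalized draws).
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  z <- rank_normalize(draws)
  sum(vapply(seq_len(ncol(z)), function(j) {
    unname(coda::effectiveSize(coda::mcmc(z[, j])))
  }, numeric(1)))
}
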