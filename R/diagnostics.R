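#' Acceptance rate of a chain
#'
#' @param accept_flags logical (or 0/1) vector of per-update acceptance
#'   flags.
#' @return fraction of accepted updates.
#' @export
acceptance_rate <- function(accept_flags) {
  if (length(accept_flags) == 0L) stop("'accept_flags' is empty")
  mean(as.logical(accept_flags))
}

#' Empirical mixing distribution of the proposal statistic
#'
#' Estimates the marginal law \eqn{\pi(t(x^*))} of the composite-sampling
#' proposal statistic -- the distribution over Metropolis transition
#' kernels in the mixture representation of the exchange algorithm -- by
#' direct simulation.
#'
#' @param model an `irt_model`.
#' @param prior a `person_prior` (origin index 1 is used).
#' @param n_draws number of composite-sampling draws.
#' @return data frame of class `"mixing_distribution"` with columns `stat`
#'   and `prob` (summing to one).
#' @export
mixing_distribution <- function(model, prior, n_draws = 1e5) {
  if (n_draws < 1) stop("'n_draws' must be at least 1")
  stat <- simulate_stats(model, sample_prior(prior, rep(1L, n_draws)))
  tab <- table(stat) / n_draws
  structure(data.frame(stat = as.numeric(names(tab)),
                       prob = as.numeric(tab)),
            class = c("mixing_distribution", "data.frame"))
}

#' Tail mass of a mixing distribution around a center
#'
#' Total probability of statistic values farther than `radius` from
#' `center`; the mass of transition kernels with low probability of moving
#' a chain whose observed statistic is `center`.
#'
#' @param histogram a [mixing_distribution()] (or any data frame with
#'   `stat` and `prob` columns).
#' @param center reference statistic value (e.g. the observed score).
#' @param radius nonnegative distance.
#' @return fraction in \[0, 1\].
#' @export
tail_mass <- function(histogram, center, radius) {
  sum(histogram$prob[abs(histogram$stat - center) > radius])
}

#' Sample autocorrelation function
#'
#' Standard sample autocorrelation of a chain up to `max_lag`; lag 0 is
#' always 1. A constant chain has no defined autocorrelation beyond lag 0,
#' reported as `NA` with a warning.
#'
#' @param chain numeric vector.
#' @param max_lag largest lag, `< length(chain)`.
#' @return numeric vector of length `max_lag + 1` (lags 0..`max_lag`).
#' @export
autocorrelation <- function(chain, max_lag) {
  if (length(chain) <= max_lag)
    stop("'chain' must be longer than 'max_lag'")
  if (stats::var(chain) == 0) {
    warning("constant chain: autocorrelation undefined beyond lag 0")
    return(c(1, rep(NA_real_, max_lag)))
  }
  as.numeric(stats::acf(chain, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
}

#' Effective sample size
#'
#' ESS from the initial-positive-sequence truncation of the
#' autocorrelation sum: \eqn{n / (1 + 2\sum_\ell \rho_\ell)} with the sum
#' running over leading lags with positive autocorrelation. Clamped to
#' \[1, n\].
#'
#' @param chain numeric vector.
#' @param max_lag largest lag considered (default `min(n - 1, 200)`).
#' @return scalar effective sample size.
#' @export
effective_sample_size <- function(chain,
                                  max_lag = min(length(chain) - 1L, 200L)) {
  n <- length(chain)
  if (n < 2L || stats::var(chain) == 0) return(1)
  rho <- autocorrelation(chain, max_lag)[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  ess <- n / (1 + 2 * sum(rho))
  min(max(ess, 1), n)
}

#' Summarize a chain
#'
#' @param chain numeric vector of posterior draws.
#' @param accept_flags logical acceptance flags.
#' @param hit_flags logical direct-hit flags (proposal statistic equal to
#'   the observed statistic); optional.
#' @param max_lag largest autocorrelation lag retained.
#' @return list of class `"chain_summary"` with the acceptance rate,
#'   direct-hit rate, autocorrelations and effective sample size.
#' @export
chain_summary <- function(chain, accept_flags, hit_flags = NULL,
                          max_lag = min(length(chain) - 1L, 50L)) {
  structure(list(
    acceptance_rate = acceptance_rate(accept_flags),
    direct_hit_rate = if (is.null(hit_flags)) NA_real_
                      else mean(as.logical(hit_flags)),
    autocorrelations = if (stats::var(chain) == 0)
      c(1, rep(NA_real_, max_lag)) else autocorrelation(chain, max_lag),
    ess = effective_sample_size(chain)
  ), class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  cat(sprintf("acceptance rate: %.3f\n", x$acceptance_rate))
  if (!is.na(x$direct_hit_rate))
    cat(sprintf("direct-hit rate: %.3f\n", x$direct_hit_rate))
  cat(sprintf("lag-1 autocorrelation: %.3f\n", x$autocorrelations[2]))
  cat(sprintf("effective sample size: %.1f\n", x$ess))
  invisible(x)
}
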