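#' Exchange acceptance probability for exponential-family models
#'
#' The Single-Variable-Exchange acceptance probability
#' \deqn{\phi = \min\{1, \exp[(\theta^* - \theta')(t(x) - t(x^*))]\},}
#' where \eqn{t(x)} is the observed sufficient statistic and \eqn{t(x^*)} the
#' statistic of the data simulated at the proposed \eqn{\theta^*}. The
#' intractable normalizing constants of the likelihood cancel, so only the
#' two parameter values and the two statistics enter. Computed on the log
#' scale with the exponent clipped at 0.
#'
#' @param theta_cur current chain value \eqn{\theta'}.
#' @param theta_star proposed value \eqn{\theta^*}.
#' @param stat_obs observed sufficient statistic \eqn{t(x)}.
#' @param stat_star simulated sufficient statistic \eqn{t(x^*)}.
#' @return acceptance probability in \[0, 1\] (vectorized).
#' @examples
#' accept_probability(0, 1, 9, 11) # exp(-2)
#' @export
accept_probability <- function(theta_cur, theta_star, stat_obs, stat_star) {
  if (!all(is.finite(c(theta_cur, theta_star, stat_obs, stat_star))))
    stop("all arguments must be finite")
  exp(pmin(0, (theta_star - theta_cur) * (stat_obs - stat_star)))
}

#' Cross-prior exchange acceptance probability
#'
#' Acceptance probability when a proposal generated from person \eqn{q}'s
#' prior \eqn{\pi_q} is offered to the posterior of person \eqn{p} with prior
#' \eqn{\pi_p}: the exchange factor times the prior ratio
#' \eqn{\pi_p(\theta^*)\pi_q(\theta') / [\pi_p(\theta')\pi_q(\theta^*)]},
#' which ensures the target posterior stays invariant. When `target` and
#' `origin` share the same prior the ratio cancels and this reduces to
#' [accept_probability()].
#'
#' @inheritParams accept_probability
#' @param prior a `person_prior`.
#' @param target index \eqn{p} of the target person.
#' @param origin index \eqn{q} of the prior the proposal was drawn from.
#' @return acceptance probability in \[0, 1\].
#' @export
accept_probability_cross_prior <- function(theta_cur, theta_star,
                                           stat_obs, stat_star,
                                           prior, target, origin) {
  if (!all(is.finite(c(theta_cur, theta_star, stat_obs, stat_star))))
    stop("all arguments must be finite")
  lr <- (theta_star - theta_cur) * (stat_obs - stat_star) +
    log_prior_density(prior, target, theta_star) -
    log_prior_density(prior, target, theta_cur) +
    log_prior_density(prior, origin, theta_cur) -
    log_prior_density(prior, origin, theta_star)
  exp(pmin(0, lr))
}

#' Generate an exchange proposal by composite sampling
#'
#' Draws \eqn{\theta^*} from the prior of person `origin`, simulates a
#' response vector from the model at \eqn{\theta^*}, and returns the pair
#' together with its sufficient statistic. Marginally the statistic follows
#' the mixing distribution \eqn{\pi(t(x^*))}, and conditional on
#' \eqn{t(x^*)} the value \eqn{\theta^*} is an exact draw from the posterior
#' \eqn{\pi(\theta \mid t(x^*))}.
#'
#' @param model an `irt_model`.
#' @param prior a `person_prior`.
#' @param origin prior index used to draw \eqn{\theta^*}.
#' @return list of class `"sve_proposal"` with elements `theta_star`,
#'   `stat_star`, `origin`.
#' @export
generate_proposal <- function(model, prior, origin = 1L) {
  theta_star <- sample_prior(prior, origin)
  structure(list(theta_star = theta_star,
                 stat_star = simulate_stats(model, theta_star),
                 origin = as.integer(origin)),
            class = "sve_proposal")
}

#' Chain state for one or more target posteriors
#'
#' Bundles the current \eqn{\theta'} and observed statistic \eqn{t(x)} for
#' each of `n` simultaneous targets, plus the history of acceptance and
#' direct-hit flags appended by the step functions.
#'
#' @param thetas numeric vector of current chain values, one per target.
#' @param observed_stats observed sufficient statistics, same length.
#' @return list of class `"chain_state"`.
#' @export
chain_state <- function(thetas, observed_stats) {
  if (length(thetas) != length(observed_stats))
    stop("'thetas' and 'observed_stats' must have equal length")
  structure(list(thetas = as.numeric(thetas),
                 observed_stats = as.numeric(observed_stats),
                 accept_history = logical(0),
                 hit_history = logical(0)),
            class = "chain_state")
}

# select index of the proposal whose statistic is closest to the target
# statistic; ties broken uniformly at random
select_closest <- function(stat_star, stat_obs) {
  d <- abs(stat_star - stat_obs)
  j <- which(d == min(d))
  if (length(j) > 1L) j <- j[sample.int(length(j), 1L)]
  j
}

#' One Single-Variable-Exchange update
#'
#' Generates one proposal from the target's own prior by composite sampling
#' and accepts it with the exchange probability. Equivalent to
#' [oversampled_sve_step()] with `m = 1`.
#'
#' @param state a [chain_state()].
#' @param target index of the target to update.
#' @param model an `irt_model`.
#' @param prior a `person_prior`.
#' @return the updated `chain_state`, with one acceptance flag and one
#'   direct-hit flag appended.
#' @export
sve_step <- function(state, target, model, prior)
  oversampled_sve_step(state, target, model, prior, m = 1L)

#' Oversampled Single-Variable-Exchange update
#'
#' Generates `m >= 1` proposals, keeps the one whose simulated statistic is
#' closest to the observed statistic (ties broken uniformly at random), and
#' offers only that proposal to the standard exchange accept step. Because
#' the selection uses the statistics alone -- never the current state -- the
#' target posterior remains the invariant distribution. `m = 1` is the
#' original SVE algorithm.
#'
#' @inheritParams sve_step
#' @param m number of proposals to oversample.
#' @return the updated `chain_state`.
#' @export
oversampled_sve_step <- function(state, target, model, prior, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be a positive integer")
  target <- as.integer(target)
  stat_obs <- state$observed_stats[target]
  theta_star <- sample_prior(prior, rep(target, m))
  stat_star <- simulate_stats(model, theta_star)
  j <- select_closest(stat_star, stat_obs)
  phi <- accept_probability(state$thetas[target], theta_star[j],
                            stat_obs, stat_star[j])
  accept <- stats::runif(1) < phi
  if (accept) state$thetas[target] <- theta_star[j]
  state$accept_history <- c(state$accept_history, accept)
  state$hit_history <- c(state$hit_history, stat_star[j] == stat_obs)
  state
}

# rank-match n proposals to n targets: order both by their matching
# statistic with a uniform tie-shuffle, pair by rank
match_by_rank <- function(target_match, proposal_match) {
  n <- length(target_match)
  ot <- order(target_match, stats::runif(n))
  op <- order(proposal_match, stats::runif(n))
  list(target = ot, proposal = op)
}

#' Matched multi-target exchange sweep
#'
#' Updates all `n` targets at once: generates exactly one proposal per
#' person (from that person's own prior), sorts targets and proposals by
#' their matching statistics (covariate-shifted under a latent regression
#' prior), pairs them by rank, and accepts each pair independently with the
#' cross-prior exchange probability. Every proposal is used at most once.
#' Rank pairing sends low simulated scores to low observed scores, so most
#' pairs are near-matches and acceptance rises sharply with `n`.
#'
#' @inheritParams sve_step
#' @return the updated `chain_state`, with `n` acceptance and hit flags
#'   appended (in target order).
#' @export
matched_multistep <- function(state, model, prior) {
  n <- length(state$thetas)
  persons <- seq_len(n)
  theta_star <- sample_prior(prior, persons)
  stat_star <- simulate_stats(model, theta_star)
  pairing <- match_by_rank(
    matching_statistic(prior, persons, state$observed_stats),
    matching_statistic(prior, persons, stat_star))
  p <- pairing$target
  q <- pairing$proposal
  phi <- accept_probability_cross_prior(
    state$thetas[p], theta_star[q],
    state$observed_stats[p], stat_star[q], prior, p, q)
  accept <- stats::runif(n) < phi
  state$thetas[p[accept]] <- theta_star[q[accept]]
  acc <- hit <- logical(n)
  acc[p] <- accept
  hit[p] <- stat_star[q] == state$observed_stats[p]
  state$accept_history <- c(state$accept_history, acc)
  state$hit_history <- c(state$hit_history, hit)
  state
}

#' Binned exchange proposal
#'
#' Regenerates composite-sampling proposals until the simulated statistic
#' falls in the open interval `(stat_obs - half_width, stat_obs +
#' half_width)`, up to `max_tries` draws. The returned proposal then enters
#' the ordinary exchange accept step; the Metropolis correction keeps the
#' target posterior invariant for any `half_width`, which only tunes
#' proposal quality. `half_width = Inf` returns the first draw (original
#' SVE).
#'
#' @inheritParams generate_proposal
#' @param stat_obs observed sufficient statistic at the bin center.
#' @param half_width bin half-width \eqn{a > 0}, possibly `Inf`.
#' @param max_tries cap on the number of draws; if exhausted the last draw
#'   is returned with `capped = TRUE` rather than looping forever.
#' @return list with elements `proposal` (an `"sve_proposal"`), `tries`
#'   (number of draws generated) and `capped` (logical).
#' @export
binned_proposal <- function(model, prior, stat_obs, half_width,
                            max_tries = 1e5, origin = 1L) {
  if (!(half_width > 0)) stop("'half_width' must be > 0")
  tries <- 0L
  repeat {
    prop <- generate_proposal(model, prior, origin)
    tries <- tries + 1L
    inside <- is.infinite(half_width) ||
      abs(prop$stat_star - stat_obs) < half_width
    if (inside)
      return(list(proposal = prop, tries = tries, capped = FALSE))
    if (tries >= max_tries)
      return(list(proposal = prop, tries = tries, capped = TRUE))
  }
}

#' Binned exchange update
#'
#' One chain update using [binned_proposal()] followed by the standard
#' exchange accept step.
#'
#' @inheritParams sve_step
#' @inheritParams binned_proposal
#' @return the updated `chain_state`; the number of draws used is appended
#'   to `state$tries_history`.
#' @export
binned_sve_step <- function(state, target, model, prior, half_width,
                            max_tries = 1e5) {
  target <- as.integer(target)
  stat_obs <- state$observed_stats[target]
  bp <- binned_proposal(model, prior, stat_obs, half_width, max_tries,
                        origin = target)
  phi <- accept_probability(state$thetas[target], bp$proposal$theta_star,
                            stat_obs, bp$proposal$stat_star)
  accept <- stats::runif(1) < phi
  if (accept) state$thetas[target] <- bp$proposal$theta_star
  state$accept_history <- c(state$accept_history, accept)
  state$hit_history <- c(state$hit_history,
                         bp$proposal$stat_star == stat_obs)
  state$tries_history <- c(state$tries_history, bp$tries)
  state
}

#' Score-count multiset for recycling rejection
#'
#' Multiplicities \eqn{n_{x_+}} of the observed discrete scores among the
#' persons to be sampled, used by [recycling_rejection()].
#'
#' @param scores integer vector of observed test scores.
#' @param k number of items (support is `0:k`).
#' @return named integer vector of class `"score_counts"` over `0:k`.
#' @export
score_counts <- function(scores, k) {
  if (any(scores != round(scores)) || any(scores < 0 | scores > k))
    stop("scores must lie in the statistic's support 0..k")
  scores <- as.integer(round(scores))
  counts <- tabulate(scores + 1L, nbins = k + 1L)
  structure(stats::setNames(counts, 0:k), class = "score_counts")
}

# consume a fixed stream of proposals: retain a draw whenever its score
# still has positive multiplicity, stopping when all multiplicities are 0.
# Returns retained draws per score and the index of the last draw consumed.
recycle_stream <- function(stat_stream, theta_stream, counts) {
  remaining <- as.integer(counts)
  support <- as.integer(names(counts))
  draws <- lapply(seq_along(support), function(i)
    numeric(0))
  names(draws) <- names(counts)
  used <- 0L
  for (t in seq_along(stat_stream)) {
    i <- match(stat_stream[t], support)
    if (!is.na(i) && remaining[i] > 0L) {
      remaining[i] <- remaining[i] - 1L
      draws[[i]] <- c(draws[[i]], theta_stream[t])
      if (all(remaining == 0L)) {
        used <- t
        break
      }
    }
    used <- t
  }
  list(draws = draws, used = used, remaining = remaining)
}

#' Recycling rejection sampler for pooled discrete scores
#'
#' Exact posterior sampling for many persons under a common prior by
#' recycling composite-sampling proposals: each proposal \eqn{(\theta^*,
#' x_+^*)} is retained for any person whose observed score equals
#' \eqn{x_+^*} and still has outstanding multiplicity, otherwise it is
#' rejected. Retained values are exact i.i.d. draws from \eqn{\pi(\theta
#' \mid x_+)} -- no Metropolis step is needed. With total multiplicity 1
#' this is the classical single-target rejection sampler; as the number of
#' pooled targets grows, the cost approaches one proposal per retained
#' draw.
#'
#' @param counts a [score_counts()] multiset of required draws per score.
#' @param model an `irt_model` whose statistic has support `0:k` (Rasch).
#' @param prior a common [normal_prior()] (the pooling argument requires
#'   all persons to share one prior).
#' @param max_draws cap on generated proposals; on exhaustion a partial
#'   result is returned with the unfilled multiplicities reported.
#' @param batch internal batch size for vectorized generation.
#' @return list with `draws` (list of numeric vectors, one per score),
#'   `proposals_generated`, and `unfilled` (remaining multiplicities,
#'   all zero unless `max_draws` was exhausted).
#' @export
recycling_rejection <- function(counts, model, prior, max_draws = 1e7,
                                batch = 10000L) {
  if (!inherits(prior, "normal_prior"))
    stop("recycling rejection requires a common normal prior")
  if (!inherits(counts, "score_counts"))
    stop("'counts' must be a score_counts object")
  k <- n_items(model)
  if (length(counts) != k + 1L)
    stop("'counts' support does not match the model's item count")
  if (sum(counts) < 1L) stop("total multiplicity must be at least 1")
  remaining <- as.integer(counts)
  support <- 0:k
  draws <- lapply(support, function(s) numeric(0))
  names(draws) <- names(counts)
  generated <- 0L
  while (any(remaining > 0L) && generated < max_draws) {
    nb <- as.integer(min(batch, max_draws - generated))
    theta <- sample_prior(prior, rep(1L, nb))
    stat <- simulate_stats(model, theta)
    # index, per needed score, of its remaining-th occurrence in the batch
    last_needed <- 0L
    for (i in which(remaining > 0L)) {
      idx <- which(stat == support[i])
      take <- idx[seq_len(min(length(idx), remaining[i]))]
      if (length(take)) {
        draws[[i]] <- c(draws[[i]], theta[take])
        remaining[i] <- remaining[i] - length(take)
      }
      if (remaining[i] == 0L && length(take))
        last_needed <- max(last_needed, take[length(take)])
    }
    if (all(remaining == 0L)) {
      # count only the proposals up to the draw that filled the last slot
      generated <- generated + last_needed
    } else {
      generated <- generated + nb
    }
  }
  list(draws = draws, proposals_generated = generated,
       unfilled = stats::setNames(remaining, names(counts)))
}

#' Binned recycling for continuous statistics
#'
#' Composition of statistic binning and recycling: observed (possibly
#' continuous) statistics are partitioned into non-overlapping bins, a
#' proposal whose simulated statistic falls in a bin with outstanding
#' targets is assigned to one of them, and the assignment is then subjected
#' to the ordinary exchange accept step (exact matches are no longer
#' guaranteed, so the Metropolis correction is required).
#'
#' @param state a [chain_state()].
#' @param model an `irt_model`.
#' @param prior a common [normal_prior()].
#' @param breaks increasing numeric vector of bin boundaries covering all
#'   observed statistics.
#' @param max_draws cap on generated proposals.
#' @return the updated `chain_state` with `n` flags appended, plus an
#'   attribute `"proposals_generated"` on the returned state.
#' @export
binned_recycling_sweep <- function(state, model, prior, breaks,
                                   max_draws = 1e6) {
  if (!inherits(prior, "normal_prior"))
    stop("binned recycling requires a common normal prior")
  n <- length(state$thetas)
  bin_of <- findInterval(state$observed_stats, breaks,
                         rightmost.closed = TRUE)
  n_bins <- length(breaks) - 1L
  if (any(bin_of < 1L | bin_of > n_bins))
    stop("'breaks' must cover all observed statistics")
  unfilled <- lapply(seq_len(n_bins), function(b) which(bin_of == b))
  filled_theta <- rep(NA_real_, n)
  filled_stat <- rep(NA_real_, n)
  generated <- 0L
  while (any(lengths(unfilled) > 0L) && generated < max_draws) {
    theta <- sample_prior(prior, 1L)
    stat <- simulate_stats(model, theta)
    generated <- generated + 1L
    b <- findInterval(stat, breaks, rightmost.closed = TRUE)
    if (b >= 1L && b <= length(unfilled) && length(unfilled[[b]]) > 0L) {
      pick <- unfilled[[b]][1L]
      unfilled[[b]] <- unfilled[[b]][-1L]
      filled_theta[pick] <- theta
      filled_stat[pick] <- stat
    }
  }
  got <- which(!is.na(filled_theta))
  acc <- hit <- logical(n)
  if (length(got)) {
    phi <- accept_probability(state$thetas[got], filled_theta[got],
                              state$observed_stats[got], filled_stat[got])
    accept <- stats::runif(length(got)) < phi
    state$thetas[got[accept]] <- filled_theta[got[accept]]
    acc[got] <- accept
    hit[got] <- filled_stat[got] == state$observed_stats[got]
  }
  state$accept_history <- c(state$accept_history, acc)
  state$hit_history <- c(state$hit_history, hit)
  attr(state, "proposals_generated") <- generated
  state
}
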