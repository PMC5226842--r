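#' Draw the augmented vector for a Rasch person
#'
#' Draws the joint vector \eqn{w = (w_1, \ldots, w_k, w_{k+1})} behind the
#' logistic latent-response representation of the Rasch model:
#' \eqn{w_{k+1} = \theta} from the person prior and \eqn{w_i = z_i +
#' \delta_i} with \eqn{z_i} standard logistic, so that \eqn{x_i = 1 \iff
#' w_i < w_{k+1}} reproduces the Rasch response law
#' \eqn{P(X_i = 1 \mid \theta) = \mathrm{logit}^{-1}(\theta - \delta_i)}.
#'
#' @param model a [rasch_model()].
#' @param prior a common [normal_prior()].
#' @return numeric vector of length `n_items(model) + 1`, the last element
#'   being the person parameter.
#' @export
draw_augmented <- function(model, prior) {
  if (!inherits(model, "rasch"))
    stop("the augmented construction is defined for the Rasch model")
  k <- n_items(model)
  c(stats::rlogis(k) + model$difficulties, sample_prior(prior, 1L))
}

#' Candidate proposals and their statistics from an augmented vector
#'
#' Every component \eqn{w_j} of the augmented vector is a candidate
#' proposal, with realized statistic \eqn{s_j = \#\{i \ne j : w_i < w_j\}}
#' -- the test score the remaining components generate when \eqn{w_j} plays
#' the role of the person parameter. Candidate \eqn{k+1} reproduces the
#' ordinary simulated test score. When all components are distinct the
#' statistics are a permutation of \eqn{\{0, \ldots, k\}}, so every
#' possible observed score has exactly one exactly-matching candidate.
#' Exact ties (a measure-zero event for continuous draws) count
#' \eqn{[w_i < w_j]} as false.
#'
#' @param w augmented vector from [draw_augmented()].
#' @return list with `values` (= `w`) and integer `stats` of the same
#'   length.
#' @export
candidate_statistics <- function(w) {
  if (!all(is.finite(w))) stop("'w' must be finite")
  stats <- vapply(seq_along(w),
                  function(j) sum(w[-j] < w[j]), integer(1))
  list(values = w, stats = stats)
}

#' Augmented-variable exchange update
#'
#' One chain update using the augmented proposal scheme: a single draw of
#' the augmented vector yields \eqn{k + 1} candidate proposals, of which
#' the one whose realized statistic equals the observed score is selected
#' (it exists with probability one) and offered with the exchange ratio
#' \eqn{\min\{1, \exp[(\theta^* - \theta')(x_+ - s_j)]\}} times a
#' candidate-model correction. For the exact-match candidate the exponent
#' is zero and the default correction is unity, so the move is accepted
#' with probability one; acceptance therefore stays high however large
#' \eqn{k} grows, in contrast to the plain SVE kernel. The correction for
#' non-exact-match candidates (reached only through the degenerate tie
#' fallback) is exposed through `log_correction`.
#'
#' @inheritParams sve_step
#' @param log_correction function `(w, j, stat_obs)` returning the log of
#'   the candidate-model correction factor; the default returns 0.
#' @return the updated `chain_state`.
#' @export
augmented_sve_step <- function(state, target, model, prior,
                               log_correction = function(w, j, stat_obs) 0) {
  target <- as.integer(target)
  stat_obs <- state$observed_stats[target]
  w <- draw_augmented(model, prior)
  cs <- candidate_statistics(w)
  j <- which(cs$stats == stat_obs)
  if (length(j) == 0L) {
    # fully tied draw: fall back to the ordinary candidate theta = w[k+1]
    j <- length(w)
  } else if (length(j) > 1L) {
    j <- j[sample.int(length(j), 1L)]
  }
  lr <- (w[j] - state$thetas[target]) * (stat_obs - cs$stats[j]) +
    log_correction(w, j, stat_obs)
  accept <- stats::runif(1) < exp(min(0, lr))
  if (accept) state$thetas[target] <- w[j]
  state$accept_history <- c(state$accept_history, accept)
  state$hit_history <- c(state$hit_history, cs$stats[j] == stat_obs)
  state
}
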