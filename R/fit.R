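#' Sample person posteriors by the exchange algorithm
#'
#' The main fitting function: draws from the posterior distributions
#' \eqn{\pi(\theta_p \mid x_p)} of the person parameters of a fixed Rasch or
#' two-parameter logistic model, using the Single-Variable-Exchange
#' algorithm or one of its generalizations. All kernels rely only on the
#' ability to simulate data from the model: a proposal is a prior draw
#' \eqn{\theta^*} together with the sufficient statistic of data simulated
#' at \eqn{\theta^*}, and the exchange acceptance ratio
#' \eqn{\min\{1, \exp[(\theta^* - \theta')(t(x) - t(x^*))]\}} never touches
#' the likelihood's normalizing constant.
#'
#' Kernels:
#' \describe{
#'   \item{`"sve"`}{the original algorithm; one proposal per target per
#'     iteration.}
#'   \item{`"oversample"`}{`m` proposals per target; the one with statistic
#'     closest to the observed statistic is offered.}
#'   \item{`"match"`}{all `n` targets updated per sweep from `n` proposals
#'     paired to targets by the rank of their matching statistics.}
#'   \item{`"bin"`}{proposals regenerated until the statistic falls within
#'     `half_width` of the observed statistic (for weighted 2PL scores).}
#'   \item{`"augment"`}{one augmented-vector draw yields `k + 1`
#'     candidates; the exactly-matching one is offered (Rasch, common
#'     prior).}
#'   \item{`"recycle"`}{exact i.i.d. posterior draws by pooled rejection
#'     over the discrete score multiset (Rasch, common prior); no Markov
#'     chain is involved.}
#' }
#'
#' @param responses binary response matrix (persons x items), a single
#'   response vector, or `NULL` if `observed_stats` is given directly.
#' @param model an `irt_model` from [rasch_model()] or [twopl_model()].
#' @param prior a `person_prior`; defaults to the standard normal.
#' @param kernel which transition kernel to use; see Details.
#' @param m oversampling count (kernel `"oversample"`).
#' @param half_width bin half-width \eqn{a} (kernel `"bin"`); `Inf`
#'   reproduces plain SVE.
#' @param iterations number of post-initialization sweeps (or i.i.d.
#'   draws per person for `"recycle"`).
#' @param burn fraction of initial sweeps discarded by the summary
#'   methods (draws are kept; default 0.1).
#' @param observed_stats observed sufficient statistics, overriding
#'   `responses`.
#' @param init initial chain values (default: prior means).
#' @param seed optional integer passed to [set.seed()].
#' @param max_tries cap on draws per binned proposal.
#' @return An object of class `"sve_fit"`: a list with `draws`
#'   (iterations x persons), `accept` and `hits` (logical matrices),
#'   `observed_stats`, the model, prior and sampler settings, and -- for
#'   the recycling kernel -- `proposals_generated`.
#' @examples
#' m <- rasch_model(rep(0, 10))
#' fit <- sve(observed_stats = 4, model = m, iterations = 2000, seed = 1)
#' coef(fit)
#' summary(fit)
#' @export
sve <- function(responses = NULL, model, prior = normal_prior(),
                kernel = c("sve", "oversample", "match", "bin",
                           "augment", "recycle"),
                m = 1L, half_width = Inf, iterations = 10000L,
                burn = 0.1, observed_stats = NULL, init = NULL,
                seed = NULL, max_tries = 1e5) {
  kernel <- match.arg(kernel)
  if (!inherits(model, "irt_model")) stop("'model' must be an irt_model")
  if (is.null(observed_stats)) {
    if (is.null(responses))
      stop("supply 'responses' or 'observed_stats'")
    if (is.vector(responses)) responses <- matrix(responses, nrow = 1L)
    if (ncol(responses) != n_items(model))
      stop("response matrix has wrong number of items")
    observed_stats <- apply(responses, 1L, sufficient_statistic,
                            model = model)
  }
  n <- length(observed_stats)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("'iterations' must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- prior_moments(prior, seq_len(n))$mean
  init <- rep_len(as.numeric(init), n)

  res <- switch(kernel,
    sve = run_independent(model, prior, observed_stats, init,
                          iterations, 1L),
    oversample = run_independent(model, prior, observed_stats, init,
                                 iterations, as.integer(m)),
    match = run_matched(model, prior, observed_stats, init, iterations),
    bin = run_binned(model, prior, observed_stats, init, iterations,
                     half_width, max_tries),
    augment = run_augmented(model, prior, observed_stats, init,
                            iterations),
    recycle = run_recycled(model, prior, observed_stats, iterations))

  structure(c(res, list(
    observed_stats = observed_stats, model = model, prior = prior,
    kernel = kernel, m = as.integer(m), half_width = half_width,
    iterations = iterations, burn = burn, seed = seed,
    call = match.call())), class = "sve_fit")
}

# independent per-person updates, m-fold oversampled (m = 1: plain SVE)
run_independent <- function(model, prior, sobs, init, iters, m) {
  if (m < 1L) stop("'m' must be a positive integer")
  n <- length(sobs)
  persons <- seq_len(n)
  draws <- matrix(NA_real_, iters, n)
  accept <- hits <- matrix(NA, iters, n)
  th <- init
  sobs_rep <- rep(sobs, each = m)
  origin <- rep(persons, each = m)
  for (t in seq_len(iters)) {
    th_star <- sample_prior(prior, origin)
    st <- simulate_stats(model, th_star)
    if (m == 1L) {
      j <- persons
    } else {
      d <- matrix(abs(st - sobs_rep), m, n)
      j <- (persons - 1L) * m +
        max.col(-t(d), ties.method = "random")
    }
    lr <- (th_star[j] - th) * (sobs - st[j])
    acc <- log(stats::runif(n)) < pmin(0, lr)
    th[acc] <- th_star[j][acc]
    draws[t, ] <- th
    accept[t, ] <- acc
    hits[t, ] <- st[j] == sobs
  }
  list(draws = draws, accept = accept, hits = hits)
}

# rank-matched joint sweep over all persons
run_matched <- function(model, prior, sobs, init, iters) {
  n <- length(sobs)
  persons <- seq_len(n)
  draws <- matrix(NA_real_, iters, n)
  accept <- hits <- matrix(NA, iters, n)
  th <- init
  tmatch <- matching_statistic(prior, persons, sobs)
  for (t in seq_len(iters)) {
    th_star <- sample_prior(prior, persons)
    st <- simulate_stats(model, th_star)
    pr <- match_by_rank(tmatch, matching_statistic(prior, persons, st))
    p <- pr$target
    q <- pr$proposal
    lr <- (th_star[q] - th[p]) * (sobs[p] - st[q]) +
      log_prior_density(prior, p, th_star[q]) -
      log_prior_density(prior, p, th[p]) +
      log_prior_density(prior, q, th[p]) -
      log_prior_density(prior, q, th_star[q])
    acc <- log(stats::runif(n)) < pmin(0, lr)
    th[p[acc]] <- th_star[q][acc]
    draws[t, ] <- th
    accept[t, p] <- acc
    hits[t, p] <- st[q] == sobs[p]
  }
  list(draws = draws, accept = accept, hits = hits)
}

# binned proposals: regenerate until the statistic is within half_width
run_binned <- function(model, prior, sobs, init, iters, half_width,
                       max_tries) {
  if (!(half_width > 0)) stop("'half_width' must be > 0")
  n <- length(sobs)
  persons <- seq_len(n)
  draws <- matrix(NA_real_, iters, n)
  accept <- hits <- matrix(NA, iters, n)
  tries <- matrix(NA_integer_, iters, n)
  th <- init
  for (t in seq_len(iters)) {
    open <- persons
    th_star <- st <- numeric(n)
    ntry <- integer(n)
    repeat {
      cand <- sample_prior(prior, open)
      cst <- simulate_stats(model, cand)
      ntry[open] <- ntry[open] + 1L
      ok <- is.infinite(half_width) |
        abs(cst - sobs[open]) < half_width
      give_up <- !ok & ntry[open] >= max_tries
      done <- ok | give_up
      th_star[open[done]] <- cand[done]
      st[open[done]] <- cst[done]
      open <- open[!done]
      if (!length(open)) break
    }
    lr <- (th_star - th) * (sobs - st)
    acc <- log(stats::runif(n)) < pmin(0, lr)
    th[acc] <- th_star[acc]
    draws[t, ] <- th
    accept[t, ] <- acc
    hits[t, ] <- st == sobs
    tries[t, ] <- ntry
  }
  list(draws = draws, accept = accept, hits = hits, tries = tries)
}

# augmented-variable proposals (Rasch, common prior)
run_augmented <- function(model, prior, sobs, init, iters) {
  if (!inherits(model, "rasch"))
    stop("the augmented kernel is defined for the Rasch model")
  if (!inherits(prior, "normal_prior"))
    stop("the augmented kernel requires a common prior")
  n <- length(sobs)
  k <- n_items(model)
  draws <- matrix(NA_real_, iters, n)
  accept <- hits <- matrix(NA, iters, n)
  th <- init
  for (t in seq_len(iters)) {
    for (p in seq_len(n)) {
      w <- c(stats::rlogis(k) + model$difficulties,
             sample_prior(prior, p))
      s <- rank(w, ties.method = "min") - 1L
      j <- which(s == sobs[p])
      if (length(j) == 0L) j <- k + 1L
      else if (length(j) > 1L) j <- j[sample.int(length(j), 1L)]
      lr <- (w[j] - th[p]) * (sobs[p] - s[j])
      if (log(stats::runif(1)) < min(0, lr)) {
        th[p] <- w[j]
        accept[t, p] <- TRUE
      } else accept[t, p] <- FALSE
      hits[t, p] <- s[j] == sobs[p]
    }
    draws[t, ] <- th
  }
  list(draws = draws, accept = accept, hits = hits)
}

# exact i.i.d. draws via pooled recycling rejection
run_recycled <- function(model, prior, sobs, iters) {
  if (!inherits(model, "rasch"))
    stop("the recycling kernel requires a discrete score (Rasch model)")
  k <- n_items(model)
  counts <- score_counts(sobs, k)
  total <- structure(counts * iters, names = names(counts),
                     class = "score_counts")
  rr <- recycling_rejection(total, model, prior)
  if (any(rr$unfilled > 0L))
    warning("recycling rejection exhausted 'max_draws'; ",
            "some draws are missing")
  n <- length(sobs)
  draws <- matrix(NA_real_, iters, n)
  for (s in unique(sobs)) {
    cols <- which(sobs == s)
    got <- rr$draws[[as.character(s)]]
    sub <- matrix(NA_real_, iters, length(cols))
    sub[seq_len(min(length(got), length(sub)))] <-
      got[seq_len(min(length(got), length(sub)))]
    draws[, cols] <- sub
  }
  list(draws = draws,
       accept = matrix(NA, iters, n), hits = matrix(TRUE, iters, n),
       proposals_generated = rr$proposals_generated)
}

#' Post-burn-in posterior draws
#'
#' @param object an `sve_fit`.
#' @return numeric matrix of retained draws (rows) by person (columns).
#' @export
posterior_draws <- function(object) {
  stopifnot(inherits(object, "sve_fit"))
  nb <- floor(object$burn * object$iterations)
  object$draws[(nb + 1):object$iterations, , drop = FALSE]
}

#' @export
print.sve_fit <- function(x, ...) {
  n <- ncol(x$draws)
  cat(sprintf("Exchange-algorithm fit (kernel \"%s\"): %d person%s, %d iterations\n",
              x$kernel, n, if (n > 1) "s" else "", x$iterations))
  ar <- x$accept
  if (!all(is.na(ar)))
    cat(sprintf("  acceptance rate: %.3f\n", mean(ar, na.rm = TRUE)))
  if (!is.null(x$proposals_generated))
    cat(sprintf("  proposals generated: %d (%.2f per retained draw)\n",
                x$proposals_generated,
                x$proposals_generated / length(x$draws)))
  invisible(x)
}

#' @export
summary.sve_fit <- function(object, ...) {
  d <- posterior_draws(object)
  nb <- floor(object$burn * object$iterations)
  keep <- (nb + 1):object$iterations
  n <- ncol(d)
  per <- data.frame(
    person = seq_len(n),
    observed_stat = object$observed_stats,
    mean = colMeans(d, na.rm = TRUE),
    sd = apply(d, 2L, stats::sd, na.rm = TRUE),
    acceptance = colMeans(object$accept[keep, , drop = FALSE]),
    direct_hit = colMeans(object$hits[keep, , drop = FALSE]),
    ess = apply(d, 2L, function(z)
      effective_sample_size(z[!is.na(z)]))
  )
  structure(list(kernel = object$kernel, per_person = per,
                 burn_discarded = nb),
            class = "summary.sve_fit")
}

#' @export
print.summary.sve_fit <- function(x, ...) {
  cat(sprintf("Kernel \"%s\" (%d burn-in sweeps discarded)\n",
              x$kernel, x$burn_discarded))
  print(format(x$per_person, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.sve_fit <- function(object, ...) {
  means <- colMeans(posterior_draws(object), na.rm = TRUE)
  stats::setNames(means, paste0("theta.", seq_along(means)))
}

#' @export
predict.sve_fit <- function(object, type = c("probability", "score"),
                            thin_to = 500L, ...) {
  type <- match.arg(type)
  d <- posterior_draws(object)
  idx <- unique(round(seq(1L, nrow(d), length.out = min(thin_to, nrow(d)))))
  n <- ncol(d)
  k <- n_items(object$model)
  pp <- matrix(0, n, k)
  for (i in idx) pp <- pp + prob_matrix(object$model, d[i, ])
  pp <- pp / length(idx)
  if (type == "probability") pp else
    as.numeric(pp %*% (if (inherits(object$model, "twopl"))
      object$model$discriminations else rep(1, k)))
}

#' @export
residuals.sve_fit <- function(object, ...) {
  object$observed_stats - predict(object, type = "score")
}

#' @export
simulate.sve_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- posterior_draws(object)
  k <- n_items(object$model)
  n <- ncol(d)
  lapply(seq_len(nsim), function(s) {
    th <- d[cbind(sample.int(nrow(d), n, replace = TRUE), seq_len(n))]
    p <- prob_matrix(object$model, th)
    (matrix(stats::runif(n * k), n, k) < p) + 0L
  })
}

#' @export
plot.sve_fit <- function(x, person = 1L, ...) {
  d <- posterior_draws(x)[, person]
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(d, type = "l", xlab = "iteration",
                 ylab = expression(theta),
                 main = sprintf("trace, person %d", person))
  graphics::hist(d, breaks = 40, freq = FALSE, xlab = expression(theta),
                 main = sprintf("posterior, person %d", person))
  invisible(x)
}
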