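#' Rasch model
#'
#' Constructs a Rasch (one-parameter logistic) item response model with fixed
#' item difficulties. Under the Rasch model the probability of a correct
#' response to item \eqn{i} for a person with ability \eqn{\theta} is
#' \eqn{P(X_i = 1 \mid \theta) = \mathrm{logit}^{-1}(\theta - \delta_i)}, and
#' the test score \eqn{x_+ = \sum_i x_i} is sufficient for \eqn{\theta}.
#'
#' @param difficulties numeric vector of item difficulties \eqn{\delta} on the
#'   logit scale; its length sets the number of items.
#' @return An object of class `c("rasch", "irt_model")`.
#' @examples
#' m <- rasch_model(c(-1, 0, 1))
#' response_probabilities(m, theta = 0)
#' @export
rasch_model <- function(difficulties) {
  difficulties <- as.numeric(difficulties)
  if (length(difficulties) < 1L || !all(is.finite(difficulties)))
    stop("'difficulties' must be a nonempty vector of finite values")
  structure(list(difficulties = difficulties),
            class = c("rasch", "irt_model"))
}

#' Two-parameter logistic model
#'
#' Constructs a two-parameter logistic (2PL) model with fixed item
#' discriminations \eqn{\alpha} and difficulties \eqn{\delta}:
#' \eqn{P(X_i = 1 \mid \theta) = \mathrm{logit}^{-1}(\alpha_i \theta -
#' \delta_i)}. The discrimination-weighted score \eqn{t(x) = \sum_i \alpha_i
#' x_i} is sufficient for \eqn{\theta}.
#'
#' @param discriminations numeric vector of item discriminations \eqn{\alpha}
#'   (typically positive).
#' @param difficulties numeric vector of item difficulties \eqn{\delta}, same
#'   length as `discriminations`.
#' @return An object of class `c("twopl", "irt_model")`.
#' @examples
#' m <- twopl_model(discriminations = c(0.5, 2), difficulties = c(0, 0))
#' sufficient_statistic(m, c(1, 1))
#' @export
twopl_model <- function(discriminations, difficulties) {
  discriminations <- as.numeric(discriminations)
  difficulties <- as.numeric(difficulties)
  if (length(discriminations) != length(difficulties))
    stop("'discriminations' and 'difficulties' must have equal length")
  if (length(difficulties) < 1L || !all(is.finite(difficulties)) ||
      !all(is.finite(discriminations)))
    stop("item parameters must be nonempty and finite")
  structure(list(discriminations = discriminations,
                 difficulties = difficulties),
            class = c("twopl", "irt_model"))
}

#' Number of items of a model
#' @param model an `irt_model`.
#' @return integer item count \eqn{k}.
#' @export
n_items <- function(model) length(model$difficulties)

#' @export
print.irt_model <- function(x, ...) {
  k <- n_items(x)
  if (inherits(x, "rasch")) {
    cat(sprintf("Rasch model, %d items\n", k))
  } else {
    cat(sprintf("Two-parameter logistic model, %d items\n", k))
    cat("  discriminations:", format(x$discriminations, digits = 3), "\n")
  }
  cat("  difficulties:   ", format(x$difficulties, digits = 3), "\n")
  invisible(x)
}

#' Item response probabilities
#'
#' Success probability of each item at a given ability.
#'
#' @param model an `irt_model` (from [rasch_model()] or [twopl_model()]).
#' @param theta finite scalar ability.
#' @return numeric vector of length `n_items(model)` with values in (0, 1).
#' @export
response_probabilities <- function(model, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("'theta' must be a finite scalar")
  UseMethod("response_probabilities")
}

#' @export
response_probabilities.rasch <- function(model, theta)
  stats::plogis(theta - model$difficulties)

#' @export
response_probabilities.twopl <- function(model, theta)
  stats::plogis(model$discriminations * theta - model$difficulties)

# success-probability matrix for a vector of abilities (persons x items);
# the vectorized workhorse behind simulation and the chain drivers
prob_matrix <- function(model, thetas) UseMethod("prob_matrix")

#' @export
prob_matrix.rasch <- function(model, thetas)
  stats::plogis(outer(thetas, model$difficulties, "-"))

#' @export
prob_matrix.twopl <- function(model, thetas)
  stats::plogis(outer(thetas, model$discriminations) -
                  matrix(model$difficulties, length(thetas),
                         n_items(model), byrow = TRUE))

#' Simulate an item response vector
#'
#' Draws one binary response vector from the model at ability `theta`
#' (independent Bernoulli items). Reproducible under [set.seed()].
#'
#' @inheritParams response_probabilities
#' @return integer 0/1 vector of length `n_items(model)`.
#' @export
simulate_responses <- function(model, theta) {
  p <- response_probabilities(model, theta)
  as.integer(stats::runif(length(p)) < p)
}

# simulate sufficient statistics for a vector of abilities in one shot
simulate_stats <- function(model, thetas) {
  n <- length(thetas)
  if (n == 0L) return(numeric(0))
  k <- n_items(model)
  x <- matrix(stats::runif(n * k), n, k) < prob_matrix(model, thetas)
  if (inherits(model, "rasch")) rowSums(x) else
    as.numeric(x %*% model$discriminations)
}

#' Sufficient statistic of a response vector
#'
#' The test score \eqn{x_+ = \sum_i x_i} for the Rasch model, or the
#' discrimination-weighted score \eqn{\sum_i \alpha_i x_i} for the 2PL.
#'
#' @param model an `irt_model`.
#' @param x binary response vector of length `n_items(model)`.
#' @return scalar statistic.
#' @export
sufficient_statistic <- function(model, x) {
  if (length(x) != n_items(model))
    stop("response vector length does not match the model's item count")
  if (!all(x %in% c(0, 1)))
    stop("responses must be 0/1")
  UseMethod("sufficient_statistic")
}

#' @export
sufficient_statistic.rasch <- function(model, x) sum(x)

#' @export
sufficient_statistic.twopl <- function(model, x)
  sum(model$discriminations * x)

#' Common normal prior
#'
#' A single normal prior \eqn{N(\mu, \sigma^2)} shared by all persons.
#'
#' @param mean prior mean.
#' @param sd prior standard deviation, > 0.
#' @return An object of class `c("normal_prior", "person_prior")`.
#' @export
normal_prior <- function(mean = 0, sd = 1) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0)
    stop("'mean' must be finite and 'sd' > 0")
  structure(list(mean = mean, sd = sd),
            class = c("normal_prior", "person_prior"))
}

#' Latent regression prior
#'
#' Person-specific normal priors indexed by covariates: person \eqn{p} has
#' prior \eqn{\theta_p \sim N(y_p^T \beta, \sigma^2)} where \eqn{y_p} is row
#' \eqn{p} of the covariate matrix.
#'
#' @param covariates numeric matrix Y (persons x covariates).
#' @param weights numeric vector \eqn{\beta}, length `ncol(covariates)`.
#' @param residual_var residual variance \eqn{\sigma^2 > 0}.
#' @return An object of class `c("latreg_prior", "person_prior")`.
#' @export
latent_regression_prior <- function(covariates, weights, residual_var) {
  covariates <- as.matrix(covariates)
  if (ncol(covariates) != length(weights))
    stop("'weights' length must equal ncol(covariates)")
  if (!is.finite(residual_var) || residual_var <= 0)
    stop("'residual_var' must be > 0")
  structure(list(covariates = covariates, weights = as.numeric(weights),
                 residual_var = residual_var,
                 means = as.numeric(covariates %*% weights)),
            class = c("latreg_prior", "person_prior"))
}

check_person <- function(prior, person) {
  person <- as.integer(person)
  if (inherits(prior, "latreg_prior") &&
      (any(person < 1L) || any(person > nrow(prior$covariates))))
    stop("person index out of range for the latent regression prior")
  person
}

#' Prior mean and standard deviation for a person
#' @param prior a `person_prior`.
#' @param person person index (vectorized); ignored by the common prior.
#' @return list with numeric `mean` and `sd`.
#' @export
prior_moments <- function(prior, person = 1L) {
  person <- check_person(prior, person)
  if (inherits(prior, "normal_prior"))
    list(mean = rep(prior$mean, length(person)),
         sd = rep(prior$sd, length(person)))
  else
    list(mean = prior$means[person],
         sd = rep(sqrt(prior$residual_var), length(person)))
}

#' Draw from a person's prior
#'
#' @inheritParams prior_moments
#' @return numeric vector of draws, one per element of `person`.
#' @export
sample_prior <- function(prior, person = 1L) {
  mo <- prior_moments(prior, person)
  stats::rnorm(length(mo$mean), mo$mean, mo$sd)
}

#' Log prior density for a person
#'
#' @inheritParams prior_moments
#' @param theta finite ability value (vectorized over `person`).
#' @return log normal density value(s).
#' @export
log_prior_density <- function(prior, person = 1L, theta) {
  if (!all(is.finite(theta))) stop("'theta' must be finite")
  mo <- prior_moments(prior, person)
  stats::dnorm(theta, mo$mean, mo$sd, log = TRUE)
}

#' Matching statistic for proposal-to-target assignment
#'
#' The statistic used to order targets and proposals when matching: the
#' observed (or simulated) sufficient statistic, shifted under a latent
#' regression prior by the covariate term \eqn{y_p^T \beta / \sigma^2}, so
#' that proposals land on targets whose posterior they resemble.
#'
#' @inheritParams prior_moments
#' @param stat observed or simulated sufficient statistic (vectorized).
#' @return numeric matching statistic.
#' @export
matching_statistic <- function(prior, person = 1L, stat) {
  person <- check_person(prior, person)
  if (inherits(prior, "normal_prior")) return(stat)
  stat + prior$means[person] / prior$residual_var
}
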