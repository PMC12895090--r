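#' Model configuration
#'
#' Fixed quantities of the dispersal-observation model: the Student-t
#' degrees of freedom (nu = 5, a moderate heavy tail), the reach length L
#' in meters (430, upstream terminal; the downstream end is 0), and the
#' weakly informative prior hyperparameters — Normal(0, 2.5^2) for the
#' intercept, Normal(0, 1^2) for coefficients, and Normal(0.5, 1^2)
#' truncated to (0, 1) for the recapture probability.
#'
#' @param nu Student-t degrees of freedom (fixed, not estimated).
#' @param L reach length in meters.
#' @param prior_sd_intercept,prior_sd_beta prior standard deviations.
#' @param phi_prior list with `mean`, `sd`, `lower`, `upper`.
#' @return list of class `dom_config`.
#' @export
model_config <- function(nu = 5, L = 430, prior_sd_intercept = 2.5,
                         prior_sd_beta = 1,
                         phi_prior = list(mean = 0.5, sd = 1,
                                          lower = 0, upper = 1)) {
  stopifnot(nu > 0, L > 0, prior_sd_intercept > 0, prior_sd_beta > 0)
  structure(list(nu = nu, L = L, prior_sd_intercept = prior_sd_intercept,
                 prior_sd_beta = prior_sd_beta, phi_prior = phi_prior),
            class = "dom_config")
}

#' Model parameters
#'
#' @param beta0 intercept of the log-dispersion linear predictor
#'   (log meters per day at covariate zero).
#' @param beta named coefficient vector over covariates.
#' @param phi compound recapture probability in (0, 1): the product of
#'   survival, detection, and tag-retention probabilities.
#' @return list of class `dom_params`.
#' @export
model_params <- function(beta0, beta = numeric(0), phi) {
  stopifnot(is.numeric(beta0), length(beta0) == 1,
            phi > 0, phi < 1)
  structure(list(beta0 = beta0, beta = beta, phi = phi),
            class = "dom_params")
}

#' Log dispersion of one replicate
#'
#' The linear predictor `log sigma = beta0 + sum_k beta_k x_k + log eta`,
#' with the log time interval entering as an offset (coefficient fixed at
#' 1) so that dispersion scales with elapsed days.
#'
#' @param params [model_params()] object.
#' @param x covariate vector, same length as `params$beta`.
#' @param eta_days elapsed days between the paired occasions (> 0).
#' @return log sigma (sigma = exp of it is always positive).
#' @export
log_sigma <- function(params, x, eta_days) {
  if (length(x) != length(params$beta))
    stop("covariate vector length (", length(x),
         ") does not match beta length (", length(params$beta), ")")
  if (eta_days <= 0) stop("eta_days must be positive")
  params$beta0 + sum(params$beta * x) + log(eta_days)
}

#' Location-scale Student-t log density
#'
#' The movement kernel: the end location follows a Student-t centered at
#' the start location with scale `sigma` and `nu` degrees of freedom.
#' (`sigma` is the scale of the location-scale family, not the standard
#' deviation; for nu = 5 the kernel's SD is sigma * sqrt(5/3).)
#'
#' @param x1 end location (m).
#' @param x0 start location (m).
#' @param sigma kernel scale (> 0).
#' @param nu degrees of freedom (> 0).
#' @return log density.
#' @export
t_logpdf <- function(x1, x0, sigma, nu) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (nu <= 0) stop("nu must be positive")
  dt((x1 - x0) / sigma, df = nu, log = TRUE) - log(sigma)
}

#' Probability of staying within the reach
#'
#' Mass of the movement kernel on the closed reach \[0, L\]: fish whose (possibly
#' unobserved) end location falls outside the reach have permanently
#' emigrated and can never be recaptured.
#'
#' @inheritParams t_logpdf
#' @param L reach length (m).
#' @return P(0 <= X1 <= L | X0 = x0), in \[0, 1\].
#' @export
stay_prob <- function(x0, sigma, nu, L) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  pt((L - x0) / sigma, df = nu) - pt((0 - x0) / sigma, df = nu)
}

#' Stay indicator
#'
#' 1 when the end location lies inside the closed reach \[0, L\], 0 for an
#' emigrant; both boundaries count as staying.
#'
#' @param x1 end location (m).
#' @param L reach length (m).
#' @return integer 0/1 vector.
#' @export
stay_indicator <- function(x1, L) {
  as.integer(x1 >= 0 & x1 <= L)
}

#' Log likelihood of one movement replicate
#'
#' A recaptured replicate (Y = 1) contributes the kernel density at the
#' observed end location times the recapture probability. An unrecaptured
#' replicate (Y = 0) contributes `1 - phi * P(stay)`, the latent end
#' location marginalized in closed form over the three ways of not being
#' recaptured: emigrated, died/undetected, or missed. Log arguments are
#' floored at 1e-300 and a floored evaluation is flagged via the
#' `"clipped"` attribute.
#'
#' @param rep list with fields `x0`, `x1` (NA allowed when `y = 0`), `y`,
#'   `eta_days`, and `x` (covariate vector).
#' @param params [model_params()] object.
#' @param cfg [model_config()] object.
#' @return log likelihood (scalar).
#' @export
replicate_loglik <- function(rep, params, cfg) {
  sigma <- exp(log_sigma(params, rep$x, rep$eta_days))
  if (rep$y == 1) {
    if (is.null(rep$x1) || is.na(rep$x1))
      stop("recaptured replicate lacks an end location")
    log(params$phi) + t_logpdf(rep$x1, rep$x0, sigma, cfg$nu)
  } else {
    arg <- 1 - params$phi * stay_prob(rep$x0, sigma, cfg$nu, cfg$L)
    clipped <- arg < 1e-300
    structure(log(max(arg, 1e-300)), clipped = clipped)
  }
}

#' Log prior density
#'
#' @inheritParams replicate_loglik
#' @return sum of log prior densities; `-Inf` when phi is outside its
#'   truncation support.
#' @export
log_prior <- function(params, cfg) {
  pp <- cfg$phi_prior
  if (params$phi <= pp$lower || params$phi >= pp$upper) return(-Inf)
  trunc_mass <- pnorm(pp$upper, pp$mean, pp$sd) -
    pnorm(pp$lower, pp$mean, pp$sd)
  dnorm(params$beta0, 0, cfg$prior_sd_intercept, log = TRUE) +
    sum(dnorm(params$beta, 0, cfg$prior_sd_beta, log = TRUE)) +
    dnorm(params$phi, pp$mean, pp$sd, log = TRUE) - log(trunc_mass)
}

#' Bundle replicates and covariates for likelihood evaluation
#'
#' @param replicates replicate data.frame from [build_replicates()] (or the
#'   synthetic generator) for a single species.
#' @param X covariate matrix aligned with the replicate rows (one column
#'   per coefficient), e.g. `assemble_covariates()$X`. May have zero
#'   columns for an intercept-only model.
#' @return list of class `dom_data` with fields `X`, `x0`, `x1`, `y`,
#'   `log_eta`, `n`.
#' @export
dom_data <- function(replicates, X = NULL) {
  n <- nrow(replicates)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, all(replicates$eta_days > 0))
  if (any(replicates$y == 1 & is.na(replicates$x1)))
    stop("recaptured replicate lacks an end location")
  x1 <- replicates$x1
  x1[is.na(x1)] <- 0  # placeholder; never read for y = 0 in marginal form
  structure(list(X = X, Xd = cbind(`(Intercept)` = rep(1, n), X),
                 x0 = replicates$x0, x1 = x1,
                 y = as.integer(replicates$y),
                 log_eta = log(replicates$eta_days), n = n),
            class = "dom_data")
}

#' Joint log posterior
#'
#' Sum of all replicate log likelihoods plus the log prior, evaluated
#' through the compiled vectorized path. `-Inf` from the prior propagates.
#'
#' @param params [model_params()] object.
#' @param data [dom_data()] object (may hold zero replicates, in which case
#'   the log prior alone is returned with a warning).
#' @param cfg [model_config()] object.
#' @return log posterior density (unnormalized); attribute `"clipped"`
#'   carries the number of floored log arguments.
#' @export
log_posterior <- function(params, data, cfg) {
  lp <- log_prior(params, cfg)
  if (!is.finite(lp)) return(lp)
  if (data$n == 0) {
    warning("log_posterior: no replicates; returning log prior only")
    return(structure(lp, clipped = 0L))
  }
  ll <- cpp_loglik_marginal(c(params$beta0, params$beta), params$phi,
                            data$Xd, data$log_eta, data$x0, data$x1,
                            data$y, cfg$nu, cfg$L)
  structure(lp + ll[1], clipped = as.integer(ll[2]))
}
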