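#' Sampler configuration
#'
#' Defaults follow the study's protocol: 40,000 iterations, 15,000 burn-in,
#' thinning every 30 steps. The number of kept draws per chain is
#' `floor((n_iter - burn_in) / thin)` (833 at the defaults). Four chains
#' are run by default so that split R-hat is well defined.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded before retention and after which
#'   proposal adaptation is frozen.
#' @param thin retention stride.
#' @param n_chains number of chains (>= 2 for R-hat).
#' @param seed integer seed; chain c uses `seed + c`.
#' @param adapt_window iterations between proposal-scale updates during
#'   burn-in.
#' @param target_accept target acceptance rate of the random-walk updates.
#' @return list of class `dom_sampler_config`.
#' @export
sampler_config <- function(n_iter = 40000, burn_in = 15000, thin = 30,
                           n_chains = 4, seed = 1, adapt_window = 50,
                           target_accept = 0.3) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1, adapt_window >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, seed = seed,
                 adapt_window = adapt_window,
                 target_accept = target_accept),
            class = "dom_sampler_config")
}

# Unnormalized log posterior in the sampling parameterization
# theta = (beta0, beta_k..., logit phi); includes the logit Jacobian.
make_target <- function(data, cfg, mode, prior_only) {
  p <- ncol(data$Xd) - 1L
  pp <- cfg$phi_prior
  trunc_mass <- pnorm(pp$upper, pp$mean, pp$sd) -
    pnorm(pp$lower, pp$mean, pp$sd)
  function(theta, x1_full = NULL) {
    beta <- theta[seq_len(p + 1L)]
    phi <- plogis(theta[p + 2L])
    lp <- dnorm(beta[1], 0, cfg$prior_sd_intercept, log = TRUE) +
      sum(dnorm(beta[-1], 0, cfg$prior_sd_beta, log = TRUE)) +
      dnorm(phi, pp$mean, pp$sd, log = TRUE) - log(trunc_mass) +
      log(phi) + log1p(-phi)  # Jacobian d phi / d logit phi
    if (prior_only) return(lp)
    ll <- if (mode == "marginalized") {
      cpp_loglik_marginal(beta, phi, data$Xd, data$log_eta, data$x0,
                          data$x1, data$y, cfg$nu, cfg$L)
    } else {
      cpp_loglik_augmented(beta, phi, data$Xd, data$log_eta, data$x0,
                           x1_full, data$y, cfg$nu, cfg$L)
    }
    lp + ll[1]
  }
}

#' Sample the posterior of the dispersal-observation model
#'
#' Adaptive random-walk Metropolis-within-Gibbs over the intercept, the
#' covariate coefficients, and the recapture probability on the logit
#' scale. In `"marginalized"` mode the unrecaptured replicates' latent end
#' locations are integrated out in closed form; in `"augmented"` mode they
#' are imputed each iteration by drawing a proposal from the movement
#' kernel and accepting it against the non-recapture observation term, as
#' a latent-state MCMC would. Identical seed and configuration give
#' identical draws.
#'
#' @param data [dom_data()] object; may hold zero replicates, in which
#'   case the prior is sampled.
#' @param cfg [model_config()] object.
#' @param sampler [sampler_config()] object.
#' @param mode `"marginalized"` (default) or `"augmented"`.
#' @return object of class `dom_draws`: a list with `draws` (array chains
#'   x kept iterations x parameters), `parameters`, `accept_rates`
#'   (post-burn-in, per chain x parameter), `mode`, `sampler`, `n_clipped`.
#' @export
sample_posterior <- function(data, cfg, sampler,
                             mode = c("marginalized", "augmented")) {
  mode <- match.arg(mode)
  prior_only <- data$n == 0
  p <- ncol(data$Xd) - 1L
  beta_names <- if (p > 0) {
    nm <- colnames(data$X)
    if (is.null(nm)) paste0("beta_", seq_len(p)) else paste0("beta_", nm)
  } else character(0)
  par_names <- c("beta0", beta_names, "phi")
  n_par <- p + 2L
  target <- make_target(data, cfg, mode, prior_only)
  kept <- floor((sampler$n_iter - sampler$burn_in) / sampler$thin)
  if (kept < 1) stop("sampler settings retain no draws")
  draws <- array(NA_real_, c(sampler$n_chains, kept, n_par),
                 dimnames = list(NULL, NULL, par_names))
  accept <- matrix(0, sampler$n_chains, n_par,
                   dimnames = list(NULL, par_names))
  idx_y0 <- if (!prior_only) which(data$y == 0L) else integer(0)
  augment <- mode == "augmented" && length(idx_y0) > 0

  for (ch in seq_len(sampler$n_chains)) {
    set.seed(sampler$seed + ch)
    theta <- c(rnorm(p + 1L, 0, 0.1), qlogis(runif(1, 0.2, 0.8)))
    x1_full <- NULL
    if (!prior_only) x1_full <- data$x1
    if (augment) x1_full[idx_y0] <- data$x0[idx_y0]  # latent init at start
    lp <- target(theta, x1_full)
    if (!is.finite(lp))
      stop("non-finite log posterior at initialization (chain ", ch,
           "); theta = ", paste(signif(theta, 3), collapse = ", "))
    scale <- rep(0.1, n_par)
    win_acc <- rep(0, n_par)
    post_acc <- rep(0, n_par)
    for (it in seq_len(sampler$n_iter)) {
      for (j in seq_len(n_par)) {
        prop <- theta
        prop[j] <- prop[j] + rnorm(1, 0, scale[j])
        lp_prop <- target(prop, x1_full)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          win_acc[j] <- win_acc[j] + 1
          if (it > sampler$burn_in) post_acc[j] <- post_acc[j] + 1
        }
      }
      if (augment) {
        # Latent end locations: independence proposal from the current
        # kernel; the kernel density cancels, leaving the observation term
        # (1 - phi z') / (1 - phi z).
        beta_cur <- theta[seq_len(p + 1L)]
        phi_cur <- plogis(theta[n_par])
        sig0 <- exp(as.vector(data$Xd[idx_y0, , drop = FALSE] %*% beta_cur) +
                      data$log_eta[idx_y0])
        prop_x1 <- data$x0[idx_y0] + sig0 * rt(length(idx_y0), cfg$nu)
        z_new <- prop_x1 >= 0 & prop_x1 <= cfg$L
        z_old <- x1_full[idx_y0] >= 0 & x1_full[idx_y0] <= cfg$L
        ratio <- (1 - phi_cur * z_new) / (1 - phi_cur * z_old)
        take <- runif(length(idx_y0)) < ratio
        x1_full[idx_y0[take]] <- prop_x1[take]
        lp <- target(theta, x1_full)
      }
      if (it <= sampler$burn_in && it %% sampler$adapt_window == 0) {
        rate <- win_acc / sampler$adapt_window
        scale <- scale * exp(rate - sampler$target_accept)
        win_acc[] <- 0
      }
      if (it > sampler$burn_in &&
            (it - sampler$burn_in) %% sampler$thin == 0) {
        k <- (it - sampler$burn_in) %/% sampler$thin
        out <- theta
        out[n_par] <- plogis(theta[n_par])
        draws[ch, k, ] <- out
      }
    }
    accept[ch, ] <- post_acc / (sampler$n_iter - sampler$burn_in)
  }
  structure(list(draws = draws, parameters = par_names,
                 accept_rates = accept, mode = mode, sampler = sampler,
                 config = cfg),
            class = "dom_draws")
}

#' Pool chains into a draws matrix
#'
#' @param x `dom_draws` object.
#' @param ... unused.
#' @return matrix (chains * kept iterations) x parameters.
#' @export
as.matrix.dom_draws <- function(x, ...) {
  d <- x$draws
  out <- matrix(aperm(d, c(2, 1, 3)), nrow = dim(d)[1] * dim(d)[2],
                ncol = dim(d)[3])
  colnames(out) <- x$parameters
  out
}

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half (guarding against within-chain trends), the
#' between- and within-half variances are compared, and
#' `sqrt((n - 1)/n + B/(n W))` is returned. Values near 1 indicate the
#' chains are sampling the same distribution; the conventional convergence
#' rule is R-hat < 1.1 for all parameters.
#'
#' @param draws `dom_draws` object.
#' @param parameter parameter name.
#' @return R-hat (approximately >= 1); `NaN` with a warning when the
#'   within-chain variance is zero (degenerate chains).
#' @export
rhat <- function(draws, parameter) {
  d <- draws$draws[, , parameter, drop = FALSE]
  m0 <- dim(d)[1]
  n0 <- dim(d)[2]
  if (m0 < 2) stop("R-hat requires at least 2 chains")
  if (n0 < 4) stop("R-hat requires at least 4 kept draws per chain")
  half <- n0 %/% 2
  splits <- vector("list", 2 * m0)
  for (ch in seq_len(m0)) {
    splits[[2 * ch - 1]] <- d[ch, seq_len(half), 1]
    splits[[2 * ch]] <- d[ch, half + seq_len(half), 1]
  }
  n <- half
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) {
    warning("zero within-chain variance for ", parameter)
    return(NaN)
  }
  sqrt((n - 1) / n + B / (n * W))
}

#' Convergence report over all monitored parameters
#'
#' @param draws `dom_draws` object.
#' @param threshold R-hat pass threshold (1.1 by convention).
#' @return list with `table` (parameter, rhat, pass), `max_rhat`, `pass`.
#' @export
check_convergence <- function(draws, threshold = 1.1) {
  if (length(draws$parameters) == 0) stop("no parameters to check")
  rh <- vapply(draws$parameters, function(pn) rhat(draws, pn), 0)
  tab <- data.frame(parameter = draws$parameters, rhat = rh,
                    pass = is.finite(rh) & rh < threshold,
                    row.names = NULL)
  list(table = tab, max_rhat = max(rh), pass = all(tab$pass),
       threshold = threshold)
}

#' Serialize posterior draws
#'
#' Long-format CSV (chain, iteration, parameter, value) with a JSON
#' metadata sidecar recording the sampler settings, mode, and acceptance
#' rates.
#'
#' @param draws `dom_draws` object.
#' @param path CSV path; metadata goes to `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  d <- draws$draws
  long <- expand.grid(chain = seq_len(dim(d)[1]),
                      iteration = seq_len(dim(d)[2]),
                      parameter = draws$parameters,
                      stringsAsFactors = FALSE)
  long$value <- as.vector(d)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta <- list(mode = draws$mode, sampler = unclass(draws$sampler),
               accept_rates = as.data.frame(draws$accept_rates))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
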