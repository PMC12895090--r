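cfg <- model_config()

test_that("log dispersion is linear with a log-time offset", {
  p <- model_params(0, numeric(0), 0.5)
  expect_equal(log_sigma(p, numeric(0), 1), 0)
  p2 <- model_params(log(2), numeric(0), 0.5)
  expect_equal(log_sigma(p2, numeric(0), 1), log(2))
  expect_equal(log_sigma(p, numeric(0), 93), log(93))
  p3 <- model_params(0.2, c(a = 0.5, b = -1), 0.5)
  expect_equal(log_sigma(p3, c(1, 2), 10), 0.2 + 0.5 - 2 + log(10))
  expect_error(log_sigma(p3, c(1), 10), "length")
  expect_error(log_sigma(p3, c(1, 2), 0), "positive")
})

test_that("movement kernel is a proper symmetric density", {
  # symmetry about the start location
  for (d in c(0.5, 3, 40)) {
    expect_equal(t_logpdf(100 + d, 100, 7, 5), t_logpdf(100 - d, 100, 7, 5))
  }
  # normalization against quadrature of the unnormalized Student-t form
  for (nu in c(1, 5, 50)) {
    un <- function(z) (1 + z^2 / nu)^(-(nu + 1) / 2)
    Z <- integrate(un, -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(t_logpdf(0, 0, 1, nu), log(un(0) / Z), tolerance = 1e-10)
    expect_equal(t_logpdf(2.4, 1, 1.7, nu),
                 log(un((2.4 - 1) / 1.7) / Z) - log(1.7),
                 tolerance = 1e-10)
    total <- integrate(function(x) exp(t_logpdf(x, 12, 3.1, nu)),
                       -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # normal limit at enormous degrees of freedom
  z <- seq(-3, 3, by = 0.5)
  expect_equal(exp(t_logpdf(z, 0, 1, 1e6)), dnorm(z), tolerance = 1e-4)
  expect_error(t_logpdf(0, 0, -1, 5), "sigma")
})

test_that("stay probability is the kernel mass on the reach", {
  expect_equal(stay_prob(215, 1e-9, 5, 430), 1, tolerance = 1e-9)
  expect_lt(stay_prob(215, 1e9, 5, 430), 1e-6)
  # midpoint symmetry identity
  sig <- 37
  expect_equal(stay_prob(215, sig, 5, 430),
               1 - 2 * pt(-215 / sig, 5), tolerance = 1e-12)
  # complement of the emigration mass by quadrature
  for (x0 in c(5, 215, 425)) {
    inside <- integrate(function(x) exp(t_logpdf(x, x0, 60, 5)), 0, 430,
                        rel.tol = 1e-10)$value
    expect_equal(stay_prob(x0, 60, 5, 430), inside, tolerance = 1e-8)
  }
})

test_that("stay indicator includes both boundaries", {
  expect_equal(stay_indicator(-0.1, 430), 0L)
  expect_equal(stay_indicator(0, 430), 1L)
  expect_equal(stay_indicator(430, 430), 1L)
  expect_equal(stay_indicator(430.01, 430), 0L)
  expect_equal(stay_indicator(215, 430), 1L)
})

test_that("replicate likelihood marginalizes non-recapture correctly", {
  p_half <- list(beta0 = log(0.3), beta = numeric(0), phi = 0.5)
  base <- list(x0 = 215, x1 = NA, y = 0, eta_days = 93, x = numeric(0))

  # phi = 0: Y = 0 is certain whatever the movement
  p0 <- list(beta0 = log(0.3), beta = numeric(0), phi = 1e-300)
  expect_equal(as.numeric(replicate_loglik(base, p0, cfg)), 0,
               tolerance = 1e-12)

  # certain recapture with a degenerate kernel contradicts Y = 0: floored
  p1 <- list(beta0 = -150, beta = numeric(0), phi = 1)
  ll <- replicate_loglik(base, p1, cfg)
  expect_true(is.finite(ll))
  expect_true(attr(ll, "clipped"))

  # Y = 1 requires an end location
  expect_error(replicate_loglik(
    list(x0 = 10, x1 = NA, y = 1, eta_days = 93, x = numeric(0)),
    model_params(0, numeric(0), 0.5), cfg), "end location")

  # monotone in sigma for an interior start (more spread, more emigration)
  sig_grid <- c(-3, -2, -1, 0, 1)
  vals <- vapply(sig_grid, function(b0)
    as.numeric(replicate_loglik(base, list(beta0 = b0, beta = numeric(0),
                                           phi = 0.5), cfg)), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("marginalized Y=0 likelihood matches a Monte Carlo oracle", {
  set.seed(101)
  n_mc <- 1e6
  for (case in 1:3) {
    x0 <- runif(1, 0, 430)
    sigma <- exp(runif(1, log(5), log(200)))
    phi <- runif(1, 0.2, 0.8)
    x1 <- x0 + sigma * rt(n_mc, 5)
    g <- 1 - phi * (x1 >= 0 & x1 <= 430)
    mc <- mean(g)
    se <- sd(g) / sqrt(n_mc)
    marg <- 1 - phi * stay_prob(x0, sigma, 5, 430)
    expect_lt(abs(marg - mc), 3 * se)
  }
})

test_that("priors are correctly normalized", {
  p <- list(beta0 = 0, beta = numeric(0), phi = 1.2)
  expect_identical(log_prior(p, cfg), -Inf)
  # intercept contribution at zero
  p1 <- list(beta0 = 0, beta = numeric(0), phi = 0.5)
  p2 <- list(beta0 = 2.5, beta = numeric(0), phi = 0.5)
  expect_equal(log_prior(p1, cfg) - log_prior(p2, cfg), 0.5)  # half a sd^2
  expect_equal(log_prior(p1, cfg) -
                 (dnorm(0.5, 0.5, 1, log = TRUE) -
                    log(pnorm(1, 0.5, 1) - pnorm(0, 0.5, 1))),
               -log(2.5 * sqrt(2 * pi)))
  # truncated-normal phi prior integrates to 1 on (0, 1)
  dens <- function(phi) vapply(phi, function(ph) exp(
    log_prior(list(beta0 = 0, beta = numeric(0), phi = ph), cfg) -
      dnorm(0, 0, 2.5, log = TRUE)), 0)
  expect_equal(integrate(dens, 0, 1, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
})

test_that("joint log posterior equals the brute-force replicate sum", {
  set.seed(5)
  gen <- simulate_replicates(80, beta = c(body_size = 0.4, hra = -0.2),
                             seed = 5)
  dat <- dom_data(gen$replicates, gen$X)
  pars <- model_params(log(0.2), c(body_size = 0.3, hra = 0.1), 0.6)
  lp <- log_posterior(pars, dat, cfg)
  loop <- log_prior(pars, cfg)
  for (i in seq_len(80)) {
    loop <- loop + as.numeric(replicate_loglik(
      list(x0 = gen$replicates$x0[i], x1 = gen$replicates$x1[i],
           y = gen$replicates$y[i], eta_days = gen$replicates$eta_days[i],
           x = gen$X[i, ]), pars, cfg))
  }
  expect_equal(as.numeric(lp), loop, tolerance = 1e-12)

  # order invariance
  perm <- sample(80)
  dat2 <- dom_data(gen$replicates[perm, ], gen$X[perm, ])
  expect_equal(as.numeric(log_posterior(pars, dat2, cfg)),
               as.numeric(lp), tolerance = 1e-12)

  # empty data returns the prior with a warning
  empty <- dom_data(gen$replicates[0, ], gen$X[0, , drop = FALSE])
  expect_warning(lp0 <- log_posterior(pars, empty, cfg), "no replicates")
  expect_equal(as.numeric(lp0), log_prior(pars, cfg))
})
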