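test_that("retained-draw bookkeeping follows the settings identity", {
  s <- mcmc_settings()   # protocol defaults
  rd <- retained_draws(s)
  expect_equal(rd$pre_thin, 30000L)
  expect_equal(rd$retained, 6000L)
  for (cfg in list(c(2, 1000, 200, 4), c(4, 5000, 1000, 10),
                   c(1, 300, 100, 1))) {
    s <- mcmc_settings(cfg[1], cfg[2], cfg[3], cfg[4])
    expect_equal(retained_draws(s)$retained,
                 cfg[1] * ((cfg[2] - cfg[3]) %/% cfg[4]))
  }
  expect_error(mcmc_settings(n_burnin = 2000, n_iterations = 1000), "burn-in")
  expect_error(mcmc_settings(thin = 0), "thin")
})

test_that("log_posterior matches a term-by-term oracle and its supports", {
  set.seed(3)
  data <- lapply(1:2, function(i)
    manual_trials(sample(c("A", "B"), 10, TRUE), sample(0:1, 10, TRUE)))
  sp <- data.frame(alpha = c(0.3, 0.6), beta = c(1.2, 2.5))
  hy <- c(mu_alpha = 0.4, sigma_alpha = 0.2, mu_beta = 2, sigma_beta = 1)
  # independent oracle: brute-force likelihoods + truncated-normal terms
  tn <- function(x, m, s, lo, hi) {
    stats::dnorm(x, m, s, log = TRUE) -
      log(stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s))
  }
  oracle <- brute_force_ll(0.3, 1.2, data[[1]]) +
    brute_force_ll(0.6, 2.5, data[[2]]) +
    sum(tn(sp$alpha, hy["mu_alpha"], hy["sigma_alpha"], 0, 1)) +
    sum(tn(sp$beta, hy["mu_beta"], hy["sigma_beta"], 0, Inf)) +
    log(1) + log(1) + log(1 / 10) + log(1 / 5)
  expect_equal(log_posterior(sp, hy, data), oracle, tolerance = 1e-10)

  # outside the uniform prior bounds the density vanishes
  bad <- hy; bad["mu_beta"] <- 11
  expect_identical(log_posterior(sp, bad, data), -Inf)
  bad <- hy; bad["sigma_alpha"] <- -0.1
  expect_identical(log_posterior(sp, bad, data), -Inf)
  expect_identical(log_posterior(data.frame(alpha = 1.2, beta = 1), hy,
                                 data[1]), -Inf)

  # flat-choice subject: the data term is n * log(0.5)
  one <- manual_trials(rep("A", 8), rep(1, 8))
  flat <- log_posterior(data.frame(alpha = 0.3, beta = 0), hy, list(one))
  prior_terms <- tn(0.3, hy["mu_alpha"], hy["sigma_alpha"], 0, 1) +
    tn(0, hy["mu_beta"], hy["sigma_beta"], 0, Inf) + log(1 / 50)
  expect_equal(flat, unname(8 * log(0.5) + prior_terms), tolerance = 1e-10)
})

test_that("gelman_rubin distinguishes converged from separated chains", {
  make_samples <- function(chains) {
    draws <- do.call(rbind, lapply(seq_along(chains), function(i)
      data.frame(chain = i, draw = seq_along(chains[[i]]),
                 mu_alpha = chains[[i]])))
    structure(list(draws = draws), class = "posterior_samples")
  }
  set.seed(9)
  conv <- make_samples(lapply(1:3, function(i) rnorm(2000)))
  expect_true(gelman_rubin(conv, "mu_alpha") >= 0.99 &&
              gelman_rubin(conv, "mu_alpha") <= 1.05)
  apart <- make_samples(list(rnorm(500), rnorm(500, 10)))
  expect_gt(gelman_rubin(apart, "mu_alpha"), 1.5)
  const <- make_samples(list(rep(1, 100), rep(1, 100)))
  expect_warning(rh <- gelman_rubin(const, "mu_alpha"), "zero")
  expect_identical(rh, 1)
  single <- make_samples(list(rnorm(100)))
  expect_error(gelman_rubin(single, "mu_alpha"), "split")
  expect_error(gelman_rubin(conv, "nope"), "unknown parameter")
})

test_that("wald_compare matches its closed form and is antisymmetric", {
  make <- function(x) structure(
    list(draws = data.frame(chain = 1, draw = seq_along(x), mu_beta = x)),
    class = "posterior_samples")
  set.seed(4)
  a <- make(rnorm(4000, 0, 0.5)); b <- make(rnorm(4000, 1, 0.5))
  w <- wald_compare(a, b, "mu_beta")
  expect_equal(w$z, -1 / sqrt(0.5), tolerance = 0.12)
  expect_equal(wald_compare(b, a, "mu_beta")$z, -w$z)
  same <- wald_compare(a, a, "mu_beta")
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(wald_compare(make(rep(2, 50)), make(rep(2, 50)), "mu_beta"),
               "zero pooled")
})

test_that("the sampler respects truncation, counting and reproducibility", {
  set.seed(11)
  data <- lapply(1:3, function(i)
    manual_trials(sample(c("A", "B"), 40, TRUE), sample(0:1, 40, TRUE)))
  st <- mcmc_settings(2, 400, 100, 3, seed = 7)
  fit <- fit_hierarchical(data, settings = st)
  expect_equal(nrow(fit$draws), retained_draws(st)$retained)
  expect_equal(fit$pre_thin, retained_draws(st)$pre_thin)
  al <- as.matrix(fit$draws[, paste0("alpha_", 1:3)])
  be <- as.matrix(fit$draws[, paste0("beta_", 1:3)])
  expect_true(all(al >= 0 & al <= 1))
  expect_true(all(be >= 0))
  expect_true(all(fit$draws$sigma_alpha > 0 & fit$draws$sigma_alpha <= 1))
  fit2 <- fit_hierarchical(data, settings = st)
  expect_identical(fit$draws, fit2$draws)
  expect_error(fit_hierarchical(list()), "length")
})

test_that("posterior mean of alpha matches a grid-integration oracle", {
  set.seed(21)
  sch <- generate_schedule(small_task(), 31)
  rw <- realize_rewards(sch, 32)
  tr <- simulate_agent(agent_params(0.4, 3), sch, rw, 33)[1:5, ]

  # oracle: the hyper-priors integrate out independently for alpha and beta,
  # leaving a 2D posterior on a dense grid
  marg_prior <- function(x, mu_bounds, sd_bounds, lo, hi) {
    mus <- seq(mu_bounds[1], mu_bounds[2], length.out = 101)[-1]
    sds <- seq(sd_bounds[1], sd_bounds[2], length.out = 101)[-1]
    g <- outer(mus, sds, function(m, s)
      stats::dnorm(x, m, s) /
        (stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s)))
    mean(g)
  }
  alphas <- seq(0.005, 0.995, by = 0.01)
  betas <- seq(0.025, 9.975, by = 0.05)
  pa <- vapply(alphas, marg_prior, numeric(1), c(0, 1), c(0, 1), 0, 1)
  pb <- vapply(betas, marg_prior, numeric(1), c(0, 10), c(0, 5), 0, Inf)
  like <- outer(alphas, betas, Vectorize(function(a, b)
    exp(brute_force_ll(a, b, tr))))
  post <- like * outer(pa, pb)
  oracle_mean <- sum(alphas * rowSums(post)) / sum(post)

  fit <- fit_hierarchical(list(tr),
                          settings = mcmc_settings(3, 4000, 1000, 1,
                                                   seed = 5))
  expect_equal(mean(fit$draws$alpha_1), oracle_mean, tolerance = 0.02)
})

test_that("posterior uncertainty shrinks with more data", {
  sds <- vapply(c(4, 8), function(n_sub) {
    spec <- group_spec("NN", n_subjects = n_sub)
    task <- if (n_sub == 4) task_config(2L, 80L, c(35L, 45L))
            else task_config(4L, 160L, c(35L, 45L))
    co <- synth_cohort(spec, task, seed = 17)
    fit <- fit_hierarchical(co$trials,
                            settings = mcmc_settings(2, 1200, 400, 1,
                                                     seed = 3))
    stats::sd(fit$draws$mu_alpha)
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})
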