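#' Hyper-prior bounds for the group-level parameters
#'
#' Non-informative uniform priors: `U(0,1)` for both the group mean and SD of
#' the learning rate, `U(0,10)` for the group mean and `U(0,5)` for the group
#' SD of the choice perseveration.
#'
#' @return An object of class `hyper_priors`: a list of `c(lower, upper)`
#'   bounds for `mu_alpha`, `sigma_alpha`, `mu_beta`, `sigma_beta`.
#' @export
hyper_priors <- function(mu_alpha = c(0, 1), sigma_alpha = c(0, 1),
                         mu_beta = c(0, 10), sigma_beta = c(0, 5)) {
  pr <- list(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
             mu_beta = mu_beta, sigma_beta = sigma_beta)
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (length(b) != 2L || !(b[1] < b[2]))
      stop("prior bounds for ", nm, " must be strictly ordered")
  }
  structure(pr, class = "hyper_priors")
}

#' MCMC sampler settings
#'
#' Defaults follow the full analysis protocol: 3 chains of 16,000 iterations,
#' the first 6,000 discarded as burn-in (30,000 post-burn-in draws in total),
#' thinned at interval 5 to 6,000 retained draws. Reduced settings (e.g.
#' `n_iterations = 2000, n_burnin = 500, thin = 1`) are adequate for tests
#' and simulations.
#'
#' @param n_chains Number of independent chains (>= 1).
#' @param n_iterations Iterations per chain.
#' @param n_burnin Leading iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_iterations = 16000L,
                          n_burnin = 6000L, thin = 5L, seed = 1L) {
  n_chains <- as.integer(n_chains); n_iterations <- as.integer(n_iterations)
  n_burnin <- as.integer(n_burnin); thin <- as.integer(thin)
  if (n_burnin >= n_iterations) stop("burn-in must be shorter than the chain")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 n_burnin = n_burnin, thin = thin, seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Retained and pre-thinning draw counts implied by MCMC settings
#' @param settings An [mcmc_settings()].
#' @return A list with `pre_thin` and `retained` counts over all chains.
#' @export
retained_draws <- function(settings) {
  post <- settings$n_iterations - settings$n_burnin
  list(pre_thin = settings$n_chains * post,
       retained = settings$n_chains * (post %/% settings$thin))
}

# --- truncated normal helpers -------------------------------------------

# log-density of Normal(mean, sd) truncated to [lower, upper]
.dtnorm <- function(x, mean, sd, lower, upper) {
  if (any(sd <= 0)) return(rep(-Inf, length(x)))
  lz <- if (is.finite(upper)) {
    log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd))
  } else {
    stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
  }
  out <- stats::dnorm(x, mean, sd, log = TRUE) - lz
  out[x < lower | x > upper] <- -Inf
  out
}

# inverse-CDF sampler for the truncated normal
.rtnorm <- function(n, mean, sd, lower, upper) {
  fa <- stats::pnorm(lower, mean, sd)
  fb <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, fa, fb)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

# --- joint density -------------------------------------------------------

.hyper_in_support <- function(hypers, priors) {
  all(vapply(names(priors), function(nm) {
    b <- priors[[nm]]
    hypers[[nm]] >= b[1] && hypers[[nm]] <= b[2]
  }, logical(1))) && hypers[["sigma_alpha"]] > 0 && hypers[["sigma_beta"]] > 0
}

#' Joint log-posterior density of the hierarchical Q-learning model
#'
#' Sum of the per-subject choice log-likelihoods, the truncated-normal
#' group-level densities of the subject parameters (`alpha_i` truncated to
#' `[0,1]`, `beta_i` to `[0, Inf)`), and the log hyper-prior. Returns `-Inf`
#' whenever any parameter falls outside its support.
#'
#' @param subject_params A `data.frame` with columns `alpha`, `beta`, one row
#'   per subject.
#' @param hypers Named numeric vector/list with `mu_alpha`, `sigma_alpha`,
#'   `mu_beta`, `sigma_beta`.
#' @param data A list of per-subject trial logs (columns `pair`, `choice`,
#'   `reward`).
#' @param priors A [hyper_priors()].
#' @param q_init Initial deck value used when replaying the likelihood.
#' @return The log-density (a scalar, possibly `-Inf`).
#' @export
log_posterior <- function(subject_params, hypers, data,
                          priors = hyper_priors(), q_init = 0.5) {
  stopifnot(nrow(subject_params) == length(data))
  hypers <- as.list(hypers)
  if (!.hyper_in_support(hypers, priors)) return(-Inf)
  a <- subject_params$alpha; b <- subject_params$beta
  if (any(a < 0 | a > 1 | b < 0)) return(-Inf)
  ll <- sum(vapply(seq_along(data), function(i) {
    log_likelihood(agent_params(a[i], b[i], q_init), data[[i]])
  }, numeric(1)))
  lp <- sum(.dtnorm(a, hypers$mu_alpha, hypers$sigma_alpha, 0, 1)) +
    sum(.dtnorm(b, hypers$mu_beta, hypers$sigma_beta, 0, Inf))
  # uniform hyper-priors: constant log-density inside the support
  lprior <- -sum(vapply(priors, function(bb) log(diff(bb)), numeric(1)))
  ll + lp + lprior
}

# --- sampler -------------------------------------------------------------

# coarse maximum-likelihood grid estimate of (alpha, beta) for one subject
.ml_grid <- function(enc, q_init) {
  alphas <- seq(0.05, 0.95, by = 0.1)
  betas <- c(0.25, 0.5, 1, 2, 3, 5, 8)
  best <- c(0.5, 1); best_ll <- -Inf
  for (a in alphas) for (b in betas) {
    ll <- .ll_qlearn_cpp(enc$pair_idx, enc$choice_idx, enc$reward,
                         a, b, q_init, enc$n_pairs)
    if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
  }
  best
}

#' Fit the hierarchical Q-learning model by MCMC
#'
#' Component-wise random-walk Metropolis within Gibbs: each subject-level
#' `alpha_i` and `beta_i` and each group-level parameter is updated in turn
#' with a Gaussian proposal. Proposal scales are adapted during burn-in
#' toward a 20--50% acceptance rate and frozen afterwards. Subject
#' parameters are initialized at coarse grid maximum-likelihood estimates
#' (jittered per chain), group-level parameters at their sample mean/SD,
#' which guarantees a finite starting density.
#'
#' @param data A list of per-subject trial logs (columns `pair`, `choice`,
#'   `reward`), each with at least one trial.
#' @param priors A [hyper_priors()].
#' @param settings An [mcmc_settings()].
#' @param q_init Initial deck value for the likelihood replay.
#' @return An object of class `posterior_samples`: `draws` (a `data.frame`
#'   with columns `chain`, `draw`, the four group-level parameters and
#'   `alpha_i`/`beta_i` per subject), `acceptance` rates per parameter,
#'   `settings`, `priors` and the subject count.
#' @export
fit_hierarchical <- function(data, priors = hyper_priors(),
                             settings = mcmc_settings(), q_init = 0.5) {
  stopifnot(length(data) >= 1L)
  if (any(vapply(data, nrow, integer(1)) < 1L))
    stop("every subject needs at least one trial")
  n_sub <- length(data)
  encs <- lapply(data, .encode_trials)
  prior_lo <- vapply(priors, `[`, numeric(1), 1)
  prior_hi <- vapply(priors, `[`, numeric(1), 2)

  ml <- t(vapply(encs, .ml_grid, numeric(2), q_init = q_init))

  n_iter <- settings$n_iterations; n_burn <- settings$n_burnin
  thin <- settings$thin
  n_keep <- (n_iter - n_burn) %/% thin
  par_names <- c("mu_alpha", "sigma_alpha", "mu_beta", "sigma_beta",
                 paste0("alpha_", seq_len(n_sub)),
                 paste0("beta_", seq_len(n_sub)))
  n_par <- length(par_names)

  ll_fun <- function(i, a, b)
    .ll_qlearn_cpp(encs[[i]]$pair_idx, encs[[i]]$choice_idx,
                   encs[[i]]$reward, a, b, q_init, encs[[i]]$n_pairs)

  all_draws <- vector("list", settings$n_chains)
  acc_all <- matrix(0, settings$n_chains, n_par,
                    dimnames = list(NULL, par_names))

  for (chain in seq_len(settings$n_chains)) {
    set.seed(settings$seed + chain)
    alpha <- pmin(pmax(ml[, 1] + stats::rnorm(n_sub, 0, 0.05), 0.01), 0.99)
    beta <- pmax(ml[, 2] * exp(stats::rnorm(n_sub, 0, 0.2)), 0.01)
    sd_or <- function(x, fallback) {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) fallback else s
    }
    hy <- c(mu_alpha = min(max(mean(alpha), 0.05), 0.95),
            sigma_alpha = min(max(sd_or(alpha, 0.1), 0.05), 0.9),
            mu_beta = min(max(mean(beta), 0.1), 9.5),
            sigma_beta = min(max(sd_or(beta, 0.5), 0.1), 4.5))
    ll_sub <- vapply(seq_len(n_sub), function(i) ll_fun(i, alpha[i], beta[i]),
                     numeric(1))
    if (any(!is.finite(ll_sub)))
      stop("non-finite initial posterior; check the trial logs")

    scale <- c(0.05, 0.05, 0.2, 0.2, rep(0.1, n_sub), rep(0.4, n_sub))
    names(scale) <- par_names
    acc <- att <- stats::setNames(rep(0, n_par), par_names)
    acc_win <- att_win <- acc

    draws <- matrix(NA_real_, n_keep, n_par,
                    dimnames = list(NULL, par_names))
    ki <- 0L

    for (iter in seq_len(n_iter)) {
      # subject-level updates
      for (i in seq_len(n_sub)) {
        nm <- paste0("alpha_", i)
        prop <- alpha[i] + stats::rnorm(1, 0, scale[[nm]])
        att_win[[nm]] <- att_win[[nm]] + 1
        if (prop >= 0 && prop <= 1) {
          ll_new <- ll_fun(i, prop, beta[i])
          lr <- ll_new - ll_sub[i] +
            .dtnorm(prop, hy[["mu_alpha"]], hy[["sigma_alpha"]], 0, 1) -
            .dtnorm(alpha[i], hy[["mu_alpha"]], hy[["sigma_alpha"]], 0, 1)
          if (log(stats::runif(1)) < lr) {
            alpha[i] <- prop; ll_sub[i] <- ll_new
            acc_win[[nm]] <- acc_win[[nm]] + 1
          }
        }
        nm <- paste0("beta_", i)
        prop <- beta[i] + stats::rnorm(1, 0, scale[[nm]])
        att_win[[nm]] <- att_win[[nm]] + 1
        if (prop >= 0) {
          ll_new <- ll_fun(i, alpha[i], prop)
          lr <- ll_new - ll_sub[i] +
            .dtnorm(prop, hy[["mu_beta"]], hy[["sigma_beta"]], 0, Inf) -
            .dtnorm(beta[i], hy[["mu_beta"]], hy[["sigma_beta"]], 0, Inf)
          if (log(stats::runif(1)) < lr) {
            beta[i] <- prop; ll_sub[i] <- ll_new
            acc_win[[nm]] <- acc_win[[nm]] + 1
          }
        }
      }
      # group-level updates (likelihood terms unaffected)
      for (nm in c("mu_alpha", "sigma_alpha", "mu_beta", "sigma_beta")) {
        prop <- hy[[nm]] + stats::rnorm(1, 0, scale[[nm]])
        att_win[[nm]] <- att_win[[nm]] + 1
        if (prop >= prior_lo[[nm]] && prop <= prior_hi[[nm]] &&
            !(nm %in% c("sigma_alpha", "sigma_beta") && prop <= 0)) {
          hy_new <- hy; hy_new[[nm]] <- prop
          cur <- sum(.dtnorm(alpha, hy[["mu_alpha"]], hy[["sigma_alpha"]],
                             0, 1)) +
            sum(.dtnorm(beta, hy[["mu_beta"]], hy[["sigma_beta"]], 0, Inf))
          new <- sum(.dtnorm(alpha, hy_new[["mu_alpha"]],
                             hy_new[["sigma_alpha"]], 0, 1)) +
            sum(.dtnorm(beta, hy_new[["mu_beta"]], hy_new[["sigma_beta"]],
                        0, Inf))
          if (log(stats::runif(1)) < new - cur) {
            hy <- hy_new
            acc_win[[nm]] <- acc_win[[nm]] + 1
          }
        }
      }
      # adapt proposal scales during burn-in, freeze afterwards
      if (iter <= n_burn && iter %% 50L == 0L) {
        rate <- acc_win / pmax(att_win, 1)
        scale[rate < 0.20] <- scale[rate < 0.20] * 0.8
        scale[rate > 0.50] <- scale[rate > 0.50] * 1.25
        acc <- acc + acc_win; att <- att + att_win
        acc_win[] <- 0; att_win[] <- 0
      }
      if (iter > n_burn && (iter - n_burn) %% thin == 0L) {
        ki <- ki + 1L
        draws[ki, ] <- c(hy, alpha, beta)
      }
    }
    acc <- acc + acc_win; att <- att + att_win
    acc_all[chain, ] <- acc / pmax(att, 1)
    all_draws[[chain]] <- data.frame(chain = chain, draw = seq_len(n_keep),
                                     draws)
  }

  structure(list(draws = do.call(rbind, all_draws),
                 acceptance = colMeans(acc_all),
                 settings = settings, priors = priors,
                 n_subjects = n_sub, q_init = q_init,
                 pre_thin = settings$n_chains * (n_iter - n_burn),
                 retained = settings$n_chains * n_keep),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Hierarchical Q-learning posterior:", x$n_subjects, "subjects,",
      x$settings$n_chains, "chains,", x$retained, "retained draws\n")
  print(posterior_summary(x, c("mu_alpha", "sigma_alpha",
                               "mu_beta", "sigma_beta")))
  invisible(x)
}

# pull one parameter's draws as a draws-by-chain matrix
.param_matrix <- function(samples, parameter) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (!parameter %in% names(samples$draws))
    stop("unknown parameter: ", parameter)
  chains <- sort(unique(samples$draws$chain))
  sapply(chains, function(ch)
    samples$draws[samples$draws$chain == ch, parameter])
}

#' Gelman--Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance ratio: with `m` chains of `n`
#' draws, `W` the mean within-chain variance and `B/n` the variance of the
#' chain means, `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1
#' indicate convergence.
#'
#' @param samples A [fit_hierarchical()] result.
#' @param parameter Parameter name (e.g. `"mu_alpha"`, `"alpha_3"`).
#' @return The R-hat statistic.
#' @export
gelman_rubin <- function(samples, parameter) {
  x <- .param_matrix(samples, parameter)
  if (is.null(dim(x)) || ncol(x) < 2L)
    stop("R-hat needs >= 2 chains; split a single chain in half instead")
  if (nrow(x) < 10L) stop("R-hat needs >= 10 draws per chain")
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  b_over_n <- stats::var(colMeans(x))
  if (w == 0) {
    warning("zero within-chain variance; R-hat defined as 1")
    return(1)
  }
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Wald comparison of a parameter between two fitted groups
#'
#' `z = (mean1 - mean2) / sqrt(sd1^2 + sd2^2)` over the retained draws, with
#' a two-sided normal p-value.
#'
#' @param samples_g1,samples_g2 [fit_hierarchical()] results for the two
#'   groups.
#' @param parameter Parameter name present in both.
#' @return A list with `z`, `p`, and the two posterior means and SDs.
#' @export
wald_compare <- function(samples_g1, samples_g2, parameter) {
  x1 <- as.vector(.param_matrix(samples_g1, parameter))
  x2 <- as.vector(.param_matrix(samples_g2, parameter))
  m1 <- mean(x1); m2 <- mean(x2)
  v <- stats::var(x1) + stats::var(x2)
  if (v == 0) stop("zero pooled posterior variance")
  z <- (m1 - m2) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       mean1 = m1, sd1 = stats::sd(x1), mean2 = m2, sd2 = stats::sd(x2))
}

#' Posterior means, SDs and R-hats
#'
#' @param samples A [fit_hierarchical()] result.
#' @param parameters Parameter names; default the four group-level ones.
#' @return A `data.frame` with one row per parameter.
#' @export
posterior_summary <- function(samples,
                              parameters = c("mu_alpha", "sigma_alpha",
                                             "mu_beta", "sigma_beta")) {
  do.call(rbind, lapply(parameters, function(p) {
    x <- .param_matrix(samples, p)
    rh <- if (!is.null(dim(x)) && ncol(x) >= 2L && nrow(x) >= 10L)
      suppressWarnings(gelman_rubin(samples, p)) else NA_real_
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(as.vector(x)),
               rhat = rh, stringsAsFactors = FALSE)
  }))
}
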