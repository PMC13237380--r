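# Hierarchical Bayesian individual-subject fitting of the
# Rescorla-Wagner avoidance model.
#
# Model (subject i in group g, trial t):
#   y[i,t] ~ Bernoulli(p[i,t]),  p[i,1] = v1[i],
#   p[i,t+1] = p[i,t] + alpha[i] * (beta[i] - p[i,t])
#   logit(theta[i,k]) = z[i,k] ~ Normal(mu[g,k], sigma[g,k])   (pooled)
#   mu[g,k] ~ Normal(0, 1.5),  sigma[g,k] ~ half-Normal(1)
# The likelihood uses the latent probability directly (no softmax link);
# it is the model's own "probability of avoidance". The priors are a
# documented stand-in: weakly informative with full support on (0, 1).

PARAM_NAMES <- c("alpha", "beta", "v1")

#' Specify the hierarchical model
#'
#' @param mu_loc,mu_scale Normal hyperprior on the group-level location of
#'   each logit-scale parameter (defaults 0 and 1.5). In the unpooled
#'   model these act directly as the fixed prior on each subject's
#'   logit-parameter.
#' @param sigma_scale Scale of the half-Normal hyperprior on the
#'   group-level SD.
#' @param pooled If `TRUE` (default), subjects share group-level
#'   hyperparameters; if `FALSE`, each subject parameter has the fixed
#'   `Normal(mu_loc, mu_scale)` prior on the logit scale (used for small
#'   oracle checks).
#' @param fixed Named list of parameters held at a constant value (on the
#'   natural scale), e.g. `list(alpha = 0.3)`; fixed parameters are not
#'   sampled and carry no hyperparameters.
#' @param prior_only If `TRUE`, the likelihood is dropped so the sampler
#'   targets the prior (prior-predictive checks).
#' @return A `hier_model_spec` object.
#' @export
hier_model_spec <- function(mu_loc = 0, mu_scale = 1.5, sigma_scale = 1,
                            pooled = TRUE, fixed = list(),
                            prior_only = FALSE) {
  if (mu_scale <= 0 || sigma_scale <= 0) abort("prior scales must be > 0")
  if (length(fixed) &&
      !all(names(fixed) %in% PARAM_NAMES)) {
    abort("`fixed` names must be among alpha, beta, v1")
  }
  structure(list(mu_loc = mu_loc, mu_scale = mu_scale,
                 sigma_scale = sigma_scale, pooled = pooled,
                 fixed = fixed, prior_only = prior_only),
            class = "hier_model_spec")
}

#' Bernoulli log-likelihood of an outcome sequence under the model
#'
#' `sum_t [y_t log p(t) + (1 - y_t) log(1 - p(t))]` with `p(t)` from the
#' Rescorla-Wagner recursion, probabilities clipped to
#' `[1e-9, 1 - 1e-9]`.
#'
#' @param outcomes Integer 0/1 vector.
#' @param params An [agent_params()] (or coercible; `tau` unused).
#' @return Scalar log-likelihood.
#' @export
loglik_subject <- function(outcomes, params) {
  params <- as_agent_params(params)
  y <- as.integer(outcomes)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    abort("`outcomes` must be binary 0/1")
  }
  .rw_loglik_cpp(params$alpha, params$beta, params$v1, y, 1e-9)
}

# One MCMC chain. `y` is a trials x subjects integer matrix (or NULL for
# prior-only), `grp` an integer group index per subject.
run_chain <- function(y, grp, n_group, spec, iterations, warmup, seed,
                      sweeps = 16L) {
  n_subj <- length(grp)
  free <- setdiff(PARAM_NAMES, names(spec$fixed))
  kf <- match(free, PARAM_NAMES)
  set.seed(seed)

  z <- matrix(rnorm(n_subj * 3, 0, 1), n_subj, 3)
  for (k in seq_along(PARAM_NAMES)) {
    nm <- PARAM_NAMES[k]
    if (nm %in% names(spec$fixed)) z[, k] <- qlogis(spec$fixed[[nm]])
  }
  mu <- matrix(spec$mu_loc, n_group, 3)
  sigma <- matrix(spec$sigma_scale / 2, n_group, 3)

  ll_vec <- numeric(n_subj)
  subj_ll <- function(i, zi) {
    if (spec$prior_only || is.null(y)) return(0)
    th <- plogis(zi)
    .rw_loglik_cpp(th[1], th[2], th[3], y[, i], 1e-9)
  }
  for (i in seq_len(n_subj)) ll_vec[i] <- subj_ll(i, z[i, ])

  prop_z <- matrix(0.5, n_subj, 3)
  prop_s <- matrix(0.3, n_group, 3)
  acc_z <- matrix(0L, n_subj, 3)
  try_z <- matrix(0L, n_subj, 3)
  acc_s <- matrix(0L, n_group, 3)
  try_s <- matrix(0L, n_group, 3)
  prop_nc <- matrix(0.3, n_group, 3)
  acc_nc <- matrix(0L, n_group, 3)
  try_nc <- matrix(0L, n_group, 3)

  # Phase-2 warmup: per-subject joint multivariate proposals whose
  # covariance is learned from the chain history (alpha and v1 are
  # strongly correlated in this model, so component-wise proposals mix
  # poorly). `chol_prop[[i]]` holds the Cholesky factor of the scaled
  # empirical covariance.
  phase2_start <- max(200L, floor(warmup * 0.3))
  hist_len <- 0L
  z_hist <- array(NA_real_, c(min(warmup, 2000L), n_subj, length(kf)))
  chol_prop <- vector("list", n_subj)
  jump_scale <- rep(2.38^2 / max(length(kf), 1L), n_subj)
  acc_j <- integer(n_subj)
  try_j <- integer(n_subj)

  n_keep <- iterations - warmup
  free_names <- c(
    unlist(lapply(free, function(nm) sprintf("%s[%d]", nm, seq_len(n_subj)))),
    if (spec$pooled) unlist(lapply(free, function(nm)
      c(sprintf("mu_%s[%d]", nm, seq_len(n_group)),
        sprintf("sigma_%s[%d]", nm, seq_len(n_group)))))
  )
  draws <- matrix(NA_real_, n_keep, length(free_names))
  colnames(draws) <- free_names

  prior_lp <- function(zi, g) {
    if (spec$pooled) {
      sum(stats::dnorm(zi[kf], mu[g, kf], sigma[g, kf], log = TRUE))
    } else {
      sum(stats::dnorm(zi[kf], spec$mu_loc, spec$mu_scale, log = TRUE))
    }
  }

  for (it in seq_len(iterations)) {
    joint <- !is.null(chol_prop[[1L]])
    for (sw in seq_len(sweeps)) {
      for (i in seq_len(n_subj)) {
        g <- grp[i]
        if (joint) {
          # mixture proposal: occasional 5x jumps reach the heavy tails
          # of ridge-shaped subject posteriors (beta poorly pinned when
          # alpha is small)
          big <- if (runif(1) < 0.1) 5 else 1
          zi_new <- z[i, ]
          zi_new[kf] <- zi_new[kf] +
            big * sqrt(jump_scale[i]) * drop(rnorm(length(kf)) %*% chol_prop[[i]])
          ll_new <- subj_ll(i, zi_new)
          lr <- ll_new - ll_vec[i] + prior_lp(zi_new, g) - prior_lp(z[i, ], g)
          try_j[i] <- try_j[i] + 1L
          if (log(runif(1)) < lr) {
            z[i, ] <- zi_new
            ll_vec[i] <- ll_new
            acc_j[i] <- acc_j[i] + 1L
          }
        } else {
          for (k in kf) {
            zc <- z[i, k]
            zp <- zc + rnorm(1, 0, prop_z[i, k])
            zi_new <- z[i, ]
            zi_new[k] <- zp
            ll_new <- subj_ll(i, zi_new)
            if (spec$pooled) {
              lp <- stats::dnorm(zp, mu[g, k], sigma[g, k], log = TRUE) -
                stats::dnorm(zc, mu[g, k], sigma[g, k], log = TRUE)
            } else {
              lp <- stats::dnorm(zp, spec$mu_loc, spec$mu_scale, log = TRUE) -
                stats::dnorm(zc, spec$mu_loc, spec$mu_scale, log = TRUE)
            }
            try_z[i, k] <- try_z[i, k] + 1L
            if (log(runif(1)) < ll_new - ll_vec[i] + lp) {
              z[i, k] <- zp
              ll_vec[i] <- ll_new
              acc_z[i, k] <- acc_z[i, k] + 1L
            }
          }
        }
      }
      if (spec$pooled) {
        for (g in seq_len(n_group)) {
          members <- which(grp == g)
          for (k in kf) {
            # conjugate Gibbs update for the group location
            ng <- length(members)
            prec <- ng / sigma[g, k]^2 + 1 / spec$mu_scale^2
            mean_post <- (sum(z[members, k]) / sigma[g, k]^2 +
                            spec$mu_loc / spec$mu_scale^2) / prec
            mu[g, k] <- rnorm(1, mean_post, sqrt(1 / prec))
            # Metropolis on log(sigma) with half-Normal prior + Jacobian
            ls <- log(sigma[g, k])
            lsp <- ls + rnorm(1, 0, prop_s[g, k])
            sp <- exp(lsp)
            lr <- sum(stats::dnorm(z[members, k], mu[g, k], sp, log = TRUE)) -
              sum(stats::dnorm(z[members, k], mu[g, k], sigma[g, k],
                               log = TRUE)) +
              (-sp^2 / (2 * spec$sigma_scale^2)) -
              (-sigma[g, k]^2 / (2 * spec$sigma_scale^2)) +
              (lsp - ls)
            try_s[g, k] <- try_s[g, k] + 1L
            if (log(runif(1)) < lr) {
              sigma[g, k] <- sp
              acc_s[g, k] <- acc_s[g, k] + 1L
            }
            # Interweaved non-centered move (ASIS): holding the
            # standardised effects eta = (z - mu)/sigma fixed, propose
            # (mu, log sigma) jointly and drag the subject parameters
            # along. Breaks the funnel that stalls the centered updates
            # when a parameter is weakly identified.
            eta <- (z[members, k] - mu[g, k]) / sigma[g, k]
            mup <- mu[g, k] + rnorm(1, 0, prop_nc[g, k])
            lsn <- log(sigma[g, k]) + rnorm(1, 0, prop_nc[g, k])
            spn <- exp(lsn)
            znew <- mup + spn * eta
            ll_new <- ll_vec[members]
            if (!spec$prior_only && !is.null(y)) {
              for (jj in seq_along(members)) {
                zi <- z[members[jj], ]
                zi[k] <- znew[jj]
                ll_new[jj] <- subj_ll(members[jj], zi)
              }
            }
            lr2 <- sum(ll_new - ll_vec[members]) +
              stats::dnorm(mup, spec$mu_loc, spec$mu_scale, log = TRUE) -
              stats::dnorm(mu[g, k], spec$mu_loc, spec$mu_scale, log = TRUE) +
              (-spn^2 / (2 * spec$sigma_scale^2)) -
              (-sigma[g, k]^2 / (2 * spec$sigma_scale^2)) +
              (lsn - log(sigma[g, k]))
            try_nc[g, k] <- try_nc[g, k] + 1L
            if (log(runif(1)) < lr2) {
              mu[g, k] <- mup
              sigma[g, k] <- spn
              z[members, k] <- znew
              ll_vec[members] <- ll_new
              acc_nc[g, k] <- acc_nc[g, k] + 1L
            }
          }
        }
      }
    }
    if (it <= warmup) {
      hist_len <- hist_len + 1L
      if (hist_len <= dim(z_hist)[1]) z_hist[hist_len, , ] <- z[, kf]
    }
    # proposal adaptation, warmup only
    if (it <= warmup && it %% 50L == 0L) {
      rate_z <- acc_z / pmax(try_z, 1L)
      prop_z <- pmin(pmax(prop_z * exp(1.2 * (rate_z - 0.44)), 0.02), 5)
      acc_z[] <- 0L; try_z[] <- 0L
      rate_s <- acc_s / pmax(try_s, 1L)
      prop_s <- pmin(pmax(prop_s * exp(1.2 * (rate_s - 0.44)), 0.02), 5)
      acc_s[] <- 0L; try_s[] <- 0L
      rate_nc <- acc_nc / pmax(try_nc, 1L)
      prop_nc <- pmin(pmax(prop_nc * exp(1.2 * (rate_nc - 0.3)), 0.02), 5)
      acc_nc[] <- 0L; try_nc[] <- 0L
      if (it >= phase2_start) {
        # (re)build joint proposals from the accumulated history
        use <- max(1L, floor(hist_len / 2)):hist_len
        for (i in seq_len(n_subj)) {
          hz <- matrix(z_hist[use, i, ], nrow = length(use))
          cv <- stats::cov(hz) + diag(1e-4, length(kf))
          chol_prop[[i]] <- chol(cv)
        }
        rate_j <- acc_j / pmax(try_j, 1L)
        jump_scale <- pmin(pmax(jump_scale * exp(1.2 * (rate_j - 0.3)),
                                1e-3), 25)
        acc_j[] <- 0L; try_j[] <- 0L
      }
    }
    if (it > warmup) {
      row <- it - warmup
      # column order matches free_names: subject params first, then hypers
      idx <- 1L
      for (nm in free) {
        k <- match(nm, PARAM_NAMES)
        draws[row, idx:(idx + n_subj - 1L)] <- plogis(z[, k])
        idx <- idx + n_subj
      }
      if (spec$pooled) {
        for (nm in free) {
          k <- match(nm, PARAM_NAMES)
          draws[row, idx:(idx + n_group - 1L)] <- mu[, k]
          idx <- idx + n_group
          draws[row, idx:(idx + n_group - 1L)] <- sigma[, k]
          idx <- idx + n_group
        }
      }
    }
  }
  draws
}

#' Sample the posterior of the hierarchical model
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler: component-wise
#' random-walk Metropolis on each subject's logit-scale parameters
#' (proposal scales adapted during warmup toward a 0.44 acceptance rate),
#' a conjugate Gibbs step for each group-level location, and a
#' log-scale Metropolis step for each group-level SD. Chains are run
#' sequentially with seeds derived from `seed`, so results are
#' bit-reproducible.
#'
#' @param table A behavior table (columns `subject_id`, `group`, `trial`,
#'   `outcome`).
#' @param spec A [hier_model_spec()].
#' @param chains Number of chains (>= 2 for diagnostics).
#' @param iterations Total iterations per chain (the full-scale analysis
#'   uses 20000 with 10000 warmup; the default 2000/1000 is the
#'   desk-scale setting).
#' @param warmup Warmup iterations discarded (and used for adaptation).
#' @param seed Integer seed.
#' @param sweeps Update sweeps (subject parameters plus hyperparameter
#'   moves) per stored iteration; the counterpart of a sampler's internal
#'   steps-per-iteration setting.
#' @return A `safeval_posterior`: list with `draws` (array
#'   chain x draw x parameter; subject parameters on the natural scale,
#'   hyperparameters `mu_*`/`sigma_*` on the logit scale), `subjects`,
#'   `groups`, `spec`, and the sampler settings.
#' @export
sample_posterior <- function(table, spec = hier_model_spec(), chains = 4L,
                             iterations = 2000L, warmup = 1000L, seed = 1L,
                             sweeps = 16L) {
  if (iterations <= warmup) abort("`iterations` must exceed `warmup`")
  if (chains < 2L) abort("use >= 2 chains so convergence can be assessed")
  if (spec$prior_only) {
    subjects <- unique(table$subject_id)
    groups_of <- table$group[match(subjects, table$subject_id)]
    y <- NULL
  } else {
    y <- outcome_matrix(table)
    subjects <- colnames(y)
    groups_of <- table$group[match(subjects, table$subject_id)]
  }
  group_levels <- unique(groups_of)
  grp <- match(groups_of, group_levels)

  chain_draws <- lapply(seq_len(chains), function(ch) {
    run_chain(y, grp, length(group_levels), spec, iterations, warmup,
              seed = derive_seed(seed, ch), sweeps = sweeps)
  })
  p <- ncol(chain_draws[[1]])
  pn <- colnames(chain_draws[[1]])
  # rename indices to subject / group labels
  pn <- vapply(pn, function(nm) {
    m <- regmatches(nm, regexec("^(mu_|sigma_)?(alpha|beta|v1)\\[(\\d+)\\]$",
                                nm))[[1]]
    i <- as.integer(m[4])
    if (m[2] == "") sprintf("%s[%s]", m[3], subjects[i])
    else sprintf("%s%s[%s]", m[2], m[3], group_levels[i])
  }, character(1), USE.NAMES = FALSE)
  arr <- array(NA_real_, c(chains, iterations - warmup, p),
               dimnames = list(chain = NULL, draw = NULL, parameter = pn))
  for (ch in seq_len(chains)) arr[ch, , ] <- chain_draws[[ch]]
  structure(list(
    draws = arr, subjects = subjects, groups = group_levels,
    group_of = setNames(groups_of, subjects), spec = spec,
    settings = list(chains = chains, iterations = iterations,
                    warmup = warmup, seed = as.integer(seed),
                    sweeps = sweeps)
  ), class = "safeval_posterior")
}

#' @export
print.safeval_posterior <- function(x, ...) {
  cat(sprintf(
    "<safeval_posterior> %d chains x %d draws, %d parameters (%d subjects, %d groups)\n",
    dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3],
    length(x$subjects), length(x$groups)))
  invisible(x)
}

#' Split-half potential-scale-reduction diagnostic
#'
#' Each chain is halved; with `m` resulting half-chains of length `n`,
#' `W` is the mean within-half variance, `B = n * Var(half means)`, and
#' `R = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate mixing;
#' the package flags anything `>= 1.01`.
#'
#' @param draws A `safeval_posterior`, a chains x draws x parameters
#'   array, or a draws x chains matrix for a single parameter.
#' @return Named numeric vector of R-hat values (or a scalar for a
#'   matrix input).
#' @export
split_rhat <- function(draws) {
  if (inherits(draws, "safeval_posterior")) draws <- draws$draws
  if (is.matrix(draws)) {
    return(split_rhat_one(draws))
  }
  out <- apply(draws, 3, function(m) split_rhat_one(t(m)))
  out
}

split_rhat_one <- function(m) {
  # m: draws x chains
  n2 <- floor(nrow(m) / 2)
  if (n2 < 2L) abort("chains too short to split")
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(n2), j], m[nrow(m) - n2 + seq_len(n2), j])
  }))
  w <- apply(halves, 2, var)
  if (any(w == 0)) abort("constant chain: within-half variance is zero")
  n <- n2
  W <- mean(w)
  B <- n * var(colMeans(halves))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial-positive-sequence estimator
# on split chains (means removed per half-chain).
ess_one <- function(m) {
  n2 <- floor(nrow(m) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(n2), j], m[nrow(m) - n2 + seq_len(n2), j])
  }))
  M <- ncol(halves); n <- nrow(halves)
  ac <- rowMeans(vapply(seq_len(M), function(j) {
    stats::acf(halves[, j], lag.max = min(n - 2L, 200L),
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(min(n - 2L, 200L) + 1L)))
  rho_sum <- 0
  k <- 2L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    rho_sum <- rho_sum + pair
    k <- k + 2L
  }
  M * n / (1 + 2 * rho_sum)
}

#' Posterior summary with convergence diagnostics
#'
#' @param x A `safeval_posterior`.
#' @param ... Unused.
#' @return A tibble: `parameter`, `mean`, `median`, `q2.5`, `q97.5`,
#'   `rhat`, `ess`.
#' @export
tidy.safeval_posterior <- function(x, ...) {
  arr <- x$draws
  pn <- dimnames(arr)$parameter
  purrr::map_dfr(seq_along(pn), function(j) {
    m <- t(arr[, , j])  # draws x chains
    v <- as.vector(m)
    tibble::tibble(
      parameter = pn[j], mean = mean(v), median = median(v),
      q2.5 = quantile(v, 0.025, names = FALSE),
      q97.5 = quantile(v, 0.975, names = FALSE),
      rhat = split_rhat_one(m), ess = ess_one(m))
  })
}

#' @rdname tidy.safeval_posterior
#' @export
glance.safeval_posterior <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(
    n_parameters = nrow(s), max_rhat = max(s$rhat), min_ess = min(s$ess),
    converged = max(s$rhat) < 1.01,
    chains = x$settings$chains,
    draws_per_chain = dim(x$draws)[2])
}

#' Posterior group differences of the hyperparameters
#'
#' For each free parameter, forms the posterior of the difference of
#' group-level means mapped to the natural (probability) scale,
#' `plogis(mu_A) - plogis(mu_B)`, for every ordered pair of groups, with
#' the probability of direction (largest posterior mass on one sign).
#'
#' @param x A `safeval_posterior` fitted to >= 2 groups with pooling.
#' @return A tibble: `parameter`, `group_a`, `group_b`, `mean_diff`,
#'   `q2.5`, `q97.5`, `p_direction`.
#' @export
compare_groups <- function(x) {
  if (length(x$groups) < 2L) abort("model contains a single group")
  free <- setdiff(PARAM_NAMES, names(x$spec$fixed))
  pairs <- utils::combn(x$groups, 2, simplify = FALSE)
  purrr::map_dfr(free, function(nm) {
    purrr::map_dfr(pairs, function(pr) {
      da <- plogis(as.vector(x$draws[, , sprintf("mu_%s[%s]", nm, pr[1])]))
      db <- plogis(as.vector(x$draws[, , sprintf("mu_%s[%s]", nm, pr[2])]))
      d <- da - db
      tibble::tibble(
        parameter = nm, group_a = pr[1], group_b = pr[2],
        mean_diff = mean(d),
        q2.5 = quantile(d, 0.025, names = FALSE),
        q97.5 = quantile(d, 0.975, names = FALSE),
        p_direction = max(mean(d > 0), mean(d < 0)))
    })
  })
}

#' Parameter-recovery audit of the hierarchical sampler
#'
#' Simulates a cohort from known per-subject parameters, refits with
#' [sample_posterior()], and reports per-parameter 95% credible-interval
#' coverage and the rank correlation between truth and posterior mean.
#'
#' @param truth A tibble with columns `alpha`, `beta`, `v1` (and
#'   optionally `tau`, default 0.8), one row per subject (>= 5).
#' @param schedule A [make_schedule()] tibble.
#' @param spec,chains,iterations,warmup,seed Passed to
#'   [sample_posterior()].
#' @param link Outcome link for the simulation step; default
#'   `"identity"` (outcomes drawn directly from the latent probability),
#'   so the audit is performed under the model's own likelihood.
#' @return A `recovery_report`: list with `summary` (tibble `parameter`,
#'   `coverage`, `rank_cor`), `pairs` (per subject x parameter truth,
#'   estimate, CI, coverage flag), and the posterior object.
#' @export
parameter_recovery <- function(truth, schedule, spec = hier_model_spec(),
                               chains = 4L, iterations = 2000L,
                               warmup = 1000L, seed = 1L,
                               link = "identity") {
  if (nrow(truth) < 5L) abort("recovery needs >= 5 subjects")
  if (!"tau" %in% names(truth)) truth$tau <- 0.8
  blocks <- purrr::map(seq_len(nrow(truth)), function(i) {
    rec <- simulate_agent(
      agent_params(truth$alpha[i], truth$beta[i], truth$v1[i], truth$tau[i]),
      schedule, seed = derive_seed(seed, i), link = link)
    dplyr::mutate(rec, subject_id = sprintf("s%02d", i), group = "sim",
                  .before = 1)
  })
  table <- dplyr::bind_rows(blocks)
  post <- sample_posterior(table, spec = spec, chains = chains,
                           iterations = iterations, warmup = warmup,
                           seed = derive_seed(seed, 9999L))
  s <- tidy(post)
  free <- setdiff(PARAM_NAMES, names(spec$fixed))
  pairs <- purrr::map_dfr(free, function(nm) {
    rows <- s[grepl(sprintf("^%s\\[", nm), s$parameter), ]
    sid <- sub("^.*\\[(.*)\\]$", "\\1", rows$parameter)
    tv <- truth[[nm]][as.integer(sub("^s", "", sid))]
    tibble::tibble(
      subject = sid, parameter = nm, truth = tv,
      estimate = rows$mean, lower = rows$q2.5, upper = rows$q97.5,
      covered = tv >= rows$q2.5 & tv <= rows$q97.5)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(pairs, .data$parameter),
    coverage = mean(.data$covered),
    rank_cor = suppressWarnings(
      cor(.data$truth, .data$estimate, method = "spearman")),
    .groups = "drop")
  structure(list(summary = summary, pairs = pairs, posterior = post),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True value", y = "Posterior mean (95% CI)",
                  title = "Parameter recovery")
}
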