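# Group-level Rescorla-Wagner fitting and resampling inference.

#' Rescorla-Wagner avoidance-probability trajectory
#'
#' Iterates `p(t+1) = p(t) + alpha * (beta - p(t))` from `p(1) = v1`. The
#' update contains no outcome term, so the trajectory is deterministic
#' given the parameters.
#'
#' @param params An [agent_params()] (or coercible list; `tau` is ignored
#'   here).
#' @param n_trials Number of trials (>= 1).
#' @return Numeric vector of length `n_trials`, all values in `[0, 1]`.
#' @examples
#' rw_trajectory(agent_params(0.5, 0.8, 0.2), 3)  # 0.20 0.50 0.65
#' @export
rw_trajectory <- function(params, n_trials) {
  params <- as_agent_params(params)
  if (n_trials < 1L) abort("`n_trials` must be >= 1")
  .rw_traj_cpp(params$alpha, params$beta, params$v1, as.integer(n_trials))
}

#' Closed-form Rescorla-Wagner trajectory value
#'
#' The recursion has the geometric-series solution
#' `p(t) = beta + (v1 - beta) * (1 - alpha)^(t - 1)`, which this evaluates
#' directly (vectorised over `t`).
#'
#' @param params An [agent_params()].
#' @param t Trial index (1-based), vectorised.
#' @return Probability value(s).
#' @export
rw_closed_form <- function(params, t) {
  params <- as_agent_params(params)
  if (any(t < 1)) abort("`t` must be >= 1")
  params$beta + (params$v1 - params$beta) * (1 - params$alpha)^(t - 1)
}

default_start_grid <- function(n = 5) seq(0.05, 0.95, length.out = n)

#' Least-squares fit of the Rescorla-Wagner model to a group curve
#'
#' Minimises the sum of squared errors between the empirical per-trial
#' mean avoidance probability and the model trajectory over
#' `(alpha, beta, v1) in [0,1]^3`. The fit is multi-start: SSE is
#' evaluated on a 5 x 5 x 5 grid of starts over `{0.05 ... 0.95}^3`, the
#' best starts are refined by Nelder-Mead simplex search on the logit
#' scale (which keeps parameters inside the unit cube) with small-step
#' polish restarts; ties are broken by lowest SSE then smallest `alpha`.
#' The fit target is the raw latent probability (no softmax link), which
#' is also how the curve is displayed against data.
#'
#' @param curve A tibble from [empirical_group_curve()] (columns `trial`,
#'   `p_avoid`) or a plain numeric vector of per-trial means.
#' @param grid Numeric vector of start values per dimension.
#' @param n_refine How many of the best grid starts to refine.
#' @return An object of class `safeval_fit` with elements `params` (named
#'   vector `alpha`, `beta`, `v1`), `sse`, `n_starts`,
#'   `alpha_identifiable` (FALSE when the fitted trajectory is flat, in
#'   which case `alpha` is arbitrary), `convergence`, and the input curve.
#' @examples
#' curve <- rw_trajectory(agent_params(0.1, 0.9, 0.05), 150)
#' fit <- fit_group(curve)
#' tidy(fit)
#' @export
fit_group <- function(curve, grid = default_start_grid(), n_refine = 3L) {
  y <- if (is.data.frame(curve)) curve$p_avoid else as.numeric(curve)
  if (length(y) < 3L) abort("`curve` must have length >= 3")
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    abort("curve values must be probabilities in [0, 1]")
  }
  res <- .rw_fit_cpp(y, grid, as.integer(n_refine))
  par <- setNames(res[1:3], c("alpha", "beta", "v1"))
  structure(list(
    params = par,
    sse = res[4],
    n_starts = length(grid)^3,
    alpha_identifiable = abs(par[["beta"]] - par[["v1"]]) > 1e-4,
    convergence = 0L,
    curve = y
  ), class = "safeval_fit")
}

#' @export
print.safeval_fit <- function(x, ...) {
  cat(sprintf(
    "<safeval_fit> alpha = %.4f, beta = %.4f, v1 = %.4f (SSE %.3g over %d trials)%s\n",
    x$params["alpha"], x$params["beta"], x$params["v1"], x$sse,
    length(x$curve),
    if (!x$alpha_identifiable) " [alpha not identifiable: flat trajectory]" else ""))
  invisible(x)
}

#' @rdname fit_group
#' @param x A `safeval_fit` object.
#' @param ... Unused.
#' @export
tidy.safeval_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_group
#' @export
glance.safeval_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_trials = length(x$curve),
                 n_starts = x$n_starts,
                 alpha_identifiable = x$alpha_identifiable,
                 converged = x$convergence == 0L)
}

#' @export
autoplot.safeval_fit <- function(object, ...) {
  df <- tibble::tibble(
    trial = seq_along(object$curve),
    empirical = object$curve,
    fitted = rw_trajectory(c(object$params, tau = 0.8),
                           length(object$curve)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$empirical), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Trial", y = "Avoidance probability",
                  title = "Empirical group curve and best-fit model")
}

outcome_matrix <- function(table) {
  wide <- tidyr::pivot_wider(
    dplyr::arrange(table[, c("subject_id", "trial", "outcome")],
                   .data$trial),
    names_from = "subject_id", values_from = "outcome")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) abort("subjects have ragged/misaligned trial indices")
  m
}

#' Subject-level bootstrap standard errors for fitted group parameters
#'
#' Resamples subjects with replacement, rebuilds the group mean curve,
#' and refits the model for each resample; the standard error of each
#' parameter is the standard deviation of its bootstrap draws. (The
#' within-group uncertainty procedure is an ordinary nonparametric
#' bootstrap at the subject level.)
#'
#' @param table A behavior table.
#' @param group Optional group label to select.
#' @param n_boot Number of bootstrap draws (1000 in the full analysis).
#' @param seed Integer seed; draws are bit-reproducible given it.
#' @return A `safeval_boot` object: `estimate` (fit on the original
#'   curve), `draws` (tibble `draw`, `alpha`, `beta`, `v1`), `se` (named
#'   vector), `n_boot`, `seed`.
#' @export
bootstrap_se <- function(table, group = NULL, n_boot = 1000L, seed = 1L) {
  if (!is.null(group)) table <- table[table$group == group, ]
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2L) abort("bootstrap needs >= 2 subjects")
  m <- outcome_matrix(table)
  est <- fit_group(rowMeans(m))
  grid <- default_start_grid()
  draws <- seeded(seed, function() {
    t(vapply(seq_len(n_boot), function(b) {
      take <- sample(length(subjects), replace = TRUE)
      .rw_fit_cpp(rowMeans(m[, take, drop = FALSE]), grid, 3L)[1:3]
    }, numeric(3)))
  })
  colnames(draws) <- c("alpha", "beta", "v1")
  structure(list(
    estimate = est,
    draws = tibble::as_tibble(draws) |>
      dplyr::mutate(draw = dplyr::row_number(), .before = 1),
    se = apply(draws, 2, sd),
    n_boot = as.integer(n_boot),
    seed = as.integer(seed)
  ), class = "safeval_boot")
}

#' @export
print.safeval_boot <- function(x, ...) {
  cat(sprintf("<safeval_boot> %d draws (seed %d)\n", x$n_boot, x$seed))
  print(tidy(x))
  invisible(x)
}

#' @rdname bootstrap_se
#' @param x A `safeval_boot`.
#' @param ... Unused.
#' @export
tidy.safeval_boot <- function(x, ...) {
  tibble::tibble(term = names(x$estimate$params),
                 estimate = unname(x$estimate$params),
                 std.error = unname(x$se[names(x$estimate$params)]))
}

#' Label-permutation test for group differences in fitted parameters
#'
#' The observed statistic is the difference (A - B) of the group-level
#' fitted parameters. The null distribution is built by randomly
#' reassigning subjects to groups (preserving group sizes) and refitting
#' both groups; the two-sided p-value is
#' `(1 + #\{|diff_perm| >= |diff_obs|\}) / (1 + n_perm)`.
#'
#' @param table_a,table_b Behavior tables for the two groups.
#' @param n_perm Number of permutations (5000 in the full analysis).
#' @param seed Integer seed.
#' @return A `safeval_perm` object; `tidy()` gives a tibble with
#'   `term`, `estimate` (observed difference), `p.value`.
#' @export
permutation_test <- function(table_a, table_b, n_perm = 5000L, seed = 1L) {
  ma <- outcome_matrix(table_a)
  mb <- outcome_matrix(table_b)
  if (ncol(ma) < 2L || ncol(mb) < 2L) {
    abort("each group needs >= 2 subjects")
  }
  if (nrow(ma) != nrow(mb)) abort("groups must share the trial axis")
  na <- ncol(ma)
  pool <- cbind(ma, mb)
  grid <- default_start_grid()
  fit_pair <- function(ia) {
    ib <- setdiff(seq_len(ncol(pool)), ia)
    .rw_fit_cpp(rowMeans(pool[, ia, drop = FALSE]), grid, 3L)[1:3] -
      .rw_fit_cpp(rowMeans(pool[, ib, drop = FALSE]), grid, 3L)[1:3]
  }
  obs <- setNames(fit_pair(seq_len(na)), c("alpha", "beta", "v1"))
  perm <- seeded(seed, function() {
    t(vapply(seq_len(n_perm), function(i) {
      fit_pair(sample(ncol(pool), na))
    }, numeric(3)))
  })
  colnames(perm) <- names(obs)
  pvals <- vapply(names(obs), function(k) {
    (1 + sum(abs(perm[, k]) >= abs(obs[[k]]))) / (1 + n_perm)
  }, numeric(1))
  structure(list(
    observed = obs, p_values = pvals,
    draws = tibble::as_tibble(perm),
    n_perm = as.integer(n_perm), seed = as.integer(seed)
  ), class = "safeval_perm")
}

#' @export
print.safeval_perm <- function(x, ...) {
  cat(sprintf("<safeval_perm> %d permutations (seed %d)\n",
              x$n_perm, x$seed))
  print(tidy(x))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `safeval_perm`.
#' @param ... Unused.
#' @export
tidy.safeval_perm <- function(x, ...) {
  tibble::tibble(term = names(x$observed),
                 estimate = unname(x$observed),
                 p.value = unname(x$p_values[names(x$observed)]))
}

#' Mean simulated avoidance curve under the softmax outcome model
#'
#' Averages `n_sims` simulated 0/1 outcome sequences generated from the
#' latent trajectory through the softmax link (inverse temperature
#' `params$tau`). Its expectation at trial `t` is
#' `plogis(tau * (2 * p(t) - 1))`.
#'
#' @param params An [agent_params()].
#' @param n_trials Trials per simulation.
#' @param n_sims Number of simulations to average (100 in the full
#'   analysis).
#' @param seed Integer seed.
#' @return A tibble `trial`, `p_avoid`.
#' @export
simulate_model_mean <- function(params, n_trials, n_sims = 100L, seed = 1L) {
  params <- as_agent_params(params)
  if (n_sims < 1L) abort("`n_sims` must be >= 1")
  p <- rw_trajectory(params, n_trials)
  q <- softmax_avoid_prob(p, params$tau)
  sims <- seeded(seed, function() {
    matrix(rbinom(n_trials * n_sims, 1L, rep(q, n_sims)),
           nrow = n_trials)
  })
  tibble::tibble(trial = seq_len(n_trials), p_avoid = rowMeans(sims))
}
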