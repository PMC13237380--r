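#' Rescorla-Wagner agent parameters
#'
#' Bundles the parameter triple of the avoidance-learning model — learning
#' rate `alpha`, asymptotic safety value `beta`, initial avoidance
#' probability `v1` — together with the softmax inverse temperature `tau`
#' used when latent avoidance probability is turned into trial outcomes.
#'
#' The latent state evolves as `p(t+1) = p(t) + alpha * (beta - p(t))`
#' starting from `p(1) = v1`; it is deterministic (no outcome feedback).
#' `tau` only matters at outcome generation time, where
#' `P(avoid at t) = plogis(tau * (2 * p(t) - 1))`.
#'
#' @param alpha Learning rate, in `[0, 1]`.
#' @param beta Asymptotic value of safety (avoidance-probability units), in
#'   `[0, 1]`.
#' @param v1 Initial avoidance probability, in `[0, 1]`.
#' @param tau Softmax inverse temperature, `>= 0`. Default 0.8, the value
#'   used for outcome simulation throughout.
#'
#' @return An object of class `agent_params` (a named list).
#' @examples
#' agent_params(alpha = 0.3, beta = 0.8, v1 = 0.1)
#' @export
agent_params <- function(alpha, beta, v1, tau = 0.8) {
  for (nm in c("alpha", "beta", "v1")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must be a single number in [0, 1].", nm))
    }
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    abort("`tau` must be a single non-negative number.")
  }
  structure(list(alpha = alpha, beta = beta, v1 = v1, tau = tau),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> alpha = %.3g, beta = %.3g, v1 = %.3g, tau = %.3g\n",
    x$alpha, x$beta, x$v1, x$tau))
  invisible(x)
}

as_agent_params <- function(x) {
  if (inherits(x, "agent_params")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    return(agent_params(x[["alpha"]], x[["beta"]], x[["v1"]],
                        if ("tau" %in% names(x)) x[["tau"]] else 0.8))
  }
  if (is.list(x)) {
    return(agent_params(x$alpha, x$beta, x$v1, x$tau %||% 0.8))
  }
  abort("Cannot interpret `params`; use `agent_params()`.")
}

#' Softmax mapping from latent avoidance probability to outcome probability
#'
#' Two-option softmax over the action values `(p, 1 - p)`:
#' `P(avoid) = plogis(tau * (2 * p - 1))`. With `tau = 0` every trial is a
#' coin flip; as `tau` grows the outcome tracks the latent state ever more
#' deterministically.
#'
#' @param p Latent avoidance probability (vectorised).
#' @param tau Inverse temperature, `>= 0`.
#' @return Outcome probabilities, same length as `p`.
#' @export
softmax_avoid_prob <- function(p, tau) {
  if (any(tau < 0)) abort("`tau` must be non-negative.")
  plogis(tau * (2 * p - 1))
}
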