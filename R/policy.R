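#' Recruitment policy: how units are chosen for a shift
#'
#' In postural muscle, recruitment of individual units during a contraction is
#' stochastic; the selection distribution is either uniform across units or
#' biased towards small units. The small-unit bias uses the power-weight
#' family `weight_i proportional to twitch_force_i^(-bias_strength)`: weights
#' fall strictly with force for any positive `bias_strength`, and
#' `bias_strength = 0` recovers the uniform policy exactly.
#'
#' @param kind `"uniform"` or `"small_biased"`.
#' @param bias_strength non-negative exponent of the small-unit bias
#'   (ignored for the uniform policy). Default 1.
#' @return An object of class `mu_policy`.
#' @examples
#' recruitment_policy("small_biased", bias_strength = 2)
#' @export
recruitment_policy <- function(kind = c("uniform", "small_biased"),
                               bias_strength = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(bias_strength) || length(bias_strength) != 1 ||
      is.na(bias_strength) || bias_strength < 0)
    stop("`bias_strength` must be a single non-negative number", call. = FALSE)
  structure(list(kind = kind, bias_strength = bias_strength),
            class = "mu_policy")
}

#' @export
print.mu_policy <- function(x, ...) {
  if (x$kind == "uniform") {
    cat("<recruitment policy: uniform>\n")
  } else {
    cat(sprintf("<recruitment policy: small-unit biased, bias_strength = %g>\n",
                x$bias_strength))
  }
  invisible(x)
}

as_mu_policy <- function(policy) {
  if (inherits(policy, "mu_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1)
    return(recruitment_policy(policy))
  if (is.list(policy))
    return(recruitment_policy(policy$kind %||% "uniform",
                              policy$bias_strength %||% 1))
  stop("`policy` must be a recruitment_policy() object", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-unit selection probabilities under a policy
#'
#' Uniform: every unit gets weight `1/n`. Small-biased: weight of unit `i` is
#' proportional to `twitch_force^(-bias_strength)`, normalized to sum to 1.
#' These are the probabilities of being sampled first; within a shift,
#' sampling proceeds without replacement with weights renormalized among the
#' remaining units.
#'
#' @param pool a `mu_pool` data frame.
#' @param policy a [recruitment_policy()].
#' @return Numeric vector of strictly positive weights summing to 1, one per
#'   unit in pool order.
#' @examples
#' selection_weights(mu_pool(4), recruitment_policy("uniform"))
#' @export
selection_weights <- function(pool, policy = recruitment_policy("uniform")) {
  validate_mu_pool(pool)
  policy <- as_mu_policy(policy)
  n <- nrow(pool)
  if (policy$kind == "uniform" || policy$bias_strength == 0)
    return(rep(1 / n, n))
  w <- pool$twitch_force^(-policy$bias_strength)
  w / sum(w)
}
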