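#' Category response probabilities of an ordinal item
#'
#' Evaluates the graded-response category probability mass function
#' \eqn{P(Y_i = k \mid \eta)} implied by the cumulative category response
#' function \eqn{P(Y_i \ge k \mid \eta) = \Phi(\lambda_i\eta - \kappa_{ik})}
#' (for \eqn{k \ge 2}; the lowest category has cumulative probability 1).
#' Category probabilities are successive differences of the cumulative
#' probabilities.
#'
#' @param params A [grm_parameters] object.
#' @param item Item index or name; must be an ordinal item.
#' @param eta Scalar latent value.
#' @return Numeric probability vector of length \eqn{K_i} (sums to 1).
#' @examples
#' p <- grm_parameters(c(y1 = 1, y2 = 1, y3 = 1),
#'                     thresholds = list(y1 = 0, y2 = 0, y3 = 0))
#' response_distribution(p, "y1", eta = 0) # 0.5, 0.5
#' @export
response_distribution <- function(params, item, eta) {
  nm <- item_name(params, item)
  assert_that(item_kind(params, nm) == "ordinal",
              sprintf("item '%s' is not ordinal", nm))
  assert_that(is.finite(eta), "eta must be finite")
  kappa <- params$thresholds[[nm]]
  assert_that(all(diff(kappa) > 0) || length(kappa) == 1,
              "thresholds must be strictly increasing")
  drop(grm_category_probs(params$loadings[[nm]], kappa, eta))
}

# Vectorised pmf: rows = eta values, cols = categories 1..K.
grm_category_probs <- function(lambda, kappa, eta) {
  cum <- cbind(1, stats::pnorm(outer(lambda * eta, kappa, "-")), 0)
  p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE]
  pmax(p, 0)
}

#' Conditional mean of a numeric item
#'
#' For numeric items the model is linear: \eqn{E(Y_i \mid \eta) = \pi_i +
#' \lambda_i \eta}.
#' @inheritParams response_distribution
#' @return Numeric scalar (or vector if `eta` is a vector).
#' @export
numeric_conditional_mean <- function(params, item, eta) {
  nm <- item_name(params, item)
  assert_that(item_kind(params, nm) == "numeric",
              sprintf("item '%s' is not numeric", nm))
  params$intercepts[[nm]] + params$loadings[[nm]] * eta
}

#' Simulate item responses at given latent values
#'
#' Draws one row of item responses per entry of `etas`: ordinal items from
#' the graded-response category distribution at that row's latent value,
#' numeric items from a Gaussian with mean \eqn{\pi_i + \lambda_i\eta} and
#' the item's residual variance. Reproducible under a fixed RNG state.
#'
#' @param params A [grm_parameters] object.
#' @param etas Numeric vector of latent values (one per row).
#' @return A tibble with one column per item; ordinal columns are integer
#'   codes `1..K`.
#' @export
simulate_responses <- function(params, etas) {
  assert_that(all(is.finite(etas)), "etas must be finite")
  n <- length(etas)
  items <- names(params$loadings)
  out <- vector("list", length(items))
  names(out) <- items
  u <- NULL
  for (nm in items) {
    if (item_kind(params, nm) == "ordinal") {
      kappa <- params$thresholds[[nm]]
      cum <- stats::pnorm(outer(params$loadings[[nm]] * etas, kappa, "-"))
      # category = 1 + number of exceeded cumulative boundaries
      u <- stats::runif(n)
      out[[nm]] <- as.integer(1L + rowSums(u < cum))
    } else {
      mu <- params$intercepts[[nm]] + params$loadings[[nm]] * etas
      out[[nm]] <- stats::rnorm(n, mu, sqrt(params$residual_variances[[nm]]))
    }
  }
  tibble::as_tibble(out)
}
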