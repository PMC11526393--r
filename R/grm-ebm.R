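#' Empirical Bayes modal (EBM) latent variable scores
#'
#' For each response pattern, maximises the log posterior of the latent
#' variable: normal prior \eqn{N(\mu_\eta, \phi)} plus the ordinal
#' graded-response log-likelihood and/or numeric Gaussian log-likelihood of
#' the pattern. The log posterior is strictly concave in \eqn{\eta}
#' (probit category probabilities are log-concave), so the mode is the
#' unique root of the posterior score function, found by vectorised
#' bisection on \eqn{[\mu_\eta - 8\sqrt\phi, \mu_\eta + 8\sqrt\phi]};
#' identical response patterns are scored once. A pattern whose posterior
#' mode sits at the interval boundary is flagged unavailable.
#'
#' @param data Data frame (or matrix) containing the item columns named in
#'   `params`.
#' @param params A [grm_parameters] object.
#' @param tol Bisection tolerance on the latent scale (default 1e-8).
#' @return A tibble with one row per input row: `.row`, `score` (posterior
#'   mode, `NA` when unavailable), `available`.
#' @examples
#' p <- grm_parameters(c(y1 = 1, y2 = 1, y3 = 1),
#'                     thresholds = list(y1 = 0, y2 = 0, y3 = 0))
#' ebm_scores(data.frame(y1 = c(1, 2), y2 = c(1, 2), y3 = c(1, 2)), p)
#' @export
ebm_scores <- function(data, params, tol = 1e-8) {
  items <- names(params$loadings)
  y <- as.matrix(as.data.frame(data)[, items, drop = FALSE])
  storage.mode(y) <- "double"
  n <- nrow(y)
  key <- apply(y, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  uy <- y[first, , drop = FALSE]
  uscore <- ebm_modes(uy, params, tol)
  names(uscore) <- key[first]
  score <- unname(uscore[key])
  tibble::tibble(.row = seq_len(n), score = score,
                 available = is.finite(score))
}

# Posterior score function (d log posterior / d eta), vectorised over
# patterns (rows of y) at a vector of eta values (one per pattern).
ebm_score_fun <- function(eta, y, params, ord, num) {
  g <- -(eta - params$factor_mean) / params$factor_variance
  for (nm in ord) {
    lam <- params$loadings[[nm]]
    kappa <- params$thresholds[[nm]]
    k <- y[, nm]
    le <- lam * eta
    # P(Y = k) = pnorm(a_hi) - pnorm(a_lo), a = lambda*eta - kappa;
    # a_hi uses the lower boundary (k-1), a_lo the upper boundary (k).
    a_hi <- ifelse(k <= 1, Inf, le - kappa[pmax(k - 1, 1)])
    a_lo <- ifelse(k > length(kappa), -Inf, le - kappa[pmin(k, length(kappa))])
    a_hi_c <- pmin(pmax(a_hi, -12), 12)
    a_lo_c <- pmin(pmax(a_lo, -12), 12)
    p <- pmax(stats::pnorm(a_hi_c) - stats::pnorm(a_lo_c), 1e-300)
    g <- g + lam * (stats::dnorm(a_hi_c) - stats::dnorm(a_lo_c)) / p
  }
  for (nm in num) {
    lam <- params$loadings[[nm]]
    g <- g + lam * (y[, nm] - params$intercepts[[nm]] - lam * eta) /
      params$residual_variances[[nm]]
  }
  g
}

# Vectorised bisection for the posterior modes of unique patterns.
ebm_modes <- function(y, params, tol = 1e-8) {
  nu <- nrow(y)
  if (!nu) return(numeric(0))
  items <- names(params$loadings)
  ord <- intersect(items, names(params$thresholds))
  num <- setdiff(items, ord)
  mu <- params$factor_mean
  s <- sqrt(params$factor_variance)
  lo <- rep(mu - 8 * s, nu)
  hi <- rep(mu + 8 * s, nu)
  g_lo <- ebm_score_fun(lo, y, params, ord, num)
  g_hi <- ebm_score_fun(hi, y, params, ord, num)
  # score is decreasing; interior root iff g_lo > 0 > g_hi
  at_lo <- g_lo <= 0
  at_hi <- g_hi >= 0
  res <- numeric(nu)
  res[at_lo] <- lo[at_lo]
  res[at_hi] <- hi[at_hi]
  act <- which(!at_lo & !at_hi)
  if (length(act)) {
    l <- lo[act]; h <- hi[act]
    ya <- y[act, , drop = FALSE]
    for (it in seq_len(60)) {
      mid <- (l + h) / 2
      gm <- ebm_score_fun(mid, ya, params, ord, num)
      up <- gm > 0
      l[up] <- mid[up]
      h[!up] <- mid[!up]
      if (max(h - l) < tol) break
    }
    res[act] <- (l + h) / 2
  }
  # boundary modes are not trusted scores
  res[at_lo | at_hi] <- NA_real_
  # flat posteriors (all loadings zero) have g linear in eta: mode = mu
  res[!is.finite(res) & abs(g_lo - g_hi) < 1e-12] <- mu
  res
}
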