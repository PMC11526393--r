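# Shared fixtures: small parameter sets, simulators, and independent
# oracles used across the test files.

# 3-item, 3-category graded model (small enough for exhaustive checks)
small_grm <- function(factor_mean = 0.3, factor_variance = 1.2) {
  grm_parameters(
    loadings = c(y1 = 1, y2 = 0.8, y3 = 1.3),
    thresholds = list(y1 = c(0, 1), y2 = c(-0.5, 0.6), y3 = c(-1, 0.8)),
    factor_mean = factor_mean, factor_variance = factor_variance
  )
}

small_spec <- function() grm_spec(paste0("y", 1:3), n_categories = 3)

# single-factor Gaussian data (numeric items) from known parameters
simulate_gaussian_factor <- function(n, lambda = c(1, 0.7, 1.3),
                                     psi = c(1, 0.6, 0.9),
                                     intercepts = c(2, -1, 0.5),
                                     phi = 0.8) {
  eta <- rnorm(n, 0, sqrt(phi))
  y <- sapply(seq_along(lambda), function(i) {
    intercepts[i] + lambda[i] * eta + rnorm(n, 0, sqrt(psi[i]))
  })
  colnames(y) <- paste0("x", seq_along(lambda))
  list(data = as.data.frame(y), eta = eta,
       spec = grm_spec(colnames(y), kind = "numeric"))
}

# two-regime ordinal data with a planted breakpoint on a numeric covariate:
# regimes use two of the printed heterogeneous parameter sets (they differ
# in every parameter), mirroring the designed subgroup heterogeneity.
simulate_breakpoint <- function(n = 1000, cut = 50, zmax = 200,
                                regimes = c(1, 6)) {
  pars <- sim1_parameters()[regimes]
  z <- sample.int(zmax, n, replace = TRUE)
  g <- ifelse(z <= cut, 1L, 2L)
  eta <- numeric(n)
  y <- matrix(0L, n, 5, dimnames = list(NULL, paste0("y", 1:5)))
  for (k in 1:2) {
    idx <- which(g == k)
    p <- pars[[k]]
    eta[idx] <- rnorm(length(idx), p$factor_mean, sqrt(p$factor_variance))
    y[idx, ] <- as.matrix(simulate_responses(p, eta[idx]))
  }
  list(data = as.data.frame(y), z = z, eta = eta, group = g,
       spec = sim1_spec())
}

# grid-search oracle for the posterior mode: coarse pass then a fine pass
# around the coarse argmax (resolution ~1e-6)
ebm_grid_oracle <- function(yrow, params, half_width = 6) {
  mu <- params$factor_mean
  s <- sqrt(params$factor_variance)
  logpost <- function(eta) {
    lp <- dnorm(eta, mu, s, log = TRUE)
    for (nm in names(params$loadings)) {
      lam <- params$loadings[[nm]]
      if (nm %in% names(params$thresholds)) {
        kap <- params$thresholds[[nm]]
        k <- yrow[[nm]]
        hi <- if (k <= 1) 1 else pnorm(lam * eta - kap[k - 1])
        lo <- if (k > length(kap)) 0 else pnorm(lam * eta - kap[k])
        lp <- lp + log(pmax(hi - lo, 1e-300))
      } else {
        lp <- lp + dnorm(yrow[[nm]],
                         params$intercepts[[nm]] + lam * eta,
                         sqrt(params$residual_variances[[nm]]), log = TRUE)
      }
    }
    lp
  }
  g1 <- seq(mu - half_width * s, mu + half_width * s, length.out = 2001)
  c1 <- g1[which.max(logpost(g1))]
  step <- g1[2] - g1[1]
  g2 <- seq(c1 - step, c1 + step, length.out = 4001)
  g2[which.max(logpost(g2))]
}

# brute-force graded-response pmf: evaluate Phi at every threshold and
# difference adjacent cumulative values
pmf_oracle <- function(lambda, kappa, eta) {
  cum <- c(1, pnorm(lambda * eta - kappa), 0)
  cum[-length(cum)] - cum[-1]
}
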