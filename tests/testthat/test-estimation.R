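test_that("ML fit recovers a known single-factor Gaussian model", {
  set.seed(21)
  sim <- simulate_gaussian_factor(50000)
  fit <- fit_ml_cfa(sim$data, sim$spec)
  expect_true(fit$converged)
  expect_false(fit$heywood)
  truth <- c(pi_x1 = 2, pi_x2 = -1, pi_x3 = 0.5,
             lambda_x2 = 0.7, lambda_x3 = 1.3,
             psi_x1 = 1, psi_x2 = 0.6, psi_x3 = 0.9, phi = 0.8)
  expect_true(all(abs(fit$theta[names(truth)] - truth) < 0.05))
})

test_that("log-likelihood matches an independent multivariate-normal oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(22)
  sim <- simulate_gaussian_factor(400)
  fit <- fit_ml_cfa(sim$data, sim$spec)
  ll <- sum(mvtnorm::dmvnorm(as.matrix(sim$data), mean = fit$mu,
                             sigma = fit$Sigma, log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("casewise scores are the per-row density gradients", {
  skip_if_not_installed("mvtnorm")
  set.seed(23)
  sim <- simulate_gaussian_factor(60)
  fit <- fit_ml_cfa(sim$data, sim$spec)
  sc <- casewise_scores(fit, sim$data)

  # column sums vanish at the optimum
  expect_true(all(abs(colSums(sc)) < nrow(sc) * 1e-6 + 1e-4))

  # duplicated rows produce identical score rows
  d2 <- sim$data[c(1, 1, 2), ]
  sc2 <- casewise_scores(fit, d2)
  expect_equal(sc2[1, ], sc2[2, ])

  # finite differences of the casewise log density
  m <- 3
  free <- fit$free_loadings
  rebuild <- function(th) {
    mu <- th[1:m]
    lam <- rep(1, m); lam[free] <- th[m + seq_along(free)]
    psi <- th[m + length(free) + 1:m]
    phi <- th[length(th)]
    list(mu = mu, Sigma = phi * tcrossprod(lam) + diag(psi, m))
  }
  th0 <- unname(fit$theta)
  rows <- c(3, 17, 42)
  for (j in rows) {
    yj <- as.numeric(sim$data[j, ])
    for (par in seq_along(th0)) {
      h <- 1e-5 * max(1, abs(th0[par]))
      tp <- th0; tp[par] <- tp[par] + h
      tm <- th0; tm[par] <- tm[par] - h
      up <- rebuild(tp); dn <- rebuild(tm)
      fd <- (mvtnorm::dmvnorm(yj, up$mu, up$Sigma, log = TRUE) -
               mvtnorm::dmvnorm(yj, dn$mu, dn$Sigma, log = TRUE)) / (2 * h)
      expect_equal(unname(sc[j, par]), fd,
                   tolerance = 1e-5 * max(1, abs(fd)) + 1e-7)
    }
  }
})

test_that("univariate thresholds are probit-transformed cumulative proportions", {
  d <- data.frame(y1 = rep(1:2, each = 50), y2 = rep(1:2, 50),
                  y3 = rep(c(1, 1, 2, 2), 25))
  sp <- grm_spec(paste0("y", 1:3), n_categories = 2)
  st <- estimate_polychoric(d, sp)
  expect_equal(unname(st$tau$y1), 0)
  expect_equal(unname(st$tau$y3), qnorm(0.5))
})

test_that("polychoric correlation of independent items is near zero", {
  set.seed(24)
  n <- 100000
  d <- data.frame(y1 = sample(1:4, n, TRUE),
                  y2 = sample(1:4, n, TRUE),
                  y3 = sample(1:4, n, TRUE))
  sp <- grm_spec(paste0("y", 1:3), n_categories = 4)
  st <- estimate_polychoric(d, sp)
  expect_true(all(abs(st$cors$rho) < 0.02))
})

test_that("pairwise polychoric matches a brute-force grid oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(25)
  # correlated ordinal pair via a latent bivariate normal
  n <- 2000
  rho_true <- 0.55
  z <- matrix(rnorm(2 * n), ncol = 2) %*% chol(matrix(c(1, rho_true,
                                                        rho_true, 1), 2))
  cutq <- c(-0.6, 0.4)
  d <- data.frame(y1 = findInterval(z[, 1], cutq) + 1L,
                  y2 = findInterval(z[, 2], cutq) + 1L,
                  y3 = sample(1:3, n, TRUE))
  sp <- grm_spec(paste0("y", 1:3), n_categories = 3)
  st <- estimate_polychoric(d, sp)
  rho_hat <- st$cors$rho[st$cors$item1 == "y1" & st$cors$item2 == "y2"]

  tab <- table(d$y1, d$y2)
  tau1 <- st$tau$y1; tau2 <- st$tau$y2
  cellp <- function(r) {
    a <- c(-Inf, tau1, Inf); b <- c(-Inf, tau2, Inf)
    Fg <- outer(seq_along(a), seq_along(b), Vectorize(function(i, j) {
      if (is.infinite(a[i]) && a[i] < 0 || is.infinite(b[j]) && b[j] < 0) {
        if ((is.infinite(a[i]) && a[i] < 0) || (is.infinite(b[j]) && b[j] < 0)) return(0)
      }
      mvtnorm::pmvnorm(upper = c(min(a[i], 8), min(b[j], 8)),
                       corr = matrix(c(1, r, r, 1), 2))[1]
    }))
    Fg[2:4, 2:4] - Fg[1:3, 2:4] - Fg[2:4, 1:3] + Fg[1:3, 1:3]
  }
  grid <- seq(-0.99, 0.99, by = 0.002)
  ll <- sapply(grid, function(r) sum(tab * log(pmax(cellp(r), 1e-12))))
  expect_equal(rho_hat, grid[which.max(ll)], tolerance = 1e-3 + 0.002)
})

test_that("WLS recovers the generating parameters of a printed subgroup", {
  set.seed(26)
  p <- sim1_parameters()$R1
  eta <- rnorm(100000, p$factor_mean, sqrt(p$factor_variance))
  d <- simulate_responses(p, eta)
  f <- fit_wls(d, sim1_spec())
  expect_true(f$converged)
  est <- f$parameters
  expect_true(all(abs(est$loadings - p$loadings) < 0.05))
  expect_lt(abs(est$factor_mean - p$factor_mean), 0.05)
  expect_lt(abs(est$factor_variance - p$factor_variance), 0.05)
  for (i in 1:5) {
    expect_true(all(abs(est$thresholds[[i]] - p$thresholds[[i]]) < 0.05))
  }
})

test_that("degrees of freedom bookkeeping matches the closed-form count", {
  set.seed(27)
  p <- sim1_parameters()$R2
  d <- simulate_responses(p, rnorm(2000, p$factor_mean,
                                   sqrt(p$factor_variance)))
  f <- fit_wls(d, sim1_spec())
  # 5 ordinal items x 7 categories: 30 thresholds + 10 correlations = 40
  # statistics; 29 free thresholds + 4 loadings + variance + mean = 35
  expect_equal(length(f$stats$stat), 40)
  expect_equal(f$df, 5)
})

test_that("ML and WLS agree on large homogeneous numeric-item data", {
  set.seed(28)
  # 4 items so the numeric-item model keeps positive degrees of freedom
  sim <- simulate_gaussian_factor(50000, lambda = c(1, 0.7, 1.3, 0.9),
                                  psi = c(1, 0.6, 0.9, 1.2),
                                  intercepts = c(2, -1, 0.5, 0))
  ml <- fit_ml_cfa(sim$data, sim$spec)
  wls <- fit_wls(sim$data, sim$spec)
  expect_true(wls$converged)
  p <- wls$parameters
  expect_true(all(abs(p$loadings[2:4] -
                        ml$theta[c("lambda_x2", "lambda_x3", "lambda_x4")]) < 0.05))
  expect_lt(abs(p$factor_variance - ml$theta[["phi"]]), 0.05)
  expect_true(all(abs(p$residual_variances -
                        ml$theta[paste0("psi_x", 1:4)]) < 0.05))
})

test_that("the DWLS objective at the solution beats the generating values", {
  set.seed(29)
  p <- sim1_parameters()$R4
  d <- simulate_responses(p, rnorm(1500, p$factor_mean,
                                   sqrt(p$factor_variance)))
  f <- fit_wls(d, sim1_spec())
  st <- f$stats
  pairs <- utils::combn(5, 2)
  rho_names <- paste0("rho_y", pairs[1, ], "_y", pairs[2, ])
  w <- diag(st$Gamma)[rho_names]
  objective <- function(l) {
    sum((st$stat[rho_names] - l[pairs[1, ]] * l[pairs[2, ]])^2 / w)
  }
  l_hat <- unname(f$standardized_loadings)
  lt_true <- p$loadings * sqrt(p$factor_variance)
  l_true <- lt_true / sqrt(1 + lt_true^2)
  expect_lte(objective(l_hat), objective(unname(l_true)) + 1e-10)
})

test_that("RMSEA follows the population-discrepancy formula", {
  expect_equal(rmsea(3, 5, 100), 0)        # T below df truncates to zero
  expect_equal(rmsea(10, 5, 100), sqrt(1 / 100))
  Ts <- seq(0, 50, by = 5)
  vals <- sapply(Ts, rmsea, df = 5, n = 200)
  expect_true(all(diff(vals) >= 0))
  expect_error(rmsea(1, 0, 10), "positive")
})

test_that("empty categories are collapsed and flagged", {
  set.seed(30)
  d <- data.frame(y1 = sample(c(1, 2, 4), 400, TRUE),
                  y2 = sample(1:4, 400, TRUE),
                  y3 = sample(1:4, 400, TRUE))
  sp <- grm_spec(paste0("y", 1:3), n_categories = 4)
  st <- estimate_polychoric(d, sp)
  expect_equal(unname(st$collapsed["y1"]), 1L)
  expect_equal(length(st$tau$y1), 2)       # 3 observed categories
  expect_equal(unname(st$category_map$y1), c(1L, 2L, 2L, 3L))
})

test_that("mixed ordinal/numeric models fit with polyserial statistics", {
  set.seed(31)
  pm <- grm_parameters(c(y1 = 1, y2 = 0.8, z1 = 0.9, z2 = 1.2),
                       thresholds = list(y1 = c(0, 0.8), y2 = c(-0.5, 0.7)),
                       intercepts = c(z1 = 1, z2 = -0.5),
                       residual_variances = c(z1 = 0.7, z2 = 1.1),
                       factor_mean = 0.4, factor_variance = 0.9)
  eta <- rnorm(20000, 0.4, sqrt(0.9))
  d <- simulate_responses(pm, eta)
  sp <- grm_spec(c("y1", "y2", "z1", "z2"), n_categories = c(3, 3, NA, NA),
                 kind = c("ordinal", "ordinal", "numeric", "numeric"))
  f <- fit_wls(d, sp)
  expect_true(f$converged)
  est <- f$parameters
  expect_true(all(abs(est$loadings - pm$loadings) < 0.1))
  expect_lt(abs(est$factor_variance - 0.9), 0.1)
  expect_lt(abs(est$factor_mean - 0.4), 0.1)
  expect_true(all(abs(est$residual_variances -
                        pm$residual_variances) < 0.1))
})
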