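test_that("category probabilities follow the cumulative probit form", {
  p1 <- grm_parameters(c(y1 = 1, y2 = 1, y3 = 1),
                       thresholds = list(y1 = 0, y2 = 0, y3 = 0))
  expect_equal(response_distribution(p1, "y1", 0), c(0.5, 0.5))

  # printed subgroup R1, item 1: second threshold 0.31, so the cumulative
  # probability of category >= 3 at eta = 0.31 is Phi(0) = 0.5
  pR1 <- sim1_parameters()$R1
  pmf <- response_distribution(pR1, "y1", 0.31)
  expect_equal(sum(pmf[3:7]), 0.5, tolerance = 1e-12)

  # full pmf equals the brute-force oracle for random parameter sets
  set.seed(1)
  for (r in 1:20) {
    lam <- runif(1, 0.3, 2)
    kap <- sort(rnorm(sample(2:6, 1), 0, 1.5))
    eta <- rnorm(1, 0, 2)
    p <- grm_parameters(
      loadings = c(a = 1, b = lam, c = 1),
      thresholds = list(a = c(0, 1), b = kap, c = c(-1, 1)))
    expect_equal(response_distribution(p, "b", eta),
                 pmf_oracle(lam, kap, eta), tolerance = 1e-12)
  }
})

test_that("pmf sums to one and cumulative probabilities are monotone", {
  p <- small_grm()
  etas <- seq(-4, 4, by = 0.5)
  for (eta in etas) {
    for (item in 1:3) {
      pmf <- response_distribution(p, item, eta)
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      cum <- rev(cumsum(rev(pmf)))       # P(Y >= k)
      expect_true(all(diff(cum) <= 1e-12))
      expect_equal(cum[1], 1, tolerance = 1e-12)
    }
  }
  # P(Y >= k | eta) nondecreasing in eta for positive loadings
  for (item in 1:3) {
    cumk <- sapply(etas, function(e) {
      pmf <- response_distribution(p, item, e)
      rev(cumsum(rev(pmf)))[2]
    })
    expect_true(all(diff(cumk) >= -1e-12))
  }
})

test_that("probability machinery rejects invalid input", {
  p <- small_grm()
  expect_error(response_distribution(p, "y1", Inf), "finite")
  pn <- grm_parameters(c(a = 1, b = 0.5, z = 2),
                       thresholds = list(a = 0, b = 0),
                       intercepts = c(z = 2),
                       residual_variances = c(z = 1))
  expect_error(response_distribution(pn, "z", 0), "not ordinal")
  expect_error(numeric_conditional_mean(pn, "a", 0), "not numeric")
  expect_error(grm_parameters(c(a = 1, b = 1, c = 1),
                              thresholds = list(a = c(1, 0), b = 0, c = 0)),
               "increasing")
  expect_error(grm_parameters(c(a = 1, b = 1, c = 1),
                              thresholds = list(a = 0, b = 0, c = 0),
                              factor_variance = -1),
               "positive")
})

test_that("numeric conditional mean is the affine model", {
  pn <- grm_parameters(c(a = 1, z = 0.5, w = 2),
                       thresholds = list(a = 0),
                       intercepts = c(z = 2, w = 0),
                       residual_variances = c(z = 1, w = 2))
  expect_equal(numeric_conditional_mean(pn, "z", 4), 4)   # 2 + 0.5*4
  expect_equal(numeric_conditional_mean(pn, "w", 0), 0)
  set.seed(2)
  pi_ <- rnorm(1); lam <- rnorm(1)
  p2 <- grm_parameters(c(a = 1, z = lam),
                       thresholds = list(a = c(0, 1), b = 0)[1],
                       intercepts = c(z = pi_),
                       residual_variances = c(z = 0.5),
                       validate_reference = TRUE)
  grid <- seq(-3, 3, by = 0.25)
  expect_equal(numeric_conditional_mean(p2, "z", grid), pi_ + lam * grid)
})

test_that("simulated responses match their generating distribution", {
  # degenerate pmf: all thresholds far below eta's range force the top
  # category with probability one
  pdeg <- grm_parameters(c(y1 = 1, y2 = 1, y3 = 1),
                         thresholds = list(y1 = c(-50, -40), y2 = c(-50, -40),
                                           y3 = c(40, 50)))
  set.seed(3)
  d <- simulate_responses(pdeg, rnorm(200))
  expect_true(all(d$y1 == 3) && all(d$y2 == 3))
  expect_true(all(d$y3 == 1))

  # support and law of large numbers against the pmf oracle
  p <- small_grm()
  set.seed(4)
  d <- simulate_responses(p, rep(0.7, 2e5))
  expect_true(all(unlist(d) %in% 1:3))
  for (item in 1:3) {
    freq <- tabulate(d[[item]], 3) / 2e5
    expect_equal(freq, response_distribution(p, item, 0.7), tolerance = 0.01)
  }

  # bit reproducibility under a fixed seed
  set.seed(11); a <- simulate_responses(p, rnorm(500, 0.3, 1))
  set.seed(11); b <- simulate_responses(p, rnorm(500, 0.3, 1))
  expect_identical(a, b)
})

test_that("EBM scores maximise the posterior", {
  p <- small_grm()
  set.seed(5)
  eta <- rnorm(300, p$factor_mean, sqrt(p$factor_variance))
  d <- simulate_responses(p, eta)
  sc <- ebm_scores(d, p)
  expect_true(all(sc$available))
  idx <- sample(300, 25)
  for (j in idx) {
    expect_equal(sc$score[j], ebm_grid_oracle(d[j, ], p), tolerance = 1e-4)
  }
  # mixed ordinal + numeric pattern
  pm <- grm_parameters(c(y1 = 1, y2 = 0.8, z = 0.9),
                       thresholds = list(y1 = c(0, 1), y2 = c(-0.5, 0.5)),
                       intercepts = c(z = 1),
                       residual_variances = c(z = 0.7),
                       factor_mean = 0.2, factor_variance = 1.1)
  set.seed(6)
  dm <- simulate_responses(pm, rnorm(50, 0.2, 1))
  scm <- ebm_scores(dm, pm)
  for (j in c(1, 10, 25)) {
    expect_equal(scm$score[j], ebm_grid_oracle(dm[j, ], pm),
                 tolerance = 1e-4)
  }
})

test_that("flat likelihood returns the prior mean for every pattern", {
  p0 <- grm_parameters(c(y1 = 0, y2 = 0, y3 = 0),
                       thresholds = list(y1 = c(0, 1), y2 = c(0, 1),
                                         y3 = c(0, 1)),
                       factor_mean = 0.7, factor_variance = 2,
                       validate_reference = FALSE)
  patterns <- expand.grid(y1 = 1:3, y2 = 1:3, y3 = 1:3)
  sc <- ebm_scores(patterns, p0)
  expect_true(all(abs(sc$score - 0.7) < 1e-6))
})

test_that("higher responses never decrease the score under positive loadings", {
  p <- small_grm()
  patterns <- expand.grid(y1 = 1:3, y2 = 1:3, y3 = 1:3)
  sc <- ebm_scores(patterns, p)$score
  for (item in 1:3) {
    for (k in 1:2) {
      lower <- patterns[, item] == k
      bumped <- patterns
      bumped[, item] <- bumped[, item] + ifelse(lower, 1L, 0L)
      key <- function(df) apply(df, 1, paste, collapse = "-")
      sc_b <- sc[match(key(bumped), key(patterns))]
      expect_true(all(sc_b[lower] >= sc[lower] - 1e-8))
    }
  }
})

test_that("parameter sets round-trip through JSON", {
  p <- sim1_parameters()$R7
  q <- grm_parameters_from_json(json = grm_parameters_to_json(p))
  expect_equal(q$loadings, p$loadings)
  expect_equal(q$thresholds, p$thresholds)
  expect_equal(q$factor_mean, p$factor_mean)
  expect_equal(q$factor_variance, p$factor_variance)
})
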