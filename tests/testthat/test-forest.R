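test_that("trees stop immediately when no admissible cut can exist", {
  d <- simulate_homogeneous(n = 350, seed = 61)
  tr <- grow_tree(d, sim1_spec(), c("num1", "cat1", "ord1"),
                  lv_control(min_size = 200))
  expect_equal(n_splits(tr), 0)
  expect_equal(tree_terminal_nodes(tr)[[1]]$reason, "min_size")
})

test_that("homogeneous data produce (almost) no splits across trees", {
  set.seed(62)
  zero <- integer(0)
  for (r in 1:3) {
    d <- simulate_homogeneous(n = 1200, seed = 620 + r)
    f <- lv_forest(d, sim1_spec(), c("num1", "cat1", "ord1"),
                   n_trees = 10, min_size = 200, mtry = 2, n_sim = 999,
                   seed = 63 + r)
    zero <- c(zero, f$trees$n_splits == 0)
  }
  expect_gte(mean(zero), 0.9)
})

test_that("a two-regime design yields a depth-one tree with the right cut", {
  set.seed(64)
  ok <- replicate(15, {
    bp <- simulate_breakpoint(n = 1000, cut = 50)
    d <- bp$data
    d$z <- bp$z
    tr <- grow_tree(d, bp$spec, "z",
                    lv_control(min_size = 200, mtry = 1, n_sim = 999))
    n_splits(tr) >= 1 && abs(tr$root$split$cut - 50) <= 5
  })
  expect_gte(mean(ok), 0.9)
})

test_that("validation rejects misfitting and unstable nodes", {
  set.seed(65)
  sp <- sim1_spec()
  ctl <- lv_control(min_size = 200, rmsea_cutoff = 0.05, n_sim = 999)

  # planted misfit: two orthogonal factors forced into the one-factor model
  n <- 600
  eta1 <- rnorm(n); eta2 <- rnorm(n)
  p1 <- sim1_parameters()$R1
  d_bad <- simulate_responses(p1, eta1)
  d2 <- simulate_responses(p1, eta2)
  d_bad$y4 <- d2$y4; d_bad$y5 <- d2$y5   # items 4-5 measure another factor
  d_bad$z1 <- sample(1:100, n, TRUE)
  v <- lvforest:::validate_rows(seq_len(n), d_bad, sp, "z1", ctl)
  expect_true(v$verdict %in% c("misfit", "wls_failure"))

  # planted instability confined to a covariate never used during growth:
  # a pure latent-mean shift keeps the factor structure (so the model
  # fits) but moves the intercepts along the hidden covariate
  p1b <- sim1_parameters()$R1
  z <- sample(1:200, 1000, TRUE)
  eta <- ifelse(z <= 100,
                rnorm(1000, p1b$factor_mean, sqrt(p1b$factor_variance)),
                rnorm(1000, p1b$factor_mean + 0.8,
                      sqrt(p1b$factor_variance)))
  d_unst <- simulate_responses(p1b, eta)
  d_unst$z_hidden <- z
  v2 <- lvforest:::validate_rows(seq_len(1000), d_unst, sp, "z_hidden", ctl)
  expect_equal(v2$verdict, "unstable")

  # a genuine model-compliant subgroup is retained with accurate parameters
  d1 <- simulate_sim1(seed = 66)
  covs <- c(paste0("num_", 1:10), paste0("cat_", 1:10), paste0("ord_", 1:10))
  rows <- which(d1$.subgroup == 2)
  v3 <- lvforest:::validate_rows(rows, d1, sp, covs, ctl)
  expect_equal(v3$verdict, "relevant")
  p2 <- sim1_parameters()$R2
  lt_true <- p2$loadings * sqrt(p2$factor_variance)
  l_true <- lt_true / sqrt(1 + lt_true^2)
  expect_true(all(abs(v3$wls$standardized_loadings - l_true) < 0.15))
  expect_lt(abs(v3$wls$parameters$factor_mean - p2$factor_mean), 0.15)
})

test_that("aggregation averages subgroup scores and tracks coverage", {
  d <- simulate_homogeneous(n = 1000, seed = 67)
  sp <- sim1_spec()
  f <- lv_forest(d, sp, c("num1", "cat1", "ord1"),
                 n_trees = 2, min_size = 200, n_sim = 999, seed = 68)
  expect_true(lvforest:::forest_invariants_ok(f))
  cov <- score_coverage(f)
  expect_equal(cov$nonconvergence_rate,
               mean(f$scores$n_subgroups == 0))
  # rows covered by exactly one subgroup carry that subgroup's score
  one <- which(f$scores$n_subgroups == 1)
  if (length(one)) {
    sg_scores <- rep(NA_real_, 1000)
    hits <- rep(0L, 1000)
    for (sg in f$subgroup_details) {
      sg_scores[sg$scores$.row] <- sg$scores$score
      hits[sg$scores$.row] <- hits[sg$scores$.row] + 1L
    }
    j <- one[hits[one] == 1]
    expect_equal(f$scores$score[j], sg_scores[j])
  }
})

test_that("the forest is deterministic under a fixed seed", {
  d <- simulate_homogeneous(n = 900, seed = 69)
  sp <- sim1_spec()
  covs <- c("num1", "cat1", "ord1")
  f1 <- lv_forest(d, sp, covs, n_trees = 3, min_size = 200, n_sim = 999,
                  seed = 70)
  f2 <- lv_forest(d, sp, covs, n_trees = 3, min_size = 200, n_sim = 999,
                  seed = 70)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$subgroups, f2$subgroups)
  expect_identical(f1$tree_log, f2$tree_log)
})

test_that("identical trees without resampling aggregate to the single tree", {
  d <- simulate_homogeneous(n = 800, seed = 71)
  sp <- sim1_spec()
  covs <- c("num1", "cat1", "ord1")
  f <- lv_forest(d, sp, covs, n_trees = 3, min_size = 200, mtry = 3,
                 n_sim = 999, seed = 72, resample = FALSE)
  if (nrow(f$subgroups) >= 2) {
    # every tree found the same subgroups, so averaging leaves scores as-is
    first <- f$subgroup_details[[1]]$scores
    expect_equal(f$scores$score[first$.row], first$score)
  }
  expect_true(all(f$trees$n_splits == f$trees$n_splits[1]))
})

test_that("every stored subgroup satisfies the retention invariants", {
  d <- simulate_sim1(seed = 73)
  sp <- sim1_spec()
  covs <- c(paste0("num_", 1:10), paste0("cat_", 1:10), paste0("ord_", 1:10))
  # force qualifying nodes cheaply: validate two true subgroups directly
  ctl <- lv_control(min_size = 200, rmsea_cutoff = 0.05, n_sim = 999)
  for (h in c(3, 8)) {
    v <- lvforest:::validate_rows(which(d$.subgroup == h), d, sp, covs, ctl)
    if (v$verdict == "relevant") {
      expect_lte(v$wls$rmsea, ctl$rmsea_cutoff)
      expect_gt(min(v$stability$p_value), ctl$alpha / length(covs))
      expect_true(all(is.finite(v$scores$score)))
    }
  }
})
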