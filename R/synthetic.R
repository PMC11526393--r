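# Synthetic study designs with known latent scores and subgroup structure.
# Design A ("sim1"): 10 heterogeneous subgroups x 500 rows, 5 ordinal items
# with 7 categories, 30 partitioning covariates with overlapping rules.
# Design B ("sim2"): 3 subgroups x 500 rows, 8 items x 5 categories,
# 6 covariates. Design C ("sim3"): homogeneous data, covariates pure noise.

# Threshold matrices (rows: boundaries 1..6, cols: items 1..5) and
# discrimination / latent-moment table for the 10 subgroups of design A.
sim1_thresholds <- list(
  R1 = cbind(c(0.00, 0.31, 0.90, 1.20, 1.47, 1.96),
             c(1.54, 1.73, 2.08, 2.40, 2.51, 2.76),
             c(0.27, 0.79, 0.86, 1.21, 1.31, 1.69),
             c(-0.45, 0.13, 0.42, 0.84, 1.20, 1.37),
             c(-1.24, -0.74, -0.09, 0.35, 1.13, 1.55)),
  R2 = cbind(c(0.00, 0.25, 0.85, 1.20, 1.49, 2.00),
             c(1.06, 1.69, 1.98, 2.24, 2.51, 3.25),
             c(-0.43, -0.03, 0.11, 0.37, 0.69, 0.80),
             c(-1.03, -0.40, 0.18, 0.94, 1.31, 1.80),
             c(-0.14, 0.20, 0.40, 0.98, 1.29, 1.73)),
  R3 = cbind(c(0.00, 0.56, 1.11, 1.74, 1.91, 2.59),
             c(0.60, 1.22, 1.80, 2.15, 2.85, 3.43),
             c(0.37, 0.78, 0.96, 1.30, 1.53, 1.92),
             c(1.94, 2.16, 2.30, 2.54, 2.70, 2.95),
             c(0.78, 1.27, 1.69, 2.34, 3.03, 3.63)),
  R4 = cbind(c(0.00, 0.33, 0.54, 1.07, 1.41, 1.77),
             c(-1.02, -0.49, -0.19, 0.38, 0.59, 1.19),
             c(-0.43, -0.22, 0.13, 0.76, 1.08, 1.52),
             c(0.33, 0.56, 0.84, 1.17, 1.34, 1.54),
             c(0.30, 0.71, 1.23, 1.56, 1.85, 2.17)),
  R5 = cbind(c(0.00, 0.32, 0.71, 1.14, 1.38, 1.91),
             c(-1.85, -1.24, -0.99, -0.33, 0.30, 1.00),
             c(1.45, 1.76, 1.96, 2.12, 2.22, 2.49),
             c(-0.13, 0.30, 0.83, 1.27, 1.68, 2.17),
             c(0.44, 1.00, 1.65, 2.14, 2.50, 3.21)),
  R6 = cbind(c(0.00, 0.75, 1.34, 2.06, 2.33, 2.95),
             c(1.50, 1.94, 2.06, 2.34, 2.47, 2.70),
             c(-0.17, 0.43, 0.92, 1.47, 1.68, 2.17),
             c(-1.56, -1.15, -0.58, 0.09, 0.73, 1.49),
             c(-0.17, 0.10, 0.70, 1.66, 2.07, 2.78)),
  R7 = cbind(c(0.00, 0.83, 1.49, 1.95, 2.46, 2.80),
             c(0.99, 1.96, 2.65, 3.73, 4.33, 5.34),
             c(1.98, 2.43, 2.52, 2.68, 2.94, 3.08),
             c(-1.86, -0.68, -0.19, 0.23, 0.84, 1.43),
             c(2.66, 3.89, 4.22, 5.14, 5.48, 6.04)),
  R8 = cbind(c(0.00, 0.64, 1.03, 1.45, 1.87, 2.45),
             c(0.20, 1.44, 1.63, 2.33, 3.16, 4.04),
             c(-1.69, -1.23, -0.54, 0.23, 0.62, 1.48),
             c(1.54, 1.98, 2.12, 2.37, 2.47, 2.64),
             c(0.00, 0.71, 1.32, 1.84, 2.25, 2.76)),
  R9 = cbind(c(0.00, 0.52, 0.78, 1.16, 1.54, 2.08),
             c(-0.94, -0.89, -0.71, -0.58, -0.41, -0.17),
             c(0.99, 1.76, 1.93, 2.60, 3.30, 3.60),
             c(-0.93, -0.63, -0.07, 0.34, 0.94, 1.69),
             c(-1.39, -0.74, -0.30, 0.50, 0.77, 1.63)),
  R10 = cbind(c(0.00, 0.64, 0.96, 1.46, 1.84, 2.09),
              c(1.28, 1.51, 1.81, 2.00, 2.30, 2.62),
              c(1.52, 2.01, 2.37, 3.01, 3.40, 4.17),
              c(0.51, 1.45, 1.77, 2.22, 2.54, 3.27),
              c(-0.91, 0.22, 0.60, 1.47, 2.01, 2.43))
)

# columns: Var(eta), E(eta), lambda_2..lambda_5 (lambda_1 fixed to 1)
sim1_moments <- rbind(
  R1  = c(0.66, 0.99, 0.67, 0.57, 0.80, 1.47),
  R2  = c(0.67, 0.95, 0.80, 0.58, 1.36, 0.89),
  R3  = c(1.13, 1.21, 1.20, 0.48, 0.37, 1.17),
  R4  = c(0.68, 0.77, 1.12, 1.12, 0.66, 0.97),
  R5  = c(0.54, 0.80, 1.51, 0.50, 1.54, 1.33),
  R6  = c(1.04, 1.76, 0.39, 0.90, 1.00, 1.19),
  R7  = c(1.15, 1.67, 1.46, 0.39, 1.23, 1.21),
  R8  = c(0.68, 1.21, 1.57, 1.46, 0.52, 1.36),
  R9  = c(0.54, 1.03, 0.40, 1.44, 1.32, 1.51),
  R10 = c(0.70, 1.25, 0.74, 1.30, 1.21, 1.50)
)

#' Generating parameter sets of the heterogeneous study design
#'
#' Returns the 10 subgroup parameter sets of the built-in heterogeneous
#' design (design "sim1"): 5 ordinal items with 7 categories, probit-scale
#' thresholds, item-1 loading fixed to 1, and subgroup-specific latent
#' means and variances.
#'
#' @return A named list of 10 [grm_parameters] objects (`R1`..`R10`).
#' @export
sim1_parameters <- function() {
  items <- paste0("y", 1:5)
  out <- lapply(rownames(sim1_moments), function(h) {
    mom <- sim1_moments[h, ]
    kap <- sim1_thresholds[[h]]
    grm_parameters(
      loadings = stats::setNames(c(1, mom[3:6]), items),
      thresholds = stats::setNames(
        lapply(1:5, function(i) kap[, i]), items),
      factor_mean = mom[2], factor_variance = mom[1],
      reference_item = 1L
    )
  })
  names(out) <- rownames(sim1_moments)
  out
}

#' @rdname sim1_parameters
#' @return `sim1_spec()`: the matching [grm_spec] (5 items, 7 categories).
#' @export
sim1_spec <- function() grm_spec(paste0("y", 1:5), n_categories = 7)

# Simulate one subgroup's responses at its own parameters.
simulate_subgroup <- function(params, n) {
  eta <- stats::rnorm(n, params$factor_mean, sqrt(params$factor_variance))
  list(eta = eta, responses = simulate_responses(params, eta))
}

# Covariate block for overlapping-rule designs: each subgroup h owns a set
# of covariates; rows of h are clamped into the rule region, other rows are
# uniform except that the "decoy" rows falling in the clamped num/cat range
# get their ord pushed below the rule threshold, so the conjunction rule
# identifies the subgroup exactly.
overlap_covariates <- function(group, H, with_cat = TRUE) {
  n <- length(group)
  out <- list()
  for (h in seq_len(H)) {
    in_h <- group == h
    num <- ifelse(in_h, sample(1:50, n, replace = TRUE),
                  sample(1:200, n, replace = TRUE))
    if (with_cat) {
      cat_ <- ifelse(in_h, sample(c(1L, 3L, 5L), n, replace = TRUE),
                     sample(1:5, n, replace = TRUE))
    }
    ord <- ifelse(in_h, sample(4:5, n, replace = TRUE),
                  sample(1:5, n, replace = TRUE))
    decoy <- !in_h & num <= 50 & (if (with_cat) cat_ %in% c(1, 3, 5) else TRUE)
    ord[decoy] <- sample(1:3, sum(decoy), replace = TRUE)
    out[[paste0("num_", h)]] <- as.integer(num)
    if (with_cat) out[[paste0("cat_", h)]] <- factor(cat_, levels = 1:5)
    out[[paste0("ord_", h)]] <- factor(ord, levels = 1:5, ordered = TRUE)
  }
  tibble::as_tibble(out)
}

#' Simulate the heterogeneous 10-subgroup study design
#'
#' Ten model-compliant subgroups of `n_per_group` rows each, generated from
#' the printed parameter sets ([sim1_parameters()]): per-subgroup latent
#' scores \eqn{\eta \sim N(E_h, Var_h)}, 5 ordinal items with 7 categories,
#' and 30 partitioning covariates (`num_h` in 1..200, `cat_h` and `ord_h`
#' on 5-point scales). Rows of subgroup h are clamped to
#' `num_h <= 50, cat_h in {1,3,5}, ord_h >= 4`; rows of other subgroups
#' falling inside the clamped `num`/`cat` region get `ord_h <= 3`, so the
#' three-condition rule recovers subgroup h exactly.
#'
#' @param n_per_group Rows per subgroup (default 500).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A tibble with item columns `y1..y5`, covariates
#'   `num_1..num_10`, `cat_1..cat_10` (factor), `ord_1..ord_10` (ordered),
#'   and truth columns `.eta` (generating latent score) and `.subgroup`.
#'   Attribute `"parameters"` holds the generating parameter list.
#' @export
simulate_sim1 <- function(n_per_group = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pars <- sim1_parameters()
  H <- length(pars)
  group <- rep(seq_len(H), each = n_per_group)
  sims <- lapply(pars, simulate_subgroup, n = n_per_group)
  responses <- dplyr::bind_rows(lapply(sims, `[[`, "responses"))
  eta <- unlist(lapply(sims, `[[`, "eta"), use.names = FALSE)
  cov <- overlap_covariates(group, H, with_cat = TRUE)
  out <- dplyr::bind_cols(responses, cov)
  out$.eta <- eta
  out$.subgroup <- group
  attr(out, "parameters") <- pars
  out
}

#' Simulate the 3-subgroup 8-item design
#'
#' Three model-compliant subgroups of `n_per_group` rows, 8 ordinal items
#' with 5 categories, and 6 covariates (`num_h`, `ord_h` per subgroup) with
#' the two-condition rule `num_h <= 50 & ord_h >= 4` (plus the cross-group
#' `ord` clamping that makes the rule exact). Generating parameters are
#' drawn per subgroup by `param_sampler`.
#'
#' @param n_per_group Rows per subgroup (default 500).
#' @param param_sampler Function `(n_items, n_categories)` returning a
#'   [grm_parameters] object; the default draws loadings from U(0.4, 1.6)
#'   (item 1 fixed to 1), thresholds as sorted N(0, sd 1.5) draws (item 1's
#'   first threshold shifted to 0), Var(eta) from U(0.5, 1.5) and E(eta)
#'   from U(-0.5, 1.5).
#' @param seed Optional integer seed.
#' @return A tibble like [simulate_sim1()] with items `y1..y8` and
#'   covariates `num_1..num_3`, `ord_1..ord_3`.
#' @export
simulate_sim2 <- function(n_per_group = 500,
                          param_sampler = default_param_sampler,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- 3
  pars <- lapply(seq_len(H), function(h) param_sampler(8L, 5L))
  names(pars) <- paste0("R", seq_len(H))
  group <- rep(seq_len(H), each = n_per_group)
  sims <- lapply(pars, simulate_subgroup, n = n_per_group)
  responses <- dplyr::bind_rows(lapply(sims, `[[`, "responses"))
  eta <- unlist(lapply(sims, `[[`, "eta"), use.names = FALSE)
  cov <- overlap_covariates(group, H, with_cat = FALSE)
  out <- dplyr::bind_cols(responses, cov)
  out$.eta <- eta
  out$.subgroup <- group
  attr(out, "parameters") <- pars
  out
}

#' @rdname simulate_sim2
#' @param n_items,n_categories Model size for the default sampler.
#' @export
default_param_sampler <- function(n_items = 8L, n_categories = 5L) {
  items <- paste0("y", seq_len(n_items))
  lam <- c(1, stats::runif(n_items - 1, 0.4, 1.6))
  thr <- lapply(seq_len(n_items), function(i) {
    k <- sort(stats::rnorm(n_categories - 1, 0, 1.5))
    if (i == 1) k <- k - k[1]
    k
  })
  grm_parameters(
    loadings = stats::setNames(lam, items),
    thresholds = stats::setNames(thr, items),
    factor_mean = stats::runif(1, -0.5, 1.5),
    factor_variance = stats::runif(1, 0.5, 1.5)
  )
}

#' Simulate a homogeneous data set (no parameter heterogeneity)
#'
#' One parameter set for the whole sample; the three covariates (`num1`,
#' `cat1`, `ord1`) are random noise, independent of the responses and of
#' the latent score. Under this design a correctly sized instability test
#' should find nothing, and the forest should reduce to the naive model.
#'
#' @param params A [grm_parameters] object (default: the first
#'   heterogeneous-design parameter set).
#' @param n Number of rows (default 5000).
#' @param seed Optional integer seed.
#' @return A tibble with item columns, `num1`, `cat1`, `ord1`, `.eta` and
#'   `.subgroup` (all 1).
#' @export
simulate_homogeneous <- function(params = sim1_parameters()[[1]], n = 5000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_subgroup(params, n)
  out <- sim$responses
  out$num1 <- sample(1:200, n, replace = TRUE)
  out$cat1 <- factor(sample(1:5, n, replace = TRUE), levels = 1:5)
  out$ord1 <- factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                     ordered = TRUE)
  out$.eta <- sim$eta
  out$.subgroup <- 1L
  attr(out, "parameters") <- list(R1 = params)
  out
}

#' The exact covariate rule of a designed subgroup
#'
#' Returns the logical row filter `num_h <= 50 & cat_h in {1,3,5} &
#' ord_h >= 4` (the `cat` clause is dropped for designs without `cat`
#' covariates) used to verify that designed subgroups are exactly
#' recoverable from the covariates.
#' @param data A simulated dataset.
#' @param h Subgroup index.
#' @return Logical vector over rows.
#' @export
sim_design_rule <- function(data, h) {
  num <- data[[paste0("num_", h)]]
  ordv <- as.integer(as.character(data[[paste0("ord_", h)]]))
  keep <- num <= 50 & ordv >= 4
  catnm <- paste0("cat_", h)
  if (catnm %in% names(data)) {
    catv <- as.integer(as.character(data[[catnm]]))
    keep <- keep & catv %in% c(1, 3, 5)
  }
  keep
}
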