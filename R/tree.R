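# Score-based model trees: recursive partitioning driven by M-fluctuation
# instability tests, with the split point chosen to maximise the
# score-based statistic. The node model is the normal-theory ML fit
# (fast, gives casewise scores); terminal nodes are re-fitted with the
# limited-information WLS estimator at validation/scoring time.

#' Hyperparameters of trees and forests
#'
#' @param n_trees Number of trees in the ensemble.
#' @param min_size Minimum sample size of a node (both children of any
#'   split, and any subgroup used for scoring).
#' @param mtry Number of partitioning variables sampled at each node
#'   (random split selection); capped at the number of covariates.
#' @param alpha Family-wise significance level for the Bonferroni-corrected
#'   instability tests.
#' @param rmsea_cutoff Maximum RMSEA for a terminal-node model to qualify
#'   as a relevant subgroup.
#' @param n_sim Replicates for simulated Brownian-bridge critical values.
#' @param trim supLM trimming window (fraction at each end).
#' @param sample_fraction Fraction of rows subsampled (without
#'   replacement) for each tree. Subsampling — rather than a
#'   with-replacement bootstrap — keeps the rows of a tree's sample
#'   distinct, which the ordered cumulative score process requires: with
#'   duplicated rows the process is locally over-dispersed relative to its
#'   Brownian-bridge null and the instability tests reject under
#'   homogeneity. The default 0.9 keeps most of the sample per tree (so a
#'   tree can still reach the depth a size-n bootstrap tree would, where
#'   `min_size` counts duplicated rows) while random subsampling plus
#'   per-node random split selection provides the ensemble diversity.
#' @return A list of class `lv_control`.
#' @export
lv_control <- function(n_trees = 100, min_size = 200, mtry = 2,
                       alpha = 0.05, rmsea_cutoff = 0.05,
                       n_sim = 1999, trim = 0.1, sample_fraction = 0.9) {
  assert_that(n_trees >= 1, "n_trees must be at least 1")
  assert_that(min_size >= 10, "min_size must be at least 10")
  assert_that(mtry >= 1, "mtry must be at least 1")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(rmsea_cutoff > 0, "rmsea_cutoff must be positive")
  assert_that(n_sim >= 199, "n_sim too small for usable p-values")
  assert_that(sample_fraction > 0 && sample_fraction <= 1,
              "sample_fraction must be in (0, 1]")
  structure(list(n_trees = as.integer(n_trees),
                 min_size = as.integer(min_size), mtry = as.integer(mtry),
                 alpha = alpha, rmsea_cutoff = rmsea_cutoff,
                 n_sim = as.integer(n_sim), trim = trim,
                 sample_fraction = sample_fraction),
            class = "lv_control")
}

# ---- rules -----------------------------------------------------------------

new_condition <- function(covariate, kind, op, value, label_value = value) {
  list(covariate = covariate, kind = kind, op = op, value = value,
       label_value = label_value)
}

condition_matches <- function(cond, data) {
  x <- data[[cond$covariate]]
  v <- if (cond$kind %in% c("numeric", "ordinal")) covariate_codes(x) else
    as.character(x)
  switch(cond$op,
         le = v <= cond$value,
         gt = v > cond$value,
         "in" = v %in% cond$value,
         notin = !(v %in% cond$value),
         stop("unknown condition op: ", cond$op))
}

#' Evaluate a subgroup rule on a data set
#'
#' A rule is a conjunction of atomic conditions on covariates
#' (`Z <= c` / `Z > c` for numeric and ordinal, `Z in S` / `Z not in S`
#' for categorical). The empty rule matches every row.
#'
#' @param rule List of conditions (as stored in tree nodes and subgroups).
#' @param data Data frame with the covariate columns.
#' @return Logical vector over rows.
#' @export
rule_matches <- function(rule, data) {
  out <- rep(TRUE, nrow(data))
  for (cond in rule) out <- out & condition_matches(cond, data)
  out
}

#' @rdname rule_matches
#' @export
rule_label <- function(rule) {
  if (!length(rule)) return("<all rows>")
  lab <- vapply(rule, function(cond) {
    val <- cond$label_value
    switch(cond$op,
           le = paste0(cond$covariate, " <= ", val),
           gt = paste0(cond$covariate, " > ", val),
           "in" = paste0(cond$covariate, " in {",
                         paste(val, collapse = ","), "}"),
           notin = paste0(cond$covariate, " not in {",
                          paste(val, collapse = ","), "}"))
  }, character(1))
  paste(lab, collapse = " & ")
}

split_conditions <- function(split, covariate_values) {
  if (split$kind %in% c("numeric", "ordinal")) {
    cutcode <- if (split$kind == "ordinal" && is.character(split$cut)) {
      match(split$cut, levels(covariate_values))
    } else as.numeric(split$cut)
    list(
      left = new_condition(split$covariate, split$kind, "le", cutcode,
                           label_value = split$cut),
      right = new_condition(split$covariate, split$kind, "gt", cutcode,
                            label_value = split$cut)
    )
  } else {
    list(
      left = new_condition(split$covariate, "categorical", "in",
                           split$levels),
      right = new_condition(split$covariate, "categorical", "notin",
                            split$levels)
    )
  }
}

# ---- tree growth -----------------------------------------------------------

#' Grow a score-based model tree
#'
#' Recursive procedure: fit the single-factor model by ML, draw `mtry`
#' candidate partitioning variables, test each for parameter instability
#' with the generalized M-fluctuation test, stop if none is significant at
#' the Bonferroni-corrected level (or the node is too small to split, or
#' the ML fit fails); otherwise split at the score-maximising cut point of
#' the most unstable covariate and recurse into both children.
#'
#' @param data Data frame (for a bagged tree: the bootstrap sample).
#' @param spec A [grm_spec].
#' @param covariates Character vector of partitioning variable column
#'   names; kinds are inferred from column classes (`ordered` = ordinal,
#'   `factor` = categorical, otherwise numeric).
#' @param control An [lv_control] list.
#' @return An object of class `lv_tree` (root node plus metadata).
#' @export
grow_tree <- function(data, spec, covariates, control = lv_control()) {
  assert_that(all(covariates %in% names(data)),
              "covariates missing from data")
  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L
  root <- grow_node(data, spec, covariates, control,
                    rows = seq_len(nrow(data)), rule = list(),
                    depth = 0L, counter = counter)
  structure(list(root = root, spec = spec, covariates = covariates,
                 control = control, n = nrow(data)),
            class = "lv_tree")
}

grow_node <- function(data, spec, covariates, control, rows, rule, depth,
                      counter) {
  id <- counter$next_id
  counter$next_id <- id + 1L
  node <- list(id = id, depth = depth, n = length(rows), rows = rows,
               rule = rule, terminal = TRUE, reason = NA_character_,
               tests = NULL, split = NULL, children = NULL,
               ml_ok = FALSE)
  d <- data[rows, , drop = FALSE]
  fit <- tryCatch(fit_ml_cfa(d, spec), error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged)) {
    node$reason <- "ml_failure"
    return(node)
  }
  node$ml_ok <- TRUE
  if (isTRUE(fit$heywood)) {
    node$reason <- "heywood"
    return(node)
  }
  if (length(rows) < 2L * control$min_size) {
    node$reason <- "min_size"
    return(node)
  }
  sc <- casewise_scores(fit, d)
  mtry <- min(control$mtry, length(covariates))
  cand <- if (mtry < length(covariates)) sample(covariates, mtry)
          else covariates
  tests <- dplyr::bind_rows(lapply(cand, function(nm) {
    test_instability(sc, d[[nm]], n_sim = control$n_sim,
                     trim = control$trim, name = nm)
  }))
  node$tests <- tests
  sel <- bonferroni_select(tests, control$alpha)
  if (is.null(sel)) {
    node$reason <- "stable"
    return(node)
  }
  zsel <- d[[sel$covariate]]
  sp <- best_split(sc, zsel, min_size = control$min_size,
                   name = sel$covariate)
  if (is.null(sp)) {
    node$reason <- "no_admissible_cut"
    return(node)
  }
  conds <- split_conditions(sp, zsel)
  left_in <- condition_matches(conds$left, d)
  node$terminal <- FALSE
  node$reason <- NA_character_
  node$split <- sp
  node$children <- list(
    left = grow_node(data, spec, covariates, control,
                     rows = rows[left_in], rule = c(rule, list(conds$left)),
                     depth = depth + 1L, counter = counter),
    right = grow_node(data, spec, covariates, control,
                      rows = rows[!left_in],
                      rule = c(rule, list(conds$right)),
                      depth = depth + 1L, counter = counter)
  )
  node
}

# Collect nodes (as a flat list) satisfying a predicate.
collect_nodes <- function(node, pred = function(nd) TRUE) {
  out <- if (pred(node)) list(node) else list()
  if (!is.null(node$children)) {
    out <- c(out, collect_nodes(node$children$left, pred),
             collect_nodes(node$children$right, pred))
  }
  out
}

#' Terminal nodes of a tree
#' @param tree An `lv_tree`.
#' @return List of terminal node records (id, rule, n, reason).
#' @export
tree_terminal_nodes <- function(tree) {
  collect_nodes(tree$root, function(nd) isTRUE(nd$terminal))
}

#' @export
print.lv_tree <- function(x, ...) {
  terms <- tree_terminal_nodes(x)
  cat("<lv_tree> n =", x$n, ";", length(terms), "terminal nodes,",
      n_splits(x), "splits\n")
  for (nd in terms) {
    cat(sprintf("  node %d (n=%d): %s [%s]\n", nd$id, nd$n,
                rule_label(nd$rule), nd$reason %||% "split"))
  }
  invisible(x)
}

n_splits <- function(tree) {
  length(collect_nodes(tree$root, function(nd) !isTRUE(nd$terminal)))
}

#' @exportS3Method generics::tidy
tidy.lv_tree <- function(x, ...) {
  nodes <- collect_nodes(x$root)
  dplyr::bind_rows(lapply(nodes, function(nd) {
    tibble::tibble(
      node = nd$id, depth = nd$depth, n = nd$n,
      terminal = nd$terminal, reason = nd$reason,
      rule = rule_label(nd$rule),
      split_covariate = if (is.null(nd$split)) NA_character_
        else nd$split$covariate,
      split_statistic = if (is.null(nd$split)) NA_real_
        else nd$split$statistic
    )
  }))
}

#' Terminal-node latent scores of a single tree
#'
#' The single-tree comparator: re-fits every terminal node with the WLS
#' estimator on its own rows and estimates EBM scores for those rows, with
#' no RMSEA or stability screening. Rows in terminals whose WLS fit fails
#' stay unavailable.
#'
#' @param tree An `lv_tree` grown on `data`.
#' @param data The data the tree was grown on.
#' @return Tibble `.row`, `score`, `available`, `node`.
#' @export
semtree_scores <- function(tree, data) {
  n <- nrow(data)
  score <- rep(NA_real_, n)
  nodeid <- rep(NA_integer_, n)
  for (nd in tree_terminal_nodes(tree)) {
    rows <- which(rule_matches(nd$rule, data))
    if (length(rows) < 3 * nrow(tree$spec)) next
    fit <- tryCatch(fit_wls(data[rows, , drop = FALSE], tree$spec),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) next
    sc <- ebm_scores_wls(data[rows, , drop = FALSE], fit)
    score[rows] <- sc$score
    nodeid[rows] <- nd$id
  }
  tibble::tibble(.row = seq_len(n), score = score,
                 available = is.finite(score), node = nodeid)
}
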