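# File I/O, run configuration, and the end-to-end pipeline.

#' Load and validate an item-response dataset from CSV
#'
#' Reads a comma-separated file (UTF-8, header required), checks that all
#' declared item and covariate columns are present, coerces covariates to
#' their declared kinds, validates ordinal category codes against the
#' declared ranges (1-based integer codes), and drops rows with missing
#' values in any declared column (logged via `message()`).
#'
#' @param path CSV file path.
#' @param spec A [grm_spec] for the item columns.
#' @param covariates Named character vector or list: covariate column name
#'   -> kind (`"numeric"`, `"ordinal"`, `"categorical"`); or a plain
#'   character vector of names (kinds inferred from the parsed columns).
#' @return A tibble with attribute `"dropped"` (number of dropped rows);
#'   ordinal/categorical covariates are returned as (ordered) factors.
#' @export
load_dataset <- function(path, spec, covariates = character()) {
  assert_that(file.exists(path), paste("no such file:", path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cov_names <- if (is.null(names(covariates)) || !length(covariates)) {
    as.character(covariates)
  } else names(covariates)
  missing_cols <- setdiff(c(spec$item, cov_names), names(raw))
  assert_that(length(missing_cols) == 0,
              paste("missing declared columns:",
                    paste(missing_cols, collapse = ", ")))
  keep_cols <- c(spec$item, cov_names)
  d <- raw[, keep_cols, drop = FALSE]
  complete <- stats::complete.cases(d) &
    !apply(d == "", 1, any, simplify = TRUE)
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(dropped, " row(s) dropped for missing declared columns")
  }
  d <- d[complete, , drop = FALSE]
  # validate item codes (response_matrix errors with row/column identity)
  invisible(response_matrix(d, spec))
  if (length(cov_names) && !is.null(names(covariates))) {
    for (nm in cov_names) {
      kind <- covariates[[nm]]
      d[[nm]] <- switch(kind,
        numeric = as.numeric(d[[nm]]),
        ordinal = factor(d[[nm]], levels = sort(unique(d[[nm]])),
                         ordered = TRUE),
        categorical = factor(d[[nm]]),
        stop("unknown covariate kind: ", kind))
    }
  }
  out <- tibble::as_tibble(d)
  attr(out, "dropped") <- dropped
  out
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognised keys: `data` (CSV path), `items` (list: `names`,
#' `n_categories`, optional `kinds`, `reference_item`), `covariates`
#' (mapping name -> kind), `hyperparameters` (any [lv_control()]
#' argument), `seed` (integer, required), `out_dir`, `verbose`. Unknown
#' keys — anywhere, including inside `hyperparameters` — are errors, so
#' typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A named list of class `lv_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("data", "items", "covariates", "hyperparameters", "seed",
             "out_dir", "verbose")
  unknown <- setdiff(names(cfg), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  known_items <- c("names", "n_categories", "kinds", "reference_item")
  unknown <- setdiff(names(cfg$items), known_items)
  assert_that(length(unknown) == 0,
              paste("unknown items keys:", paste(unknown, collapse = ", ")))
  hp <- cfg$hyperparameters %||% list()
  unknown <- setdiff(names(hp), names(formals(lv_control)))
  assert_that(length(unknown) == 0,
              paste("unknown hyperparameters:",
                    paste(unknown, collapse = ", ")))
  assert_that(!is.null(cfg$seed), "config must set a seed")
  assert_that(!is.null(cfg$data), "config must name a data file")
  assert_that(!is.null(cfg$items$names), "config must list item names")
  structure(cfg, class = "lv_run_config")
}

config_spec <- function(cfg) {
  grm_spec(cfg$items$names,
           n_categories = cfg$items$n_categories,
           kind = cfg$items$kinds %||% NULL,
           reference_item = cfg$items$reference_item %||% 1L)
}

#' Run the full pipeline from a configuration
#'
#' Loads the dataset, runs [lv_forest()], and writes `scores.csv` (row id,
#' aggregated score, number of covering subgroups, availability),
#' `subgroups.json` (rules as typed conditions, fits, verdict summaries),
#' and `manifest.json` (configuration, seed, package version) into
#' `out_dir`. Completion with zero relevant subgroups is a warning, not an
#' error.
#'
#' @param config An `lv_run_config` (from [read_run_config()]) or a path
#'   to one.
#' @return The `lv_forest` result, invisibly; attribute `"files"` lists
#'   the written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  spec <- config_spec(config)
  cov_kinds <- unlist(config$covariates) %||% character()
  data <- load_dataset(config$data, spec, cov_kinds)
  control <- do.call(lv_control, as.list(config$hyperparameters %||% list()))
  forest <- lv_forest(data, spec, names(cov_kinds), control = control,
                      seed = config$seed,
                      verbose = isTRUE(config$verbose))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    scores = file.path(out_dir, "scores.csv"),
    subgroups = file.path(out_dir, "subgroups.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  sc <- forest$scores
  utils::write.csv(
    data.frame(row = sc$.row,
               score = ifelse(sc$available, sc$score, NA),
               n_subgroups = sc$n_subgroups,
               available = sc$available),
    files["scores"], row.names = FALSE, na = "")
  writeLines(forest_to_json(forest), files["subgroups"])
  manifest <- list(
    package = "lvforest",
    version = as.character(utils::packageVersion("lvforest")),
    seed = config$seed,
    data = config$data,
    items = config$items,
    covariates = config$covariates,
    hyperparameters = forest$control[setdiff(names(forest$control), NULL)],
    n = forest$n,
    n_relevant_subgroups = nrow(forest$subgroups),
    nonconvergence_rate = forest$nonconvergence_rate
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             files["manifest"])
  attr(forest, "files") <- files
  invisible(forest)
}

#' Serialize a forest's relevant subgroups to JSON
#'
#' Rules are stored as typed conditions (covariate, kind, op, value), so a
#' reloaded rule can be re-applied to a data set with the same covariate
#' schema; fits are stored with their parameters, chi-square, df, RMSEA
#' and sample size.
#'
#' @param forest An `lv_forest`.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
forest_to_json <- function(forest, path = NULL) {
  doc <- list(
    n = forest$n,
    n_trees = forest$control$n_trees,
    control = unclass(forest$control),
    nonconvergence_rate = forest$nonconvergence_rate,
    subgroups = lapply(forest$subgroup_details, function(sg) {
      list(
        tree = sg$tree, node = sg$node, n = sg$n,
        rule = lapply(sg$rule, function(cond) {
          cond[c("covariate", "kind", "op", "value")]
        }),
        rule_label = sg$rule_label,
        fit = list(
          T = sg$wls$T, df = sg$wls$df, rmsea = sg$wls$rmsea,
          n = sg$wls$n,
          parameters = jsonlite::fromJSON(
            grm_parameters_to_json(sg$wls$parameters))
        ),
        min_stability_p = min(sg$stability$p_value)
      )
    })
  )
  json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                        null = "null", pretty = TRUE))
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Reload serialized subgroup rules
#'
#' @param path Path to a `subgroups.json` written by [forest_to_json()].
#' @return A list with `subgroups`: each element holding `rule` (usable
#'   with [rule_matches()]), `n`, `rmsea`, and `parameters`.
#' @export
forest_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$subgroups <- lapply(doc$subgroups, function(sg) {
    sg$rule <- lapply(sg$rule, function(cond) {
      cond$value <- unlist(cond$value)
      cond$label_value <- cond$value
      cond
    })
    sg
  })
  doc
}
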