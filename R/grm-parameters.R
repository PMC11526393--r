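#' Parameter set for a single-factor graded response / factor model
#'
#' Bundles item loadings, probit-scale thresholds (ordinal items),
#' intercepts and residual variances (numeric items), and the latent
#' factor's mean and variance. The reference item's loading must be exactly
#' 1; thresholds must be strictly increasing within each item.
#'
#' The ordinal part follows the cumulative probit parameterisation
#' \eqn{P(Y_i \ge k \mid \eta) = \Phi(\lambda_i \eta - \kappa_{ik})} with a
#' unit-variance conditional probit, so parameters are on the same metric as
#' the data-generating item response model. Numeric items follow
#' \eqn{Y_i = \pi_i + \lambda_i \eta + \epsilon_i}.
#'
#' @param loadings Named numeric vector of loadings \eqn{\lambda_i}, one per
#'   item, in model order; names are item names.
#' @param thresholds Named list of strictly increasing numeric vectors
#'   \eqn{\kappa_{i,1..K_i-1}}, one entry per ordinal item.
#' @param factor_mean Latent mean \eqn{\mu_\eta}.
#' @param factor_variance Latent variance \eqn{\phi > 0}.
#' @param intercepts Named numeric vector \eqn{\pi_i} for numeric items
#'   (NULL if none).
#' @param residual_variances Named numeric vector \eqn{Var(\epsilon_i) > 0}
#'   for numeric items (NULL if none).
#' @param reference_item Index (in `loadings`) of the unit-loading item.
#' @param validate_reference Enforce the unit reference loading (default
#'   `TRUE`; disable only for deliberately degenerate parameter sets, e.g.
#'   a flat likelihood with all loadings zero).
#'
#' @return An object of class `grm_parameters`.
#' @examples
#' grm_parameters(
#'   loadings = c(y1 = 1, y2 = 0.8, y3 = 1.2),
#'   thresholds = list(y1 = c(0, 1), y2 = c(-0.5, 0.5), y3 = c(-1, 1))
#' )
#' @export
grm_parameters <- function(loadings, thresholds = list(),
                           factor_mean = 0, factor_variance = 1,
                           intercepts = NULL, residual_variances = NULL,
                           reference_item = 1L, validate_reference = TRUE) {
  assert_that(is.numeric(loadings) && !is.null(names(loadings)),
              "loadings must be a named numeric vector")
  items <- names(loadings)
  assert_that(all(names(thresholds) %in% items),
              "thresholds name items not present in loadings")
  ord_items <- names(thresholds)
  num_items <- setdiff(items, ord_items)
  if (length(num_items)) {
    assert_that(!is.null(intercepts) && !is.null(residual_variances) &&
                  all(num_items %in% names(intercepts)) &&
                  all(num_items %in% names(residual_variances)),
                "numeric items need intercepts and residual_variances")
    assert_that(all(residual_variances[num_items] > 0),
                "residual variances must be positive")
  }
  for (nm in ord_items) {
    k <- thresholds[[nm]]
    assert_that(length(k) >= 1 && all(diff(k) > 0),
                sprintf("thresholds of item '%s' must be strictly increasing", nm))
  }
  assert_that(factor_variance > 0, "factor_variance must be positive")
  if (validate_reference) {
    assert_that(abs(loadings[[reference_item]] - 1) < 1e-12,
                "the reference item's loading must be exactly 1")
  }
  structure(
    list(
      loadings = loadings,
      thresholds = thresholds,
      intercepts = intercepts,
      residual_variances = residual_variances,
      factor_mean = as.numeric(factor_mean),
      factor_variance = as.numeric(factor_variance),
      reference_item = as.integer(reference_item)
    ),
    class = "grm_parameters"
  )
}

#' @export
print.grm_parameters <- function(x, ...) {
  cat("<grm_parameters>", length(x$loadings), "items;",
      length(x$thresholds), "ordinal\n")
  cat("  factor mean", format(x$factor_mean, digits = 3),
      " variance", format(x$factor_variance, digits = 3), "\n")
  cat("  loadings:", paste(format(x$loadings, digits = 3), collapse = " "), "\n")
  invisible(x)
}

item_kind <- function(params, item) {
  nm <- item_name(params, item)
  if (nm %in% names(params$thresholds)) "ordinal" else "numeric"
}

item_name <- function(params, item) {
  if (is.character(item)) item else names(params$loadings)[item]
}

#' Serialize / deserialize parameter sets
#'
#' Parameter sets round-trip through a plain JSON document with explicit
#' field names.
#' @param params A [grm_parameters] object.
#' @param path File path; if `NULL`, `grm_parameters_to_json()` returns the
#'   JSON string.
#' @return `grm_parameters_to_json()`: the path or JSON string, invisibly;
#'   `grm_parameters_from_json()`: a [grm_parameters] object.
#' @export
grm_parameters_to_json <- function(params, path = NULL) {
  doc <- list(
    loadings = as.list(params$loadings),
    thresholds = params$thresholds,
    intercepts = if (is.null(params$intercepts)) NULL else as.list(params$intercepts),
    residual_variances = if (is.null(params$residual_variances)) NULL
      else as.list(params$residual_variances),
    factor_mean = params$factor_mean,
    factor_variance = params$factor_variance,
    reference_item = params$reference_item
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' @rdname grm_parameters_to_json
#' @param json JSON string (used when `path` is `NULL`).
#' @export
grm_parameters_from_json <- function(path = NULL, json = NULL) {
  doc <- jsonlite::fromJSON(if (is.null(path)) json else path,
                            simplifyVector = TRUE)
  grm_parameters(
    loadings = unlist(doc$loadings),
    thresholds = lapply(doc$thresholds, as.numeric),
    intercepts = if (length(doc$intercepts)) unlist(doc$intercepts) else NULL,
    residual_variances = if (length(doc$residual_variances))
      unlist(doc$residual_variances) else NULL,
    factor_mean = doc$factor_mean,
    factor_variance = doc$factor_variance,
    reference_item = doc$reference_item %||% 1L
  )
}
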