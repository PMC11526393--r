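#' Define a unidimensional graded-response / factor model
#'
#' Describes the measurement model: which columns of a data set are items,
#' whether each item is ordinal (graded) or numeric (linear), how many
#' response categories each ordinal item has, and which item anchors the
#' latent scale (its loading is fixed to 1). A single latent factor is
#' assumed throughout.
#'
#' @param items Character vector of item (column) names, in model order.
#' @param n_categories Integer vector: number of response categories per
#'   ordinal item (recycled if length 1). Ignored (may be `NA`) for numeric
#'   items. Ordinal categories are coded `1..K`.
#' @param kind Character vector, `"ordinal"` or `"numeric"` per item.
#'   Defaults to all ordinal.
#' @param reference_item Index of the item whose loading is fixed to 1
#'   (default: the first item).
#'
#' @return An object of class `grm_spec`: a tibble with columns `item`,
#'   `kind`, `n_categories`, plus attributes `reference_item` and
#'   `n_factors` (always 1).
#' @examples
#' grm_spec(paste0("y", 1:5), n_categories = 7)
#' @export
grm_spec <- function(items, n_categories = NULL, kind = NULL,
                     reference_item = 1L) {
  assert_that(is.character(items) && length(items) >= 3,
              "a model needs at least 3 items")
  assert_that(!anyDuplicated(items), "item names must be unique")
  m <- length(items)
  kind <- kind %||% rep("ordinal", m)
  if (length(kind) == 1) kind <- rep(kind, m)
  assert_that(all(kind %in% c("ordinal", "numeric")),
              "item kind must be 'ordinal' or 'numeric'")
  if (is.null(n_categories)) {
    assert_that(all(kind == "numeric"),
                "n_categories is required for ordinal items")
    n_categories <- rep(NA_integer_, m)
  }
  if (length(n_categories) == 1) n_categories <- rep(n_categories, m)
  n_categories <- as.integer(n_categories)
  n_categories[kind == "numeric"] <- NA_integer_
  assert_that(all(n_categories[kind == "ordinal"] >= 2, na.rm = FALSE),
              "every ordinal item needs at least 2 categories")
  reference_item <- as.integer(reference_item)
  assert_that(reference_item >= 1 && reference_item <= m,
              "reference_item out of range")
  out <- tibble::tibble(item = items, kind = kind,
                        n_categories = n_categories)
  attr(out, "reference_item") <- reference_item
  attr(out, "n_factors") <- 1L
  class(out) <- c("grm_spec", class(out))
  out
}

#' Derive a model spec from a data frame
#'
#' Convenience constructor: ordinal items get their category count from the
#' declared maximum (`n_categories`) or the observed maximum code.
#' @param data A data frame containing the item columns.
#' @param items Character vector of item column names.
#' @inheritParams grm_spec
#' @return A [grm_spec] object.
#' @export
grm_spec_from_data <- function(data, items, n_categories = NULL,
                               reference_item = 1L) {
  assert_that(all(items %in% names(data)), "missing item columns in data")
  kind <- vapply(items, function(nm) {
    x <- data[[nm]]
    if (is.numeric(x) && all(x == round(x), na.rm = TRUE)) "ordinal" else "numeric"
  }, character(1))
  if (is.null(n_categories)) {
    n_categories <- vapply(items, function(nm) {
      x <- data[[nm]]
      if (is.numeric(x) && all(x == round(x), na.rm = TRUE)) {
        as.integer(max(x, na.rm = TRUE))
      } else NA_integer_
    }, integer(1))
  }
  grm_spec(items, n_categories = n_categories, kind = unname(kind),
           reference_item = reference_item)
}

reference_item <- function(spec) attr(spec, "reference_item")

is_ordinal <- function(spec) spec$kind == "ordinal"

#' @export
print.grm_spec <- function(x, ...) {
  cat("<grm_spec> single-factor model,", nrow(x), "items",
      sprintf("(reference item: %s)\n", x$item[reference_item(x)]))
  NextMethod()
  invisible(x)
}

#' Extract the item response matrix declared by a spec
#'
#' Validates ordinal codes against the declared category counts.
#' @noRd
response_matrix <- function(data, spec) {
  assert_that(all(spec$item %in% names(data)),
              "data is missing declared item columns")
  y <- as.matrix(as.data.frame(data)[, spec$item, drop = FALSE])
  storage.mode(y) <- "double"
  assert_that(!anyNA(y), "item responses contain missing values")
  for (i in which(is_ordinal(spec))) {
    yi <- y[, i]
    bad <- yi < 1 | yi > spec$n_categories[i] | yi != round(yi)
    if (any(bad)) {
      stop(sprintf(
        "item '%s': invalid category code %s in row %d (declared range 1..%d)",
        spec$item[i], format(yi[which(bad)[1]]), which(bad)[1],
        spec$n_categories[i]), call. = FALSE)
    }
  }
  y
}
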