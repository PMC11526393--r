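# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with an isolated, fixed RNG stream
#'
#' Saves the caller's `.Random.seed`, seeds a private stream, runs `code`,
#' and restores the caller's stream. Used for simulated null distributions
#' so that p-values do not depend on call order and do not perturb the
#' user's RNG.
#' @noRd
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Symmetric inverse square root with pseudo-inverse fallback
#'
#' @param m symmetric positive semi-definite matrix.
#' @return list with `isqrt` (matrix), `rank`.
#' @noRd
inv_sqrt_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  tol <- max(e$values, 0) * 1e-10
  keep <- e$values > tol
  d <- ifelse(keep, 1 / sqrt(pmax(e$values, tol)), 0)
  list(
    isqrt = e$vectors %*% (d * t(e$vectors)),
    rank = sum(keep)
  )
}

#' Pseudo-inverse of a symmetric matrix
#' @noRd
pinv_sym <- function(m, tol_factor = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * tol_factor
  keep <- abs(e$values) > tol
  d <- ifelse(keep, 1 / e$values, 0)
  e$vectors %*% (d * t(e$vectors))
}

# stable log of pmax(x, tiny)
log_safe <- function(x) log(pmax(x, 1e-300))

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
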