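#' Normal-theory maximum likelihood fit of the single-factor model
#'
#' Fits the single-factor covariance structure
#' \eqn{\Sigma(\theta) = \phi\lambda\lambda' + \mathrm{diag}(\psi)},
#' \eqn{\mu(\theta) = \pi}, treating every item as numeric (ordinal codes
#' are used as-is). This is the fast fit used during tree growth: its
#' casewise score contributions feed the M-fluctuation tests. Terminal-node
#' models are re-fitted with the limited-information WLS estimator
#' ([fit_wls()]), which respects the ordinal scale.
#'
#' Identification: the reference item's loading is fixed to 1, the factor
#' mean to 0; intercepts, residual variances and the factor variance are
#' free. Intercepts are profiled out (their MLE is the sample mean);
#' variances are optimised on the log scale with a lower bound that clamps
#' Heywood cases at 1e-6 (flagged).
#'
#' @param data Data frame containing the item columns.
#' @param spec A [grm_spec] object.
#' @return An object of class `lv_ml_fit`: list with `theta` (named
#'   parameter vector: intercepts, free loadings, residual variances,
#'   factor variance), `loglik`, `converged`, `heywood`, `n`, `spec`, and
#'   internals used by [casewise_scores()].
#' @export
fit_ml_cfa <- function(data, spec) {
  y <- response_matrix(data, spec)
  n <- nrow(y)
  m <- ncol(y)
  assert_that(n >= 3 * m, "need at least 3 rows per item for the ML fit")
  ref <- reference_item(spec)
  ybar <- colMeans(y)
  yc <- sweep(y, 2, ybar)
  S <- crossprod(yc) / n
  sd0 <- sqrt(diag(S))
  if (any(sd0 < 1e-10)) {
    return(ml_failure(spec, n, "constant item"))
  }

  free <- setdiff(seq_len(m), ref)
  # moment starting values via the reference column
  covr <- S[, ref]
  phi0 <- abs(S[ref, ref]) * 0.5
  if (m >= 3) {
    others <- free[1:2]
    tri <- S[others[1], ref] * S[others[2], ref] / S[others[1], others[2]]
    if (is.finite(tri) && tri > 1e-8) phi0 <- tri
  }
  lam0 <- covr / phi0
  lam0[ref] <- 1
  psi0 <- pmax(diag(S) - lam0^2 * phi0, 0.05 * diag(S))

  par0 <- c(lam0[free], log(psi0), log(phi0))
  idx_lam <- seq_along(free)
  idx_psi <- length(free) + seq_len(m)
  idx_phi <- length(free) + m + 1L

  unpack <- function(par) {
    lam <- rep(1, m)
    lam[free] <- par[idx_lam]
    list(lam = lam, psi = exp(par[idx_psi]), phi = exp(par[idx_phi]))
  }
  objgrad <- function(par) {
    p <- unpack(par)
    Sig <- p$phi * tcrossprod(p$lam) + diag(p$psi, m)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(par))))
    Sinv <- chol2inv(ch)
    val <- n / 2 * (2 * sum(log(diag(ch))) + sum(Sinv * S))
    A <- Sinv - Sinv %*% S %*% Sinv
    Al <- A %*% p$lam
    g_lam <- n * p$phi * Al[free]
    g_psi <- (n / 2) * diag(A) * p$psi
    g_phi <- (n / 2) * sum(p$lam * Al) * p$phi
    list(value = val, grad = c(g_lam, g_psi, g_phi))
  }
  fn <- function(par) objgrad(par)$value
  gr <- function(par) objgrad(par)$grad

  lower <- rep(-Inf, length(par0))
  lower[idx_psi] <- log(1e-6)
  opt <- tryCatch(
    stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    return(ml_failure(spec, n, "optimizer error"))
  }
  p <- unpack(opt$par)
  heywood <- any(opt$par[idx_psi] <= log(1e-6) + 1e-8)
  Sig <- p$phi * tcrossprod(p$lam) + diag(p$psi, m)
  Sinv <- chol2inv(chol(Sig))
  loglik <- -n / 2 * m * log(2 * pi) - opt$value
  # L-BFGS-B occasionally reports a stalled line search (code 52) at a
  # point whose gradient already vanishes; trust the gradient.
  at_optimum <- opt$convergence == 0 ||
    max(abs(objgrad(opt$par)$grad)) < 1e-5 * n
  theta <- c(
    stats::setNames(ybar, paste0("pi_", spec$item)),
    stats::setNames(p$lam[free], paste0("lambda_", spec$item[free])),
    stats::setNames(p$psi, paste0("psi_", spec$item)),
    phi = p$phi
  )
  fit <- structure(list(
    theta = theta, loglik = loglik,
    converged = at_optimum, heywood = heywood,
    n = n, spec = spec,
    mu = ybar, lambda = p$lam, psi = p$psi, phi = p$phi,
    Sigma = Sig, Sigma_inv = Sinv, free_loadings = free
  ), class = "lv_ml_fit")
  fit
}

ml_failure <- function(spec, n, reason) {
  structure(list(theta = NULL, loglik = NA_real_, converged = FALSE,
                 heywood = FALSE, n = n, spec = spec, reason = reason),
            class = "lv_ml_fit")
}

#' @export
print.lv_ml_fit <- function(x, ...) {
  cat("<lv_ml_fit> n =", x$n,
      if (isTRUE(x$converged)) "converged" else "NOT converged",
      if (isTRUE(x$heywood)) "(Heywood)" else "", "\n")
  if (!is.null(x$theta)) {
    cat("  logLik:", format(x$loglik, digits = 6), "\n")
  }
  invisible(x)
}

#' Casewise score contributions of an ML fit
#'
#' Row j is the gradient of observation j's log density with respect to the
#' model parameters (intercepts, free loadings, residual variances, factor
#' variance), evaluated at the estimate. At the optimum the columns sum to
#' (numerically) zero; the sample covariance of the rows is the
#' outer-product-of-gradients estimate of the information matrix.
#'
#' @param fit An `lv_ml_fit` from [fit_ml_cfa()].
#' @param data The data the model was fitted to.
#' @return A numeric matrix (n rows, one column per parameter) with
#'   attribute `"info"` (OPG information estimate, k x k).
#' @export
casewise_scores <- function(fit, data) {
  assert_that(isTRUE(fit$converged), "scores need a converged ML fit")
  spec <- fit$spec
  y <- response_matrix(data, spec)
  m <- ncol(y)
  yc <- sweep(y, 2, fit$mu)
  Q <- yc %*% fit$Sigma_inv            # rows: q_j' = (y_j - mu)' Sigma^-1
  u <- drop(Q %*% fit$lambda)
  Sil <- drop(fit$Sigma_inv %*% fit$lambda)
  sc_pi <- Q
  sc_lam <- fit$phi * (Q[, fit$free_loadings, drop = FALSE] * u -
                         matrix(Sil[fit$free_loadings], nrow(y),
                                length(fit$free_loadings), byrow = TRUE))
  sc_psi <- 0.5 * sweep(Q^2, 2, diag(fit$Sigma_inv))
  sc_phi <- 0.5 * (u^2 - sum(fit$lambda * Sil))
  sc <- cbind(sc_pi, sc_lam, sc_psi, sc_phi)
  colnames(sc) <- names(fit$theta)
  info <- crossprod(sc) / nrow(sc)
  attr(sc, "info") <- info
  sc
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.lv_ml_fit <- function(x, ...) {
  if (is.null(x$theta)) return(tibble::tibble(term = character(),
                                              estimate = numeric()))
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @exportS3Method generics::glance
glance.lv_ml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, converged = x$converged,
                 heywood = x$heywood)
}
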