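# Limited-information stage 1: univariate thresholds and pairwise
# polychoric / polyserial / Pearson correlations, with the asymptotic
# covariance of the stacked statistics from per-case influence functions.

#' Bivariate standard normal CDF
#'
#' P(X <= h, Y <= k) for correlation `rho`, vectorised over `h`, `k`
#' (scalar `rho`). Uses the single-integral identity
#' Phi2(h,k,rho) = Phi(h)Phi(k) + int_0^rho phi2(h,k;r) dr with
#' Gauss-Legendre quadrature; the integrand is smooth in r for |rho| < 1.
#' @noRd
pbinorm <- function(h, k, rho) {
  h <- pmin(pmax(h, -10), 10)
  k <- pmin(pmax(k, -10), 10)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (abs(rho) < 1e-12) return(base)
  gl <- gauss_legendre_48
  # split near-singular tail for very high correlation
  brk <- if (abs(rho) > 0.95) c(0, sign(rho) * 0.95, rho) else c(0, rho)
  r <- w <- NULL
  for (s in seq_len(length(brk) - 1)) {
    a <- brk[s]; b <- brk[s + 1]
    r <- c(r, (a + b) / 2 + (b - a) / 2 * gl$nodes)
    w <- c(w, (b - a) / 2 * gl$weights)
  }
  om <- 1 - r^2
  # integrand exp(-(h^2 - 2 r h k + k^2)/(2 om)) as one outer product
  E <- exp(tcrossprod(h * k, r / om) - tcrossprod(h^2 + k^2, 1 / (2 * om)))
  acc <- drop(E %*% (w / (2 * pi * sqrt(om))))
  pmin(pmax(base + acc, 0), 1)
}

# 48-point Gauss-Legendre rule on [-1, 1]
gauss_legendre_48 <- local({
  # Golub-Welsch from the Jacobi matrix of Legendre polynomials
  n <- 48
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
})

# Cell probabilities of a two-way ordinal table given thresholds and rho.
# tau_i, tau_j: finite threshold vectors (may be length >= 1).
cell_probs <- function(tau_i, tau_j, rho) {
  a <- c(-Inf, tau_i, Inf)
  b <- c(-Inf, tau_j, Inf)
  Fg <- outer(a, b, function(x, y) pbinorm(x, y, rho))
  ni <- length(tau_i) + 1
  nj <- length(tau_j) + 1
  p <- Fg[2:(ni + 1), 2:(nj + 1), drop = FALSE] -
    Fg[1:ni, 2:(nj + 1), drop = FALSE] -
    Fg[2:(ni + 1), 1:nj, drop = FALSE] +
    Fg[1:ni, 1:nj, drop = FALSE]
  pmax(p, 1e-12)
}

# Two-step polychoric correlation: maximise the table likelihood over rho
# with thresholds fixed.
polychoric_rho <- function(counts, tau_i, tau_j) {
  nll <- function(rho) -sum(counts * log(cell_probs(tau_i, tau_j, rho)))
  o <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-7)
  rho <- o$minimum
  clipped <- FALSE
  if (abs(rho) > 0.9985) {
    rho <- sign(rho) * 0.999
    clipped <- TRUE
  }
  list(rho = rho, clipped = clipped)
}

# Two-step polyserial correlation (numeric z standardised, thresholds fixed).
polyserial_rho <- function(z, ycat, tau) {
  lo_t <- c(-Inf, tau)
  hi_t <- c(tau, Inf)
  nll <- function(rho) {
    cc <- sqrt(1 - rho^2)
    hi <- stats::pnorm((hi_t[ycat] - rho * z) / cc)
    lo <- stats::pnorm((lo_t[ycat] - rho * z) / cc)
    -sum(log_safe(hi - lo))
  }
  o <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-7)
  rho <- o$minimum
  clipped <- abs(rho) > 0.9985
  if (clipped) rho <- sign(rho) * 0.999
  list(rho = rho, clipped = clipped, nll = nll)
}

#' Polychoric/polyserial summary statistics for a WLS fit
#'
#' Stage one of the limited-information estimator: per-ordinal-item probit
#' thresholds from cumulative proportions (empty categories collapsed into
#' the adjacent category), pairwise polychoric (ordinal-ordinal),
#' polyserial (ordinal-numeric) and Pearson (numeric-numeric) correlations
#' by two-step maximum likelihood with thresholds fixed, numeric means and
#' variances, and the asymptotic covariance of the stacked statistics from
#' per-case influence functions (the two-step/delta method, including the
#' threshold-estimation contribution to the correlations).
#'
#' @param data Data frame with the item columns.
#' @param spec A [grm_spec] object.
#' @return An object of class `lv_polychoric` with elements `stat` (named
#'   vector of stacked statistics), `Gamma` (their asymptotic covariance),
#'   `tau`, `tau_keep`, `category_map`, `cors`, `num_means`, `num_vars`,
#'   `n`, `spec`, `collapsed`, `clipped`.
#' @export
estimate_polychoric <- function(data, spec) {
  y <- response_matrix(data, spec)
  n <- nrow(y)
  m <- ncol(y)
  ord <- which(is_ordinal(spec))
  num <- which(!is_ordinal(spec))

  tau <- list(); tau_keep <- list(); category_map <- list()
  collapsed <- integer(0)
  ord_codes <- y  # collapsed codes
  for (i in ord) {
    K <- spec$n_categories[i]
    cnt <- tabulate(y[, i], nbins = K)
    assert_that(sum(cnt > 0) >= 2,
                sprintf("item '%s' has fewer than 2 observed categories",
                        spec$item[i]))
    # map each original code to its collapsed (observed, contiguous) code;
    # empty categories merge downward into the previous observed category
    # (the lowest codes merge upward).
    obs <- which(cnt > 0)
    mapv <- cumsum(cnt > 0)
    mapv[mapv == 0] <- 1L
    category_map[[spec$item[i]]] <- as.integer(mapv)
    collapsed[spec$item[i]] <- K - length(obs)
    ord_codes[, i] <- mapv[y[, i]]
    cprop <- cumsum(cnt[obs]) / n
    kk <- seq_len(length(obs) - 1)
    tau_i <- stats::qnorm(cprop[kk])
    # original boundary index of each kept threshold: boundary between
    # collapsed categories k and k+1 corresponds to original boundary obs[k]
    names(tau_i) <- obs[kk]
    tau[[spec$item[i]]] <- tau_i
    tau_keep[[spec$item[i]]] <- as.integer(obs[kk])
  }

  num_means <- if (length(num)) colMeans(y[, num, drop = FALSE]) else NULL
  num_vars <- if (length(num))
    apply(y[, num, drop = FALSE], 2, function(v) mean((v - mean(v))^2)) else NULL
  if (length(num)) {
    names(num_means) <- spec$item[num]
    names(num_vars) <- spec$item[num]
  }

  # ---- influence matrix, thresholds block ------------------------------
  infl <- list(); stat <- numeric(0); stat_names <- character(0)
  tau_col <- list()  # column index of each (item, kept boundary) in infl
  col <- 0L
  for (i in ord) {
    nm <- spec$item[i]
    ti <- tau[[nm]]
    dens <- stats::dnorm(ti)
    ci <- ord_codes[, i]
    for (k in seq_along(ti)) {
      col <- col + 1L
      infl[[col]] <- ((ci <= k) - stats::pnorm(ti[k])) / dens[k]
      stat <- c(stat, ti[k]); stat_names <- c(stat_names,
        paste0("tau_", nm, "_", names(ti)[k]))
      tau_col[[nm]] <- c(tau_col[[nm]] %||% integer(0), col)
    }
  }

  # ---- correlations -----------------------------------------------------
  pairs <- utils::combn(m, 2)
  cors <- vector("list", ncol(pairs))
  clipped_any <- FALSE
  zs <- NULL
  if (length(num)) {
    zs <- scale(y[, num, drop = FALSE], center = num_means,
                scale = sqrt(num_vars))
    colnames(zs) <- spec$item[num]
  }
  for (pidx in seq_len(ncol(pairs))) {
    i <- pairs[1, pidx]; j <- pairs[2, pidx]
    nmi <- spec$item[i]; nmj <- spec$item[j]
    col <- col + 1L
    if (i %in% ord && j %in% ord) {
      counts <- table(factor(ord_codes[, i], levels = seq_len(length(tau[[nmi]]) + 1)),
                      factor(ord_codes[, j], levels = seq_len(length(tau[[nmj]]) + 1)))
      counts <- matrix(as.numeric(counts), nrow(counts))
      pr <- polychoric_rho(counts, tau[[nmi]], tau[[nmj]])
      clipped_any <- clipped_any || pr$clipped
      infl[[col]] <- polychoric_influence(
        pr$rho, tau[[nmi]], tau[[nmj]], counts, n,
        ord_codes[, i], ord_codes[, j],
        infl[tau_col[[nmi]]], infl[tau_col[[nmj]]])
      kind <- "polychoric"; rho <- pr$rho
    } else if (i %in% num && j %in% num) {
      z1 <- zs[, nmi]; z2 <- zs[, nmj]
      rho <- mean(z1 * z2)
      infl[[col]] <- z1 * z2 - rho / 2 * (z1^2 + z2^2)
      kind <- "pearson"
    } else {
      oi <- if (i %in% ord) i else j   # ordinal member
      ni_ <- if (i %in% ord) j else i  # numeric member
      nmo <- spec$item[oi]; nmn <- spec$item[ni_]
      ps <- polyserial_rho(zs[, nmn], ord_codes[, oi], tau[[nmo]])
      clipped_any <- clipped_any || ps$clipped
      rho <- ps$rho
      infl[[col]] <- polyserial_influence(
        rho, tau[[nmo]], zs[, nmn], ord_codes[, oi],
        infl[tau_col[[nmo]]],
        y[, ni_] - num_means[nmn], (y[, ni_] - num_means[nmn])^2 - num_vars[nmn],
        sqrt(num_vars[nmn]))
      kind <- "polyserial"
    }
    stat <- c(stat, rho)
    stat_names <- c(stat_names, paste0("rho_", nmi, "_", nmj))
    cors[[pidx]] <- tibble::tibble(item1 = nmi, item2 = nmj,
                                   kind = kind, rho = rho)
  }

  # ---- numeric means and variances -------------------------------------
  for (nm in spec$item[num]) {
    col <- col + 1L
    infl[[col]] <- y[, nm] - num_means[nm]
    stat <- c(stat, num_means[nm]); stat_names <- c(stat_names, paste0("mean_", nm))
  }
  for (nm in spec$item[num]) {
    col <- col + 1L
    infl[[col]] <- (y[, nm] - num_means[nm])^2 - num_vars[nm]
    stat <- c(stat, num_vars[nm]); stat_names <- c(stat_names, paste0("var_", nm))
  }

  IM <- do.call(cbind, infl)
  Gamma <- crossprod(IM) / n - tcrossprod(colMeans(IM))
  names(stat) <- stat_names
  dimnames(Gamma) <- list(stat_names, stat_names)

  structure(list(
    stat = stat, Gamma = Gamma, tau = tau, tau_keep = tau_keep,
    category_map = category_map,
    cors = dplyr::bind_rows(cors),
    num_means = num_means, num_vars = num_vars,
    n = n, spec = spec, collapsed = collapsed, clipped = clipped_any
  ), class = "lv_polychoric")
}

# Influence function of a two-step polychoric correlation, including the
# propagated threshold-estimation noise (two-stage M-estimator expansion).
polychoric_influence <- function(rho, tau_i, tau_j, counts, n,
                                 ci, cj, tau_infl_i, tau_infl_j) {
  h <- 1e-4
  phat <- counts / n
  lp <- function(r, ti = tau_i, tj = tau_j) log(cell_probs(ti, tj, r))
  l0 <- lp(rho); lp_p <- lp(rho + h); lp_m <- lp(rho - h)
  s_cell <- (lp_p - lp_m) / (2 * h)            # d log p / d rho
  s2_cell <- (lp_p - 2 * l0 + lp_m) / h^2       # d2 log p / d rho2
  A <- -sum(phat * s2_cell)
  g <- s_cell[cbind(ci, cj)]
  out <- g
  taus <- list(i = tau_i, j = tau_j)
  tau_infl <- list(i = tau_infl_i, j = tau_infl_j)
  for (side in c("i", "j")) {
    tv <- taus[[side]]
    for (t in seq_along(tv)) {
      tp <- tv; tp[t] <- tv[t] + h
      tm <- tv; tm[t] <- tv[t] - h
      if (side == "i") {
        sp <- (lp(rho + h, ti = tp) - lp(rho - h, ti = tp)) / (2 * h)
        sm <- (lp(rho + h, ti = tm) - lp(rho - h, ti = tm)) / (2 * h)
      } else {
        sp <- (lp(rho + h, tj = tp) - lp(rho - h, tj = tp)) / (2 * h)
        sm <- (lp(rho + h, tj = tm) - lp(rho - h, tj = tm)) / (2 * h)
      }
      dst <- (sp - sm) / (2 * h)                # d2 log p / d rho d tau_t
      Dt <- sum(phat * dst)
      out <- out + Dt * tau_infl[[side]][[t]]
    }
  }
  out / A
}

# Influence function of a two-step polyserial correlation (thresholds and
# numeric standardisation treated as estimated nuisances).
polyserial_influence <- function(rho, tau, z, ycat, tau_infl,
                                 mean_infl, var_infl, sdn) {
  h <- 1e-4
  g_fun <- function(r, tv = tau, zshift = 0, zscale = 1) {
    zz <- (z - zshift) / zscale
    lo_t <- c(-Inf, tv); hi_t <- c(tv, Inf)
    ll <- function(rr) {
      cc <- sqrt(1 - rr^2)
      log_safe(stats::pnorm((hi_t[ycat] - rr * zz) / cc) -
                 stats::pnorm((lo_t[ycat] - rr * zz) / cc))
    }
    (ll(r + h) - ll(r - h)) / (2 * h)
  }
  g <- g_fun(rho)
  A <- -mean((g_fun(rho + h) - g_fun(rho - h)) / (2 * h))
  out <- g
  for (t in seq_along(tau)) {
    tp <- tau; tp[t] <- tau[t] + h
    tm <- tau; tm[t] <- tau[t] - h
    Dt <- mean((g_fun(rho, tv = tp) - g_fun(rho, tv = tm)) / (2 * h))
    out <- out + Dt * tau_infl[[t]]
  }
  # standardisation nuisances: z = (x - mu)/sd; d z/d mu = -1/sd,
  # d z/d sigma2 = -z/(2 sigma2)
  hmu <- 1e-4 * sdn
  Dmu <- mean((g_fun(rho, zshift = hmu / sdn) -
                 g_fun(rho, zshift = -hmu / sdn)) / (2 * hmu))
  out <- out + Dmu * mean_infl
  hs <- 1e-4
  Dvar <- mean((g_fun(rho, zscale = sqrt(1 + hs)) -
                  g_fun(rho, zscale = sqrt(1 - hs))) / (2 * hs * sdn^2))
  out <- out + Dvar * var_infl
  out / A
}

#' @export
print.lv_polychoric <- function(x, ...) {
  cat("<lv_polychoric> n =", x$n, ";", length(x$stat), "statistics\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lv_polychoric <- function(x, ...) {
  tibble::tibble(statistic = names(x$stat), estimate = unname(x$stat),
                 std_error = sqrt(pmax(diag(x$Gamma), 0) / x$n))
}
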