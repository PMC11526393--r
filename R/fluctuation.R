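# Generalized M-fluctuation tests for parameter instability along a
# covariate, and score-maximising split-point selection.
#
# The empirical fluctuation process is the scaled cumulative sum of the
# casewise scores ordered by the covariate,
#   B(t_j) = Ihat^{-1/2} n^{-1/2} sum_{l<=j} psi_(l),
# with Ihat the outer-product-of-gradients information estimate. Test
# families: supLM for numeric covariates (max over a trimmed time grid of
# ||B(t)||^2 / (t(1-t))), the same functional restricted to level
# boundaries for ordinal covariates, and the chi-square LM statistic over
# level blocks for unordered categorical covariates. Critical values for
# the sup-type statistics are obtained by simulating the corresponding
# Brownian-bridge functional; the null draws use a dedicated fixed RNG
# stream so p-values are reproducible and independent of call order.

.lv_cache <- new.env(parent = emptyenv())

#' Empirical fluctuation process of casewise scores
#'
#' @param scores n x k casewise score matrix (see [casewise_scores()]).
#' @param info k x k information estimate; defaults to the OPG estimate
#'   attached to `scores`.
#' @param order Integer permutation of rows (typically the covariate
#'   ordering).
#' @return n x k matrix of the decorrelated, scaled cumulative score
#'   process; attribute `"rank"` gives the rank used for the (pseudo-)
#'   inverse square root of `info`.
#' @export
fluctuation_process <- function(scores, info = attr(scores, "info"),
                                order = seq_len(nrow(scores))) {
  n <- nrow(scores)
  is2 <- inv_sqrt_psd(info)
  U <- (scores[order, , drop = FALSE] %*% is2$isqrt) / sqrt(n)
  B <- apply(U, 2, cumsum)
  if (is.null(dim(B))) B <- matrix(B, nrow = n)
  attr(B, "rank") <- is2$rank
  B
}

# Decorrelated scaled scores (rows sum to B(1) ~ 0); shared by the tests.
scaled_scores <- function(scores, info) {
  is2 <- inv_sqrt_psd(info)
  U <- (scores %*% is2$isqrt) / sqrt(nrow(scores))
  attr(U, "rank") <- is2$rank
  U
}

# Simulated null distribution of the supLM functional on the canonical
# trimmed grid, cached per (k, n_sim, ngrid).
suplm_null <- function(k, n_sim = 4999, ngrid = 300, trim = 0.1) {
  key <- paste("suplm", k, n_sim, ngrid, round(trim * 1000), sep = "_")
  if (!is.null(.lv_cache[[key]])) return(.lv_cache[[key]])
  tg <- seq(trim, 1 - trim, length.out = ngrid)
  dt <- c(tg[1], diff(tg), 1 - tg[ngrid])
  denom <- tg * (1 - tg)
  out <- with_private_seed(900101 + k, {
    res <- numeric(n_sim)
    chunk <- max(1, floor(2e6 / ((ngrid + 1) * k)))
    done <- 0
    while (done < n_sim) {
      nc <- min(chunk, n_sim - done)
      Z <- matrix(stats::rnorm((ngrid + 1) * k * nc) * sqrt(dt),
                  nrow = ngrid + 1)
      W <- apply(Z, 2, cumsum)
      Wlast <- W[ngrid + 1, ]
      B <- W[seq_len(ngrid), , drop = FALSE] -
        tcrossprod(tg, Wlast)
      B2 <- B^2
      dim(B2) <- c(ngrid, k, nc)
      S <- apply(B2, 3, rowSums)          # ngrid x nc
      res[done + seq_len(nc)] <- apply(S / denom, 2, max)
      done <- done + nc
    }
    res
  })
  .lv_cache[[key]] <- out
  out
}

# Simulated null of the ordinal maxLM functional at boundary fractions ts.
# Fractions are rounded to 1/100 so nodes with near-identical level splits
# share one cached null sample.
maxlm_null <- function(k, ts, n_sim = 4999) {
  ts <- sort(unique(pmin(pmax(round(ts, 2), 0.01), 0.99)))
  key <- paste("maxlm", k, n_sim, paste(ts * 100, collapse = "."), sep = "_")
  if (!is.null(.lv_cache[[key]])) return(.lv_cache[[key]])
  seed <- 910000 + k * 131 + (round(sum(ts) * 1e4) %% 10000)
  out <- with_private_seed(seed, {
    G <- length(ts)
    dt <- c(ts[1], diff(ts), 1 - ts[G])
    denom <- ts * (1 - ts)
    res <- numeric(n_sim)
    chunk <- max(1, floor(2e6 / ((G + 1) * k)))
    done <- 0
    while (done < n_sim) {
      nc <- min(chunk, n_sim - done)
      Z <- matrix(stats::rnorm((G + 1) * k * nc) * sqrt(dt), nrow = G + 1)
      W <- apply(Z, 2, cumsum)
      if (G == 0) break
      B <- W[seq_len(G), , drop = FALSE] - tcrossprod(ts, W[G + 1, ])
      B2 <- B^2
      dim(B2) <- c(G, k, nc)
      S <- apply(B2, 3, rowSums)
      if (G == 1) S <- matrix(S, nrow = 1)
      res[done + seq_len(nc)] <- apply(S / denom, 2, max)
      done <- done + nc
    }
    res
  })
  .lv_cache[[key]] <- out
  out
}

covariate_kind <- function(x) {
  if (is.ordered(x)) "ordinal"
  else if (is.factor(x) || is.character(x) || is.logical(x)) "categorical"
  else "numeric"
}

# z as an orderable integer/numeric vector for ordinal/numeric kinds
covariate_codes <- function(x) {
  if (is.ordered(x) || is.factor(x)) as.integer(x) else as.numeric(x)
}

#' Parameter instability test along one covariate
#'
#' Generalized M-fluctuation test of the null of parameter stability,
#' ordering the casewise scores by the covariate. Numeric covariates use
#' the supLM statistic over a trimmed time window, ordinal covariates the
#' same functional restricted to observed level boundaries (both with
#' simulated Brownian-bridge critical values), and unordered categorical
#' covariates the LM statistic with its asymptotic chi-square null.
#' Tied covariate values stay in one block: the process is evaluated only
#' at the last row of each tie group.
#'
#' @param scores n x k casewise score matrix.
#' @param covariate Vector of covariate values (numeric; `ordered` for
#'   ordinal; `factor`/character for categorical).
#' @param info Information estimate (default: OPG attribute of `scores`).
#' @param kind Override the covariate kind inferred from the vector class.
#' @param n_sim Null-simulation replicates for sup-type statistics.
#' @param trim Trimming for the supLM window (default 0.1).
#' @param name Covariate name used in the output.
#' @return One-row tibble: `covariate`, `family`, `statistic`, `p_value`,
#'   `n`, `k`.
#' @export
test_instability <- function(scores, covariate,
                             info = attr(scores, "info"),
                             kind = NULL, n_sim = 4999, trim = 0.1,
                             name = NA_character_) {
  assert_that(length(covariate) == nrow(scores),
              "covariate length must match the score matrix")
  kind <- kind %||% covariate_kind(covariate)
  n <- nrow(scores)
  k <- ncol(scores)
  U <- scaled_scores(scores, info)
  degenerate <- function(family) {
    tibble::tibble(covariate = name, family = family, statistic = 0,
                   p_value = 1, n = n, k = k)
  }
  if (kind %in% c("numeric", "ordinal")) {
    z <- covariate_codes(covariate)
    if (length(unique(z)) < 2) {
      return(degenerate(if (kind == "numeric") "supLM" else "maxLM-ordinal"))
    }
    o <- order(z)
    B <- apply(U[o, , drop = FALSE], 2, cumsum)
    zs <- z[o]
    ends <- c(which(diff(zs) != 0), n)
    if (kind == "numeric") {
      ngrid <- 300
      tg <- seq(trim, 1 - trim, length.out = ngrid)
      jj <- findInterval(tg * n + 1e-9, ends)
      ok <- jj >= 1
      if (!any(ok)) return(degenerate("supLM"))
      sel <- !duplicated(jj) & ok
      pos <- ends[jj[sel]]
      denom <- tg[sel] * (1 - tg[sel])
      ss <- rowSums(B[pos, , drop = FALSE]^2) / denom
      stat <- max(ss)
      null <- suplm_null(k, n_sim = n_sim, ngrid = ngrid, trim = trim)
      p <- (1 + sum(null >= stat)) / (length(null) + 1)
      return(tibble::tibble(covariate = name, family = "supLM",
                            statistic = stat, p_value = p, n = n, k = k))
    } else {
      bnd <- ends[ends < n]
      if (!length(bnd)) return(degenerate("maxLM-ordinal"))
      ts <- bnd / n
      ss <- rowSums(B[bnd, , drop = FALSE]^2) / (ts * (1 - ts))
      stat <- max(ss)
      null <- maxlm_null(k, ts, n_sim = n_sim)
      p <- (1 + sum(null >= stat)) / (length(null) + 1)
      return(tibble::tibble(covariate = name, family = "maxLM-ordinal",
                            statistic = stat, p_value = p, n = n, k = k))
    }
  }
  # categorical
  f <- droplevels(factor(covariate))
  C <- nlevels(f)
  if (C < 2) return(degenerate("LM-categorical"))
  nc <- tabulate(f, nbins = C)
  A <- rowsum(U, f)                       # C x k level sums of scaled scores
  stat <- sum(rowSums(A^2) * n / nc)
  df <- k * (C - 1)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  tibble::tibble(covariate = name, family = "LM-categorical",
                 statistic = stat, p_value = p, n = n, k = k)
}

#' Bonferroni covariate selection
#'
#' Given instability test results for R covariates tested on the same node
#' sample, selects the covariate with the smallest p-value if that p-value
#' is at most `alpha / R`; otherwise selects none. Ties go to the first
#' covariate in input order.
#'
#' @param results Tibble of [test_instability()] rows.
#' @param alpha Family-wise level (default 0.05).
#' @return The selected row (one-row tibble) or `NULL`.
#' @export
bonferroni_select <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) return(NULL)
  R <- nrow(results)
  i <- which.min(results$p_value)
  if (results$p_value[i] > alpha / R) return(NULL)
  results[i, ]
}

#' Score-maximising split point on a covariate
#'
#' Evaluates the score-based statistic at every admissible cut (both
#' children at least `min_size` rows) and returns the maximiser. Numeric
#' and ordinal covariates search unique-value cuts `Z <= c`; categorical
#' covariates search binary level partitions exhaustively up to 10 levels
#' and otherwise order levels by their mean first score coordinate and
#' search that ordering.
#'
#' @inheritParams test_instability
#' @param min_size Minimum child size.
#' @return `NULL` when no admissible cut exists; otherwise a list with
#'   `kind`, `statistic`, `n_left`, `n_right`, and `cut` (numeric/ordinal)
#'   or `levels` (categorical: levels of the left child).
#' @export
best_split <- function(scores, covariate, info = attr(scores, "info"),
                       kind = NULL, min_size = 200, name = NA_character_) {
  kind <- kind %||% covariate_kind(covariate)
  n <- nrow(scores)
  if (n < 2 * min_size) return(NULL)
  U <- scaled_scores(scores, info)
  if (kind %in% c("numeric", "ordinal")) {
    z <- covariate_codes(covariate)
    o <- order(z)
    zs <- z[o]
    ends <- c(which(diff(zs) != 0), n)
    cand <- ends[ends >= min_size & (n - ends) >= min_size]
    if (!length(cand)) return(NULL)
    B <- apply(U[o, , drop = FALSE], 2, cumsum)
    ts <- cand / n
    ss <- rowSums(B[cand, , drop = FALSE]^2) / (ts * (1 - ts))
    j <- which.max(ss)
    cutpos <- cand[j]
    cutval <- zs[cutpos]
    if (is.ordered(covariate) || is.factor(covariate)) {
      cutval <- levels(covariate)[cutval]
    }
    return(list(covariate = name, kind = kind, cut = cutval,
                statistic = ss[j], n_left = cutpos, n_right = n - cutpos))
  }
  f <- droplevels(factor(covariate))
  C <- nlevels(f)
  if (C < 2) return(NULL)
  nc <- tabulate(f, nbins = C)
  A <- rowsum(U, f)
  if (C <= 10) {
    best <- NULL
    for (mask in seq_len(2^(C - 1) - 1)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(C) - 1)))
      nS <- sum(nc[sel])
      if (nS < min_size || n - nS < min_size) next
      aS <- colSums(A[sel, , drop = FALSE])
      stat <- n * (1 / nS + 1 / (n - nS)) * sum(aS^2)
      if (is.null(best) || stat > best$statistic) {
        best <- list(covariate = name, kind = "categorical",
                     levels = levels(f)[sel], statistic = stat,
                     n_left = nS, n_right = n - nS)
      }
    }
    return(best)
  }
  # many levels: order by mean first score coordinate, scan that ordering
  ordl <- order(A[, 1] / nc)
  csize <- cumsum(nc[ordl])
  best <- NULL
  for (g in seq_len(C - 1)) {
    nS <- csize[g]
    if (nS < min_size || n - nS < min_size) next
    aS <- colSums(A[ordl[seq_len(g)], , drop = FALSE])
    stat <- n * (1 / nS + 1 / (n - nS)) * sum(aS^2)
    if (is.null(best) || stat > best$statistic) {
      best <- list(covariate = name, kind = "categorical",
                   levels = levels(f)[ordl[seq_len(g)]], statistic = stat,
                   n_left = nS, n_right = n - nS)
    }
  }
  best
}
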