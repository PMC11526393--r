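# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot forest results
#'
#' Aggregated score distribution split by how many relevant subgroups
#' cover each individual, plus the coverage bar. Uncovered individuals
#' (no score) appear as the zero-subgroup bar only.
#'
#' @param object An `lv_forest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lv_forest <- function(object, ...) {
  sc <- object$scores
  sc$coverage <- factor(pmin(sc$n_subgroups, 5),
                        levels = 0:5,
                        labels = c("0", "1", "2", "3", "4", "5+"))
  ggplot2::ggplot(sc[sc$available, ],
                  ggplot2::aes(x = .data$score, fill = .data$coverage)) +
    ggplot2::geom_histogram(bins = 40, colour = "grey30",
                            linewidth = 0.1) +
    ggplot2::labs(
      x = "aggregated EBM score",
      y = "individuals",
      fill = "covering\nsubgroups",
      title = sprintf("LV forest scores (%d relevant subgroups, %.0f%% covered)",
                      nrow(object$subgroups),
                      100 * (1 - object$nonconvergence_rate))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fluctuation process
#'
#' Shows the squared norm of the decorrelated cumulative score process
#' against the ordering fraction, the quantity whose maximum is the
#' sup-type instability statistic.
#'
#' @param scores Casewise score matrix (see [casewise_scores()]).
#' @param covariate Covariate vector ordering the process.
#' @param info Information estimate (default: OPG attribute of `scores`).
#' @param name Covariate name for the title.
#' @return A ggplot object.
#' @export
plot_fluctuation <- function(scores, covariate,
                             info = attr(scores, "info"),
                             name = "covariate") {
  o <- order(covariate_codes(covariate))
  B <- fluctuation_process(scores, info, o)
  n <- nrow(B)
  df <- tibble::tibble(t = seq_len(n) / n, norm2 = rowSums(B^2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$norm2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = sprintf("fraction of sample ordered by %s", name),
                  y = expression("||B(t)||"^2),
                  title = "Empirical fluctuation process") +
    ggplot2::theme_minimal()
}

#' Plot a WLS fit
#'
#' Model-implied versus sample polychoric correlations; a well-fitting
#' single-factor model puts all pairs on the diagonal.
#'
#' @param object An `lv_wls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lv_wls_fit <- function(object, ...) {
  l <- object$standardized_loadings
  cors <- object$stats$cors
  cors$implied <- l[cors$item1] * l[cors$item2]
  ggplot2::ggplot(cors, ggplot2::aes(x = .data$rho, y = .data$implied)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "sample correlation", y = "model-implied",
                  title = sprintf("Single-factor fit (RMSEA = %.3f)",
                                  object$rmsea)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
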