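# ggplot2 methods for the result containers.

estimand_label <- function(desc) {
  if (is.null(desc)) return("estimate")
  if (desc$type == "fixed") {
    s <- desc$surgeon %||% "average"
    k <- desc$center %||% "average"
    sprintf("surgeon %s / center %s", s, k)
  } else {
    sprintf("%s %s (marginal over %s)", desc$level, desc$cluster,
            if (desc$level == "center") "surgeons" else "centers")
  }
}

#' Plot a standardized survival curve
#'
#' @param object A `std_surv` tibble.
#' @param ... Unused.
#' @return A ggplot: survival probability over time, with a ribbon when
#'   confidence bands are present.
#' @method autoplot std_surv
#' @export
autoplot.std_surv <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$estimate))
  if (all(c("lower", "upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Standardized survival probability",
                  title = estimand_label(attr(object, "estimand")))
}

#' Plot a contrast of standardized survival curves
#'
#' @param object A `std_contrast` tibble.
#' @param ... Unused.
#' @return A ggplot of the survival difference over time with a zero
#'   reference line.
#' @method autoplot std_contrast
#' @export
autoplot.std_contrast <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$estimate))
  if (all(c("lower", "upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.2)
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time", y = "Survival difference",
                  title = sprintf("%s vs %s",
                                  estimand_label(attr(object, "minuend")),
                                  estimand_label(attr(object, "subtrahend"))))
}

#' Caterpillar plot of empirical-Bayes predictions
#'
#' @param object An `eb_predictions` tibble.
#' @param level Which level to show (default both, faceted).
#' @param ... Unused.
#' @return A ggplot of predictions with +/- 1.96 SD bars, ordered by rank.
#' @method autoplot eb_predictions
#' @export
autoplot.eb_predictions <- function(object, level = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(level)) df <- df[df$level == level, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$sd,
                   ymax = .data$estimate + 1.96 * .data$sd)) +
    ggplot2::facet_wrap(~level, scales = "free_x") +
    ggplot2::labs(x = "Rank (1 = lowest hazard)",
                  y = "Predicted random intercept")
}

#' Ranking plot of clusters versus the reference survival
#'
#' Point estimates (with CI bars when available) ordered by rank, colored
#' by risk category, with a horizontal line at the reference value.
#'
#' @param object A `cluster_ranking` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_ranking
#' @export
autoplot.cluster_ranking <- function(object, ...) {
  cols <- c(low = "forestgreen", medium = "black", high = "red",
            uncategorized = "grey50")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$rank, y = .data$estimate,
                                    color = .data$category))
  if (!anyNA(object$lower)) {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::geom_hline(yintercept = attr(object, "reference"),
                          linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$cluster),
                       vjust = -0.8, size = 2.8, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::labs(x = "Rank", y = "Standardized survival probability",
                  color = "Risk")
}

#' Combine standardized curves (and contrasts) in a faceted figure
#'
#' Stacks a named list of `std_surv` objects into one faceted panel of
#' survival curves; with `contrasts` given, a second faceted panel of
#' differences is returned alongside (via patchwork when available,
#' otherwise as a list of two ggplots).
#'
#' @param estimates Named list of `std_surv` objects.
#' @param contrasts Optional named list of `std_contrast` objects.
#' @return A ggplot (or combined patchwork / list of two ggplots).
#' @export
plot_curves <- function(estimates, contrasts = NULL) {
  if (length(estimates) == 0) {
    abort("Need at least one standardized estimate to plot.")
  }
  nm <- names(estimates) %||%
    vapply(estimates, function(e) estimand_label(attr(e, "estimand")),
           character(1))
  df <- dplyr::bind_rows(
    purrr::map2(estimates, nm,
                function(e, n) dplyr::mutate(as_tibble(e), estimand = n)))
  pa <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time,
                                         y = .data$estimate))
  if (all(c("lower", "upper") %in% names(df))) {
    pa <- pa + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.2)
  }
  pa <- pa + ggplot2::geom_line() +
    ggplot2::facet_wrap(~estimand) +
    ggplot2::labs(x = "Time", y = "Standardized survival probability")
  if (is.null(contrasts)) return(pa)
  nmc <- names(contrasts) %||% paste0("contrast_", seq_along(contrasts))
  dfc <- dplyr::bind_rows(
    purrr::map2(contrasts, nmc,
                function(e, n) dplyr::mutate(as_tibble(e), estimand = n)))
  pb <- ggplot2::ggplot(dfc, ggplot2::aes(x = .data$time,
                                          y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~estimand) +
    ggplot2::labs(x = "Time", y = "Survival difference")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    pa + pb + patchwork::plot_layout(ncol = 1)
  } else {
    list(survival = pa, differences = pb)
  }
}
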