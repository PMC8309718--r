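#' Tidy an evaluation report
#'
#' One row per repeat and stage with sensitivity, specificity, Dice similarity
#' coefficient and accuracy.
#'
#' @param x A `rccad_eval` from [evaluate_cohort()].
#' @param ... Unused.
#' @export
tidy.rccad_eval <- function(x, ...) {
  dplyr::select(x$metrics, "stage", "repeat_id", "sensitivity", "specificity",
                "dsc", "accuracy", "tp", "fn", "tn", "fp")
}

#' Summarize an evaluation report
#'
#' Mean and standard deviation of each metric across repeats, per stage — the
#' mean +/- SD form diagnostic studies report.
#'
#' @inheritParams tidy.rccad_eval
#' @export
glance.rccad_eval <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "dsc", "accuracy"),
                        names_to = "metric") |>
    dplyr::group_by(.data$stage, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop") |>
    dplyr::mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd))
}

#' @export
print.rccad_eval <- function(x, ...) {
  cat(sprintf("<evaluation> %s, %d repeat(s), seed %d\n", x$scheme, x$repeats, x$seed))
  g <- glance(x)
  g$mean <- signif(g$mean, 4)
  g$sd <- signif(g$sd, 2)
  print(as.data.frame(g))
  invisible(x)
}

#' Plot per-repeat evaluation metrics
#'
#' @param object A `rccad_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rccad_eval <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "dsc", "accuracy"),
                        names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Cross-validated diagnostic performance") +
    ggplot2::theme_minimal()
}

#' Tidy an SHRE spectrum
#'
#' @param x A `rccad_shre` from [shre_features()].
#' @param ... Unused.
#' @return Tibble with `order` and `error` columns.
#' @export
tidy.rccad_shre <- function(x, ...) {
  tibble(order = seq_along(x), error = as.numeric(x))
}

#' Plot an SHRE spectrum
#'
#' Reconstruction error against spherical-harmonic order; complex (malignant-
#' like) surfaces decay slower than smooth (benign-like) ones.
#'
#' @param object A `rccad_shre`.
#' @param ... Unused.
#' @export
autoplot.rccad_shre <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$order, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "SH model order", y = "relative RMS reconstruction error",
                  title = "Spherical-harmonic reconstruction-error spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a three-phase enhancement curve
#'
#' @param object A `rccad_curve` from [enhancement_curve()].
#' @param ... Unused.
#' @export
autoplot.rccad_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean_hu)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time since injection (s)", y = "mean attenuation (HU)",
                  title = "Tumor enhancement curve") +
    ggplot2::theme_minimal()
}

#' Tidy / summarize a trained MLP
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary.
#'
#' @param x A `rccad_mlp`.
#' @param ... Unused.
#' @export
tidy.rccad_mlp <- function(x, ...) x$history

#' @rdname tidy.rccad_mlp
#' @export
glance.rccad_mlp <- function(x, ...) {
  tibble(epochs = nrow(x$history),
         final_train_mse = x$history$train[nrow(x$history)],
         stopped_by = x$stopped_by,
         optimizer = x$optimizer,
         n_parameters = n_params(x$sizes))
}
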