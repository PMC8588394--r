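#' Plot a CGM series
#'
#' Glucose trace with meal (carbohydrate) and bolus events marked, one panel
#' per patient.
#'
#' @param x A `cgm_series`.
#' @param days Optional number of leading days to show.
#' @return A ggplot object.
#' @export
plot_series <- function(x, days = NULL) {
  df <- tibble::as_tibble(x)
  if (!is.null(days)) df <- df[df$time < days * 1440, ]
  events <- df[df$ch > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 60, y = .data$bg)) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_vline(data = events,
                        ggplot2::aes(xintercept = .data$time / 60),
                        colour = "orange", alpha = 0.4) +
    ggplot2::facet_wrap(~patient_id, ncol = 1) +
    ggplot2::labs(x = "time (h)", y = "blood glucose (mg/dL)") +
    ggplot2::theme_minimal()
}

#' Training-history curves of a fitted model
#'
#' @param object A `glybench_fit`.
#' @param ... Unused.
#' @return A ggplot object with train/validation loss per epoch.
#' @export
autoplot.glybench_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           cols = c("loss", "val_loss"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = object$spec_id, y = "loss") +
    ggplot2::theme_minimal()
}

#' Posterior win probabilities of the Plackett-Luce ranking
#'
#' @param object A `pl_ranking`.
#' @param ... Unused.
#' @return A ggplot object: posterior mean and 5--95% credible interval of
#'   each model's probability of being the best.
#' @export
autoplot.pl_ranking <- function(object, ...) {
  r <- object$ranking
  r$model <- factor(r$model, levels = rev(r$model))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$p_best, y = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "probability of being the best model", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
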