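# Parkes (consensus) error grid for type 1 diabetes.
#
# Zone boundaries are the published piecewise-linear consensus curves for
# type 1 diabetes (Parkes et al., Diabetes Care 2000; exact vertex
# coordinates as tabulated by Pfutzner et al., J Diabetes Sci Technol 2013).
# The grid partitions the (reference, prediction) square (0, 550]^2 into
# five nested zones A-E of increasing clinical risk: a point escalates one
# zone each time it crosses a boundary curve moving away from the identity
# line. Boundary ties are assigned to the inner (better) zone.

peg_boundaries <- function() {
  list(
    upper = list( # prediction above reference
      B = list(x = c(0, 30, 140, 280, 430), y = c(50, 50, 170, 380, 550)),
      C = list(x = c(0, 30, 50, 70, 260), y = c(60, 60, 80, 110, 550)),
      D = list(x = c(0, 25, 50, 80, 125), y = c(100, 100, 125, 215, 550)),
      E = list(x = c(0, 35, 50), y = c(150, 155, 550))
    ),
    lower = list( # prediction below reference; each curve rises vertically
      # from the axis at its first x, so below that x the zone is absent and
      # the polyline is evaluated from the top of the vertical segment
      B = list(x = c(50, 170, 385, 550), y = c(30, 145, 300, 450)),
      C = list(x = c(120, 260, 550), y = c(30, 130, 250)),
      D = list(x = c(250, 550), y = c(40, 150))
    )
  )
}

# piecewise-linear boundary value at reference x; outside the polyline's x
# span the boundary does not constrain (upper -> +Inf, lower -> -Inf)
peg_boundary_at <- function(bnd, x, side) {
  y <- stats::approx(bnd$x, bnd$y, xout = x, ties = "ordered")$y
  oob <- x > max(bnd$x) | x < min(bnd$x)
  y[oob] <- if (side == "upper") Inf else -Inf
  y
}

#' Parkes error-grid zone of prediction--reference pairs
#'
#' @param reference Reference glucose, mg/dL, in (0, 550].
#' @param prediction Predicted glucose, mg/dL, in (0, 550].
#' @return Factor with levels A--E; A is clinically accurate, E is the
#'   clinically dangerous confusion of hypo- and hyperglycemia.
#' @export
peg_zone <- function(reference, prediction) {
  stopifnot(length(reference) == length(prediction))
  if (any(reference <= 0 | reference > 550 | prediction <= 0 |
            prediction > 550)) {
    stop("coordinates outside the grid domain (0, 550]", call. = FALSE)
  }
  bounds <- peg_boundaries()
  zone <- rep(0L, length(reference)) # 0 = A
  for (i in seq_along(bounds$upper)) {
    y <- peg_boundary_at(bounds$upper[[i]], reference, "upper")
    zone <- pmax(zone, ifelse(prediction > y, i, 0L))
  }
  for (i in seq_along(bounds$lower)) {
    y <- peg_boundary_at(bounds$lower[[i]], reference, "lower")
    zone <- pmax(zone, ifelse(prediction < y, i, 0L))
  }
  factor(LETTERS[zone + 1L], levels = c("A", "B", "C", "D", "E"))
}

#' Summarize predictions on the Parkes error grid
#'
#' @param data A data frame of aligned pairs.
#' @param truth,estimate Column names of reference and predicted glucose.
#' @return A `peg_summary` tibble: one row per zone with count and
#'   percentage, plus the A-union-B percentage as attribute `ab_pct`.
#' @export
peg_summary <- function(data, truth = "actual", estimate = "predicted") {
  if (nrow(data) == 0) stop("no prediction pairs", call. = FALSE)
  z <- peg_zone(data[[truth]], data[[estimate]])
  counts <- as.integer(table(z))
  out <- tibble::tibble(
    zone = factor(c("A", "B", "C", "D", "E"), levels = levels(z)),
    count = counts,
    pct = 100 * counts / length(z)
  )
  attr(out, "ab_pct") <- sum(out$pct[out$zone %in% c("A", "B")])
  class(out) <- c("peg_summary", class(out))
  out
}

#' @export
print.peg_summary <- function(x, ...) {
  NextMethod()
  cat(sprintf("A+B: %.2f%%\n", attr(x, "ab_pct")))
  invisible(x)
}

#' Parkes error-grid scatter plot
#'
#' Reference versus predicted glucose with the type-1 zone boundaries
#' overlaid.
#'
#' @param data A data frame of aligned pairs.
#' @param truth,estimate Column names of reference and predicted glucose.
#' @return A ggplot object.
#' @export
plot_peg <- function(data, truth = "actual", estimate = "predicted") {
  bounds <- peg_boundaries()
  lines <- dplyr::bind_rows(lapply(names(bounds), function(side) {
    dplyr::bind_rows(lapply(names(bounds[[side]]), function(zn) {
      b <- bounds[[side]][[zn]]
      tibble::tibble(x = b$x, y = b$y, curve = paste(side, zn))
    }))
  }))
  df <- tibble::tibble(reference = data[[truth]], predicted = data[[estimate]],
                       zone = peg_zone(data[[truth]], data[[estimate]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$curve),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$zone), size = 0.6,
                        alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, 550), ylim = c(0, 550),
                             expand = FALSE) +
    ggplot2::labs(x = "reference glucose (mg/dL)",
                  y = "predicted glucose (mg/dL)", colour = "zone") +
    ggplot2::theme_minimal()
}
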