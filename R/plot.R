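# ggplot2 graphics for scan and diagnostic results.

#' Plot an occupancy scan
#'
#' R factor against trial occupancy, with the optimum marked.
#'
#' @param object An `occupancy_scan` from [estimate_sparse_occupancy()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_scan <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$occupancy, y = .data$r_factor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_occupancy,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "sparse-chain occupancy", y = "R factor",
                  title = sprintf("Occupancy scan (best = %.2f)",
                                  object$best_occupancy)) +
    ggplot2::theme_minimal()
}

#' Plot twin statistics
#'
#' For an L-test, the cumulative distribution of |L| against the
#' untwinned (`N(|L|) = |L|`) and perfect-twin
#' (`N(|L|) = |L| (3 - L^2) / 2`) references. For an H-test, the
#' cumulative distribution of H.
#'
#' @param object A `twin_stats` object from [l_test()] or [h_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twin_stats <- function(object, ...) {
  v <- sort(abs(object$values))
  df <- tibble::tibble(x = v, ecdf = seq_along(v) / length(v))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$ecdf)) +
    ggplot2::geom_step() +
    ggplot2::theme_minimal()
  if (object$test == "L") {
    refs <- tibble::tibble(
      x = seq(0, 1, 0.01),
      untwinned = seq(0, 1, 0.01),
      perfect_twin = seq(0, 1, 0.01) * (3 - seq(0, 1, 0.01)^2) / 2
    ) |>
      tidyr::pivot_longer(-"x", names_to = "reference", values_to = "y")
    p <- p +
      ggplot2::geom_line(data = refs,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      linetype = .data$reference),
                         colour = "grey50") +
      ggplot2::labs(x = "|L|", y = "N(|L|)",
                    title = sprintf("L-test: <|L|> = %.3f, <L2> = %.3f",
                                    object$mean_abs_L, object$mean_L2))
  } else {
    p <- p + ggplot2::labs(x = "H", y = "N(H)",
                           title = sprintf("H-test: alpha = %.3f",
                                           object$alpha_hat))
  }
  p
}
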