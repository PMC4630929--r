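# ggplot2 views of the main result types.

#' @export
autoplot.width_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_frac,
                                       y = .data$extent_px)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_area(alpha = 0.2, fill = "steelblue") +
    ggplot2::labs(x = "depth (fraction of root depth)",
                  y = "horizontal extent (px)",
                  title = "Root width profile")
}

#' @export
autoplot.calibration_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "threshold", "fg_fraction", "n_components"),
    cols = c("fg_fraction", "n_components"),
    names_to = "summary", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~summary, scales = "free_y") +
    ggplot2::labs(x = "segmentation threshold", y = NULL,
                  title = "Threshold calibration sweep")
}

#' Measured-versus-truth validation scatter
#'
#' One panel per trait, measured value against synthetic ground truth,
#' with the identity line; annotates each panel with the coefficient of
#' determination.
#'
#' @param validation tibble with columns `trait`, `truth`, `measured`
#'   (e.g. from [validate_suite()]).
#' @return a ggplot.
#' @export
plot_validation <- function(validation) {
  r2 <- dplyr::summarise(dplyr::group_by(validation, .data$trait),
                         r2 = cor(.data$truth, .data$measured)^2)
  ggplot2::ggplot(validation, ggplot2::aes(x = .data$truth,
                                           y = .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = r2, size = 3, hjust = 0, vjust = 1,
                       ggplot2::aes(x = -Inf, y = Inf,
                                    label = sprintf("  R² = %.3f", .data$r2))) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "ground truth", y = "measured",
                  title = "Synthetic validation")
}

#' Run the pipeline over a rendered synthetic suite and pair measured
#' values with ground truth
#'
#' @param suite result of [make_suite()] with `render = TRUE`.
#' @param config a [pipeline_config()].
#' @param traits which ground-truth traits to compare (default: all
#'   trait ids present in the truth tables).
#' @return a tibble `item`, `trait`, `truth`, `tolerance`, `measured`.
#' @export
validate_suite <- function(suite, config = pipeline_config(),
                           traits = NULL) {
  rows <- lapply(seq_len(nrow(suite)), function(i) {
    res <- process_image(suite$image[[i]], config)
    truth <- suite$truth[[i]]
    truth <- truth[truth$trait != "PIXELS_PER_MM", ]
    if (!is.null(traits)) truth <- truth[truth$trait %in% traits, ]
    measured <- if (is.null(res$record)) rep(NA_real_, nrow(truth)) else {
      vals <- setNames(res$record$value, res$record$trait)
      as.numeric(vals[truth$trait])
    }
    truth_val <- truth$value
    truth_tol <- truth$tolerance
    tibble(item = suite$item[i], trait = truth$trait,
           truth = truth_val, tolerance = truth_tol,
           measured = measured)
  })
  dplyr::bind_rows(rows)
}
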