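# ggplot2 views of the two tabular result types.

#' @exportS3Method ggplot2::autoplot
autoplot.estimate_series <- function(object, ...) {
  model <- attr(object, "model")
  parameter <- attr(object, "parameter")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$i, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "layers",
      y = "estimated dominating-set fraction",
      title = sprintf("Layer recursion (%s, %s = %g)", model,
                      if (identical(model, "kregular")) "k" else "gamma", parameter)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ratio_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::any_of(c("K", "observed_ratio", "predicted_ratio"))),
    cols = c("observed_ratio", "predicted_ratio"),
    names_to = "kind", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$ratio,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "perturbation steps K",
                  y = "multilayer / single-layer MDS size ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
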