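# ggplot2 displays for evaluations and training runs.

#' Plot per-category F1 for an evaluation
#'
#' Bar chart of per-category F1 under strict and relaxed matching, with the
#' micro average drawn as a reference line.
#'
#' @param object A `deid_eval` from [evaluate_corpus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deid_eval <- function(object, ...) {
  d <- tidy(object)
  per_cat <- d[d$category != "micro", ]
  micro <- d[d$category == "micro", ]
  ggplot2::ggplot(per_cat,
                  ggplot2::aes(x = .data$category, y = .data$f1,
                               fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(data = micro,
                        ggplot2::aes(yintercept = .data$f1,
                                     linetype = .data$mode),
                        colour = "grey30") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "F1", fill = "matching",
                  linetype = "micro F1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the training loss curve
#'
#' @param model A `deid_model`.
#' @return A ggplot object of mean per-sentence loss by epoch.
#' @export
plot_training <- function(model) {
  stopifnot(inherits(model, "deid_model"))
  d <- tibble(epoch = seq_along(model$loss), loss = model$loss)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean sentence loss") +
    ggplot2::theme_minimal()
}
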