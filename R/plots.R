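#' Plot a retrieval evaluation
#'
#' * `type = "auprc"` — AUPRC distribution per model (boxplots across
#'   conditions and seeds), models ordered by median AUPRC.
#' * `type = "condition"` — AUPRC distribution per condition.
#' * `type = "imbalance"` — mean AUPRC against imbalance ratio, one line
#'   per model.
#' * `type = "recall"` — mean recall against the top-n cutoff, one line per
#'   model.
#'
#' @param object A `retrieval_eval` object from [evaluate_retrieval()].
#' @param type Which figure to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot retrieval_eval
#' @export
autoplot.retrieval_eval <- function(object,
                                    type = c("auprc", "condition",
                                             "imbalance", "recall"),
                                    ...) {
  type <- match.arg(type)
  res <- object$results
  switch(type,
    auprc = {
      ord <- res |>
        dplyr::group_by(.data$model) |>
        dplyr::summarise(m = stats::median(.data$auprc), .groups = "drop") |>
        dplyr::arrange(dplyr::desc(.data$m))
      res |>
        dplyr::mutate(model = factor(.data$model, levels = ord$model)) |>
        ggplot2::ggplot(ggplot2::aes(x = .data$model, y = .data$auprc)) +
        ggplot2::geom_boxplot(fill = "grey85") +
        ggplot2::labs(x = NULL, y = "AUPRC") +
        ggplot2::coord_flip() +
        ggplot2::theme_minimal()
    },
    condition = {
      ggplot2::ggplot(res, ggplot2::aes(x = .data$condition,
                                        y = .data$auprc)) +
        ggplot2::geom_boxplot(fill = "grey85") +
        ggplot2::labs(x = NULL, y = "AUPRC") +
        ggplot2::coord_flip() +
        ggplot2::theme_minimal()
    },
    imbalance = {
      res |>
        dplyr::group_by(.data$model, .data$imbalance_ratio) |>
        dplyr::summarise(auprc = mean(.data$auprc), .groups = "drop") |>
        dplyr::mutate(imbalance_ratio = factor(
          .data$imbalance_ratio, levels = object$params$ratios)) |>
        ggplot2::ggplot(ggplot2::aes(x = .data$imbalance_ratio,
                                     y = .data$auprc,
                                     group = .data$model,
                                     colour = .data$model)) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::labs(x = "imbalance ratio (other : test)",
                      y = "mean AUPRC", colour = "model") +
        ggplot2::theme_minimal()
    },
    recall = {
      object$recall |>
        dplyr::group_by(.data$model, .data$n) |>
        dplyr::summarise(recall = mean(.data$recall), .groups = "drop") |>
        ggplot2::ggplot(ggplot2::aes(x = .data$n, y = .data$recall,
                                     colour = .data$model)) +
        ggplot2::geom_line() +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "top n", y = "mean recall", colour = "model") +
        ggplot2::theme_minimal()
    }
  )
}

#' @rdname autoplot.retrieval_eval
#' @param x A `retrieval_eval` object.
#' @export
plot.retrieval_eval <- function(x, type = "auprc", ...) {
  print(autoplot.retrieval_eval(x, type = type, ...))
}
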