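#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training fit
#'
#' @param x A `cq_fit` from [cq_train()].
#' @param ... Unused.
#' @return The per-epoch history as a tibble (`epoch`, `loss`,
#'   `train_accuracy`, `val_accuracy`).
#' @export
tidy.cq_fit <- function(x, ...) x$history

#' @rdname tidy.cq_fit
#' @return For `glance()`: a one-row tibble summarizing the fit.
#' @export
glance.cq_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(variant = x$model$cfg$variant, omega = x$model$cfg$omega,
                 optimizer = x$cfg$optimizer, epochs = nrow(x$history),
                 final_loss = last$loss,
                 final_train_accuracy = last$train_accuracy,
                 final_val_accuracy = last$val_accuracy,
                 n_parameters = attr(count_parameters(x$model$cfg),
                                     "grand_total"))
}

#' Tidy multi-run convergence diagnostics
#'
#' @param x A `cq_convergence` from [run_repeated()].
#' @param ... Unused.
#' @return `tidy()`: the per-run, per-epoch curves tibble. `glance()`: a
#'   one-row tibble with the ANOVA F statistic and p-value.
#' @export
tidy.cq_convergence <- function(x, ...) x$curves

#' @rdname tidy.cq_convergence
#' @export
glance.cq_convergence <- function(x, ...) {
  tibble::tibble(runs = length(x$final_accuracy),
                 epochs = max(x$curves$epoch), k = x$k,
                 anova_f = x$anova_f, anova_p = x$anova_p,
                 mean_final_accuracy = mean(x$final_accuracy),
                 sd_final_accuracy = stats::sd(x$final_accuracy))
}

#' Tidy an evaluation report
#'
#' @param x A `cq_metrics` from [evaluate_model()].
#' @param ... Unused.
#' @return A long tibble with columns `metric` and `value`.
#' @export
tidy.cq_metrics <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "precision", "recall", "f1",
                  "specificity", "accuracy"),
    cols = dplyr::everything(), names_to = "metric", values_to = "value")
}

#' Mean and standard deviation of metrics over repeated evaluations
#'
#' @param reports A list of `cq_metrics` rows (one per run).
#' @return A tibble with `metric`, `mean`, `sd` over runs.
#' @export
summarize_metrics <- function(reports) {
  long <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    dplyr::mutate(tidy.cq_metrics(reports[[i]]), run = i)
  }))
  dplyr::summarise(dplyr::group_by(long, .data$metric),
                   mean = mean(.data$value), sd = stats::sd(.data$value),
                   .groups = "drop")
}
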