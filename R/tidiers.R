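# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @describeIn epe tidy method: one row per background sequence
#'   (`log2_ratio`), with the pattern and class attached.
#' @param x An `epe_result`.
#' @param ... Unused.
#' @method tidy epe_result
#' @export
tidy.epe_result <- function(x, ...) {
  tibble(pattern_id = x$pattern_id, class = x$class_name,
         background = seq_along(x$log2_ratios), log2_ratio = x$log2_ratios)
}

#' @describeIn epe glance method: one-row summary (`alpha`, `W`, `p_value`,
#'   `p_adjusted`, `M`, `n_zero_dropped`).
#' @method glance epe_result
#' @export
glance.epe_result <- function(x, ...) {
  tibble(pattern_id = x$pattern_id, class = x$class_name, alpha = x$alpha,
         W = x$W, p_value = x$p_value, p_adjusted = x$p_adjusted, M = x$M,
         n_zero_dropped = x$n_zero_dropped)
}

#' @describeIn depe tidy method: one row per background sequence
#'   (`log2_ratio_diff`).
#' @param x A `depe_result`.
#' @param ... Unused.
#' @method tidy depe_result
#' @export
tidy.depe_result <- function(x, ...) {
  tibble(pattern_id = x$pattern_id, class1 = x$class_pair[1],
         class2 = x$class_pair[2], background = seq_along(x$per_seq),
         log2_ratio_diff = x$per_seq)
}

#' @describeIn depe glance method: one-row summary.
#' @method glance depe_result
#' @export
glance.depe_result <- function(x, ...) {
  tibble(pattern_id = x$pattern_id, class1 = x$class_pair[1],
         class2 = x$class_pair[2], depe = x$depe, W = x$W,
         p_value = x$p_value, p_adjusted = x$p_adjusted, M = x$M,
         n_zero_dropped = x$n_zero_dropped)
}

#' @describeIn train_ensemble tidy method: the per-member, per-epoch
#'   training log.
#' @param x A `model_ensemble`.
#' @param ... Unused.
#' @method tidy model_ensemble
#' @export
tidy.model_ensemble <- function(x, ...) {
  as_tibble(x$training_log)
}

#' @describeIn train_ensemble glance method: one-row configuration and
#'   training summary.
#' @method glance model_ensemble
#' @export
glance.model_ensemble <- function(x, ...) {
  tibble(
    n_members = length(x$members),
    n_classes = x$config$n_classes,
    window_length = x$config$window_length,
    epochs = x$config$epochs,
    seed = x$config$seed,
    trained = x$trained,
    final_validation_loss = if (nrow(x$training_log) &&
                                !all(is.na(x$training_log$validation_loss))) {
      mean(vapply(split(x$training_log, x$training_log$member), function(d) {
        d$validation_loss[which.min(d$validation_loss)]
      }, numeric(1)))
    } else NA_real_
  )
}

#' @describeIn spacing_scan autoplot method: EPE alpha against spacing.
#' @param object A `spacing_scan` tibble.
#' @param ... Unused.
#' @method autoplot spacing_scan
#' @export
autoplot.spacing_scan <- function(object, ...) {
  ggplot(object, aes(x = .data$spacing, y = .data$alpha,
                     colour = .data$order)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "spacing (bp)", y = "Expected Pattern Effect (alpha)",
         colour = "motif order") +
    theme_bw()
}

#' @describeIn motif_screen autoplot method: effect size against the
#'   normalized signed-rank statistic, significant motifs highlighted.
#' @param object A `motif_screen` tibble.
#' @param alpha_level Significance threshold on `p_adjusted` (default 0.05).
#' @param ... Unused.
#' @method autoplot motif_screen
#' @export
autoplot.motif_screen <- function(object, alpha_level = 0.05, ...) {
  object$significant <- object$p_adjusted < alpha_level
  xlab <- if (all(object$mode == "depe")) {
    "DEPE (mean log2 ratio difference)"
  } else {
    "EPE (alpha)"
  }
  ggplot(object, aes(x = .data$effect, y = .data$W,
                     colour = .data$significant)) +
    geom_point() +
    labs(x = xlab, y = "normalized signed-rank statistic W",
         colour = paste0("p_adj < ", alpha_level)) +
    theme_bw()
}

#' @describeIn differential_saliency autoplot method: per-position
#'   differential importance.
#' @param object A `saliency` tibble.
#' @param ... Unused.
#' @method autoplot saliency
#' @export
autoplot.saliency <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$score)) +
    geom_col() +
    labs(x = "position (bp)", y = "differential importance") +
    theme_bw()
}

#' @describeIn evaluate_ensemble autoplot method: per-class metric bars.
#' @param object Metric tibble from [evaluate_ensemble()].
#' @param ... Unused.
#' @export
plot_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("auroc", "auprc", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$class, y = .data$value)) +
    geom_col() +
    ggplot2::facet_wrap(~metric) +
    labs(x = NULL, y = NULL) +
    theme_bw()
}
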