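#' Plot a sweep family
#'
#' @param object A [sweep_set()].
#' @param ... Unused.
#' @return A ggplot object: one line per sweep, coloured by step level.
#' @export
autoplot.ck_sweep_set <- function(object, ...) {
  long <- tidy(object)
  ylab <- if (object$traces[[1]]$kind == "voltage") "V (mV)" else "I (pA)"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     group = .data$sweep,
                                     colour = .data$step)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ylab, colour = "step",
                  title = object$cell_id) +
    ggplot2::theme_minimal()
}

#' Plot a synaptic recording with detected or true events marked
#'
#' @param object A `ck_synth_recording` (or a current [trace()]).
#' @param events Optional event table with `time_s` (defaults to the
#'   recording's ground truth).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ck_synth_recording <- function(object, events = NULL, ...) {
  tr <- object$trace
  events <- events %||% object$events
  long <- tidy(tr)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "I (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    gg <- gg + ggplot2::geom_rug(data = events, sides = "t",
                                 ggplot2::aes(x = .data$time_s, y = NULL))
  }
  gg
}

#' Plot current-voltage curves from a voltage-clamp feature set
#'
#' @param object A `ck_vclamp_features` object (see [vclamp_features()]).
#' @param ... Unused.
#' @return A ggplot object with the Na, fast-K and slow-K I-V curves.
#' @export
autoplot.ck_vclamp_features <- function(object, ...) {
  long <- tidyr::pivot_longer(object$iv, -"v_cmd_mV",
                              names_to = "component", values_to = "i_pA")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$v_cmd_mV, y = .data$i_pA,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "command (mV)", y = "peak I (pA)", colour = NULL) +
    ggplot2::theme_minimal()
}
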