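#' Maturation trajectory comparison grid
#'
#' For each measure and week-in-culture, compares the mutant cells
#' against the control cells ([compare_groups()]) and tabulates both
#' group summaries, the t-test, stars, percent change, and the sign of
#' the mutant-minus-control difference. This is the per-study summary
#' grid of how a phenotype progresses over maturation.
#'
#' @param features Feature table (one row per cell) with `genotype`,
#'   `week`, and the measure columns; e.g. from [cohort_features()].
#' @param measures Character vector of feature columns to compare.
#' @param reference,comparison Genotype labels of the two groups.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#'
#' @return A tibble of class `ck_trajectory` with one row per
#'   measure-week cell of the grid, columns as [compare_groups()] plus
#'   `week` and `direction` (sign of mutant minus control means).
#' @export
trajectory_table <- function(features,
                             measures = c("total_evoked", "max_per_step",
                                          "fahp_mV", "amplitude_mV",
                                          "fwhm_ms", "threshold_mV",
                                          "capacitance_pF", "epsc_rate_hz",
                                          "burst_rate_hz", "interburst_s"),
                             reference = "control", comparison = "mutant",
                             welch = FALSE) {
  stopifnot(is.data.frame(features))
  measures <- intersect(measures, names(features))
  if (length(measures) == 0) stop("no requested measure columns present", call. = FALSE)
  weeks <- sort(unique(features$week))
  grid <- purrr::map_dfr(weeks, function(w) {
    fw <- features[features$week == w, ]
    for (g in c(reference, comparison)) {
      if (sum(fw$genotype == g, na.rm = TRUE) == 0) {
        stop("missing condition '", g, "' at week ", w, call. = FALSE)
      }
    }
    purrr::map_dfr(measures, function(m) {
      a <- fw[[m]][fw$genotype == reference]
      b <- fw[[m]][fw$genotype == comparison]
      if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
        return(tibble::tibble(week = w, measure = m,
                              n_a = sum(!is.na(a)), n_b = sum(!is.na(b)),
                              degenerate = NA))
      }
      row <- compare_groups(a, b, measure = m, welch = welch)
      row$week <- w
      row
    })
  })
  grid$direction <- sign(grid$mean_b - grid$mean_a)
  grid <- dplyr::relocate(grid, "week", "measure")
  class(grid) <- c("ck_trajectory", class(grid))
  grid
}

#' Plot a maturation trajectory grid
#'
#' Group means with SEM error bars per week, one facet per measure,
#' significance stars above each week.
#'
#' @param object A `ck_trajectory` grid from [trajectory_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ck_trajectory <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(week = object$week, measure = object$measure,
                   group = "control", mean = object$mean_a, sem = object$sem_a),
    tibble::tibble(week = object$week, measure = object$measure,
                   group = "mutant", mean = object$mean_b, sem = object$sem_b)
  )
  anno <- tibble::tibble(week = object$week, measure = object$measure,
                         stars = object$stars,
                         y = pmax(object$mean_a + object$sem_a,
                                  object$mean_b + object$sem_b, na.rm = TRUE))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::geom_text(data = anno, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$week, y = .data$y,
                                    label = .data$stars),
                       vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "weeks in culture", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
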