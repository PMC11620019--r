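#' Plot one panel of a dashboard bundle
#'
#' ggplot2 renderings of the dashboard panels: a bar series over time,
#' sex / age / unit bar charts, and the dosage-status bars. The coverage
#' gauge is a single-bar proportion chart.
#'
#' @param object a `cypddi_bundle`.
#' @param panel which panel to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cypddi_bundle <- function(object,
                                   panel = c("time_series", "sex", "age",
                                             "units", "coverage", "status"),
                                   ...) {
  panel <- rlang::arg_match(panel)
  title <- sprintf("%s: %s %s %s", object$cytochrome, object$substrate,
                   object$relation, object$perpetrator)
  p <- switch(panel,
    time_series = ggplot2::ggplot(object$time_series,
        ggplot2::aes(x = .data$bin_start, y = .data$n_patients)) +
      ggplot2::geom_col(fill = "#4878a8") +
      ggplot2::labs(x = NULL, y = "Affected patients",
                    subtitle = "Affected patients over time"),
    sex = ggplot2::ggplot(object$sex,
        ggplot2::aes(x = .data$sex, y = .data$n)) +
      ggplot2::geom_col(fill = "#4878a8") +
      ggplot2::labs(x = "Sex", y = "Patients",
                    subtitle = "Distribution by sex"),
    age = ggplot2::ggplot(object$age,
        ggplot2::aes(x = .data$band, y = .data$n)) +
      ggplot2::geom_col(fill = "#4878a8") +
      ggplot2::labs(x = "Age band", y = "Patients",
                    subtitle = "Distribution by age band"),
    units = ggplot2::ggplot(object$units,
        ggplot2::aes(x = stats::reorder(.data$unit, .data$n_patients),
                     y = .data$n_patients)) +
      ggplot2::geom_col(fill = "#4878a8") + ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "Patients",
                    subtitle = "Distribution by medical unit"),
    coverage = {
      cov <- object$dosage_coverage
      df <- tibble(what = "coverage",
                   covered = ifelse(is.na(cov), 0, cov))
      ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$covered)) +
        ggplot2::geom_col(fill = "#2a6f4e", width = 0.4) +
        ggplot2::scale_y_continuous(limits = c(0, 1),
                                    labels = function(x) paste0(100 * x, "%")) +
        ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = NULL,
                      subtitle = sprintf("Pharmacology dosage coverage: %s",
                                         ifelse(is.na(cov), "n/a",
                                                sprintf("%.1f%%", 100 * cov))))
    },
    status = ggplot2::ggplot(object$dosage_status,
        ggplot2::aes(x = .data$status, y = .data$n)) +
      ggplot2::geom_col(fill = "#4878a8") +
      ggplot2::labs(x = "Status", y = "Dosage events",
                    subtitle = "Dosage results by patient status"))
  p + ggplot2::ggtitle(title) + ggplot2::theme_minimal()
}
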