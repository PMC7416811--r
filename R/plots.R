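#' @importFrom ggplot2 ggplot aes geom_step geom_point geom_line geom_col
#'   geom_tile geom_boxplot facet_wrap labs scale_fill_gradient autoplot
NULL

#' Plot Kaplan-Meier curves
#'
#' Step curves per group with vertical ticks at right-censored times.
#'
#' @param object A `km_curve` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  has_group <- "group" %in% names(object)
  base <- dplyr::bind_rows(
    if (has_group) {
      dplyr::group_modify(dplyr::group_by(object, .data$group), function(d, g) {
        dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), d)
      })
    } else {
      dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), object)
    })
  censored <- object[object$n_censor > 0, ]
  p <- if (has_group) {
    ggplot(base, aes(.data$time, .data$survival,
                     colour = factor(.data$group))) +
      labs(colour = "cluster")
  } else {
    ggplot(base, aes(.data$time, .data$survival))
  }
  p + geom_step() +
    geom_point(data = censored, shape = 3) +
    labs(x = "time (months)", y = "overall survival") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot consensus-clustering diagnostics
#'
#' @param object A `consensus_result`.
#' @param type `"cdf"` (consensus CDFs per k), `"delta"` (delta-area plot),
#'   `"heatmap"` (consensus matrix at `k`), or `"tracking"` (per-patient
#'   assignments across k).
#' @param k Which k for `type = "heatmap"` (default: the selected k).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object,
                                      type = c("cdf", "delta", "heatmap",
                                               "tracking"),
                                      k = object$selected_k, ...) {
  type <- match.arg(type)
  switch(type,
    cdf = ggplot(object$cdf,
                 aes(.data$consensus_value, .data$cdf,
                     colour = factor(.data$k))) +
      geom_line() + labs(x = "consensus value", y = "CDF", colour = "k"),
    delta = ggplot(object$areas, aes(.data$k, .data$delta)) +
      geom_point() + geom_line() +
      labs(x = "number of clusters k", y = "relative change in area under CDF"),
    heatmap = {
      M <- object$consensus[[paste0("k", k)]]
      ord <- order(consensus_assignment(object, k))
      df <- tidyr::expand_grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
      df$consensus <- M[ord, ord][as.matrix(df)]
      ggplot(df, aes(.data$col, .data$row, fill = .data$consensus)) +
        geom_tile() +
        scale_fill_gradient(low = "white", high = "darkblue", limits = c(0, 1)) +
        labs(x = NULL, y = NULL, title = sprintf("consensus matrix, k = %d", k))
    },
    tracking = {
      long <- tidyr::pivot_longer(object$assignments, -"patient_id",
                                  names_to = "k", values_to = "cluster")
      long$k <- as.integer(sub("^k", "", long$k))
      ggplot(long, aes(.data$patient_id, factor(.data$k),
                       fill = factor(.data$cluster))) +
        geom_tile() +
        labs(x = "patient", y = "k", fill = "cluster") +
        ggplot2::theme(axis.text.x = ggplot2::element_blank())
    })
}

#' Normalised biomarker patterns per cluster
#'
#' Boxplots of the min-max normalised biomarker values, faceted by biomarker
#' and grouped by cluster.
#'
#' @param report A `characterization_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_biomarker_patterns <- function(report, ...) {
  norm <- report$normalized_biomarkers
  norm$cluster <- factor(report$assignment)
  long <- tidyr::pivot_longer(norm,
                              cols = -dplyr::any_of(c("patient_id", "cluster")),
                              names_to = "biomarker", values_to = "value")
  ggplot(long, aes(.data$cluster, .data$value, fill = .data$cluster)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~biomarker) +
    labs(x = "cluster", y = "normalised value")
}
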