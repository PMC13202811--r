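#' Plot the k-selection scan
#'
#' Silhouette and Calinski-Harabasz curves over the scanned cluster numbers,
#' each on its own scale, with the chosen k marked.
#'
#' @param x an `mm_kselect` from [select_k()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_k_selection <- function(x, ...) {
  long <- tidyr::pivot_longer(x$report, c("silhouette", "chi"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$chosen_k, linetype = "dashed") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = x$report$k) +
    ggplot2::labs(x = "number of clusters", y = NULL,
                  title = sprintf("k-selection (chosen k = %d)", x$chosen_k))
}

#' @export
autoplot.mm_kselect <- function(object, ...) plot_k_selection(object, ...)

#' Plot per-cluster community profiles
#'
#' Median relative abundance of the most abundant taxa by cluster.
#'
#' @param profiles tibble from [cluster_profile_summary()].
#' @param rank which rank rows to plot (`"taxon"` or the higher rank).
#' @param top_n number of taxa shown (ranked by maximum median abundance).
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(profiles, rank = "taxon", top_n = 12) {
  df <- profiles[profiles$rank == rank, ]
  keep <- df |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(top = max(.data$median_ra)) |>
    dplyr::arrange(dplyr::desc(.data$top)) |>
    utils::head(top_n)
  df <- df[df$taxon %in% keep$taxon, ]
  df$taxon <- factor(df$taxon, levels = rev(keep$taxon))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$taxon,
                                   fill = .data$median_ra)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 name = "median RA") +
    ggplot2::labs(x = "cluster", y = NULL)
}

#' Volcano plot of EWAS contrasts
#'
#' Beta-scale effect (percentage points) against -log10 p, faceted by
#' contrast, with the significance threshold drawn.
#'
#' @param contrasts an `mm_contrasts` tibble (after [adjust_contrasts()]).
#' @param threshold raw-p significance cut to draw.
#' @return A ggplot object.
#' @export
plot_volcano <- function(contrasts, threshold = NULL) {
  g <- ggplot2::ggplot(contrasts,
                       ggplot2::aes(x = .data$delta_beta_pct,
                                    y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "difference in % methylation", y = "-log10 p")
  if (!is.null(threshold))
    g <- g + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  g
}

#' Plot epigenetic age against chronological age
#'
#' @param x an `mm_epiage` from [compute_ead()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_epi_age <- function(x, ...) {
  ggplot2::ggplot(x$table, ggplot2::aes(x = .data$chron_age,
                                        y = .data$epi_age)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue4") +
    ggplot2::labs(x = "chronological age (years)",
                  y = "epigenetic age (years)",
                  title = sprintf("r = %.2f, MAE = %.2f years", x$r, x$mae))
}

#' @export
autoplot.mm_epiage <- function(object, ...) plot_epi_age(object, ...)
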