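#' Plot cluster regulation profiles
#'
#' Log2-ratio profiles of every site, one panel per cluster, with the
#' cluster mean overlaid — the standard view for judging whether clusters
#' captured distinct temporal archetypes.
#'
#' @param qt A complete [quant_tbl].
#' @param clusters `site_clusters` for `qt`.
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(qt, clusters) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(qt), site_id = site_ids(qt),
                  cluster = clusters$cluster[match(site_ids(qt),
                                                   clusters$site_id)]),
    dplyr::all_of(quant_conditions(qt)),
    names_to = "condition", values_to = "ratio")
  long$condition <- factor(long$condition, levels = quant_conditions(qt))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = log2(.data$ratio),
                                     group = .data$site_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40") +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "firebrick",
                          linewidth = 1) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "condition", y = "log2 ratio") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rwhn_ranking <- function(object, top_n = 10, ...) {
  top <- dplyr::slice_min(dplyr::group_by(tidy(object), .data$seed_cluster),
                          .data$rank, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(top, ggplot2::aes(x = factor(.data$seed_cluster),
                                    y = stats::reorder(.data$term_name,
                                                       -.data$rank),
                                    fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "seed cluster", y = NULL,
                  fill = "steady-state\nprobability",
                  title = "Top-ranked function terms per seed cluster") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rwhn_permtest <- function(object, ...) {
  nulls <- attr(object, "null_ranks")
  obs <- tidy(object)
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey40") +
    ggplot2::geom_rug(data = obs[obs$p_adjusted < 0.05, ],
                      ggplot2::aes(x = .data$observed_rank),
                      colour = "firebrick") +
    ggplot2::facet_wrap(~seed_cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "term rank under permutation null",
                  y = "density",
                  title = "Null rank distributions (significant observed ranks in red)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
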