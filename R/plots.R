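#' Plot session traces with stimulation onsets
#'
#' @param session a `us_session`.
#' @param neurons neuron indices to show (default first 6).
#' @param train_list optional list of `event_train` to overlay detected rising
#'   phases.
#' @return a ggplot.
#' @export
plot_session_traces <- function(session, neurons = NULL, train_list = NULL) {
  if (is.null(neurons)) neurons <- seq_len(min(6L, nrow(session$traces)))
  df <- purrr::map_dfr(neurons, function(i) {
    tibble(neuron = i, time_s = session$time, dff = session$traces[i, ])
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = session$trials$onset_s,
                        colour = "purple", alpha = 0.4, linewidth = 0.2) +
    ggplot2::facet_wrap(~neuron, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F))
  if (!is.null(train_list)) {
    rise <- purrr::map_dfr(neurons, function(i) {
      ev <- train_list[[i]]$events
      if (nrow(ev) == 0L) return(NULL)
      mutate(ev, neuron = i)
    })
    if (nrow(rise) > 0) {
      p <- p + ggplot2::geom_segment(
        data = rise,
        ggplot2::aes(x = .data$rise_start_s, xend = .data$peak_s,
                     y = 0, yend = 0),
        colour = "black", linewidth = 1, inherit.aes = FALSE)
    }
  }
  p
}

#' Plot a shuffled-baseline distribution with the observed density
#'
#' @param dist a `shuffle_dist`.
#' @param observed observed stimulation-window event density.
#' @return a ggplot.
#' @export
plot_shuffle <- function(dist, observed = NULL) {
  df <- tibble(density = dist$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$density)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = dist$p95, linetype = "dashed",
                        colour = "darkgreen") +
    ggplot2::labs(x = "shuffled mean event density", y = "iterations")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "purple")
  }
  p
}

#' Plot group-averaged transient ACC time courses
#'
#' @param tacc a [transient_acc()] table with a `group` column.
#' @return a ggplot.
#' @export
plot_transient_acc <- function(tacc) {
  df <- tacc %>%
    group_by(.data$group, .data$bin_rel_s) %>%
    summarise(acc = mean(.data$acc, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_rel_s + 0.5, y = .data$acc,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 1), colour = "purple",
                        alpha = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "time from onset (s)", y = "transient ACC",
                  colour = "pair group")
}

#' Plot per-gene expression distributions of two populations
#'
#' Density histograms of normalized expression per population (expressing cells
#' only), the display behind the effect-size comparison.
#'
#' @param counts cells x genes UMI matrix.
#' @param labels population label per cell.
#' @param gene gene (column) name.
#' @param populations length-2 populations to compare.
#' @return a ggplot.
#' @export
plot_expression_density <- function(counts, labels, gene, populations = NULL) {
  labels <- as.character(labels)
  if (is.null(populations)) populations <- unique(labels)[1:2]
  norm <- normalize_umi(as.matrix(counts))
  df <- purrr::map_dfr(populations, function(p) {
    v <- norm[labels == p, gene]
    tibble(population = p, expression = v[counts[labels == p, gene] > 0])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expression,
                                   fill = .data$population)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = sprintf("%s log2 normalized expression", gene),
                  y = "density")
}
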