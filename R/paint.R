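# Chromosome painting and contribution barplots.
#
# Plot functions are pure consumers of the tidy tables the pipeline emits:
# they never modify their inputs, and every table they draw is also
# available as TSV so users can build custom ggplot2 figures without
# re-running the pipeline.

#' Default ancestry colors
#'
#' One fixed color per label, used identically across all panels of a
#' figure: Parent1 blue, Parent2 red, Unknown gray.
#'
#' @return Named character vector of colors over [ancestry_levels()].
#' @export
ancestry_colors <- function() {
  c(Parent1 = "#3B6FB6", Parent2 = "#C23B3B", Unknown = "grey65")
}

#' Paint chromosomes by ancestry
#'
#' Draws one horizontal track per (individual, chromosome) with segments
#' colored by ancestry label spanning `[start, end]`, assembled into a
#' composite panel grid (rows = individuals, columns = chromosomes) with a
#' shared legend. Readable by construction up to roughly 200 individuals
#' and 40 chromosomes; larger tables still render, with a warning about
#' readability.
#'
#' @param clusters Cluster tibble (`ancestry_blocks` or the TSV read back)
#'   with columns (`individual`,) `chrom`, `start`, `end`, `label`.
#' @param colors Named label-to-color map; default [ancestry_colors()].
#' @param chrom_lengths Optional named vector of chromosome lengths used
#'   to scale each chromosome's axis; by default each chromosome's axis
#'   runs from 1 to the largest cluster end across individuals, keeping
#'   tracks comparable without a reference index.
#' @param out Optional output path prefix; when given, `<out>.png` and
#'   `<out>.pdf` are written.
#' @param width,height,dpi Device settings for saved figures; height
#'   defaults to scale with the number of individuals.
#' @return The ggplot object, invisibly when `out` is given.
#' @details Rows whose `label` is not a key of `colors` are an error
#'   listing the offending rows.
#' @export
#' @examples
#' cl <- tibble::tibble(individual = "off_1", chrom = "chr1",
#'                      start = 1L, end = 1000L, label = "Parent1")
#' paint_chromosomes(cl)
paint_chromosomes <- function(clusters, colors = ancestry_colors(),
                              chrom_lengths = NULL, out = NULL,
                              width = NULL, height = NULL, dpi = 300) {
  check_cols(clusters, c("chrom", "start", "end", "label"), "clusters")
  if (nrow(clusters) == 0L) {
    stop("Empty cluster table: nothing to paint.", call. = FALSE)
  }
  d <- tibble::as_tibble(clusters)
  if (!"individual" %in% names(d)) d$individual <- "offspring"
  bad <- !d$label %in% names(colors)
  if (any(bad)) {
    stop("Unknown ancestry label(s) in cluster table rows ",
         paste(head(which(bad), 5L), collapse = ", "), ": ",
         paste(unique(d$label[bad]), collapse = ", "), call. = FALSE)
  }
  n_ind <- dplyr::n_distinct(d$individual)
  n_chr <- dplyr::n_distinct(d$chrom)
  if (n_ind > 200 || n_chr > 40) {
    warning("Painting ", n_ind, " individuals x ", n_chr, " chromosomes; ",
            "the composite may not be readable at this size.",
            call. = FALSE)
  }
  d$label <- factor(d$label, names(colors))

  p <- ggplot2::ggplot(
    d,
    ggplot2::aes(xmin = .data$start, xmax = .data$end,
                 ymin = 0, ymax = 1, fill = .data$label)
  ) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(individual ~ chrom, scales = "free_x",
                        space = "free_x", switch = "y") +
    ggplot2::scale_fill_manual(values = colors, name = "Ancestry",
                               drop = FALSE) +
    ggplot2::scale_x_continuous(
      labels = function(x) paste0(x / 1e6, " Mb"),
      expand = ggplot2::expansion(mult = c(0.01, 0.01))
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank(),
      strip.text.y.left = ggplot2::element_text(angle = 0),
      legend.position = "bottom"
    )
  if (!is.null(chrom_lengths)) {
    lens <- tibble::tibble(chrom = names(chrom_lengths),
                           len = as.numeric(chrom_lengths))
    lens <- lens[lens$chrom %in% d$chrom, , drop = FALSE]
    p <- p + ggplot2::geom_blank(
      data = lens, mapping = ggplot2::aes(x = .data$len),
      inherit.aes = FALSE
    )
  }
  if (!is.null(out)) {
    if (is.null(width)) width <- max(6, 2.5 * n_chr)
    if (is.null(height)) height <- max(2, 0.6 * n_ind + 1)
    save_figure(p, out, width, height, dpi)
    return(invisible(p))
  }
  p
}

#' Stacked barplots of parental contributions
#'
#' Renders genome-percent or gene-percent tables as stacked bars, one bar
#' per individual, faceted by chromosome, with the same fixed colors as
#' the painting.
#'
#' @param rows An `ancestry_contributions` tibble (wide, from
#'   [genome_contributions()] or [gene_percentages()]) or a long tibble
#'   with columns `individual`, `chrom`, `label`, `pct`.
#' @inheritParams paint_chromosomes
#' @return The ggplot object, invisibly when `out` is given.
#' @details Negative percentages are an error; each bar's percentages are
#'   expected to sum to ~100.
#' @export
plot_contributions <- function(rows, colors = ancestry_colors(),
                               out = NULL, width = NULL, height = 4,
                               dpi = 300) {
  long <- if (all(c("label", "pct") %in% names(rows))) {
    d <- tibble::as_tibble(rows)
    if (!"individual" %in% names(d)) d$individual <- "offspring"
    d
  } else {
    contributions_long(rows)
  }
  if (any(long$pct < 0)) {
    stop("Negative percentage(s) in contribution table.", call. = FALSE)
  }
  bad <- !long$label %in% names(colors)
  if (any(bad)) {
    stop("Unknown ancestry label(s): ",
         paste(unique(long$label[bad]), collapse = ", "), call. = FALSE)
  }
  long$label <- factor(long$label, rev(names(colors)))

  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$individual, y = .data$pct, fill = .data$label)
  ) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::scale_fill_manual(
      values = colors, name = "Ancestry",
      breaks = names(colors), drop = FALSE
    ) +
    ggplot2::labs(x = NULL, y = "Contribution (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
      legend.position = "bottom"
    )
  if (!is.null(out)) {
    if (is.null(width)) {
      width <- max(5, 1.2 * dplyr::n_distinct(long$chrom) *
                     (0.4 + 0.25 * dplyr::n_distinct(long$individual)))
    }
    save_figure(p, out, width, height, dpi)
    return(invisible(p))
  }
  p
}

save_figure <- function(p, out, width, height, dpi) {
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(paste0(out, ".png"), p, width = width, height = height,
                  dpi = dpi, limitsize = FALSE)
  ggplot2::ggsave(paste0(out, ".pdf"), p, width = width, height = height,
                  limitsize = FALSE)
  invisible(c(paste0(out, ".png"), paste0(out, ".pdf")))
}

#' @rdname paint_chromosomes
#' @param object An `ancestry_blocks` tibble.
#' @param ... Passed to [paint_chromosomes()].
#' @export
autoplot.ancestry_blocks <- function(object, ...) {
  paint_chromosomes(object, ...)
}

#' @rdname plot_contributions
#' @param object An `ancestry_contributions` tibble.
#' @param ... Passed to [plot_contributions()].
#' @export
autoplot.ancestry_contributions <- function(object, ...) {
  plot_contributions(object, ...)
}
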