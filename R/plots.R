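#' Diagram a guide sequence with its seed definitions
#'
#' Draws the guide 5'->3', one nucleotide per position, with a labelled box
#' per seed definition underneath; the default definition (mer7m8) is
#' highlighted. The returned object carries the layout table the figure was
#' drawn from, so structure can be checked without pixel comparison.
#'
#' @param guide A \code{guide_sequence} or guide strand string.
#' @param definitions Character vector of built-in definition names, or a
#'   data.frame with columns \code{name}, \code{start}, \code{stop}.
#' @param highlight Name of the definition to highlight (default
#'   \code{"mer7m8"}; ignored if not drawn).
#' @param file Optional output path; the format follows the extension
#'   (\code{.pdf} recommended, \code{.png}/\code{.svg} supported by the
#'   available devices).
#' @param width,height Figure size in inches when writing a file.
#' @return A \code{seed_diagram}: list with \code{plot} (ggplot),
#'   \code{layout} (data.frame: \code{name}, \code{start}, \code{stop},
#'   \code{row}, \code{highlighted}) and \code{guide}. Invisibly when
#'   \code{file} is given.
#' @export
plot_seeds <- function(guide, definitions = c("mer8", "mer7m8", "mer7A1",
                                              "mer6"),
                       highlight = "mer7m8", file = NULL,
                       width = 7, height = 3) {
  if (is.character(guide)) guide <- guide_sequence(guide)
  stopifnot(inherits(guide, "guide_sequence"))
  n <- nchar(guide$sequence)
  if (is.character(definitions)) {
    defs <- do.call(rbind, lapply(definitions, function(nm) {
      d <- resolve_seed_definition(nm)
      data.frame(name = d$name, start = d$start, stop = d$stop,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stopifnot(is.data.frame(definitions),
              all(c("name", "start", "stop") %in% names(definitions)))
    defs <- definitions[, c("name", "start", "stop")]
  }
  if (any(defs$start < 1L | defs$stop > n | defs$start > defs$stop))
    stop("a seed definition window falls outside the guide (length ", n, ")")
  layout <- data.frame(defs, row = seq_len(nrow(defs)),
                       highlighted = defs$name == highlight,
                       stringsAsFactors = FALSE)

  letters_df <- data.frame(pos = seq_len(n),
                           nt = strsplit(guide$sequence, "")[[1]])
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = layout,
      ggplot2::aes(xmin = .data$start - 0.45, xmax = .data$stop + 0.45,
                   ymin = -.data$row - 0.35, ymax = -.data$row + 0.35,
                   fill = .data$highlighted),
      colour = "grey30", linewidth = 0.3, show.legend = FALSE) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$stop + 0.9, y = -.data$row,
                   label = .data$name),
      hjust = 0, size = 3.2) +
    ggplot2::geom_text(data = letters_df,
                       ggplot2::aes(x = .data$pos, y = 0,
                                    label = .data$nt),
                       family = "mono", size = 4) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b598d6",
                                          `FALSE` = "grey85")) +
    ggplot2::annotate("text", x = 0.4, y = 0, label = "5'", hjust = 1) +
    ggplot2::annotate("text", x = n + 0.6, y = 0, label = "3'", hjust = 0) +
    ggplot2::coord_cartesian(xlim = c(-0.5, n + 4)) +
    ggplot2::labs(title = paste0("Seed definitions for ", guide$name)) +
    ggplot2::theme_void()

  out <- structure(list(plot = p, layout = layout, guide = guide),
                   class = "seed_diagram")
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(out))
  }
  out
}

#' @export
print.seed_diagram <- function(x, ...) { print(x$plot); invisible(x) }

#' ECDF comparison plot for a group split
#'
#' Draws the two log2 fold-change ECDF step curves (match group vs
#' background) with group sizes in the legend and, when a KS result is
#' supplied, the D statistic and p-value in an annotation box. Curve points
#' come directly from [ecdf_table()]; the plot never recomputes statistics.
#'
#' @param split A \code{group_split}.
#' @param ks Optional \code{ks_result} to annotate with.
#' @param file Optional output path (vector format recommended).
#' @param xlab X axis label.
#' @param width,height Figure size in inches when writing a file.
#' @return An \code{ecdf_plot}: list with \code{plot} (ggplot),
#'   \code{curves} (data.frame: \code{group}, \code{x}, \code{F}) and
#'   \code{annotation} (character or NULL). Invisibly when \code{file} is
#'   given.
#' @export
plot_ecdf <- function(split, ks = NULL, file = NULL,
                      xlab = "log2(fold change)", width = 5, height = 4) {
  stopifnot(inherits(split, "group_split"))
  if (length(split$match_values) == 0L ||
      length(split$background_values) == 0L)
    stop("both groups must be non-empty to draw ECDF curves")
  lab_m <- paste0(split$match_label, " (n=", length(split$match_values), ")")
  lab_b <- paste0(split$background_label, " (n=",
                  length(split$background_values), ")")
  curves <- rbind(
    data.frame(group = lab_m, ecdf_table(split$match_values)),
    data.frame(group = lab_b, ecdf_table(split$background_values)))
  ann <- if (!is.null(ks)) {
    stopifnot(inherits(ks, "ks_result"))
    paste0("Dstat: ", signif(ks$d_stat, 6),
           "\np-value: ", format(ks$p_value, digits = 4))
  }
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$x, y = .data$F,
                                    colour = .data$group)) +
    ggplot2::geom_step(direction = "hv", linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = stats::setNames(
      c("#7b3294", "grey40"), c(lab_m, lab_b))) +
    ggplot2::labs(x = xlab, y = "Cumulative fraction of genes",
                  colour = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "bottom")
  if (!is.null(ann))
    p <- p + ggplot2::annotate("label", x = -Inf, y = Inf, label = ann,
                               hjust = -0.05, vjust = 1.1, size = 3)
  out <- structure(list(plot = p, curves = curves, annotation = ann),
                   class = "ecdf_plot")
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(out))
  }
  out
}

#' @export
print.ecdf_plot <- function(x, ...) { print(x$plot); invisible(x) }

#' @importFrom ggplot2 .data
NULL
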