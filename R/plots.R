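# ggplot2 views of the main result types: ring-topology arc diagrams,
# match-delta plots, and coverage maps.

#' Plot a threaded ring topology
#'
#' Draws the core as a residue line with thioether bridges as arcs, coloured
#' by bridge type (lanthionine vs 3-methyllanthionine).
#'
#' @param object A `ring_topology` from [thread_template()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ring_topology
#' @export
autoplot.ring_topology <- function(object, ...) {
  core <- attr(object, "core")
  residues <- tibble(position = seq_len(nchar(core)),
                     residue = str_split_1(core, ""))
  arcs <- list_rbind(map(seq_len(nrow(object)), function(i) {
    b <- object[i, ]
    t <- seq(0, pi, length.out = 50)
    mid <- (b$donor_pos + b$acceptor_pos) / 2
    half <- (b$acceptor_pos - b$donor_pos) / 2
    tibble(ring = b$ring, type = b$type,
           x = mid + half * cos(t), y = 0.15 + half * sin(t) / 4)
  }))
  labels <- mutate(as_tibble(object),
                   x = (.data$donor_pos + .data$acceptor_pos) / 2,
                   y = 0.2 + (.data$acceptor_pos - .data$donor_pos) / 16)
  ggplot2::ggplot() +
    ggplot2::geom_text(data = residues,
                       ggplot2::aes(x = .data$position, y = 0,
                                    label = .data$residue),
                       size = 3, family = "mono") +
    ggplot2::geom_path(data = arcs,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$ring,
                                    colour = .data$type)) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = .data$y + 0.04,
                                    label = .data$ring),
                       size = 3) +
    ggplot2::scale_colour_manual(values = c(Lan = "#D55E00",
                                            MeLan = "#0072B2")) +
    ggplot2::labs(x = "core position", colour = "bridge",
                  title = paste("Ring topology threaded from",
                                attr(object, "template_name"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title.y = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot target-vs-peak match deltas
#'
#' Theoretical m/z on the x axis, observed minus theoretical on the y axis,
#' matched targets filled.
#'
#' @param object A `lanthi_matches` tibble from [match_targets()].
#' @param tolerance Optional tolerance to draw as guide lines.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lanthi_matches
#' @export
autoplot.lanthi_matches <- function(object, tolerance = NULL, ...) {
  df <- as_tibble(object)
  xcol <- if ("mz" %in% names(df)) "mz" else "neutral_mass"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data$delta,
                                        shape = .data$matched)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = if (xcol == "mz") "theoretical m/z (Th)" else
      "theoretical mass (Da)",
      y = "observed - theoretical", shape = "matched") +
    ggplot2::theme_minimal()
  if (!is.null(tolerance)) {
    p <- p + ggplot2::geom_hline(yintercept = c(-tolerance, tolerance),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot a sequence-coverage map
#'
#' One tile per core position, filled where some matched fragment covers it.
#'
#' @param object A `coverage_report` from [sequence_coverage()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = 1,
                                   fill = .data$covered)) +
    ggplot2::geom_tile(colour = "white", height = 0.6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#009E73",
                                          `FALSE` = "grey85")) +
    ggplot2::labs(x = "core position", fill = "covered",
                  title = sprintf("Sequence coverage %.1f%%",
                                  object$coverage_pct)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title.y = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
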