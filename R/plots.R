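# ggplot2 displays for the main result types

#' @importFrom ggplot2 ggplot aes geom_col geom_segment geom_point
#'   geom_tile geom_text scale_fill_manual scale_fill_gradient labs
#'   theme_minimal coord_flip autoplot
#' @export
ggplot2::autoplot

#' Plot an HTT screen as a delta chart
#'
#' One bar per species pair, TE-minus-host identity delta; flagged
#' pairs (TE more conserved than the genomic background) highlighted.
#'
#' @param object an `htt_screen`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.htt_screen <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(pair = paste(.data$species_a, .data$species_b, sep = " ~ "),
           pair = factor(.data$pair, levels = rev(.data$pair)))
  ggplot(df, aes(x = .data$pair, y = .data$delta,
                 fill = .data$flagged)) +
    geom_col() +
    scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey65"),
                      name = "TE more conserved") +
    coord_flip() +
    labs(x = NULL, y = "TE - host identity (percentage points)",
         title = "Horizontal-transfer screen") +
    theme_minimal()
}

#' Plot an element annotation as a feature map
#'
#' @param object a `hel_annotation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hel_annotation <- function(object, ...) {
  f <- annotation_features(object)
  f$y <- as.numeric(factor(f$type))
  ggplot(f, aes(y = .data$type)) +
    geom_segment(aes(x = .data$start, xend = .data$end,
                     yend = .data$type), linewidth = 4,
                 colour = "#2166ac") +
    labs(x = "position (bp)", y = NULL,
         title = sprintf("%s (%d bp, tier %s)", object$id, object$length,
                         object$tier)) +
    theme_minimal()
}

#' Heatmap of a percent-identity matrix
#'
#' @param object an `identity_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.identity_matrix <- function(object, ...) {
  labs_v <- rownames(object)
  df <- tidyr::expand_grid(a = labs_v, b = labs_v) %>%
    mutate(identity = as.numeric(object[cbind(.data$a, .data$b)]))
  ggplot(df, aes(.data$a, .data$b, fill = .data$identity)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f", .data$identity)), size = 2.6) +
    scale_fill_gradient(low = "#f7fbff", high = "#2171b5",
                        name = "% identity") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
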