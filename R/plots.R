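# ggplot2 displays for the main result types

#' Plot dated age ranges
#'
#' One horizontal segment per (family, genome) from the reported lower to
#' upper age bound; capped estimates are marked.
#'
#' @param object A `te_ages` tibble from [date_all()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot te_ages
#' @export
autoplot.te_ages <- function(object, ...) {
  df <- mutate(object,
               label = paste0(.data$family, " (", .data$genome, ")"),
               capped = !is.na(.data$constraint_applied))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$reported_min,
                                       xend = .data$reported_max,
                                       yend = .data$label,
                                       linetype = .data$upper_bound_only)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$reported_max,
                                     shape = .data$capped), size = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (MYA)", y = NULL,
                  linetype = "upper bound only", shape = "capped") +
    ggplot2::theme_minimal()
}

#' Plot HT evidence ratios
#'
#' Observed/expected divergence ratio per family pair on a log axis, with
#' the HT and vertical-descent bands marked.
#'
#' @param object An `ht_report`.
#' @param ... Unused.
#' @return A ggplot (NULL if the report has no evidence table).
#' @method autoplot ht_report
#' @export
autoplot.ht_report <- function(object, ...) {
  ev <- object$evidence
  if (is.null(ev) || nrow(ev) == 0) return(NULL)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$ratio, y = .data$pair,
                                   colour = .data$verdict)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$params$threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$params$vertical_band, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "observed / expected divergence", y = NULL,
                  colour = "verdict") +
    ggplot2::theme_minimal()
}

#' Heatmap of a consensus identity matrix
#'
#' @param m Symmetric percent-identity matrix from [identity_matrix()].
#' @return A ggplot.
#' @export
plot_identity_matrix <- function(m) {
  df <- as_tibble(as.data.frame.table(m, responseName = "identity"))
  names(df)[1:2] <- c("a", "b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$identity)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
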