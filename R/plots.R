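#' @importFrom ggplot2 ggplot aes geom_path geom_tile geom_line geom_point
#'   geom_vline scale_fill_viridis_c coord_equal labs theme_minimal
#'   facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a trajectory in the arena
#'
#' @param object A `cpp_trajectory`.
#' @param arena Optional [arena_spec()] to draw the midline.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpp_trajectory
#' @export
autoplot.cpp_trajectory <- function(object, arena = NULL, ...) {
  p <- ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_path(alpha = 0.4, linewidth = 0.2) +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
  if (!is.null(arena)) {
    p <- p + geom_vline(xintercept = arena$midline, linetype = "dashed")
  }
  p
}

#' Plot a rate map
#'
#' @param object A `cpp_ratemap`.
#' @param smoothed Show the smoothed map (default) or the raw rates.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpp_ratemap
#' @export
autoplot.cpp_ratemap <- function(object, smoothed = TRUE, ...) {
  df <- tidy(object)
  df$value <- if (smoothed) df$rate_smooth else df$rate
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "events/s") +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
}

#' Plot a consensus matrix ordered by linkage
#'
#' @param object A `cpp_consensus`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpp_consensus
#' @export
autoplot.cpp_consensus <- function(object, ...) {
  inc <- which(object$included)
  C <- object$C[inc, inc]
  ord <- hclust(as.dist(1 - C), method = "complete")$order
  C <- C[ord, ord]
  df <- tibble::tibble(
    i = rep(seq_len(nrow(C)), times = ncol(C)),
    j = rep(seq_len(ncol(C)), each = nrow(C)),
    consensus = as.vector(C)
  )
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$consensus)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_equal() +
    labs(x = "neuron (ordered)", y = "neuron (ordered)") +
    theme_minimal()
}

#' Plot cluster-number selection curves
#'
#' @param object A `cpp_kselect` from [select_optimal_k()].
#' @param ... Unused.
#' @return A ggplot with PAC and cophenetic correlation versus K.
#' @method autoplot cpp_kselect
#' @export
autoplot.cpp_kselect <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curves, c("pac", "cophenetic"),
                            names_to = "criterion")
  ggplot(df, aes(x = .data$K, y = .data$value)) +
    geom_line() +
    geom_point() +
    facet_wrap(~criterion, scales = "free_y") +
    theme_minimal()
}

#' Plot decoded versus true positions over time
#'
#' @param pred Decoded positions from [decode()] / [decode_2step()].
#' @param binned The `cpp_binned` test data (true positions).
#' @return A ggplot of x and y traces.
#' @export
plot_decoding <- function(pred, binned) {
  M <- nrow(pred)
  df <- dplyr::bind_rows(
    tibble::tibble(bin = seq_len(M), coord = "x", true = binned$pos[, 1],
                   decoded = pred$x),
    tibble::tibble(bin = seq_len(M), coord = "y", true = binned$pos[, 2],
                   decoded = pred$y)
  ) |>
    tidyr::pivot_longer(c("true", "decoded"), names_to = "trace")
  ggplot(df, aes(x = .data$bin, y = .data$value,
                 colour = .data$trace)) +
    geom_line(alpha = 0.8) +
    facet_wrap(~coord, ncol = 1) +
    labs(x = "time bin", y = "position (cm)") +
    theme_minimal()
}
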