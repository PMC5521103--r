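#' Plot a window mismatch profile
#'
#' Step plot of per-window mismatch counts along the fragment with the
#' specificity threshold marked; windows below the threshold are the ones
#' that can silence the comparator.
#'
#' @param object A `window_profile`.
#' @param threshold Mismatch threshold to mark (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_profile
#' @export
autoplot.window_profile <- function(object, threshold = 3L, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start,
                                       y = .data$mismatches)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = threshold - 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "window start (nt, 1-based)",
      y = sprintf("mismatches per %d-nt window", attr(object, "window_len")),
      title = sprintf("%s vs %s (%s mode)", attr(object, "fragment_id"),
                      attr(object, "comparator_id"), attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot a validity mask
#'
#' Shows the worst-case off-target mismatch count per window with valid
#' windows highlighted; maximal runs of valid windows are where fragments
#' can live.
#'
#' @param object A [validity_mask()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validity_mask
#' @export
autoplot.validity_mask <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start,
                                       y = .data$min_mismatch,
                                       colour = .data$valid)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "window start (nt, 1-based)",
                  y = "minimum mismatches over off-targets",
                  colour = "valid") +
    ggplot2::theme_minimal()
}

#' Plot candidate fragments along the source gene
#'
#' @param object A `fragment_candidates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fragment_candidates
#' @export
autoplot.fragment_candidates <- function(object, ...) {
  if (nrow(object) == 0L) {
    abort("No candidates to plot.")
  }
  df <- dplyr::mutate(as_tibble(object), rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(y = stats::reorder(factor(.data$rank),
                                                      -.data$rank))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = stats::reorder(factor(.data$rank),
                                                             -.data$rank),
                                       colour = .data$min_offtarget_mismatch),
                          linewidth = 3) +
    ggplot2::labs(x = "position on source (nt, 1-based)", y = "candidate rank",
                  colour = "worst-case\nmismatches") +
    ggplot2::theme_minimal()
}

#' Identity heatmap of a subgroup partition
#'
#' @param object A [partition_subgroups()] result.
#' @param ... Unused.
#' @return A ggplot object: pairwise identity tiles, members ordered by
#'   subgroup.
#' @method autoplot subgroup_partition
#' @export
autoplot.subgroup_partition <- function(object, ...) {
  m <- attr(object, "identity_matrix")
  ord <- object$id[order(object$subgroup)]
  df <- as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal")
  names(df) <- c("id1", "id2", "identity")
  df$id1 <- factor(df$id1, levels = ord)
  df$id2 <- factor(df$id2, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$id1, .data$id2,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(m), 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity",
                  title = sprintf("single-linkage subgroups at %.0f%% identity",
                                  attr(object, "identity_threshold"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
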