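#' Plot a transcript cluster's exon-expression profile
#'
#' Line plot of every sample's intensities across the cluster's probe sets
#' in transcript 5'->3' order: the examined sample in red, reference
#' samples in pink, an optional breakpoint as a vertical blue line between
#' the flanking probe sets, and per-probe-set annotation letters along the
#' plot edges (top: evidence level C/e/f; bottom: hybridization class
#' U/S/M). This is the plot used for visual inspection of candidates.
#'
#' @param matrix Expression matrix tibble.
#' @param annotations Annotation tibble.
#' @param cluster_id Transcript cluster to plot.
#' @param sample_id Examined sample (highlighted).
#' @param cut_index Optional breakpoint: size of the 5' group, marked
#'   between probe sets `cut_index` and `cut_index + 1`.
#' @param y_scale `"linear"` (default) or `"log"`. On the log scale, zero
#'   intensities are clamped, with a warning, to half the smallest positive
#'   intensity in the cluster.
#' @param path Optional output file (`.png`, `.svg` or `.pdf`); written
#'   with [ggplot2::ggsave()].
#' @param examined_color,reference_color Line colors.
#' @param width,height Device size in inches when `path` is given.
#' @return The ggplot object, invisibly if `path` is given.
#' @export
plot_cluster_profile <- function(matrix, annotations, cluster_id, sample_id,
                                 cut_index = NULL,
                                 y_scale = c("linear", "log"),
                                 path = NULL,
                                 examined_color = "red",
                                 reference_color = "pink",
                                 width = 8, height = 5) {
  y_scale <- match.arg(y_scale)
  index <- build_cluster_index(annotations)
  idx <- index[index$transcript_cluster_id == cluster_id, ]
  if (nrow(idx) == 0) abort_validation("Unknown cluster '%s'.", cluster_id)
  if (!sample_id %in% sample_ids(matrix)) {
    abort_validation("Unknown sample '%s'.", sample_id)
  }
  sub <- matrix[match(idx$probeset_id, matrix$probeset_id), ]
  if (anyNA(sub$probeset_id)) {
    abort_validation("Cluster '%s' has probe sets missing from the matrix.",
                     cluster_id)
  }
  long <- sub |>
    dplyr::mutate(position = seq_len(nrow(sub))) |>
    tidyr::pivot_longer(cols = -c("probeset_id", "position"),
                        names_to = "sample", values_to = "intensity") |>
    dplyr::mutate(examined = .data$sample == sample_id)
  if (y_scale == "log" && any(long$intensity <= 0)) {
    clamp <- min(long$intensity[long$intensity > 0]) / 2
    warning(sprintf(
      "%d non-positive intensity value(s) clamped to %g for log display.",
      sum(long$intensity <= 0), clamp), call. = FALSE)
    long$intensity[long$intensity <= 0] <- clamp
  }
  ann <- tidy_annotations(annotations)
  letters_df <- idx |>
    dplyr::left_join(ann[c("probeset_id", "evidence_level",
                           "hybridization_target")], by = "probeset_id") |>
    dplyr::mutate(
      ev = c(core = "C", extended = "e", full = "f")[.data$evidence_level],
      hyb = c(unique = "U", similar = "S",
              mixed = "M")[.data$hybridization_target]
    )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                          y = .data$intensity,
                                          group = .data$sample)) +
    ggplot2::geom_line(data = \(d) d[!d$examined, ],
                       color = reference_color, linewidth = 0.4) +
    ggplot2::geom_line(data = \(d) d[d$examined, ],
                       color = examined_color, linewidth = 0.9) +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(idx)),
                                labels = idx$probeset_id) +
    ggplot2::annotate("text", x = seq_len(nrow(idx)),
                      y = max(long$intensity),
                      label = letters_df$ev, vjust = -0.5, size = 3) +
    ggplot2::annotate("text", x = seq_len(nrow(idx)),
                      y = min(long$intensity),
                      label = letters_df$hyb, vjust = 1.5, size = 3) +
    ggplot2::labs(
      title = sprintf("Cluster %s, examined sample %s", cluster_id,
                      sample_id),
      x = "probe set (transcript 5' -> 3' order)",
      y = "signal intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
  if (!is.null(cut_index)) {
    if (cut_index < 1 || cut_index >= nrow(idx)) {
      abort_validation("`cut_index` must be in [1, %d].", nrow(idx) - 1)
    }
    p <- p + ggplot2::geom_vline(xintercept = cut_index + 0.5,
                                 color = "blue", linetype = "solid")
  }
  if (y_scale == "log") p <- p + ggplot2::scale_y_log10()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Profile plot of one screening candidate
#'
#' @param object A `fusion_screen` tibble from [screen()].
#' @param matrix,annotations The data the screen was run on (the matrix is
#'   re-normalized with the screen's `median_target`).
#' @param row Which candidate row to plot.
#' @param ... Passed to [plot_cluster_profile()].
#' @return A ggplot object.
#' @method autoplot fusion_screen
#' @export
autoplot.fusion_screen <- function(object, matrix, annotations, row = 1,
                                   ...) {
  if (nrow(object) == 0) abort_validation("No candidates to plot.")
  cand <- object[row, ]
  p <- attr(object, "params")
  if (!is.null(p) && is.finite(p$median_target)) {
    matrix <- scale_to_median(matrix, p$median_target)
  }
  probesets <- c(cand$probesets_5p[[1]], cand$probesets_3p[[1]])
  sub_ann <- annotations[annotations$probeset_id %in% probesets, ]
  plot_cluster_profile(matrix, sub_ann, cand$transcript_cluster_id,
                       cand$examined_sample, cut_index = cand$cut_index,
                       ...)
}
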