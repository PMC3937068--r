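#' Z-score / t-test scorer for one cluster and cut
#'
#' An alternative breakpoint scorer in the style of standardized-intensity
#' methods: each probe-set row is z-scored across samples
#' (`(x - mean) / sd`), and for the examined sample the 5' and 3' terminal
#' groups of standardized values are compared with Welch's two-sample
#' t-test. Unlike the rank scan, the statistic retains intensity magnitude,
#' which makes it sensitive to outlier intensities.
#'
#' @param matrix Expression matrix tibble restricted to one cluster's probe
#'   sets, rows in transcript 5'->3' order.
#' @param examined_sample Sample (column) to score.
#' @param cut_index Size of the 5' group.
#' @return A one-row tibble: `statistic` (Welch t), `p_value` (two-sided),
#'   `n_5p`, `n_3p` (usable probe sets per group after dropping zero-SD
#'   rows).
#' @export
lin_score_cluster <- function(matrix, examined_sample, cut_index) {
  samples <- sample_ids(matrix)
  if (!examined_sample %in% samples) {
    abort_validation("Unknown sample '%s'.", examined_sample)
  }
  vals <- mat_values(matrix)
  n <- nrow(vals)
  if (cut_index < 1 || cut_index >= n) {
    abort_validation("`cut_index` must be in [1, %d].", n - 1)
  }
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  usable <- sdv > 0
  if (any(!usable)) {
    warning(sprintf("%d probe-set row(s) with zero SD dropped.",
                    sum(!usable)), call. = FALSE)
  }
  z <- (vals[, examined_sample] - mu) / sdv
  in_5p <- seq_len(n) <= cut_index
  z5 <- z[usable & in_5p]
  z3 <- z[usable & !in_5p]
  if (length(z5) < 2 || length(z3) < 2) {
    abort_validation(
      "Fewer than 2 usable probe sets in a terminal group (5': %d, 3': %d).",
      length(z5), length(z3))
  }
  if (stats::sd(z5) == 0 && stats::sd(z3) == 0) {
    # degenerate: both groups constant; t-test is undefined, report no change
    eq <- isTRUE(all.equal(mean(z5), mean(z3)))
    return(tibble::tibble(statistic = if (eq) 0 else Inf,
                          p_value = if (eq) 1 else 0,
                          n_5p = length(z5), n_3p = length(z3)))
  }
  tt <- stats::t.test(z5, z3, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_5p = length(z5), n_3p = length(z3))
}

#' Screen all clusters with the z-score / t-test scorer
#'
#' Applies [lin_score_cluster()] at every admissible cut of every retained
#' cluster and sample, reporting the minimum-p cut per (cluster, sample).
#' This scorer has no published detection threshold here; the table is
#' intended for ranking and for concordance checks against the rank scan.
#'
#' @inheritParams screen
#' @return A tibble with one row per (cluster, sample): the best cut, Welch
#'   t statistic and two-sided p-value.
#' @export
lin_screen <- function(matrix, annotations, params = screen_params()) {
  if (is.finite(params$median_target)) {
    matrix <- scale_to_median(matrix, params$median_target)
  }
  eligible <- filter_probesets(matrix, annotations, params)
  clusters <- split(eligible$probeset_id, eligible$transcript_cluster_id)
  samples <- sample_ids(matrix)
  purrr::imap(clusters, function(ps, cl) {
    sub <- matrix[match(ps, matrix$probeset_id), ]
    cuts <- enumerate_cutpoints(length(ps), params$min_group_size)
    purrr::map(samples, function(s) {
      scores <- purrr::map(cuts, function(k) {
        dplyr::mutate(
          suppressWarnings(lin_score_cluster(sub, s, k)),
          cut_index = as.integer(k))
      }) |> dplyr::bind_rows()
      best <- scores[order(scores$p_value, scores$cut_index)[1], ]
      dplyr::mutate(best, transcript_cluster_id = cl, examined_sample = s,
                    .before = 1)
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$transcript_cluster_id, .data$examined_sample)
}
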