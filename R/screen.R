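#' Linearly scale each array so its median intensity hits a target
#'
#' Per-array linear normalization: every sample column is multiplied by
#' `target / median(column)`, so all column medians equal `target`
#' afterwards. This is the only cross-array normalization the screen uses;
#' within-gene comparability is achieved by ranking, not scaling.
#'
#' @param matrix Expression matrix tibble (see [read_matrix()]).
#' @param target Target median intensity (default 100).
#' @return The scaled matrix tibble.
#' @examples
#' m <- tibble::tibble(probeset_id = c("a", "b", "c"),
#'                     s1 = c(1, 2, 3), s2 = c(10, 20, 30))
#' scale_to_median(m, 100)
#' @export
scale_to_median <- function(matrix, target = 100) {
  samples <- sample_ids(matrix)
  for (s in samples) {
    med <- stats::median(matrix[[s]])
    if (!is.finite(med) || med <= 0) {
      abort_validation(
        "Sample '%s' has a non-positive median intensity; cannot scale.", s)
    }
    matrix[[s]] <- matrix[[s]] * (target / med)
  }
  matrix
}

#' Select eligible probe sets and scannable transcript clusters
#'
#' Applies the probe-set filters: the hybridization target and evidence
#' level must be in the accepted sets, and the probe set must reach
#' `min_intensity` in at least one sample (inclusive). Transcript clusters
#' retaining fewer than `min_cluster_probesets` eligible probe sets are
#' dropped. Probe sets present in only one of matrix/annotations are dropped
#' with a warning.
#'
#' @param matrix Expression matrix tibble (already normalized if desired).
#' @param annotations Annotation tibble.
#' @param params A [screen_params()] object.
#' @return A tibble of eligible probe sets in transcript order:
#'   `transcript_cluster_id`, `probeset_id`, `position` (index within the
#'   eligible, ordered probe sets of the cluster).
#' @export
filter_probesets <- function(matrix, annotations, params = screen_params()) {
  annotations <- tidy_annotations(annotations)
  shared <- intersect(matrix$probeset_id, annotations$probeset_id)
  n_lost <- length(union(matrix$probeset_id, annotations$probeset_id)) -
    length(shared)
  if (n_lost > 0) {
    warning(sprintf(
      "%d probe set(s) present in only one of matrix/annotations were dropped.",
      n_lost), call. = FALSE)
  }
  vals <- mat_values(matrix)[shared, , drop = FALSE]
  max_int <- apply(vals, 1, max)
  eligible_ids <- annotations |>
    dplyr::filter(
      .data$probeset_id %in% shared,
      .data$hybridization_target %in% params$required_hybridization,
      .data$evidence_level %in% params$required_evidence
    ) |>
    dplyr::filter(max_int[.data$probeset_id] >= params$min_intensity)
  if (nrow(eligible_ids) == 0) {
    return(tibble::tibble(transcript_cluster_id = character(),
                          probeset_id = character(), position = integer()))
  }
  build_cluster_index(eligible_ids) |>
    dplyr::filter(dplyr::n() >= params$min_cluster_probesets,
                  .by = "transcript_cluster_id") |>
    dplyr::select("transcript_cluster_id", "probeset_id", "position")
}

#' Fractional ranks of samples at one probe set
#'
#' Ranks one probe set's intensities across samples, ascending (the lowest
#' intensity gets rank 1). Ties receive the average of the spanned ranks, so
#' the ranks of N samples always sum to N(N+1)/2.
#'
#' @param x Numeric vector of one probe set's intensities over samples.
#' @return Numeric vector of fractional ranks.
#' @examples
#' rank_samples(c(5, 2, 9))   # 2 1 3
#' rank_samples(c(4, 4, 7))   # 1.5 1.5 3
#' @export
rank_samples <- function(x) {
  if (length(x) < 2) abort_validation("Ranking requires at least 2 samples.")
  rank(x, ties.method = "average")
}

#' Enumerate admissible cut points
#'
#' A cut index k means the first k probe sets (transcript order) form the 5'
#' terminal group. Admissible cuts leave at least `min_group_size` probe
#' sets in each group.
#'
#' @param n_probesets Number of eligible probe sets in the cluster.
#' @param min_group_size Minimum terminal-group size.
#' @return Integer vector of cut indices (empty if the cluster is too small).
#' @examples
#' enumerate_cutpoints(8, 4)   # 4
#' enumerate_cutpoints(10, 4)  # 4 5 6
#' @export
enumerate_cutpoints <- function(n_probesets, min_group_size) {
  if (n_probesets < 2 * min_group_size) return(integer(0))
  seq.int(min_group_size, n_probesets - min_group_size)
}

# Vectorized cut statistics for one sample's rank vector over the ordered
# eligible probe sets. Returns a tibble with one row per cut.
cut_stats <- function(ranks, cuts, n_samples, params) {
  ranks <- unname(ranks)
  n <- length(ranks)
  cs <- cumsum(ranks)
  css <- cumsum(ranks^2)
  tot <- cs[n]
  tots <- css[n]
  k <- cuts
  m5 <- cs[k] / k
  m3 <- (tot - cs[k]) / (n - k)
  ss5 <- pmax(css[k] - cs[k]^2 / k, 0)
  ss3 <- pmax((tots - css[k]) - (tot - cs[k])^2 / (n - k), 0)
  sd5 <- sqrt(ss5 / (k - 1))
  sd3 <- sqrt(ss3 / (n - k - 1))
  diff <- abs(m5 - m3)
  tibble::tibble(
    cut_index = as.integer(k),
    mean_rank_5p = m5,
    mean_rank_3p = m3,
    rank_diff = diff,
    sd_5p = sd5,
    sd_3p = sd3,
    passes_diff = diff >= params$rank_diff_fraction * n_samples,
    passes_sd = pmin(sd5, sd3) <= params$max_group_rank_sd
  )
}

#' Score one cut point of one sample's rank profile
#'
#' Computes the 5'/3' group mean ranks, their absolute difference, the group
#' rank standard deviations (n - 1 denominator) and the two pass flags: the
#' difference must reach `rank_diff_fraction * n_samples` and at least one
#' group SD must not exceed `max_group_rank_sd` (both inclusive).
#'
#' @param ranks Numeric vector: the examined sample's fractional ranks over
#'   the cluster's eligible probe sets in transcript order.
#' @param cut_index Size of the 5' group (1 <= cut_index < length(ranks)).
#' @param n_samples Number of samples in the ranking pool.
#' @param params A [screen_params()] object.
#' @return A one-row tibble with the cut statistics and pass flags.
#' @export
score_cutpoint <- function(ranks, cut_index, n_samples,
                           params = screen_params()) {
  n <- length(ranks)
  if (cut_index < 1 || cut_index >= n) {
    abort_validation("`cut_index` must be in [1, %d].", n - 1)
  }
  cut_stats(ranks, as.integer(cut_index), n_samples, params)
}

# rank matrix (samples x probe sets) for a cluster's ordered probe sets
cluster_rank_matrix <- function(vals) {
  apply(vals, 1, rank_samples)  # returns n_samples x n_probesets
}

#' Detect breakpoint candidates within one transcript cluster
#'
#' For every sample, every admissible cut is scored; the sample becomes a
#' candidate if at least one cut passes both the rank-difference and the SD
#' criterion. Among qualifying cuts the best cut maximizes the absolute
#' mean-rank difference, ties broken by the smaller of the two group SDs,
#' then by the smaller cut index. Detection uses the absolute difference, so
#' it does not depend on the direction of the expression change.
#'
#' @param cluster_id Transcript cluster identifier (reported in the output).
#' @param probeset_ids Character vector of the cluster's eligible probe sets
#'   in transcript 5'->3' order.
#' @param matrix Expression matrix tibble containing those probe sets.
#' @param params A [screen_params()] object.
#' @return A candidate tibble, one row per flagged sample, with the best-cut
#'   statistics, flanking probe-set IDs, the number of qualifying cuts, and
#'   list-columns `cuts` (all qualifying cuts), `probesets_5p`,
#'   `probesets_3p` (probe sets on each side of the best cut).
#' @export
detect_candidates <- function(cluster_id, probeset_ids, matrix,
                              params = screen_params()) {
  vals <- mat_values(matrix)[probeset_ids, , drop = FALSE]
  n <- length(probeset_ids)
  n_samples <- ncol(vals)
  cuts <- enumerate_cutpoints(n, params$min_group_size)
  if (length(cuts) == 0) return(empty_candidates())
  rk <- cluster_rank_matrix(vals)  # n_samples x n
  samples <- colnames(vals)
  rows <- lapply(seq_len(n_samples), function(s) {
    st <- cut_stats(rk[s, ], cuts, n_samples, params)
    qual <- st[st$passes_diff & st$passes_sd, ]
    if (nrow(qual) == 0) return(NULL)
    best <- qual[order(-qual$rank_diff, pmin(qual$sd_5p, qual$sd_3p),
                       qual$cut_index)[1], ]
    k <- best$cut_index
    tibble::tibble(
      transcript_cluster_id = cluster_id,
      examined_sample = samples[s],
      cut_index = k,
      mean_rank_5p = best$mean_rank_5p,
      mean_rank_3p = best$mean_rank_3p,
      rank_diff = best$rank_diff,
      sd_5p = best$sd_5p,
      sd_3p = best$sd_3p,
      upstream_probeset_id = probeset_ids[k],
      downstream_probeset_id = probeset_ids[k + 1],
      n_qualifying_cuts = nrow(qual),
      n_samples = n_samples,
      cuts = list(qual),
      probesets_5p = list(probeset_ids[seq_len(k)]),
      probesets_3p = list(probeset_ids[seq.int(k + 1, n)])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_candidates() else out
}

empty_candidates <- function() {
  tibble::tibble(
    transcript_cluster_id = character(), examined_sample = character(),
    cut_index = integer(), mean_rank_5p = double(), mean_rank_3p = double(),
    rank_diff = double(), sd_5p = double(), sd_3p = double(),
    upstream_probeset_id = character(), downstream_probeset_id = character(),
    n_qualifying_cuts = integer(), n_samples = integer(),
    cuts = list(), probesets_5p = list(), probesets_3p = list()
  )
}

#' Screen an expression matrix for fusion-gene breakpoint candidates
#'
#' Runs the full rank-based screen: per-array median normalization (unless
#' `params$median_target` is `NA`), probe-set and cluster filtering, sample
#' ranking per probe set, and the cut-point scan of every retained cluster.
#' Each (cluster, sample) pair with at least one qualifying cut becomes one
#' candidate row. Because the statistic uses only the per-probe-set sample
#' orderings, the output is invariant under any strictly increasing
#' per-probe-set transform of the intensities (once the intensity floor has
#' been applied).
#'
#' @param matrix Expression matrix tibble (see [read_matrix()]).
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param params A [screen_params()] object.
#' @return A `fusion_screen` tibble (see [detect_candidates()] for columns),
#'   ordered by (cluster, sample), with attributes `params`, `n_samples`,
#'   `n_clusters_screened` and `n_probesets_eligible`.
#' @export
screen <- function(matrix, annotations, params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  if (nrow(matrix) == 0 || length(sample_ids(matrix)) < 2) {
    if (nrow(matrix) == 0) {
      return(as_fusion_screen(empty_candidates(), params, 0L, 0L, 0L))
    }
    abort_validation("Screening requires at least 2 samples.")
  }
  if (is.finite(params$median_target)) {
    matrix <- scale_to_median(matrix, params$median_target)
  }
  eligible <- filter_probesets(matrix, annotations, params)
  clusters <- split(eligible$probeset_id, eligible$transcript_cluster_id)
  res <- purrr::imap(clusters, \(ps, cl) detect_candidates(cl, ps, matrix,
                                                           params))
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) out <- empty_candidates()
  out <- dplyr::arrange(out, .data$transcript_cluster_id,
                        .data$examined_sample)
  as_fusion_screen(out, params, length(sample_ids(matrix)),
                   length(clusters), nrow(eligible))
}

as_fusion_screen <- function(x, params, n_samples, n_clusters, n_eligible) {
  structure(
    x,
    class = c("fusion_screen", class(tibble::tibble())),
    params = params,
    n_samples = n_samples,
    n_clusters_screened = n_clusters,
    n_probesets_eligible = n_eligible
  )
}

#' @export
print.fusion_screen <- function(x, ...) {
  cat(sprintf(
    "<fusion_screen> %d candidate(s) from %d cluster(s) x %d sample(s)\n",
    nrow(x), attr(x, "n_clusters_screened"), attr(x, "n_samples")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a screening result into a flat candidate table
#' @param x A `fusion_screen` object from [screen()].
#' @param ... Unused.
#' @return A plain tibble without list-columns, one row per candidate.
#' @method tidy fusion_screen
#' @export
tidy.fusion_screen <- function(x, ...) {
  cols <- c("transcript_cluster_id", "examined_sample", "cut_index",
            candidate_report_columns[-(1:2)])
  tibble::new_tibble(as.list(x)[cols], nrow = nrow(x))
}

#' One-row summary of a screening run
#' @param x A `fusion_screen` object from [screen()].
#' @param ... Unused.
#' @return A one-row tibble with run-level counts and key thresholds.
#' @method glance fusion_screen
#' @export
glance.fusion_screen <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_candidates = nrow(x),
    n_flagged_clusters = dplyr::n_distinct(x$transcript_cluster_id),
    n_clusters_screened = attr(x, "n_clusters_screened"),
    n_probesets_eligible = attr(x, "n_probesets_eligible"),
    n_samples = attr(x, "n_samples"),
    rank_diff_threshold = p$rank_diff_fraction * attr(x, "n_samples"),
    max_group_rank_sd = p$max_group_rank_sd
  )
}
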