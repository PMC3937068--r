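#' Screening parameters
#'
#' Bundles the tunable thresholds of the fusion-gene screen. The defaults are
#' the published operating point for Human Exon 1.0 ST data summarized at the
#' probe-set level: probe sets must be annotated `unique`/`core` and reach an
#' intensity of 30 in at least one sample; a transcript cluster is scanned
#' only if it retains 8 or more eligible probe sets; every cut point leaving
#' at least 4 probe sets in each terminal group is scored; a cut qualifies
#' when the absolute difference of the 5' and 3' mean sample ranks is at
#' least 70% of the number of samples and at least one group's rank standard
#' deviation is 2.0 or lower.
#'
#' @param min_intensity Intensity floor: a probe set is kept only if its
#'   (normalized) intensity reaches this value in at least one sample.
#'   Applied as `>=`.
#' @param min_cluster_probesets Minimum number of eligible probe sets a
#'   transcript cluster needs to be scanned. Must be at least
#'   `2 * min_group_size`.
#' @param min_group_size Minimum number of probe sets in each terminal group.
#' @param rank_diff_fraction Fraction of the sample count that the absolute
#'   mean-rank difference must reach (applied as `>=`, no rounding).
#' @param max_group_rank_sd Rank-unit ceiling for the smaller of the two
#'   group rank standard deviations (sample SD, n - 1 denominator; applied
#'   as `<=`).
#' @param required_evidence Character vector of acceptable evidence levels
#'   (subset of `"core"`, `"extended"`, `"full"`).
#' @param required_hybridization Character vector of acceptable
#'   cross-hybridization classes (subset of `"unique"`, `"mixed"`,
#'   `"similar"`).
#' @param median_target Per-array linear scaling target: every sample column
#'   is multiplied so its median equals this value before the intensity floor
#'   is applied. Use `NA` to skip normalization (e.g. for pre-scaled input).
#'
#' @return A list of class `screen_params`.
#' @examples
#' screen_params()
#' screen_params(min_intensity = 50, rank_diff_fraction = 0.8)
#' @export
screen_params <- function(min_intensity = 30,
                          min_cluster_probesets = 8,
                          min_group_size = 4,
                          rank_diff_fraction = 0.70,
                          max_group_rank_sd = 2.0,
                          required_evidence = "core",
                          required_hybridization = "unique",
                          median_target = 100) {
  required_evidence <- match_enum(required_evidence, EVIDENCE_LEVELS,
                                  "required_evidence")
  required_hybridization <- match_enum(required_hybridization, HYB_TARGETS,
                                       "required_hybridization")
  if (!is.numeric(rank_diff_fraction) || length(rank_diff_fraction) != 1 ||
      rank_diff_fraction <= 0 || rank_diff_fraction > 1) {
    abort_validation("`rank_diff_fraction` must be a single number in (0, 1].")
  }
  if (min_group_size < 1) {
    abort_validation("`min_group_size` must be at least 1.")
  }
  if (min_cluster_probesets < 2 * min_group_size) {
    abort_validation(
      "`min_cluster_probesets` must be at least 2 * `min_group_size`.")
  }
  if (max_group_rank_sd < 0) {
    abort_validation("`max_group_rank_sd` must be non-negative.")
  }
  structure(
    list(
      min_intensity = as.numeric(min_intensity),
      min_cluster_probesets = as.integer(min_cluster_probesets),
      min_group_size = as.integer(min_group_size),
      rank_diff_fraction = as.numeric(rank_diff_fraction),
      max_group_rank_sd = as.numeric(max_group_rank_sd),
      required_evidence = required_evidence,
      required_hybridization = required_hybridization,
      median_target = as.numeric(median_target)
    ),
    class = "screen_params"
  )
}

#' @export
print.screen_params <- function(x, ...) {
  cat("<screen_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Triage parameters
#'
#' Thresholds for the post-screening exclusion rules. The original candidate
#' evaluation was done by eye against genome-browser isoform tracks and
#' reference profiles; these parameters make the two "similarity" judgments
#' explicit and reproducible.
#'
#' @param match_fraction Fraction of an isoform's covered probe sets that the
#'   candidate's higher-expressed side must contain (with the lower side
#'   disjoint from the isoform) for the profile to count as isoform-explained.
#' @param similarity_fraction A reference sample's signed mean-rank difference
#'   at the candidate's best cut must reach this fraction of the examined
#'   sample's difference (same sign) for the candidate to count as
#'   reference-similar.
#' @return A list of class `triage_params`.
#' @export
triage_params <- function(match_fraction = 0.90, similarity_fraction = 0.5) {
  if (match_fraction <= 0 || match_fraction > 1) {
    abort_validation("`match_fraction` must be in (0, 1].")
  }
  if (similarity_fraction <= 0) {
    abort_validation("`similarity_fraction` must be positive.")
  }
  structure(
    list(match_fraction = as.numeric(match_fraction),
         similarity_fraction = as.numeric(similarity_fraction)),
    class = "triage_params"
  )
}

EVIDENCE_LEVELS <- c("core", "extended", "full")
HYB_TARGETS <- c("unique", "mixed", "similar")

match_enum <- function(x, levels, what) {
  x <- tolower(as.character(x))
  bad <- setdiff(x, levels)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "`%s` contains invalid value(s): %s (allowed: %s).",
      what, paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  }
  unique(x)
}

abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fusescreen_validation_error")
}

abort_io <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fusescreen_io_error")
}
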