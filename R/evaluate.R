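#' Read an isoform coverage table
#'
#' Each row names a registered transcript isoform, its transcript cluster,
#' and the comma-separated probe sets whose target regions lie within the
#' isoform's exons.
#'
#' @param path TSV with columns `isoform_id`, `cluster_id`, `probeset_ids`.
#' @return A tibble with a `covered_probesets` list-column.
#' @export
read_isoforms <- function(path) {
  if (!file.exists(path)) abort_io("Isoform file not found: %s", path)
  readr::read_tsv(path, col_types = "ccc", progress = FALSE) |>
    dplyr::mutate(covered_probesets = strsplit(.data$probeset_ids, ",")) |>
    dplyr::select("isoform_id", "cluster_id", "covered_probesets")
}

#' Read a cluster-to-gene overlap table
#' @param path TSV with columns `cluster_id`, `gene_count`.
#' @return A tibble with character `cluster_id` and integer `gene_count`.
#' @export
read_gene_overlaps <- function(path) {
  if (!file.exists(path)) abort_io("Gene overlap file not found: %s", path)
  readr::read_tsv(path, col_types = "ci", progress = FALSE)
}

candidate_sides <- function(candidate) {
  higher_is_5p <- candidate$mean_rank_5p >= candidate$mean_rank_3p
  list(
    higher = if (higher_is_5p) candidate$probesets_5p[[1]] else
      candidate$probesets_3p[[1]],
    lower = if (higher_is_5p) candidate$probesets_3p[[1]] else
      candidate$probesets_5p[[1]]
  )
}

#' Isoform-explained exclusion rule
#'
#' A candidate's aberrant profile is considered explained by a registered
#' transcript isoform when its higher-expressed side covers at least
#' `match_fraction` of some isoform's probe sets while its lower-expressed
#' side is disjoint from that isoform — i.e. the apparent breakpoint
#' coincides with an annotated isoform boundary rather than a fusion.
#'
#' @param candidate One candidate row from [screen()] (with the
#'   `probesets_5p`/`probesets_3p` list-columns).
#' @param isoforms Isoform tibble (see [read_isoforms()]), any clusters.
#' @param params A [triage_params()] object.
#' @return `"drop_isoform"` or `"keep"`.
#' @export
filter_isoform_explained <- function(candidate, isoforms,
                                     params = triage_params()) {
  iso <- isoforms[isoforms$cluster_id == candidate$transcript_cluster_id, ]
  if (nrow(iso) == 0) return("keep")
  sides <- candidate_sides(candidate)
  for (i in seq_len(nrow(iso))) {
    covered <- iso$covered_probesets[[i]]
    if (length(covered) == 0) next
    frac <- length(intersect(sides$higher, covered)) / length(covered)
    disjoint <- length(intersect(sides$lower, covered)) == 0
    if (frac >= params$match_fraction && disjoint) return("drop_isoform")
  }
  "keep"
}

#' Multi-gene cluster exclusion rule
#'
#' Transcript clusters overlapping two or more annotated genes are excluded:
#' an expression step inside such a cluster usually reflects the boundary
#' between the co-clustered genes, not a rearrangement. Clusters absent from
#' the table count as a single gene.
#'
#' @param candidate One candidate row.
#' @param gene_overlaps Overlap tibble (see [read_gene_overlaps()]).
#' @return `"drop_multigene"` or `"keep"`.
#' @export
filter_multigene <- function(candidate, gene_overlaps) {
  i <- match(candidate$transcript_cluster_id, gene_overlaps$cluster_id)
  count <- if (is.na(i)) 1L else gene_overlaps$gene_count[i]
  if (count >= 2) "drop_multigene" else "keep"
}

#' Reference-sample similarity exclusion rule
#'
#' Recomputes, at the candidate's best cut, each sample's signed mean-rank
#' difference (5' minus 3') over the cluster's eligible probe sets. The
#' candidate is dropped if any designated reference sample shows a
#' difference of the same sign as the examined sample's with magnitude at
#' least `similarity_fraction` of it — the aberrant profile is then also
#' present in normal reference material.
#'
#' @param candidate One candidate row.
#' @param matrix Normalized expression matrix tibble (reference samples are
#'   columns and members of the ranking pool).
#' @param eligible Eligible probe-set tibble from [filter_probesets()].
#' @param reference_samples Character vector of reference sample IDs.
#' @param params A [triage_params()] object.
#' @return `"drop_reference_similar"` or `"keep"`.
#' @export
filter_reference_similar <- function(candidate, matrix, eligible,
                                     reference_samples,
                                     params = triage_params()) {
  unknown <- setdiff(reference_samples, sample_ids(matrix))
  if (length(unknown) > 0) {
    abort_validation("Unknown reference sample ID(s): %s",
                     paste(unknown, collapse = ", "))
  }
  ps <- eligible$probeset_id[
    eligible$transcript_cluster_id == candidate$transcript_cluster_id]
  vals <- mat_values(matrix)[ps, , drop = FALSE]
  rk <- cluster_rank_matrix(vals)  # samples x probe sets
  k <- candidate$cut_index
  n <- length(ps)
  signed_diff <- rowMeans(rk[, seq_len(k), drop = FALSE]) -
    rowMeans(rk[, seq.int(k + 1, n), drop = FALSE])
  d0 <- signed_diff[candidate$examined_sample]
  dref <- signed_diff[reference_samples]
  similar <- sign(dref) == sign(d0) &
    abs(dref) >= params$similarity_fraction * abs(d0)
  if (any(similar)) "drop_reference_similar" else "keep"
}

#' Triage screening candidates
#'
#' Applies the exclusion rules in fixed order — isoform-explained,
#' multi-gene cluster, reference-sample similarity — and assigns each
#' candidate the verdict of the first rule that fires (or `"keep"`). Rules
#' whose side table (or reference set) is absent are skipped. Candidates
#' lacking the screening list-columns (e.g. re-read from a TSV report) are
#' reconstructed from `matrix` + `annotations`.
#'
#' @param candidates Candidate tibble from [screen()] or [read_candidates()].
#' @param isoforms Optional isoform tibble ([read_isoforms()]).
#' @param gene_overlaps Optional overlap tibble ([read_gene_overlaps()]).
#' @param matrix Expression matrix tibble; required for the reference rule
#'   or to reconstruct candidate sides. Normalized internally according to
#'   `screen_params$median_target`.
#' @param annotations Annotation tibble; required with `matrix`.
#' @param reference_samples Optional character vector of reference sample
#'   IDs; enables the reference-similarity rule.
#' @param params A [triage_params()] object.
#' @param screen_params The [screen_params()] used for the screen (needed to
#'   reproduce the eligible probe-set ordering).
#' @return The candidate tibble with `verdict` and `detail` columns
#'   appended.
#' @export
triage <- function(candidates, isoforms = NULL, gene_overlaps = NULL,
                   matrix = NULL, annotations = NULL,
                   reference_samples = NULL,
                   params = triage_params(),
                   screen_params = fusescreen::screen_params()) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, verdict = character(0),
                         detail = character(0)))
  }
  eligible <- NULL
  need_matrix <- !is.null(reference_samples) ||
    !all(c("probesets_5p", "probesets_3p", "cut_index") %in% names(candidates))
  if (need_matrix) {
    if (is.null(matrix) || is.null(annotations)) {
      abort_validation(
        "`matrix` and `annotations` are required to reconstruct candidate sides or apply the reference rule.")
    }
    if (is.finite(screen_params$median_target)) {
      matrix <- scale_to_median(matrix, screen_params$median_target)
    }
    eligible <- filter_probesets(matrix, annotations, screen_params)
    candidates <- reconstruct_sides(candidates, eligible)
  }
  verdicts <- purrr::map_chr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    if (!is.null(isoforms)) {
      v <- filter_isoform_explained(cand, isoforms, params)
      if (v != "keep") return(v)
    }
    if (!is.null(gene_overlaps)) {
      v <- filter_multigene(cand, gene_overlaps)
      if (v != "keep") return(v)
    }
    if (!is.null(reference_samples)) {
      v <- filter_reference_similar(cand, matrix, eligible,
                                    reference_samples, params)
      if (v != "keep") return(v)
    }
    "keep"
  })
  out <- dplyr::mutate(
    candidates,
    verdict = verdicts,
    detail = dplyr::case_match(
      verdicts,
      "drop_isoform" ~ "higher side matches a registered isoform",
      "drop_multigene" ~ "cluster overlaps two or more genes",
      "drop_reference_similar" ~ "similar profile in a reference sample",
      .default = "retained"
    )
  )
  counts <- table(factor(verdicts, levels = c("keep", "drop_isoform",
                                              "drop_multigene",
                                              "drop_reference_similar")))
  message(sprintf(
    "triage: %d candidate(s) -> keep %d, isoform %d, multigene %d, reference %d",
    nrow(out), counts[["keep"]], counts[["drop_isoform"]],
    counts[["drop_multigene"]], counts[["drop_reference_similar"]]))
  out
}

# rebuild cut_index and side probe-set lists from the eligible ordering
reconstruct_sides <- function(candidates, eligible) {
  by_cluster <- split(eligible$probeset_id, eligible$transcript_cluster_id)
  rebuilt <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    ps <- by_cluster[[cand$transcript_cluster_id]]
    if (is.null(ps)) {
      abort_validation("Cluster '%s' not present among eligible clusters.",
                       cand$transcript_cluster_id)
    }
    k <- if ("cut_index" %in% names(cand) && !is.na(cand$cut_index)) {
      as.integer(cand$cut_index)
    } else {
      match(cand$upstream_probeset_id, ps)
    }
    if (is.na(k) || k < 1 || k >= length(ps)) {
      abort_validation("Cannot place cut for cluster '%s' / sample '%s'.",
                       cand$transcript_cluster_id, cand$examined_sample)
    }
    list(k = k, p5 = ps[seq_len(k)], p3 = ps[seq.int(k + 1, length(ps))])
  })
  candidates$cut_index <- purrr::map_int(rebuilt, "k")
  candidates$probesets_5p <- purrr::map(rebuilt, "p5")
  candidates$probesets_3p <- purrr::map(rebuilt, "p3")
  candidates
}
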