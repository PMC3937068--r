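# Small deterministic fixtures built in code.

toy_annotations <- function(ids, cluster = "TC1", chrom = "chr1",
                            strand = "+", start = seq_along(ids) * 1000,
                            evidence = "core", hyb = "unique") {
  tibble::tibble(
    probeset_id = ids,
    transcript_cluster_id = rep_len(cluster, length(ids)),
    chromosome = rep_len(chrom, length(ids)),
    strand = rep_len(strand, length(ids)),
    start = start,
    stop = start + 100,
    evidence_level = rep_len(evidence, length(ids)),
    hybridization_target = rep_len(hyb, length(ids))
  )
}

# one cluster, values given as a probe-set x sample matrix
toy_matrix <- function(values, ids = sprintf("PS%02d", seq_len(nrow(values))),
                       samples = sprintf("S%02d", seq_len(ncol(values)))) {
  m <- tibble::as_tibble(as.data.frame(values))
  names(m) <- samples
  dplyr::mutate(m, probeset_id = ids, .before = 1)
}

# Deterministic multi-cluster dataset with one injected 5'-amplified event
# per cluster for sample "E": 8 probe sets per cluster, single cut at 4,
# 7 samples whose baselines are strictly ordered so ranks are by design.
# ref_amplified_clusters: clusters where reference "R" carries the same
# aberration (for the reference-similarity rule).
make_triage_fixture <- function(n_clusters,
                                ref_amplified_clusters = integer(0)) {
  samples <- c("E", "R", paste0("S", 3:7))
  clusters <- sprintf("TC%02d", seq_len(n_clusters))
  ann <- purrr::map(seq_len(n_clusters), function(ci) {
    toy_annotations(sprintf("%s_PS%d", clusters[ci], 1:8),
                    cluster = clusters[ci],
                    start = seq_len(8) * 1000 + ci * 100000)
  }) |> dplyr::bind_rows()
  vals <- matrix(0, nrow = nrow(ann), ncol = length(samples),
                 dimnames = list(ann$probeset_id, samples))
  for (j in seq_along(samples)) vals[, j] <- 100 * (1 + 0.02 * j)
  for (ci in seq_len(n_clusters)) {
    rows <- ann$transcript_cluster_id == clusters[ci] &
      grepl("_PS[1-4]$", ann$probeset_id)
    vals[rows, "E"] <- vals[rows, "E"] * 8
    if (ci %in% ref_amplified_clusters) {
      vals[rows, "R"] <- vals[rows, "R"] * 8
    }
  }
  list(
    matrix = toy_matrix(vals, ids = ann$probeset_id, samples = samples),
    annotations = ann,
    clusters = clusters,
    params = screen_params(min_intensity = 0, median_target = NA)
  )
}

# isoform table whose isoforms cover exactly the 5' (higher) side of the
# given clusters
isoforms_for <- function(clusters) {
  tibble::tibble(
    isoform_id = paste0("ISO_", clusters),
    cluster_id = clusters,
    covered_probesets = purrr::map(clusters,
                                   \(cl) sprintf("%s_PS%d", cl, 1:4))
  )
}
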