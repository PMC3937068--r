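# First-principles brute-force re-implementation of the screen, kept
# deliberately naive (counting ranks, explicit sum loops) and independent of
# the package's vectorized code path. Used as the oracle in equivalence
# tests.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_rank <- function(v) {
  vapply(seq_along(v), function(i) {
    1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
  }, numeric(1))
}

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# full screen by enumeration over every (cluster, sample, cut)
oracle_screen <- function(matrix, annotations, params = screen_params()) {
  samples <- setdiff(names(matrix), "probeset_id")
  vals <- as.matrix(matrix[samples])
  rownames(vals) <- matrix$probeset_id
  if (is.finite(params$median_target)) {
    for (s in seq_along(samples)) {
      vals[, s] <- vals[, s] * (params$median_target / oracle_median(vals[, s]))
    }
  }
  ann <- annotations
  ann$evidence_level <- tolower(ann$evidence_level)
  ann$hybridization_target <- tolower(ann$hybridization_target)
  ann$strand <- chartr("−", "-", ann$strand)
  ann <- ann[ann$probeset_id %in% rownames(vals), ]

  out <- list()
  for (cl in sort(unique(ann$transcript_cluster_id))) {
    sub <- ann[ann$transcript_cluster_id == cl, ]
    ord <- if (sub$strand[1] == "+") {
      order(sub$start, sub$probeset_id)
    } else {
      order(-sub$start, sub$probeset_id)
    }
    sub <- sub[ord, ]
    keep <- logical(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      row <- vals[sub$probeset_id[i], ]
      keep[i] <- sub$hybridization_target[i] %in% params$required_hybridization &&
        sub$evidence_level[i] %in% params$required_evidence &&
        max(row) >= params$min_intensity
    }
    ps <- sub$probeset_id[keep]
    n <- length(ps)
    if (n < params$min_cluster_probesets) next
    rk <- matrix(0, nrow = length(samples), ncol = n)
    for (j in seq_len(n)) rk[, j] <- oracle_rank(vals[ps[j], ])
    for (s in seq_along(samples)) {
      qual <- list()
      for (k in seq_len(n - 1)) {
        if (k < params$min_group_size || n - k < params$min_group_size) next
        g5 <- rk[s, 1:k]
        g3 <- rk[s, (k + 1):n]
        d <- abs(oracle_mean(g5) - oracle_mean(g3))
        s5 <- oracle_sd(g5)
        s3 <- oracle_sd(g3)
        if (d >= params$rank_diff_fraction * length(samples) &&
            min(s5, s3) <= params$max_group_rank_sd) {
          qual[[length(qual) + 1]] <- list(k = k, d = d, m5 = oracle_mean(g5),
                                           m3 = oracle_mean(g3), s5 = s5,
                                           s3 = s3)
        }
      }
      if (length(qual) == 0) next
      best <- qual[[1]]
      for (q in qual) {
        if (q$d > best$d ||
            (q$d == best$d && min(q$s5, q$s3) < min(best$s5, best$s3)) ||
            (q$d == best$d && min(q$s5, q$s3) == min(best$s5, best$s3) &&
             q$k < best$k)) {
          best <- q
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        transcript_cluster_id = cl, examined_sample = samples[s],
        cut_index = best$k,
        upstream_probeset_id = ps[best$k],
        downstream_probeset_id = ps[best$k + 1],
        mean_rank_5p = best$m5, mean_rank_3p = best$m3, rank_diff = best$d,
        sd_5p = best$s5, sd_3p = best$s3,
        n_qualifying_cuts = length(qual))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      transcript_cluster_id = character(), examined_sample = character(),
      cut_index = integer(), upstream_probeset_id = character(),
      downstream_probeset_id = character(), mean_rank_5p = double(),
      mean_rank_3p = double(), rank_diff = double(), sd_5p = double(),
      sd_3p = double(), n_qualifying_cuts = integer())
  }
  dplyr::arrange(res, transcript_cluster_id, examined_sample)
}
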