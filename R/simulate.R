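#' Simulation parameters
#'
#' Describes a synthetic summarized exon-array dataset. The generative model
#' mirrors the stylized facts of probe-set-level data: every probe set has
#' its own multiplicative affinity (amplification, labeling and
#' hybridization efficiency differ per targeted region, so intensity and
#' dynamic range vary greatly between probe sets of one gene), every
#' (sample, cluster) pair has a log-normal expression level, and
#' measurement noise is multiplicative. A fusion-type event silences the
#' event sample's native expression of the cluster (low-tail baseline) and
#' multiplies the fused side's probe sets by `fold_change`, producing the
#' sharp intragenic discontinuity — high on one side of the cut, low on the
#' other relative to references — that the screen targets.
#'
#' @param n_samples Number of arrays (default 17, the validation geometry).
#' @param n_clusters Number of transcript clusters.
#' @param probesets_per_cluster Single count or `c(min, max)` range.
#' @param affinity_log_mean,affinity_log_sd Log-normal parameters of the
#'   per-probe-set affinity.
#' @param expression_log_mean,expression_log_sd Log-normal parameters of
#'   the per-(sample, cluster) expression level.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (log-normal, mean 1) measurement noise.
#' @param events Optional tibble of events with columns `cluster_id`,
#'   `sample_id`, `cut_index`, `side` (`"five_prime"`/`"three_prime"`),
#'   `fold_change`. If `NULL` and `n_events > 0`, events are placed
#'   automatically at admissible cuts of randomly chosen clusters.
#' @param n_events Number of auto-placed events (ignored when `events` is
#'   supplied).
#' @param fold_change Fold change of auto-placed events.
#' @param frac_nonunique Fraction of probe sets labeled `similar`/`mixed`.
#' @param frac_noncore Fraction of probe sets labeled `extended`/`full`.
#' @param event_baseline_quantile The event sample's native expression for
#'   the fused cluster is drawn at a quantile uniform in
#'   `[0, event_baseline_quantile]` of the expression distribution (the
#'   partner gene's own promoter is weak in the rearranged sample).
#' @param min_group_size Minimum observable probe sets each side of an
#'   auto-placed event's cut must retain (matches the screen's group-size
#'   floor). A probe set counts as observable when it is label-eligible
#'   (core, unique) and reaches `placement_floor` in at least one sample of
#'   the normalized baseline matrix, so injected breakpoints are ones the
#'   screen's filters leave visible.
#' @param placement_floor Intensity floor used for the observability check
#'   during automatic event placement (matches the screen's default
#'   `min_intensity`, applied after scaling arrays to median 100).
#' @param seed Integer seed; generation is a pure function of the
#'   parameters and this seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 17,
                       n_clusters = 20,
                       probesets_per_cluster = c(10, 20),
                       affinity_log_mean = log(100),
                       affinity_log_sd = 1.0,
                       expression_log_mean = 0,
                       expression_log_sd = 0.5,
                       noise_cv = 0.15,
                       events = NULL,
                       n_events = 0,
                       fold_change = 8,
                       frac_nonunique = 0.1,
                       frac_noncore = 0.1,
                       event_baseline_quantile = 0.15,
                       min_group_size = 4,
                       placement_floor = 30,
                       seed = 20140218) {
  if (noise_cv < 0) abort_validation("`noise_cv` must be non-negative.")
  for (f in c(frac_nonunique, frac_noncore, event_baseline_quantile)) {
    if (f < 0 || f > 1) abort_validation("Fractions must lie in [0, 1].")
  }
  if (n_samples < 2 || n_clusters < 1) {
    abort_validation("Counts must be positive (and n_samples >= 2).")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_clusters = as.integer(n_clusters),
         probesets_per_cluster = as.integer(probesets_per_cluster),
         affinity_log_mean = affinity_log_mean,
         affinity_log_sd = affinity_log_sd,
         expression_log_mean = expression_log_mean,
         expression_log_sd = expression_log_sd,
         noise_cv = noise_cv,
         events = events,
         n_events = as.integer(n_events),
         fold_change = fold_change,
         frac_nonunique = frac_nonunique,
         frac_noncore = frac_noncore,
         event_baseline_quantile = event_baseline_quantile,
         min_group_size = as.integer(min_group_size),
         placement_floor = placement_floor,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate a summarized exon-array dataset with injected breakpoints
#'
#' Generates intensities `affinity(p) * expression(sample, cluster(p)) *
#' noise(p, sample)`, plus annotations (genomic placement, evidence level,
#' hybridization class) and a truth table of the injected events. Probe sets
#' are laid out so that transcript order matches their index within the
#' cluster regardless of strand (clusters alternate between `+` and `-`).
#' `cut_index` in the truth table counts probe sets in transcript order over
#' the full cluster, before any eligibility filtering.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `matrix` (expression tibble), `annotations`
#'   (annotation tibble) and `truth` (event tibble with columns
#'   `cluster_id`, `sample_id`, `cut_index`, `side`, `fold_change`).
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params
  sizes <- if (length(p$probesets_per_cluster) == 1) {
    rep(p$probesets_per_cluster, p$n_clusters)
  } else {
    sample(seq(p$probesets_per_cluster[1], p$probesets_per_cluster[2]),
           p$n_clusters, replace = TRUE)
  }
  cluster_ids <- sprintf("TC%03d", seq_len(p$n_clusters))
  samples <- sprintf("S%02d", seq_len(p$n_samples))
  ann <- purrr::map2(cluster_ids, seq_along(cluster_ids), function(cl, ci) {
    n <- sizes[ci]
    strand <- if (ci %% 2 == 1) "+" else "-"
    # transcript position t = 1..n; genomic start chosen so transcript
    # order (start asc on +, desc on -) recovers t
    t <- seq_len(n)
    start <- if (strand == "+") t * 1000 else (n - t + 1) * 1000
    tibble::tibble(
      probeset_id = sprintf("%s_PS%02d", cl, t),
      transcript_cluster_id = cl,
      chromosome = sprintf("chr%d", (ci - 1) %% 22 + 1),
      strand = strand,
      start = start,
      stop = start + 100,
      evidence_level = sample(
        c("core", "extended", "full"), n, replace = TRUE,
        prob = c(1 - p$frac_noncore, p$frac_noncore / 2, p$frac_noncore / 2)),
      hybridization_target = sample(
        c("unique", "similar", "mixed"), n, replace = TRUE,
        prob = c(1 - p$frac_nonunique, p$frac_nonunique / 2,
                 p$frac_nonunique / 2)),
      transcript_position = t
    )
  }) |> dplyr::bind_rows()

  affinity <- stats::rlnorm(nrow(ann), p$affinity_log_mean, p$affinity_log_sd)
  expr <- matrix(
    stats::rlnorm(p$n_clusters * p$n_samples, p$expression_log_mean,
                  p$expression_log_sd),
    nrow = p$n_clusters, dimnames = list(cluster_ids, samples))
  sdlog <- sqrt(log1p(p$noise_cv^2))
  noise <- matrix(
    stats::rlnorm(nrow(ann) * p$n_samples, -sdlog^2 / 2, sdlog),
    nrow = nrow(ann))
  baseline <- affinity * expr[ann$transcript_cluster_id, , drop = FALSE] *
    noise
  dimnames(baseline) <- list(ann$probeset_id, samples)

  # observability of each probe set under the screen's default filters,
  # assessed on the normalized baseline (events only raise intensities)
  scaled <- sweep(baseline, 2, 100 / apply(baseline, 2, stats::median), "*")
  floor_ok <- apply(scaled, 1, max) >= p$placement_floor

  events <- resolve_events(p, ann, cluster_ids, samples, sizes, floor_ok)

  # event samples: native expression drawn from the low tail. Events with
  # fold_change == 1 are inert by contract and leave the dataset untouched.
  vals <- baseline
  active <- which(events$fold_change > 1)
  if (length(active) > 0) {
    q <- stats::runif(length(active), 0, p$event_baseline_quantile)
    new_expr <- stats::qlnorm(q, p$expression_log_mean, p$expression_log_sd)
    old_expr <- expr[cbind(events$cluster_id[active],
                           events$sample_id[active])]
    for (j in seq_along(active)) {
      ev <- events[active[j], ]
      rows <- ann$transcript_cluster_id == ev$cluster_id
      vals[rows, ev$sample_id] <- vals[rows, ev$sample_id] *
        (new_expr[j] / old_expr[j])
    }
  }

  # apply events: multiply the fused side by fold_change (fold 1 is a no-op)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    in_cluster <- ann$transcript_cluster_id == ev$cluster_id
    on_side <- if (ev$side == "five_prime") {
      ann$transcript_position <= ev$cut_index
    } else {
      ann$transcript_position > ev$cut_index
    }
    vals[in_cluster & on_side, ev$sample_id] <-
      vals[in_cluster & on_side, ev$sample_id] * ev$fold_change
  }

  matrix <- tibble::as_tibble(vals) |>
    dplyr::mutate(probeset_id = ann$probeset_id, .before = 1)
  list(
    matrix = matrix,
    annotations = dplyr::select(ann, -"transcript_position"),
    truth = events
  )
}

# validate explicit events or place n_events automatically at cuts leaving
# >= min_group_size observable (core & unique & above-floor) probe sets on
# each side
resolve_events <- function(p, ann, cluster_ids, samples, sizes, floor_ok) {
  empty <- tibble::tibble(cluster_id = character(), sample_id = character(),
                          cut_index = integer(), side = character(),
                          fold_change = double())
  label_ok <- ann$evidence_level == "core" &
    ann$hybridization_target == "unique" & floor_ok
  elig_cum <- split(label_ok, ann$transcript_cluster_id)
  valid_cuts <- function(cl) {
    ok <- elig_cum[[cl]]
    cum <- cumsum(ok)
    tot <- cum[length(cum)]
    k <- seq_len(length(ok) - 1)
    k[cum[k] >= p$min_group_size & (tot - cum[k]) >= p$min_group_size]
  }
  if (!is.null(p$events)) {
    ev <- tibble::as_tibble(p$events)
    for (i in seq_len(nrow(ev))) {
      ci <- match(ev$cluster_id[i], cluster_ids)
      if (is.na(ci)) abort_validation("Event cluster '%s' does not exist.",
                                      ev$cluster_id[i])
      if (!ev$sample_id[i] %in% samples) {
        abort_validation("Event sample '%s' does not exist.", ev$sample_id[i])
      }
      if (ev$cut_index[i] < 1 || ev$cut_index[i] >= sizes[ci]) {
        abort_validation(
          "Event cut %d leaves an empty side in cluster '%s' (%d probe sets).",
          ev$cut_index[i], ev$cluster_id[i], sizes[ci])
      }
      if (!ev$side[i] %in% c("five_prime", "three_prime")) {
        abort_validation("Event side must be 'five_prime' or 'three_prime'.")
      }
      if (ev$fold_change[i] < 1) {
        abort_validation("Event fold_change must be >= 1.")
      }
    }
    return(if (nrow(ev) == 0) empty else ev)
  }
  if (p$n_events == 0) return(empty)
  hosts <- cluster_ids[purrr::map_int(cluster_ids,
                                      \(cl) length(valid_cuts(cl))) > 0]
  if (length(hosts) < p$n_events) {
    abort_validation(
      "Cannot place %d event(s): only %d cluster(s) admit a valid cut.",
      p$n_events, length(hosts))
  }
  chosen <- sample(hosts, p$n_events)
  tibble::tibble(
    cluster_id = chosen,
    sample_id = sample(samples, p$n_events, replace = TRUE),
    cut_index = purrr::map_int(chosen, function(cl) {
      ks <- valid_cuts(cl)
      ks[sample.int(length(ks), 1)]
    }),
    side = sample(c("five_prime", "three_prime"), p$n_events, replace = TRUE),
    fold_change = rep(p$fold_change, p$n_events)
  )
}

#' Map truth cut indices into the eligible probe-set ordering
#'
#' Truth events count probe sets over the full cluster; the screen reports
#' cuts over the eligible (filtered) probe sets. This helper recomputes each
#' truth cut as the number of eligible probe sets on its 5' side, returning
#' `NA` for events whose cluster was dropped or whose cut no longer leaves
#' both sides non-empty.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param annotations Annotation tibble of the same dataset.
#' @param eligible Eligible probe-set tibble from [filter_probesets()].
#' @return `truth` with an added `cut_index_eligible` column.
#' @export
align_truth_cuts <- function(truth, annotations, eligible) {
  index <- build_cluster_index(annotations)
  truth$cut_index_eligible <- purrr::map_int(seq_len(nrow(truth)), function(i) {
    cl <- truth$cluster_id[i]
    full <- index$probeset_id[index$transcript_cluster_id == cl]
    kept <- eligible$probeset_id[eligible$transcript_cluster_id == cl]
    if (length(kept) == 0) return(NA_integer_)
    k <- sum(full[seq_len(truth$cut_index[i])] %in% kept)
    if (k < 1 || k >= length(kept)) NA_integer_ else as.integer(k)
  })
  truth
}

#' Summarize recovery of injected events by a screening result
#'
#' Joins a screening result against the simulator truth table: an event
#' counts as detected when its (cluster, sample) pair was flagged;
#' `cut_error` is the signed distance from the reported best cut to the
#' truth cut, both in eligible-probe-set coordinates.
#'
#' @param candidates A `fusion_screen` tibble from [screen()].
#' @param truth Truth tibble from [simulate_dataset()].
#' @param matrix,annotations The simulated dataset.
#' @param params The [screen_params()] used for the screen.
#' @return `truth` with columns `cut_index_eligible`, `detected` and
#'   `cut_error` appended.
#' @export
summarize_recovery <- function(candidates, truth, matrix, annotations,
                               params = screen_params()) {
  if (is.finite(params$median_target)) {
    matrix <- scale_to_median(matrix, params$median_target)
  }
  eligible <- filter_probesets(matrix, annotations, params)
  truth <- align_truth_cuts(truth, annotations, eligible)
  hits <- tibble::as_tibble(candidates)[c("transcript_cluster_id",
                                          "examined_sample", "cut_index")]
  truth |>
    dplyr::left_join(hits, by = c(cluster_id = "transcript_cluster_id",
                                  sample_id = "examined_sample")) |>
    dplyr::mutate(detected = !is.na(.data$cut_index.y),
                  cut_error = .data$cut_index.y - .data$cut_index_eligible) |>
    dplyr::rename(cut_index = "cut_index.x",
                  detected_cut = "cut_index.y")
}

#' Write a ready-made simulated fixture to disk
#'
#' Three stock scenarios: `tall_like` — 17 samples, 12 clusters of 14 probe
#' sets, three 8-fold events in three distinct samples covering both
#' directions plus one cut at the minimum group size; `null_only` — 50
#' event-free clusters; `boundary_cases` — three clusters of exactly 8
#' fully eligible probe sets (a single admissible cut) with one event.
#' Stock fixtures use a tighter per-probe-set affinity spread
#' (`affinity_log_sd = 0.5`) so that no fixture probe set falls below the
#' default intensity floor and the advertised cluster geometry is stable.
#'
#' @param name One of `"tall_like"`, `"null_only"`, `"boundary_cases"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixture <- function(name = c("tall_like", "null_only",
                                  "boundary_cases"),
                         dir, seed = 20140218) {
  name <- match.arg(name)
  params <- switch(
    name,
    tall_like = sim_params(
      n_samples = 17, n_clusters = 12, probesets_per_cluster = 14,
      frac_nonunique = 0.05, frac_noncore = 0.05, seed = seed,
      affinity_log_sd = 0.5, noise_cv = 0.1,
      events = tibble::tibble(
        cluster_id = c("TC001", "TC002", "TC003"),
        sample_id = c("S03", "S08", "S12"),
        cut_index = c(7L, 7L, 4L),
        side = c("three_prime", "five_prime", "three_prime"),
        fold_change = c(8, 8, 8))),
    null_only = sim_params(n_samples = 17, n_clusters = 50, seed = seed,
                           affinity_log_sd = 0.5),
    boundary_cases = sim_params(
      n_samples = 17, n_clusters = 3, probesets_per_cluster = 8,
      frac_nonunique = 0, frac_noncore = 0, seed = seed,
      affinity_log_sd = 0.5,
      events = tibble::tibble(
        cluster_id = "TC001", sample_id = "S05", cut_index = 4L,
        side = "three_prime", fold_change = 8))
  )
  ds <- simulate_dataset(params)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) abort_io("Cannot create fixture directory: %s", dir)
  paths <- list(
    matrix = file.path(dir, paste0(name, "_matrix.tsv")),
    annotations = file.path(dir, paste0(name, "_annotations.csv")),
    truth = file.path(dir, paste0(name, "_truth.tsv"))
  )
  readr::write_tsv(ds$matrix, paths$matrix, progress = FALSE)
  readr::write_csv(ds$annotations, paths$annotations, progress = FALSE)
  readr::write_tsv(ds$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
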