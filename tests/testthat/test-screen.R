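test_that("median scaling hits the target and scales columns independently", {
  m <- toy_matrix(cbind(c(1, 2, 3)), samples = "S1")
  expect_equal(scale_to_median(m, 100)$S1, c(50, 100, 150))

  already <- toy_matrix(cbind(c(50, 100, 150)), samples = "S1")
  expect_equal(scale_to_median(already, 100), already)

  # 2x2 hand-computed oracle: columns scale by target/median, so
  # within-row cross-column ratios change accordingly
  m2 <- toy_matrix(cbind(c(1, 3), c(2, 4)))
  sc <- scale_to_median(m2, 100)
  expect_equal(sc$S01, c(50, 150))              # median 2 -> factor 50
  expect_equal(sc$S02, c(200 / 3, 400 / 3))     # median 3 -> factor 100/3
  expect_equal(sc$S02[1] / sc$S01[1], 4 / 3)    # was 2 before scaling

  zero <- toy_matrix(cbind(c(0, 0, 1)), samples = "BAD")
  expect_error(scale_to_median(zero, 100), "BAD")
})

test_that("probe-set filter applies annotation, intensity and cluster-size rules", {
  ids <- sprintf("PS%02d", 1:10)
  ann <- toy_annotations(ids)
  ann$hybridization_target[9] <- "similar"
  ann$evidence_level[10] <- "extended"
  vals <- matrix(100, nrow = 10, ncol = 3)
  vals[1, ] <- c(29.9, 25, 10)    # never reaches 30 -> excluded
  vals[2, ] <- c(29.9, 30.0, 10)  # boundary inclusive -> included
  m <- toy_matrix(vals, ids = ids)
  p <- screen_params(median_target = NA)

  elig <- filter_probesets(m, ann, p)
  expect_equal(nrow(elig), 0)  # only 7 probe sets survive -> cluster dropped

  # restore one probe set so 8 are eligible: cluster retained
  ann2 <- ann
  ann2$hybridization_target[9] <- "unique"
  elig2 <- filter_probesets(m, ann2, p)
  expect_equal(elig2$probeset_id, ids[2:9])
  expect_equal(elig2$position, 1:8)

  expect_warning(filter_probesets(m[1:9, ], ann2, p), "dropped")
})

test_that("sample ranking is ascending, tie-averaged and monotone-invariant", {
  expect_equal(rank_samples(c(5, 2, 9)), c(2, 1, 3))
  expect_equal(rank_samples(c(4, 4, 7)), c(1.5, 1.5, 3))
  set.seed(7)
  for (i in 1:20) {
    x <- rlnorm(11)
    expect_identical(rank_samples(x), rank_samples(log(x)))
    expect_equal(sum(rank_samples(x)), 11 * 12 / 2)  # rank conservation
  }
})

test_that("cut enumeration respects the terminal-group floor", {
  expect_equal(enumerate_cutpoints(8, 4), 4L)
  expect_equal(enumerate_cutpoints(10, 4), c(4L, 5L, 6L))
  expect_equal(enumerate_cutpoints(7, 4), integer(0))
})

test_that("cut scoring reproduces hand-computed means, SDs and pass flags", {
  p <- screen_params()
  # constant groups: ranks 10 vs 1 in a 10-sample pool
  st <- score_cutpoint(c(10, 10, 10, 10, 1, 1, 1, 1), 4, 10, p)
  expect_equal(st$rank_diff, 9)
  expect_equal(st$sd_5p, 0)
  expect_equal(st$sd_3p, 0)
  expect_true(st$passes_diff)  # 9 >= 0.7 * 10
  expect_true(st$passes_sd)

  # alternating 5' group: mean 5, sample SD sqrt(64/3); diff 0 fails
  st2 <- score_cutpoint(c(9, 1, 9, 1, 5, 5, 5, 5), 4, 10, p)
  expect_equal(st2$rank_diff, 0)
  expect_false(st2$passes_diff)
  expect_equal(st2$sd_5p, sqrt(64 / 3))  # 4.618802...
  expect_equal(st2$sd_3p, 0)
  expect_true(st2$passes_sd)

  # 17-sample qualifying bound is 0.7 * 17 = 11.9
  expect_equal(p$rank_diff_fraction * 17, 11.9)
  st3 <- score_cutpoint(c(rep(14, 4), rep(2.09, 4)), 4, 17, p)
  expect_true(st3$passes_diff)   # 11.91 >= 11.9
  st4 <- score_cutpoint(c(rep(14, 4), rep(2.2, 4)), 4, 17, p)
  expect_false(st4$passes_diff)  # 11.8 < 11.9
})

test_that("detection flags the right sample at the injected cut in either direction", {
  # 17 samples with strictly ordered baselines, 10 probe sets; sample 1 has
  # the lowest baseline and its 3' side is amplified 8x
  n_ps <- 10; n_s <- 17
  base <- outer(rep(1, n_ps), 100 * (1 + 0.05 * seq_len(n_s)))
  amp3 <- base
  amp3[7:10, 1] <- base[7:10, 1] * 8
  ann <- toy_annotations(sprintf("PS%02d", 1:n_ps))
  p <- screen_params(min_intensity = 0, median_target = NA)

  cand3 <- detect_candidates("TC1", sprintf("PS%02d", 1:n_ps),
                             toy_matrix(amp3), p)
  expect_equal(nrow(cand3), 1)
  expect_equal(cand3$examined_sample, "S01")
  expect_equal(cand3$cut_index, 6L)
  expect_equal(cand3$upstream_probeset_id, "PS06")
  expect_equal(cand3$downstream_probeset_id, "PS07")

  # amplifying the 5' side instead flags the same sample at the same cut
  amp5 <- base
  amp5[1:6, 1] <- base[1:6, 1] * 8
  cand5 <- detect_candidates("TC1", sprintf("PS%02d", 1:n_ps),
                             toy_matrix(amp5), p)
  expect_equal(cand5$examined_sample, cand3$examined_sample)
  expect_equal(cand5$cut_index, cand3$cut_index)
  expect_equal(cand5$rank_diff, cand3$rank_diff)

  # invariants of the candidate row
  expect_true(all(cand3$cuts[[1]]$passes_diff & cand3$cuts[[1]]$passes_sd))
  expect_true(cand3$cut_index %in% cand3$cuts[[1]]$cut_index)
  expect_equal(c(cand3$probesets_5p[[1]], cand3$probesets_3p[[1]]),
               sprintf("PS%02d", 1:n_ps))
})

test_that("screen output is invariant under strictly increasing per-probe-set transforms", {
  d <- simulate_dataset(sim_params(n_clusters = 8, n_events = 3, seed = 11))
  p <- screen_params(min_intensity = 0, median_target = NA)
  r1 <- screen(d$matrix, d$annotations, p)
  logged <- dplyr::mutate(d$matrix, dplyr::across(-probeset_id, log))
  r2 <- screen(logged, d$annotations, p)
  expect_identical(as.data.frame(tidy(r1)), as.data.frame(tidy(r2)))
  expect_gt(nrow(r1), 0)
})

test_that("mirroring transcript orientation mirrors the detected cut exactly", {
  d <- simulate_dataset(sim_params(n_clusters = 8, n_events = 4, seed = 5,
                                   probesets_per_cluster = 12,
                                   frac_nonunique = 0, frac_noncore = 0))
  p <- screen_params(min_intensity = 0, median_target = NA)
  fwd <- screen(d$matrix, d$annotations, p)
  # flip every cluster's strand: transcript order reverses, so a 5' event
  # becomes a 3' event at the mirrored cut with identical statistics
  flipped <- dplyr::mutate(d$annotations,
                           strand = ifelse(strand == "+", "-", "+"))
  rev <- screen(d$matrix, flipped, p)
  expect_equal(nrow(fwd), nrow(rev))
  expect_gt(nrow(fwd), 0)
  key <- function(x) dplyr::arrange(tidy(x), transcript_cluster_id,
                                    examined_sample)
  a <- key(fwd); b <- key(rev)
  n_elig <- 12L
  expect_identical(a$examined_sample, b$examined_sample)
  expect_identical(a$cut_index + b$cut_index, rep(n_elig, nrow(a)))
  expect_identical(a$rank_diff, b$rank_diff)
  expect_identical(a$sd_5p, b$sd_3p)
  expect_identical(a$sd_3p, b$sd_5p)
  expect_identical(a$mean_rank_5p, b$mean_rank_3p)
})

test_that("screen handles degenerate inputs and feasibility bounds", {
  # empty matrix -> empty candidate table
  empty <- screen(toy_matrix(matrix(0, 0, 2))[0, ], toy_annotations("PS01")[0, ])
  expect_equal(nrow(empty), 0)

  # with N = 3 samples the max rank difference is N - 1 = 2, below the
  # qualifying bound 0.7 * 3 = 2.1, so even a maximal discontinuity
  # cannot be flagged
  vals <- outer(rep(1, 8), c(1, 2, 3)) * 100
  vals[1:4, 1] <- 1e6   # sample 1: top rank on the whole 5' side
  vals[5:8, 1] <- 1e-3  # and bottom rank on the whole 3' side
  ann <- toy_annotations(sprintf("PS%02d", 1:8))
  r <- screen(toy_matrix(vals, ids = ann$probeset_id), ann,
              screen_params(min_intensity = 0, median_target = NA))
  expect_equal(nrow(r), 0)

  # rank_diff_fraction = 1 is unreachable whenever any tie exists
  d <- simulate_dataset(sim_params(n_clusters = 4, n_events = 2, seed = 3,
                                   noise_cv = 0))
  tied <- d$matrix
  tied[[sample_ids(tied)[1]]] <- tied[[sample_ids(tied)[2]]]  # force ties
  r2 <- screen(tied, d$annotations,
               screen_params(rank_diff_fraction = 1, min_intensity = 0,
                             median_target = NA))
  expect_equal(nrow(r2), 0)
})

test_that("production screener matches the brute-force oracle on random small clusters", {
  set.seed(101)
  for (rep in 1:15) {
    n_cl <- 3
    n_s <- sample(4:8, 1)
    ann <- purrr::map(seq_len(n_cl), function(ci) {
      n_ps <- sample(6:12, 1)
      a <- toy_annotations(sprintf("C%d_P%02d", ci, seq_len(n_ps)),
                           cluster = sprintf("TC%d", ci),
                           strand = sample(c("+", "-"), 1),
                           start = sample(seq_len(n_ps)) * 1000)
      a$evidence_level <- sample(c("core", "extended"), n_ps, TRUE,
                                 prob = c(0.9, 0.1))
      a$hybridization_target <- sample(c("unique", "mixed"), n_ps, TRUE,
                                       prob = c(0.9, 0.1))
      a
    }) |> dplyr::bind_rows()
    vals <- matrix(rlnorm(nrow(ann) * n_s, log(100), 1), ncol = n_s)
    # inject a discontinuity so candidate sets are often non-empty
    vals[seq_len(4), 1] <- vals[seq_len(4), 1] * 50
    vals[5:8, 1] <- vals[5:8, 1] / 50
    m <- toy_matrix(vals, ids = ann$probeset_id,
                    samples = sprintf("S%02d", seq_len(n_s)))
    got <- tidy(screen(m, ann))
    want <- oracle_screen(m, ann)
    expect_identical(got[c("transcript_cluster_id", "examined_sample",
                           "cut_index", "upstream_probeset_id",
                           "downstream_probeset_id", "n_qualifying_cuts")],
                     want[c("transcript_cluster_id", "examined_sample",
                            "cut_index", "upstream_probeset_id",
                            "downstream_probeset_id", "n_qualifying_cuts")])
    expect_equal(got$rank_diff, want$rank_diff, tolerance = 1e-12)
    expect_equal(got$sd_5p, want$sd_5p, tolerance = 1e-12)
    expect_equal(got$sd_3p, want$sd_3p, tolerance = 1e-12)
  }
})

test_that("rank conservation holds on every scored cluster", {
  d <- simulate_dataset(sim_params(n_clusters = 5, n_events = 2, seed = 9))
  m <- scale_to_median(d$matrix, 100)
  elig <- filter_probesets(m, d$annotations, screen_params())
  n_s <- length(sample_ids(m))
  vals <- as.matrix(m[match(elig$probeset_id, m$probeset_id), sample_ids(m)])
  sums <- apply(vals, 1, function(r) sum(rank_samples(r)))
  expect_true(all(sums == n_s * (n_s + 1) / 2))
})

test_that("tidy and glance summarize a screening run", {
  d <- simulate_dataset(sim_params(n_clusters = 5, n_events = 2, seed = 1))
  r <- screen(d$matrix, d$annotations)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_false(any(purrr::map_lgl(td, is.list)))
  g <- glance(r)
  expect_equal(g$n_candidates, nrow(r))
  expect_equal(g$rank_diff_threshold, 0.7 * 17)
})
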