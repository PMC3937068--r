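#' Read a probe-set annotation table
#'
#' Reads a NetAffx-style annotation table mapping each probe set to its
#' transcript cluster, genomic placement (1-based inclusive coordinates) and
#' quality annotations. Enum tokens (`evidence_level`,
#' `hybridization_target`, `strand`) are case-insensitive on input and
#' normalized to canonical lowercase / ASCII form.
#'
#' @param path Path to a delimited text file with header columns
#'   `probeset_id`, `transcript_cluster_id`, `chromosome`, `strand`, `start`,
#'   `stop`, `evidence_level`, `hybridization_target`.
#' @param format `"auto"` (by file extension; default), `"csv"` or `"tsv"`.
#' @return A tibble with one row per probe set, in file order.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "probeset_id,transcript_cluster_id,chromosome,strand,start,stop,evidence_level,hybridization_target",
#'   "PS1,TC1,chr22,+,100,200,core,unique"), path)
#' read_annotations(path)
#' @export
read_annotations <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io("Annotation file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  ann <- if (format == "tsv") {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  required <- c("probeset_id", "transcript_cluster_id", "chromosome",
                "strand", "start", "stop", "evidence_level",
                "hybridization_target")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    abort_validation("Annotation file is missing required column(s): %s",
                     paste(missing, collapse = ", "))
  }
  ann <- dplyr::select(ann, dplyr::all_of(required))
  validate_annotations(tidy_annotations(ann))
}

# normalize token case / unicode and coerce coordinate columns
tidy_annotations <- function(ann) {
  dplyr::mutate(
    ann,
    evidence_level = tolower(.data$evidence_level),
    hybridization_target = tolower(.data$hybridization_target),
    strand = chartr("−", "-", .data$strand),  # unicode minus -> ASCII
    start = suppressWarnings(as.numeric(.data$start)),
    stop = suppressWarnings(as.numeric(.data$stop))
  )
}

validate_annotations <- function(ann) {
  check_enum_column(ann$evidence_level, EVIDENCE_LEVELS, "evidence_level")
  check_enum_column(ann$hybridization_target, HYB_TARGETS,
                    "hybridization_target")
  check_enum_column(ann$strand, c("+", "-"), "strand")
  bad_coord <- which(is.na(ann$start) | is.na(ann$stop) |
                       ann$start > ann$stop)
  if (length(bad_coord) > 0) {
    abort_validation(
      "Invalid coordinates (start must be <= stop, both numeric) at data row(s): %s",
      paste(utils::head(bad_coord, 5), collapse = ", "))
  }
  dup <- ann$probeset_id[duplicated(ann$probeset_id)]
  if (length(dup) > 0) {
    abort_validation("Duplicate probeset_id in annotations: %s",
                     paste(unique(utils::head(dup, 5)), collapse = ", "))
  }
  ann
}

check_enum_column <- function(x, levels, what) {
  bad <- which(!x %in% levels)
  if (length(bad) > 0) {
    abort_validation(
      "Invalid %s token '%s' at data row %d (allowed: %s).",
      what, x[bad[1]], bad[1], paste(levels, collapse = ", "))
  }
  invisible(x)
}

#' Read a probe-set expression matrix
#'
#' Reads a tab-separated probe-set by sample intensity table. The first
#' column must be the probe-set identifier; each remaining column is one
#' sample's summarized intensities. Intensities must be finite, non-negative
#' numbers; missing values are not supported.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `probeset_id` character column followed by one
#'   numeric column per sample.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort_io("Expression matrix file not found: %s", path)
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (ncol(m) < 2) abort_validation("Expression matrix has no sample columns.")
  names(m)[1] <- "probeset_id"
  if (nrow(m) == 0) abort_validation("Expression matrix has no probe sets.")
  validate_matrix(dplyr::mutate(m, dplyr::across(-"probeset_id", as_strict_numeric)))
}

as_strict_numeric <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    abort_validation("Non-numeric or missing intensity value: '%s'.",
                     x[which(is.na(out))[1]])
  }
  out
}

validate_matrix <- function(m) {
  dup <- m$probeset_id[duplicated(m$probeset_id)]
  if (length(dup) > 0) {
    abort_validation("Duplicate probe-set ID in matrix: %s",
                     paste(unique(utils::head(dup, 5)), collapse = ", "))
  }
  samples <- setdiff(names(m), "probeset_id")
  if (anyDuplicated(samples)) {
    abort_validation("Duplicate sample ID in matrix: %s",
                     paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(m[samples])
  if (any(!is.finite(vals))) abort_validation("Intensities must be finite.")
  if (any(vals < 0)) {
    abort_validation("Negative intensity found (%s); intensities must be >= 0.",
                     format(min(vals)))
  }
  m
}

#' Matrix sample identifiers
#' @param matrix An expression matrix tibble (see [read_matrix()]).
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(matrix) setdiff(names(matrix), "probeset_id")

# numeric matrix with probeset_id rownames
mat_values <- function(matrix) {
  v <- as.matrix(matrix[sample_ids(matrix)])
  rownames(v) <- matrix$probeset_id
  v
}

#' Build a transcript-cluster index in transcript 5'->3' order
#'
#' Orders each transcript cluster's probe sets along the transcript: genomic
#' start ascending on the `+` strand, descending on the `-` strand, ties on
#' start broken by probe-set ID (lexicographic). Clusters mixing chromosomes
#' or strands are rejected.
#'
#' @param annotations Annotation tibble from [read_annotations()].
#' @return A tibble with columns `transcript_cluster_id`, `probeset_id`,
#'   `position` (1-based transcript-order index), `chromosome`, `strand`,
#'   `start`, `stop`.
#' @export
build_cluster_index <- function(annotations) {
  ann <- validate_annotations(tidy_annotations(annotations))
  bad <- ann |>
    dplyr::summarise(
      n_chrom = dplyr::n_distinct(.data$chromosome),
      n_strand = dplyr::n_distinct(.data$strand),
      .by = "transcript_cluster_id"
    ) |>
    dplyr::filter(.data$n_chrom > 1 | .data$n_strand > 1)
  if (nrow(bad) > 0) {
    abort_validation(
      "Transcript cluster(s) with mixed chromosome or strand: %s",
      paste(utils::head(bad$transcript_cluster_id, 5), collapse = ", "))
  }
  ann |>
    dplyr::mutate(
      .ord = ifelse(.data$strand == "+", .data$start, -.data$start)
    ) |>
    dplyr::arrange(.data$transcript_cluster_id, .data$.ord,
                   .data$probeset_id) |>
    dplyr::mutate(position = dplyr::row_number(),
                  .by = "transcript_cluster_id") |>
    dplyr::select("transcript_cluster_id", "probeset_id", "position",
                  "chromosome", "strand", "start", "stop")
}

candidate_report_columns <- c(
  "transcript_cluster_id", "examined_sample", "upstream_probeset_id",
  "downstream_probeset_id", "mean_rank_5p", "mean_rank_3p", "rank_diff",
  "sd_5p", "sd_3p", "n_qualifying_cuts"
)

#' Write a candidate report
#'
#' Serializes breakpoint candidates as a TSV, one row per (transcript
#' cluster, examined sample), sorted by cluster then sample. Numeric fields
#' are written with 6 significant digits so that written files round-trip
#' bit-identically through [read_candidates()].
#'
#' @param candidates A candidate tibble as returned by [screen()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  missing <- setdiff(candidate_report_columns, names(candidates))
  if (length(missing) > 0) {
    abort_validation("Candidate table is missing column(s): %s",
                     paste(missing, collapse = ", "))
  }
  out <- candidates |>
    dplyr::select(dplyr::all_of(candidate_report_columns)) |>
    dplyr::arrange(.data$transcript_cluster_id, .data$examined_sample) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double), \(x) signif(x, 6)))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io("Output directory does not exist: %s", dir)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a candidate report written by [write_candidates()]
#' @param path Path to the candidate TSV.
#' @return A tibble with the candidate report columns.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) abort_io("Candidate file not found: %s", path)
  readr::read_tsv(
    path,
    col_types = readr::cols(
      transcript_cluster_id = "c", examined_sample = "c",
      upstream_probeset_id = "c", downstream_probeset_id = "c",
      n_qualifying_cuts = "i", .default = "d"
    ),
    progress = FALSE
  )
}
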