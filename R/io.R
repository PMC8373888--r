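#' Matrix and cohort file I/O
#'
#' Matrices travel as TSV with region ids in the first row and first column;
#' missing entries are encoded as `NA`. One file per subject per input kind:
#' `<subject>_counts.tsv`, `<subject>_fa.tsv` and `<subject>_ts.tsv` (the
#' time-series file is T rows x R columns with region-id header only).
#'
#' @name conncoh-io
NULL

#' Write a square region matrix as TSV
#'
#' @param m Square matrix (region order ascending id).
#' @param path Output path.
#' @param region_ids Region id labels (default `1..R`).
#' @export
write_matrix_tsv <- function(m, path, region_ids = seq_len(nrow(m))) {
  df <- as.data.frame(m)
  names(df) <- region_ids
  df <- cbind(region_id = region_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square region matrix from TSV
#'
#' Validates the region-id header and first column, the expected dimension,
#' and symmetry (beyond tolerance 1e-9 is an error); `NA` cells map to
#' missing.
#'
#' @param path Input path.
#' @param expected_R Expected number of regions (optional).
#' @param symmetric Require symmetry (default TRUE).
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path, expected_R = NULL, symmetric = TRUE) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (names(df)[1] != "region_id") {
    stop("parse error in ", path, ": first column must be 'region_id', got '",
         names(df)[1], "'")
  }
  ids <- df$region_id
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop("parse error in ", path, ": ", nrow(m), " rows but ", ncol(m), " columns")
  }
  if (!is.null(expected_R) && nrow(m) != expected_R) {
    stop("dimension mismatch in ", path, ": expected ", expected_R,
         " regions, found ", nrow(m))
  }
  header_ids <- suppressWarnings(as.integer(colnames(m)))
  if (anyNA(header_ids) || !identical(header_ids, as.integer(ids))) {
    stop("header mismatch in ", path, ": column ids do not match row region_ids")
  }
  dimnames(m) <- NULL
  if (symmetric) check_square_symmetric(m, paste0("matrix in ", path))
  m
}

#' Write a time-series table as TSV
#'
#' @param ts `T x R` matrix.
#' @param path Output path.
#' @param region_ids Column labels (default `1..R`).
#' @export
write_timeseries_tsv <- function(ts, path, region_ids = seq_len(ncol(ts))) {
  df <- as.data.frame(ts)
  names(df) <- region_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time-series table from TSV
#'
#' @param path Input path.
#' @param expected_R Expected number of regions (optional).
#' @return `T x R` numeric matrix.
#' @export
read_timeseries_tsv <- function(path, expected_R = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.null(expected_R) && ncol(m) != expected_R) {
    stop("dimension mismatch in ", path, ": expected ", expected_R,
         " regions, found ", ncol(m))
  }
  dimnames(m) <- NULL
  m
}

#' Write a cohort's derivatives to a directory
#'
#' Produces `subjects.csv`, one `<subject>_counts.tsv`, `<subject>_fa.tsv`
#' and `<subject>_ts.tsv` per subject, and `ground_truth.json` (targets,
#' latent factors, config echo) when the cohort is synthetic.
#'
#' @param cohort A `conn_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (sid in names(cohort$bundles)) {
    b <- cohort$bundles[[sid]]
    write_matrix_tsv(b$counts, file.path(dir, paste0(sid, "_counts.tsv")))
    write_matrix_tsv(b$fa, file.path(dir, paste0(sid, "_fa.tsv")))
    write_timeseries_tsv(b$ts, file.path(dir, paste0(sid, "_ts.tsv")))
  }
  truth <- lapply(cohort$bundles, function(b) b$truth)
  if (!all(vapply(truth, is.null, logical(1)))) {
    jsonlite::write_json(
      list(seed = cohort$seed,
           config = cohort$config[c("n_regions", "n_timepoints", "n_control",
                                    "n_idhmut", "n_idhwt")],
           truth = truth),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort's derivatives from a directory
#'
#' Counterpart of [write_cohort()]; ground truth is not required.
#'
#' @param dir Directory holding `subjects.csv` and per-subject TSV files.
#' @param n_regions Expected region count (optional check).
#' @return A `conn_cohort` (without template/truth information).
#' @export
read_cohort <- function(dir, n_regions = NULL) {
  subjects <- read_subjects(file.path(dir, "subjects.csv"))
  bundles <- lapply(subjects$subject_id, function(sid) {
    counts <- read_matrix_tsv(file.path(dir, paste0(sid, "_counts.tsv")), n_regions)
    list(counts = counts,
         fa = read_matrix_tsv(file.path(dir, paste0(sid, "_fa.tsv")), n_regions),
         ts = read_timeseries_tsv(file.path(dir, paste0(sid, "_ts.tsv")), n_regions),
         truth = NULL)
  })
  names(bundles) <- subjects$subject_id
  structure(list(subjects = subjects, bundles = bundles, template = NULL,
                 config = NULL, seed = NA_integer_),
            class = "conn_cohort")
}
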