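#' Connectivity matrix construction
#'
#' Three modality matrices are built per subject over the atlas regions:
#' * `EW` — normalized streamline edge weight: the streamline count between
#'   two regions divided by the mean total number of streamlines originating
#'   or ending in either region.
#' * `FA` — per-edge mean fractional anisotropy over the connecting
#'   streamlines, undefined (missing) where no streamline connects the pair.
#' * `FC` — Fisher z-transformed zero-lag Pearson correlation between the
#'   regions' mean BOLD time series.
#'
#' All matrices are symmetric with a missing (`NA`) diagonal; entries outside
#' the analysis-eligible edge mask are marked missing by [restrict_matrix()].
#'
#' @name connectome
NULL

new_conn_matrix <- function(values, modality, subject_id = NA_character_) {
  stopifnot(modality %in% c("EW", "FA", "FC"))
  structure(values, modality = modality, subject_id = subject_id,
            class = c("conn_matrix", class(values)))
}

#' Modality tag of a connectivity matrix
#' @param m A matrix produced by [edge_weight_matrix()], [fa_connectivity()]
#'   or [fc_matrix()].
#' @return `"EW"`, `"FA"` or `"FC"`.
#' @export
conn_modality <- function(m) attr(m, "modality")

check_square_symmetric <- function(m, what, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(what, " must be a square matrix")
  d <- m - t(m)
  d[is.na(d)] <- 0
  if (max(abs(d)) > tol) stop(what, " must be symmetric (max asymmetry ",
                              format(max(abs(d))), ")")
  if (any(xor(is.na(m), is.na(t(m))))) stop(what, " missing pattern must be symmetric")
  invisible(m)
}

#' Streamline edge-weight matrix
#'
#' `EW[i,j] = N[i,j] / ((S[i] + S[j]) / 2)` where `N` is the symmetric
#' streamline count matrix and `S[i] = sum_k N[i,k]` is the total number of
#' streamlines touching region `i`. Since `S[i] >= N[i,j]` and
#' `S[j] >= N[i,j]`, every edge weight lies in `[0, 1]`. Pairs of mutually
#' isolated regions (`S[i] + S[j] = 0`) get weight 0 with a warning.
#'
#' @param counts Symmetric non-negative integer matrix of streamline counts
#'   with zero diagonal.
#' @param subject_id Optional subject identifier carried on the result.
#' @return Symmetric `EW` connectivity matrix in `[0,1]`, `NA` diagonal.
#' @export
edge_weight_matrix <- function(counts, subject_id = NA_character_) {
  check_square_symmetric(counts, "streamline count matrix")
  if (anyNA(counts) || any(counts < 0)) stop("streamline counts must be non-negative and complete")
  if (any(diag(counts) != 0)) stop("streamline count matrix must have a zero diagonal")
  s <- rowSums(counts)
  denom <- outer(s, s, "+") / 2
  ew <- counts / denom
  zero_denom <- denom == 0
  if (any(zero_denom[upper.tri(zero_denom)])) {
    iso <- which(s == 0)
    warning("isolated regions (no streamlines): ", paste(iso, collapse = ", "),
            "; their edge weights are set to 0")
    ew[zero_denom] <- 0
  }
  ew[counts == 0] <- 0
  diag(ew) <- NA_real_
  new_conn_matrix(ew, "EW", subject_id)
}

#' Functional connectivity matrix (Fisher z)
#'
#' Computes the zero-lag Pearson correlation between every pair of regional
#' time series, clamps `r` to `±(1 - 1e-12)` (clamping is reported via a
#' warning) and applies the Fisher z-transform `z = atanh(r)`. Regions with
#' zero temporal variance have an undefined correlation; their rows/columns
#' are marked missing with a warning.
#'
#' @param ts `T x R` matrix of regional time series (T time points >= 3).
#' @param subject_id Optional subject identifier.
#' @return Symmetric `FC` matrix of Fisher-z values, `NA` diagonal.
#' @export
fc_matrix <- function(ts, subject_id = NA_character_) {
  if (!is.matrix(ts)) stop("time series must be a T x R matrix")
  if (nrow(ts) < 3L) stop("at least 3 time points are required, got ", nrow(ts))
  if (any(!is.finite(ts))) stop("time series contain non-finite values")
  flat <- vapply(seq_len(ncol(ts)), function(j) all(ts[, j] == ts[1, j]), logical(1))
  r <- suppressWarnings(stats::cor(ts))
  if (any(flat)) {
    warning("regions with constant signal: ", paste(which(flat), collapse = ", "),
            "; their correlations are marked missing")
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  lim <- 1 - 1e-12
  clamped <- !is.na(r) & abs(r) > lim
  diag(clamped) <- FALSE
  if (any(clamped)) {
    warning(sum(clamped[upper.tri(clamped)]), " correlation(s) clamped to +/-(1 - 1e-12) before atanh")
    r[clamped] <- sign(r[clamped]) * lim
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  new_conn_matrix(z, "FC", subject_id)
}

#' FA connectivity matrix
#'
#' Wraps a per-edge mean-FA matrix into the modality-tagged container after
#' validation: values in `[0,1]`, symmetric, and (when `counts` is supplied)
#' missing exactly where the streamline count is zero.
#'
#' @param fa Symmetric matrix of per-edge mean FA in `[0,1]`, `NA` where no
#'   streamline connects the pair.
#' @param counts Optional streamline count matrix for consistency checking.
#' @param subject_id Optional subject identifier.
#' @return Symmetric `FA` connectivity matrix, `NA` diagonal.
#' @export
fa_connectivity <- function(fa, counts = NULL, subject_id = NA_character_) {
  check_square_symmetric(fa, "FA matrix")
  vals <- fa[!is.na(fa)]
  if (any(vals < 0 | vals > 1)) stop("FA values must lie in [0, 1]")
  if (!is.null(counts)) {
    if (!identical(dim(fa), dim(counts))) stop("FA and count matrix dimensions differ")
    off <- upper.tri(fa)
    bad_missing <- off & is.na(fa) & counts > 0
    bad_defined <- off & !is.na(fa) & counts == 0
    if (any(bad_missing)) stop("FA missing where streamline count > 0 (e.g. edge ",
                               paste(which(bad_missing, arr.ind = TRUE)[1, ], collapse = ","), ")")
    if (any(bad_defined)) stop("FA defined where streamline count = 0 (e.g. edge ",
                               paste(which(bad_defined, arr.ind = TRUE)[1, ], collapse = ","), ")")
  }
  out <- fa
  diag(out) <- NA_real_
  new_conn_matrix(out, "FA", subject_id)
}

#' Control-cohort edge mask
#'
#' An edge is analysis-eligible iff it carries at least one streamline in
#' every control subject. The mask is built from controls only and applied
#' uniformly to all subjects and modalities.
#'
#' @param control_counts Non-empty list of streamline count matrices, one per
#'   control subject, identical dimensions.
#' @param subject_ids Optional provenance ids (defaults to list names).
#' @return Symmetric logical matrix with `FALSE` diagonal; attribute
#'   `provenance` lists the contributing control ids.
#' @export
control_edge_mask <- function(control_counts, subject_ids = names(control_counts)) {
  if (!is.list(control_counts) || length(control_counts) == 0L) {
    stop("control_counts must be a non-empty list of count matrices")
  }
  dims <- vapply(control_counts, nrow, integer(1))
  if (length(unique(dims)) != 1L ||
      !all(vapply(control_counts, ncol, integer(1)) == dims[1])) {
    stop("all control count matrices must have identical dimensions")
  }
  for (m in control_counts) check_square_symmetric(m, "control count matrix")
  mask <- Reduce(`&`, lapply(control_counts, function(m) m >= 1))
  diag(mask) <- FALSE
  structure(mask, provenance = subject_ids)
}

#' Count masked-in edges per compartment
#'
#' @param mask Edge mask from [control_edge_mask()].
#' @param atlas Atlas table matching the mask dimensions.
#' @return Named integer vector `c(left, right, inter)` of eligible edge
#'   counts (unordered pairs).
#' @export
mask_edge_counts <- function(mask, atlas) {
  comp <- edge_compartments(atlas)
  ut <- upper.tri(mask)
  c(left = sum(mask[ut & comp == "intra_left"], na.rm = TRUE),
    right = sum(mask[ut & comp == "intra_right"], na.rm = TRUE),
    inter = sum(mask[ut & comp == "interhemispheric"], na.rm = TRUE))
}

#' Restrict a connectivity matrix to an edge mask
#'
#' Entries outside the mask are marked missing; masked-in entries are left
#' unchanged. Applies identically to EW, FA and FC matrices.
#'
#' @param m Connectivity matrix.
#' @param mask Logical edge mask of the same dimensions.
#' @return The restricted matrix (modality and subject id preserved).
#' @export
restrict_matrix <- function(m, mask) {
  if (!identical(dim(m), dim(mask))) stop("matrix and mask dimensions differ")
  out <- m
  out[!mask] <- NA_real_
  diag(out) <- NA_real_
  attributes(out) <- attributes(m)
  out
}
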