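#' Hemispheric summaries and the cohort analysis table
#'
#' Each subject's masked connectivity matrices are reduced to three
#' compartment means per modality (intra-left, intra-right,
#' interhemispheric). Patients are relabelled to the lesion frame
#' (ipsilesional = lesion hemisphere); controls receive the mean of their
#' left- and right-hemispheric values as the "healthy" baseline for both
#' ipsi- and contralesional slots. Per-group outlier correction replaces
#' values deviating more than a threshold (default 2.5) sample standard
#' deviations from the group mean by the most extreme remaining non-outlier
#' value in the same direction.
#'
#' @name summarize
NULL

#' Compartment means of a masked connectivity matrix
#'
#' Unweighted mean over masked-in, non-missing entries within each
#' hemispheric compartment. Edges inside the mask that are missing for this
#' subject (e.g. FA of an absent connection) are omitted and the
#' contributing-edge count reduced accordingly. An empty compartment is an
#' error, never a silent gap.
#'
#' @param m Connectivity matrix (restricted or not).
#' @param mask Logical edge mask.
#' @param atlas Atlas table matching the matrix dimensions.
#' @return List with `means` (named `left`, `right`, `inter`) and `n_edges`
#'   (contributing unordered edge counts).
#' @export
hemispheric_means <- function(m, mask, atlas) {
  if (!identical(dim(m), dim(mask))) stop("matrix and mask dimensions differ")
  if (nrow(m) != nrow(atlas)) stop("matrix dimension does not match atlas size")
  comp <- edge_compartments(atlas)
  ut <- upper.tri(m)
  labels <- c(left = "intra_left", right = "intra_right", inter = "interhemispheric")
  means <- numeric(3)
  n_edges <- integer(3)
  names(means) <- names(n_edges) <- names(labels)
  for (k in seq_along(labels)) {
    sel <- ut & mask & comp == labels[k]
    vals <- m[sel]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      stop("empty compartment: no contributing edges for ",
           conn_modality(m) %||% "matrix", " / ", labels[k])
    }
    means[k] <- mean(vals)
    n_edges[k] <- length(vals)
  }
  list(means = means, n_edges = n_edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relabel hemispheric means to the lesion frame
#'
#' @param means Named vector `c(left, right, inter)`.
#' @param lesion_hemisphere `"left"` or `"right"` (controls must use
#'   [control_baseline()] instead).
#' @return Named vector `c(ipsi, contra, inter)`.
#' @export
relabel_lesion <- function(means, lesion_hemisphere) {
  stopifnot(all(c("left", "right", "inter") %in% names(means)))
  if (!lesion_hemisphere %in% c("left", "right")) {
    stop("lesion_hemisphere must be 'left' or 'right'; controls use control_baseline()")
  }
  if (lesion_hemisphere == "left") {
    c(ipsi = unname(means["left"]), contra = unname(means["right"]),
      inter = unname(means["inter"]))
  } else {
    c(ipsi = unname(means["right"]), contra = unname(means["left"]),
      inter = unname(means["inter"]))
  }
}

#' Control baseline from hemispheric means
#'
#' The mean of the left- and right-hemispheric values serves as the healthy
#' baseline for both the ipsi- and contralesional slots; the
#' interhemispheric value passes through unchanged.
#'
#' @param means Named vector `c(left, right, inter)`.
#' @return Named vector `c(ipsi, contra, inter)` with `ipsi == contra`.
#' @export
control_baseline <- function(means) {
  stopifnot(all(c("left", "right", "inter") %in% names(means)))
  b <- unname((means["left"] + means["right"]) / 2)
  c(ipsi = b, contra = b, inter = unname(means["inter"]))
}

#' Single-pass outlier correction within a group
#'
#' Values deviating strictly more than `sd_threshold` sample standard
#' deviations (n-1 denominator) from the group mean are replaced by the most
#' extreme non-outlier value in the same direction (maximum of non-outliers
#' for high outliers, minimum for low ones). Statistics come from the
#' uncorrected data; the pass is not iterated. A zero-variance group has no
#' outliers by definition.
#'
#' @param values Numeric vector (group size >= 3).
#' @param sd_threshold Deviation threshold in SD units (default 2.5; values
#'   at exactly the threshold are retained).
#' @return List with `values` (corrected) and `replaced` (logical flags).
#' @export
outlier_correct <- function(values, sd_threshold = 2.5) {
  if (length(values) < 3L) stop("outlier correction requires group size >= 3")
  if (anyNA(values)) stop("missing values are not allowed in outlier correction")
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(values = values, replaced = rep(FALSE, length(values))))
  }
  z <- (values - m) / s
  high <- z > sd_threshold
  low <- z < -sd_threshold
  keep <- !(high | low)
  out <- values
  if (any(high)) {
    if (!any(keep)) stop("all values flagged as outliers; cannot determine replacement")
    out[high] <- max(values[keep])
  }
  if (any(low)) {
    if (!any(keep)) stop("all values flagged as outliers; cannot determine replacement")
    out[low] <- min(values[keep])
  }
  list(values = out, replaced = high | low)
}

#' Validate a subject metadata table
#'
#' Columns: `subject_id`, `group` in `{control, IDHmut, IDHwt}`,
#' `lesion_hemisphere` in `{left, right, none}` (`none` iff control), `age`
#' in `[18, 80)`, `sex` in `{m, f}`.
#'
#' @param subjects Subject metadata `data.frame`.
#' @return The validated table, rows ordered by `subject_id`.
#' @export
validate_subjects <- function(subjects) {
  req <- c("subject_id", "group", "lesion_hemisphere", "age", "sex")
  if (!all(req %in% names(subjects))) {
    stop("subject table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject_id")
  if (!all(subjects$group %in% c("control", "IDHmut", "IDHwt"))) {
    stop("group must be one of control, IDHmut, IDHwt")
  }
  if (!all(subjects$lesion_hemisphere %in% c("left", "right", "none"))) {
    stop("lesion_hemisphere must be left, right or none")
  }
  bad <- (subjects$group == "control") != (subjects$lesion_hemisphere == "none")
  if (any(bad)) {
    stop("lesion_hemisphere must be 'none' exactly for controls (violated for: ",
         paste(subjects$subject_id[bad], collapse = ", "), ")")
  }
  if (any(subjects$age < 18 | subjects$age >= 80)) {
    stop("ages must lie in [18, 80)")
  }
  if (!all(subjects$sex %in% c("m", "f"))) stop("sex must be 'm' or 'f'")
  subjects <- subjects[order(subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL
  subjects
}

#' Read subject metadata CSV
#'
#' Header: `subject_id,group,lesion_hemisphere,age,sex`.
#'
#' @param path CSV path.
#' @return Validated subject table.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path)
  validate_subjects(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Assemble the cohort summary table
#'
#' Combines per-subject compartment means into one row per subject holding
#' the 9 analysis variables (`{EW,FA,FC}_{ipsi,contra,inter}`) plus the raw
#' left/right means (used for control coherence profiles), then applies
#' outlier correction column-wise within each group. Row order is
#' `subject_id` ascending.
#'
#' @param subjects Validated subject metadata table.
#' @param subject_means Named list (by subject id); each element is a list
#'   with entries `EW`, `FA`, `FC`, each a named vector
#'   `c(left, right, inter)`.
#' @param sd_threshold Outlier threshold in SD units (default 2.5).
#' @return `data.frame` with metadata, 9 analysis columns and 6 left/right
#'   columns; attribute `outlier_flags` is a logical matrix of replacements.
#' @export
assemble_cohort_table <- function(subjects, subject_means, sd_threshold = 2.5) {
  subjects <- validate_subjects(subjects)
  modalities <- c("EW", "FA", "FC")
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    sm <- subject_means[[sid]]
    if (is.null(sm)) stop("no means supplied for subject ", sid)
    vals <- numeric(0)
    for (mod in modalities) {
      mv <- sm[[mod]]
      if (is.null(mv) || anyNA(mv) || !all(c("left", "right", "inter") %in% names(mv))) {
        stop("missing or incomplete ", mod, " means for subject ", sid)
      }
      rel <- if (subjects$group[i] == "control") control_baseline(mv) else
        relabel_lesion(mv, subjects$lesion_hemisphere[i])
      v <- c(rel, left = unname(mv["left"]), right = unname(mv["right"]))
      names(v) <- paste(mod, names(v), sep = "_")
      vals <- c(vals, v)
    }
    vals
  })
  value_mat <- do.call(rbind, rows)
  tab <- cbind(subjects[, c("subject_id", "group", "lesion_hemisphere", "age", "sex")],
               as.data.frame(value_mat))
  flags <- matrix(FALSE, nrow(tab), ncol(value_mat),
                  dimnames = list(tab$subject_id, colnames(value_mat)))
  for (g in unique(tab$group)) {
    idx <- which(tab$group == g)
    for (col in colnames(value_mat)) {
      oc <- outlier_correct(tab[[col]][idx], sd_threshold)
      tab[[col]][idx] <- oc$values
      flags[idx, col] <- oc$replaced
    }
  }
  structure(tab, outlier_flags = flags)
}
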