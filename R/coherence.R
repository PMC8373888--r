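#' Connectomic coherence profiles
#'
#' For one group, all pairwise age-controlled Pearson partial correlations
#' among the 9 hemispheric summary variables ({EW, FA, FC} x {ipsi, contra,
#' inter}; for controls the left/right-hemispheric means are used by
#' default, matching the healthy labels LEFT/RIGHT). A pair is intramodal
#' iff both variables share a modality (EW-EW, FA-FA, FC-FC: 3 pairs each),
#' intermodal otherwise (27 pairs). Significance uses the two-sided
#' Bonferroni-adjusted threshold `alpha / family_size` (default 0.05/9,
#' reported as 0.006).
#'
#' @name coherence
NULL

coherence_vars <- function(group, control_labels) {
  comps <- if (group == "control" && control_labels == "leftright") {
    c("left", "right", "inter")
  } else {
    c("ipsi", "contra", "inter")
  }
  expand <- expand.grid(comp = comps, mod = c("EW", "FA", "FC"),
                        stringsAsFactors = FALSE)
  data.frame(var = paste(expand$mod, expand$comp, sep = "_"),
             modality = expand$mod, compartment = expand$comp,
             stringsAsFactors = FALSE)
}

#' Coherence profile of one group
#'
#' @param table Cohort summary table from [assemble_cohort_table()].
#' @param group Group label present in the table (>= 6 subjects).
#' @param alpha Family-wise significance level (default 0.05).
#' @param family_size Bonferroni family size (default 9: the three
#'   compartments of the three modalities).
#' @param covariates Column name(s) partialled out (default `"age"`).
#' @param control_labels For the control group, `"leftright"` (default)
#'   correlates the raw left/right-hemispheric means; `"baseline"` uses the
#'   averaged ipsi/contra baseline columns instead.
#' @return `data.frame` of class `coherence_profile`, one row per unordered
#'   variable pair (36 rows): `group`, `var_a`, `var_b`, `pair_class`,
#'   `modality_a`, `modality_b`, `r_partial`, `df`, `p`, `significant`.
#' @export
coherence_profile <- function(table, group, alpha = 0.05, family_size = 9L,
                              covariates = "age",
                              control_labels = c("leftright", "baseline")) {
  control_labels <- match.arg(control_labels)
  rows <- table[table$group == group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("group not present in table: ", group)
  if (nrow(rows) < 6L) stop("group ", group, " has fewer than 6 subjects")
  vars <- coherence_vars(group, control_labels)
  missing_cols <- setdiff(c(vars$var, covariates), names(rows))
  if (length(missing_cols) > 0L) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  covs <- as.matrix(rows[, covariates, drop = FALSE])
  thr <- bonferroni_threshold(alpha, family_size)
  n <- nrow(rows)
  k <- ncol(covs)
  if (n < k + 4L) stop("group ", group, " too small for ", k, " covariate(s)")
  # residualize all 9 variables on [1, covariates] at once; pairwise
  # correlations of the residuals are the partial correlations
  design <- cbind(1, covs)
  if (qr(design)$rank < ncol(design)) stop("covariates are rank-deficient")
  y <- as.matrix(rows[, vars$var, drop = FALSE])
  res_mat <- stats::lm.fit(design, y)$residuals
  rmat <- stats::cor(res_mat)
  df <- n - 2L - k
  pairs <- utils::combn(nrow(vars), 2L)
  a <- pairs[1, ]; b <- pairs[2, ]
  r <- rmat[cbind(a, b)]
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  out <- data.frame(
    group = group, var_a = vars$var[a], var_b = vars$var[b],
    pair_class = ifelse(vars$modality[a] == vars$modality[b],
                        "intramodal", "intermodal"),
    modality_a = vars$modality[a], modality_b = vars$modality[b],
    r_partial = r, df = df, p = p, significant = p < thr,
    stringsAsFactors = FALSE)
  structure(out, class = c("coherence_profile", "data.frame"),
            alpha = alpha, family_size = family_size, threshold = thr,
            n_subjects = nrow(rows))
}

#' Structural/functional dissociation summary
#'
#' Counts significant intramodal pairs per group, split into structural
#' (EW-EW and FA-FA, 6 pairs) and functional (FC-FC, 3 pairs) sets, plus
#' significant intermodal pairs (of 27). Operationalizes the qualitative
#' dissociation pattern: controls retain both structural and functional
#' intramodal coherence, patients lose the structural part while functional
#' coherence is comparatively preserved.
#'
#' @param profiles List of [coherence_profile()] results (>= 1).
#' @return `data.frame`, one row per profile: `group`,
#'   `n_sig_intramodal_SC`, `n_sig_intramodal_FC`, `n_sig_intermodal`.
#' @export
dissociation_summary <- function(profiles) {
  if (inherits(profiles, "coherence_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("at least one coherence profile is required")
  rows <- lapply(profiles, function(pr) {
    intra <- pr$pair_class == "intramodal"
    sc <- intra & pr$modality_a %in% c("EW", "FA")
    fc <- intra & pr$modality_a == "FC"
    data.frame(group = pr$group[1],
               n_sig_intramodal_SC = sum(pr$significant[sc]),
               n_sig_intramodal_FC = sum(pr$significant[fc]),
               n_sig_intermodal = sum(pr$significant[!intra]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
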