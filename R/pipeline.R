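#' End-to-end cohort analysis
#'
#' Orchestrates the full analysis: control edge mask, per-subject EW/FA/FC
#' matrices, mask restriction, hemispheric compartment means, lesion
#' relabelling (controls: left/right-mean baseline), per-group outlier
#' correction, three one-way MANOVAs (ipsilesional, contralesional,
#' interhemispheric; DVs = EW, FA, FC) with unconditional univariate
#' follow-ups and pooled-error Bonferroni post-hocs (flagged `gated` by the
#' omnibus outcome), per-group coherence profiles and the dissociation
#' summary. Optionally repeats everything on the DMN sub-atlas, whose mask
#' is the whole-brain rule applied to the DMN-restricted control counts
#' (equivalent to restricting the whole-brain mask, since the rule is
#' per-edge).
#'
#' @name pipeline
NULL

build_subject_matrices <- function(bundle, sid) {
  list(EW = edge_weight_matrix(bundle$counts, sid),
       FA = fa_connectivity(bundle$fa, bundle$counts, sid),
       FC = fc_matrix(bundle$ts, sid))
}

#' Build the cohort summary table from raw derivatives
#'
#' Runs the construction and summarization stages: control edge mask,
#' per-subject EW/FA/FC matrices, mask restriction, hemispheric compartment
#' means, lesion relabelling / control baseline, and per-group outlier
#' correction. This is the input of every inferential analysis.
#'
#' @param cohort A `conn_cohort`.
#' @param atlas Atlas table (default sized to the data). A restricted
#'   sub-atlas (e.g. [dmn_subatlas()]) analyzes only its regions.
#' @param outlier_sd Outlier threshold in SD units (default 2.5).
#' @return The summary table (see [assemble_cohort_table()]) with attribute
#'   `mask_edge_counts`.
#' @export
cohort_summary_table <- function(cohort, atlas = NULL, outlier_sd = 2.5) {
  subjects <- cohort$subjects
  ids <- subjects$subject_id
  if (is.null(atlas)) atlas <- default_atlas(nrow(cohort$bundles[[1]]$counts))
  region_idx <- atlas$region_id
  control_ids <- ids[subjects$group == "control"]
  if (length(control_ids) == 0L) stop("cohort has no control subjects; cannot build the edge mask")
  control_counts <- lapply(cohort$bundles[control_ids],
                           function(b) b$counts[region_idx, region_idx, drop = FALSE])
  mask <- control_edge_mask(control_counts, control_ids)
  edge_counts <- mask_edge_counts(mask, atlas)

  # precompute linear indices of masked-in upper-triangle cells per
  # compartment; per-subject means then reduce to indexed lookups
  # (equivalent to hemispheric_means(restrict_matrix(m, mask), mask, atlas))
  comp <- edge_compartments(atlas)
  ut <- upper.tri(mask)
  labels <- c(left = "intra_left", right = "intra_right", inter = "interhemispheric")
  comp_idx <- lapply(labels, function(lb) which(ut & mask & comp == lb))
  compartment_means <- function(m, modality) {
    vapply(names(labels), function(k) {
      vals <- m[comp_idx[[k]]]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        stop("empty compartment: no contributing edges for ", modality,
             " / ", labels[k])
      }
      mean(vals)
    }, numeric(1))
  }
  subject_means <- lapply(ids, function(sid) {
    b <- cohort$bundles[[sid]]
    sub <- list(counts = b$counts[region_idx, region_idx, drop = FALSE],
                fa = b$fa[region_idx, region_idx, drop = FALSE],
                ts = b$ts[, region_idx, drop = FALSE])
    mats <- build_subject_matrices(sub, sid)
    lapply(mats, function(m) compartment_means(m, conn_modality(m)))
  })
  names(subject_means) <- ids
  table <- assemble_cohort_table(subjects, subject_means, sd_threshold = outlier_sd)
  attr(table, "mask_edge_counts") <- edge_counts
  table
}

analyze_scope <- function(cohort, atlas, alpha, family_size, outlier_sd) {
  table <- cohort_summary_table(cohort, atlas, outlier_sd)
  edge_counts <- attr(table, "mask_edge_counts")

  compartments <- c("ipsi", "contra", "inter")
  modalities <- c("EW", "FA", "FC")
  manovas <- list()
  anovas <- list()
  posthocs <- list()
  for (comp in compartments) {
    dvs <- as.matrix(table[, paste(modalities, comp, sep = "_")])
    mv <- manova_pillai(table$group, dvs)
    manovas[[comp]] <- mv
    for (mod in modalities) {
      col <- paste(mod, comp, sep = "_")
      av <- anova_oneway(table$group, table[[col]])
      av$variable <- col
      av$gated <- mv$p < alpha
      anovas[[col]] <- av
      ph <- posthoc_bonferroni(table$group, table[[col]])
      ph$variable <- col
      ph$gated <- mv$p < alpha && av$p < alpha
      posthocs[[col]] <- ph
    }
  }
  anova_table <- do.call(rbind, lapply(anovas, function(a) {
    data.frame(variable = a$variable, F = a$F, df1 = a$df1, df2 = a$df2,
               p = a$p, gated = a$gated, stringsAsFactors = FALSE)
  }))
  rownames(anova_table) <- NULL
  posthoc_table <- do.call(rbind, posthocs)
  rownames(posthoc_table) <- NULL

  profiles <- lapply(c("control", "IDHmut", "IDHwt"), function(grp) {
    if (sum(table$group == grp) >= 6L) {
      coherence_profile(table, grp, alpha = alpha, family_size = family_size)
    } else {
      NULL
    }
  })
  profiles <- Filter(Negate(is.null), profiles)

  list(mask_edge_counts = edge_counts, table = table,
       manova = manovas, anova = anova_table, posthoc = posthoc_table,
       coherence = profiles,
       dissociation = if (length(profiles) > 0L) dissociation_summary(profiles))
}

#' Run the full group analysis on a cohort
#'
#' @param cohort A `conn_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param atlas Atlas table (default: the default atlas sized to the data).
#' @param scope `"whole_brain"`, `"dmn"` or `"both"`.
#' @param alpha Significance level (default 0.05).
#' @param family_size Bonferroni family for the coherence analysis
#'   (default 9).
#' @param outlier_sd Outlier threshold in SD units (default 2.5).
#' @return List of class `conn_report` with one result block per scope;
#'   each block holds the mask edge counts, the summary table, the three
#'   MANOVAs, the univariate ANOVA and post-hoc tables, the coherence
#'   profiles and the dissociation summary.
#' @export
run_full_analysis <- function(cohort, atlas = NULL,
                              scope = c("whole_brain", "dmn", "both"),
                              alpha = 0.05, family_size = 9L, outlier_sd = 2.5) {
  scope <- match.arg(scope)
  n_regions <- nrow(cohort$bundles[[1]]$counts)
  if (is.null(atlas)) atlas <- default_atlas(n_regions)
  if (nrow(atlas) != n_regions) {
    stop("atlas has ", nrow(atlas), " regions but the data have ", n_regions)
  }
  out <- list(alpha = alpha, family_size = family_size,
              adjusted_alpha = bonferroni_threshold(alpha, family_size),
              outlier_sd = outlier_sd, scope = scope)
  if (scope %in% c("whole_brain", "both")) {
    out$whole_brain <- analyze_scope(cohort, atlas, alpha, family_size, outlier_sd)
  }
  if (scope %in% c("dmn", "both")) {
    out$dmn <- analyze_scope(cohort, dmn_subatlas(atlas), alpha, family_size, outlier_sd)
  }
  structure(out, class = "conn_report")
}

report_block_json <- function(block) {
  list(
    mask_edge_counts = as.list(block$mask_edge_counts),
    manova = lapply(block$manova, unclass),
    anova = block$anova,
    posthoc = block$posthoc,
    coherence = lapply(block$coherence, function(pr) as.data.frame(pr)),
    dissociation = block$dissociation
  )
}

#' Write a report's machine-readable outputs
#'
#' Writes per-family CSVs (`manova_results.csv`, `anova_results.csv`,
#' `posthoc_results.csv`, `coherence_profile.csv`, `summary_table.csv`) and
#' a consolidated `report.json` with full-precision statistics.
#'
#' @param report A `conn_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- Filter(Negate(is.null), report[c("whole_brain", "dmn")])
  manova_rows <- list()
  for (scope_name in names(blocks)) {
    block <- blocks[[scope_name]]
    for (comp in names(block$manova)) {
      mv <- block$manova[[comp]]
      manova_rows[[paste(scope_name, comp)]] <- data.frame(
        scope = scope_name, compartment = comp, pillai_V = mv$pillai_V,
        F = mv$F, df1 = mv$df1, df2 = mv$df2, p = mv$p,
        wilks_lambda = mv$wilks_lambda, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, manova_rows),
                   file.path(dir, "manova_results.csv"), row.names = FALSE)
  bind_scoped <- function(field) {
    do.call(rbind, lapply(names(blocks), function(sn) {
      df <- blocks[[sn]][[field]]
      if (is.list(df) && !is.data.frame(df)) df <- do.call(rbind, lapply(df, as.data.frame))
      cbind(scope = sn, df)
    }))
  }
  utils::write.csv(bind_scoped("anova"), file.path(dir, "anova_results.csv"),
                   row.names = FALSE)
  utils::write.csv(bind_scoped("posthoc"), file.path(dir, "posthoc_results.csv"),
                   row.names = FALSE)
  utils::write.csv(bind_scoped("coherence"), file.path(dir, "coherence_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(bind_scoped("table"), file.path(dir, "summary_table.csv"),
                   row.names = FALSE)
  json <- list(alpha = report$alpha, family_size = report$family_size,
               adjusted_alpha = report$adjusted_alpha,
               blocks = lapply(blocks, report_block_json))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
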