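#' Synthetic multimodal cohort generator
#'
#' Generates complete per-subject derivatives — streamline count matrices,
#' per-edge FA matrices, regional BOLD time series — plus demographics, with
#' plantable group effects and latent within-modality coherence, emulating
#' the parcellated derivatives the analysis pipeline consumes.
#'
#' Mechanism per subject:
#' 1. demographics (group, age, lesion side, sex) from group-specific
#'    distributions;
#' 2. three mutually independent standard-normal latent coherence factors,
#'    one per modality (EW, FA, FC), so intermodal correlations are null by
#'    construction; the structural coherence parameter governs the EW and
#'    FA loadings alike;
#' 3. compartment targets `v = mu + delta + sigma_b * (sqrt(lambda) * g +
#'    sqrt(1 - lambda) * eta)` where `lambda` is the *target
#'    inter-compartment correlation* within a modality, `sigma_b` the
#'    between-subject SD, `delta` the planted group effect mapped through
#'    the lesion side, and `eta` compartment-specific noise;
#' 4. edge-level data realized to match the targets: Poisson streamline
#'    counts on a fixed sparse template (calibrated by a deterministic
#'    fixed point so the expected compartment edge-weight means hit their
#'    targets), truncated-normal FA on connected edges, and an exact
#'    two-hemisphere factor model for the time series.
#'
#' The count template adds a diffuse low-rate background connection set so
#' region strengths have a component that per-compartment rate scaling does
#' not touch (edge weight is scale-invariant, so without it intrahemispheric
#' targets would be unreachable); background edges almost never survive the
#' all-controls mask, reproducing the sparse surviving-edge structure of
#' real control cohorts.
#'
#' @name synthetic-cohort
NULL

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 27 controls, 15 IDH-mutant and
#' 14 IDH-wildtype patients; ages normal 46+/-14, 37+/-11 and 65+/-8 years
#' truncated to [18, 80); left-lesion probabilities 10/15 and 9/14; male
#' probabilities 17/27, 11/15 and 6/14; 246 regions; 300 time points.
#' Planted effects: interhemispheric edge weight reduced by 15% in both
#' patient groups, ipsilesional FA lowered by 0.03 in IDHwt, contralesional
#' FA raised by 0.03 in IDHmut. Coherence: controls lambda = 0.8 in every
#' modality; patients lambda_SC = 0 (structural coherence abolished),
#' lambda_FC = 0.8 (functional coherence preserved).
#'
#' @param n_regions Number of atlas regions (even; default 246).
#' @param n_timepoints BOLD volumes per subject (default 300).
#' @param n_control,n_idhmut,n_idhwt Group sizes (each >= 4).
#' @param age_mean,age_sd Named vectors (control/IDHmut/IDHwt) of age
#'   distribution parameters; sampling truncates to `[18, 80)`.
#' @param lesion_left_prob Named vector of left-lesion probabilities for the
#'   patient groups.
#' @param male_prob Named vector of male probabilities per group.
#' @param mu_fc Baseline Fisher-z FC compartment means `c(left, right, inter)`.
#' @param mu_fa Baseline FA compartment means `c(left, right, inter)`.
#' @param delta_ew_inter_patients Relative interhemispheric edge-weight
#'   change in both patient groups (default -0.15).
#' @param delta_fa_ipsi_idhwt Additive ipsilesional FA change in IDHwt
#'   (default -0.03).
#' @param delta_fa_contra_idhmut Additive contralesional FA change in IDHmut
#'   (default +0.03).
#' @param lambda Per-group list of coherence parameters `c(SC, FC)`, each the
#'   target correlation between compartment values of one modality.
#' @param ew_rel_sd Between-subject SD of edge-weight targets, relative to
#'   the template baseline (default 0.08).
#' @param fa_subject_sd Between-subject SD of FA compartment targets
#'   (default 0.02).
#' @param fc_subject_sd Between-subject SD of Fisher-z FC targets
#'   (default 0.05).
#' @param fa_edge_sd Edge-level FA noise SD (default 0.08).
#' @param intra_rate,inter_rate Poisson rates of template intra- and
#'   interhemispheric edges (streamlines per edge).
#' @param background_rate Poisson rate of the diffuse background connections
#'   (default 1; such edges rarely survive the all-controls mask).
#' @param intra_reach Template wiring span: regions connect within this
#'   hemisphere-index distance (default 5, giving ~600 intra edges per
#'   hemisphere at R = 246).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 246L, n_timepoints = 300L,
                       n_control = 27L, n_idhmut = 15L, n_idhwt = 14L,
                       age_mean = c(control = 46, IDHmut = 37, IDHwt = 65),
                       age_sd = c(control = 14, IDHmut = 11, IDHwt = 8),
                       lesion_left_prob = c(IDHmut = 10 / 15, IDHwt = 9 / 14),
                       male_prob = c(control = 17 / 27, IDHmut = 11 / 15, IDHwt = 6 / 14),
                       mu_fc = c(left = 0.30, right = 0.30, inter = 0.15),
                       mu_fa = c(left = 0.45, right = 0.45, inter = 0.50),
                       delta_ew_inter_patients = -0.15,
                       delta_fa_ipsi_idhwt = -0.03,
                       delta_fa_contra_idhmut = 0.03,
                       lambda = list(control = c(SC = 0.8, FC = 0.8),
                                     IDHmut = c(SC = 0, FC = 0.8),
                                     IDHwt = c(SC = 0, FC = 0.8)),
                       ew_rel_sd = 0.08, fa_subject_sd = 0.02,
                       fc_subject_sd = 0.05, fa_edge_sd = 0.08,
                       intra_rate = 40, inter_rate = 30,
                       background_rate = 1, intra_reach = 5L) {
  cfg <- list(n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
              n_control = as.integer(n_control), n_idhmut = as.integer(n_idhmut),
              n_idhwt = as.integer(n_idhwt),
              age_mean = age_mean, age_sd = age_sd,
              lesion_left_prob = lesion_left_prob, male_prob = male_prob,
              mu_fc = mu_fc, mu_fa = mu_fa,
              delta_ew_inter_patients = delta_ew_inter_patients,
              delta_fa_ipsi_idhwt = delta_fa_ipsi_idhwt,
              delta_fa_contra_idhmut = delta_fa_contra_idhmut,
              lambda = lambda,
              ew_rel_sd = ew_rel_sd, fa_subject_sd = fa_subject_sd,
              fc_subject_sd = fc_subject_sd, fa_edge_sd = fa_edge_sd,
              intra_rate = intra_rate, inter_rate = inter_rate,
              background_rate = background_rate, intra_reach = as.integer(intra_reach))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_regions < 8L || cfg$n_regions %% 2L != 0L) {
    stop("n_regions must be an even integer >= 8")
  }
  if (cfg$n_timepoints < 3L) stop("n_timepoints must be >= 3")
  if (any(c(cfg$n_control, cfg$n_idhmut, cfg$n_idhwt) < 4L)) {
    stop("all group sizes must be >= 4")
  }
  probs <- c(cfg$lesion_left_prob, cfg$male_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$intra_rate, cfg$inter_rate) <= 0) || cfg$background_rate < 0) {
    stop("rates must be positive (background rate non-negative)")
  }
  fa_extremes <- c(cfg$mu_fa + cfg$delta_fa_contra_idhmut,
                   cfg$mu_fa + cfg$delta_fa_ipsi_idhwt)
  if (any(fa_extremes <= 0 | fa_extremes >= 1)) {
    stop("FA targets must stay inside (0, 1)")
  }
  lam <- unlist(cfg$lambda)
  if (any(lam < 0 | lam > 1)) stop("lambda values must lie in [0, 1]")
  if (any(c(cfg$ew_rel_sd, cfg$fa_subject_sd, cfg$fc_subject_sd, cfg$fa_edge_sd) < 0)) {
    stop("noise SDs must be non-negative")
  }
  structure(cfg, class = "sim_config")
}

#' Count-rate template for the synthetic connectome
#'
#' Deterministic given the configuration: same-hemisphere regions within
#' `intra_reach` hemisphere-index steps are wired at `intra_rate`; homotopic
#' region pairs (three of every four) at `inter_rate`; all remaining pairs
#' carry the diffuse `background_rate`. Besides the rate matrix and the
#' logical template mask (the high-rate edges expected to survive the
#' control mask), the template carries precomputed upper-triangle edge
#' lists and a strength decomposition used by the deterministic
#' edge-weight calibration.
#'
#' @param config A [sim_config()].
#' @return List with `rates`, `template` (logical matrix), `mu0` (baseline
#'   expected compartment edge-weight means, named `c(left, right, inter)`),
#'   `comp` (compartment label matrix) and internal edge-list fields.
#' @export
sim_template <- function(config) {
  r <- config$n_regions
  id <- seq_len(r)
  h <- ceiling(id / 2)
  left <- id %% 2L == 1L
  same_h <- outer(left, left, "==")
  dist <- abs(outer(h, h, "-"))
  intra <- same_h & dist >= 1L & dist <= config$intra_reach
  homotopic <- (!same_h) & dist == 0L
  keep <- outer(h %% 4L != 0L, h %% 4L != 0L, "&")
  inter <- homotopic & keep
  rates <- matrix(config$background_rate, r, r)
  rates[intra] <- config$intra_rate
  rates[inter] <- config$inter_rate
  diag(rates) <- 0
  template <- intra | inter
  comp <- matrix("interhemispheric", r, r)
  comp[outer(left, left, "&")] <- "intra_left"
  comp[outer(!left, !left, "&")] <- "intra_right"
  diag(comp) <- NA_character_

  # upper-triangle edge lists (linear cell index, endpoints, compartment)
  ut_cell <- which(upper.tri(rates))
  iu <- ((ut_cell - 1L) %% r) + 1L
  ju <- ((ut_cell - 1L) %/% r) + 1L
  comp_ut <- ifelse(left[iu] != left[ju], "inter", ifelse(left[iu], "left", "right"))
  template_ut <- template[ut_cell]
  rate_ut <- rates[ut_cell]
  pos <- lapply(c(left = "left", right = "right", inter = "inter"),
                function(cc) which(template_ut & comp_ut == cc))
  # strength decomposition: S_i(s) = bg_strength_i + sum_c s_c * L[i, c]
  bg <- !template_ut
  bg_strength <- config$background_rate *
    tabulate(c(iu[bg], ju[bg]), nbins = r)
  L <- matrix(0, r, length(pos), dimnames = list(NULL, names(pos)))
  for (k in seq_along(pos)) {
    p <- pos[[k]]
    if (length(p) > 0L) {
      # template rates are constant within a compartment
      L[, k] <- rate_ut[p][1] * tabulate(c(iu[p], ju[p]), nbins = r)
    }
  }
  tmpl <- list(rates = rates, template = template, comp = comp,
               n_regions = r, ut_cell = ut_cell, iu = iu, ju = ju,
               comp_ut = comp_ut, template_ut = template_ut, rate_ut = rate_ut,
               pos = pos, bg_strength = bg_strength, L = L)
  tmpl$mu0 <- expected_ew_means(tmpl, c(left = 1, right = 1, inter = 1))
  tmpl
}

# expected compartment EW means for per-compartment template scalings
expected_ew_means <- function(tmpl, scales) {
  s_vec <- tmpl$bg_strength + as.vector(tmpl$L %*% scales[colnames(tmpl$L)])
  out <- c(left = NA_real_, right = NA_real_, inter = NA_real_)
  for (k in names(tmpl$pos)) {
    p <- tmpl$pos[[k]]
    denom <- (s_vec[tmpl$iu[p]] + s_vec[tmpl$ju[p]]) / 2
    out[k] <- mean(scales[k] * tmpl$rate_ut[p] / denom)
  }
  out
}

calibrate_scales <- function(tmpl, target_ew, iters = 30L) {
  stopifnot(all(c("left", "right", "inter") %in% names(target_ew)))
  if (any(target_ew <= 0)) stop("edge-weight targets must be positive")
  target_ew <- target_ew[c("left", "right", "inter")]
  scales <- pmin(pmax(target_ew / tmpl$mu0, 0.02), 50)
  for (it in seq_len(iters)) {
    m <- expected_ew_means(tmpl, scales)
    scales <- pmin(pmax(scales * target_ew / m, 0.02), 50)
  }
  scales
}

#' Calibrate template rates to compartment edge-weight targets
#'
#' Deterministic fixed point: template edges of each compartment are scaled
#' by a factor, expected strengths recomputed from the template's strength
#' decomposition, and the factors updated until the expected compartment
#' edge-weight means match the targets. Because strengths include the
#' unscaled background component, the map is a contraction for reachable
#' targets; scales are clamped to `[0.02, 50]` (targets beyond the lever's
#' saturation point are met as closely as the template permits).
#'
#' @param tmpl Template from [sim_template()].
#' @param target_ew Named target means `c(left, right, inter)`.
#' @param iters Fixed-point iterations (default 8).
#' @return Calibrated rate matrix.
#' @export
calibrate_count_rates <- function(tmpl, target_ew, iters = 8L) {
  scales <- calibrate_scales(tmpl, target_ew, iters)
  rate_ut <- tmpl$rate_ut
  for (k in names(tmpl$pos)) {
    p <- tmpl$pos[[k]]
    rate_ut[p] <- rate_ut[p] * scales[k]
  }
  rates <- matrix(0, tmpl$n_regions, tmpl$n_regions)
  rates[tmpl$ut_cell] <- rate_ut
  rates + t(rates)
}

#' Sample a streamline count matrix for given edge-weight targets
#'
#' Counts are Poisson with the calibrated rates, symmetrized with a zero
#' diagonal. Uses the current RNG state unless `seed` is given.
#'
#' @param tmpl Template from [sim_template()].
#' @param target_ew Named compartment targets `c(left, right, inter)`.
#' @param seed Optional integer seed.
#' @return Symmetric integer count matrix.
#' @export
sample_counts <- function(tmpl, target_ew, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scales <- calibrate_scales(tmpl, target_ew)
  rate_ut <- tmpl$rate_ut
  for (k in names(tmpl$pos)) {
    p <- tmpl$pos[[k]]
    rate_ut[p] <- rate_ut[p] * scales[k]
  }
  r <- tmpl$n_regions
  counts <- matrix(0L, r, r)
  counts[tmpl$ut_cell] <- stats::rpois(length(rate_ut), rate_ut)
  counts <- counts + t(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Sample a per-edge FA matrix
#'
#' Every connected edge (count > 0) draws FA from a normal distribution
#' centred on its compartment's target, truncated to `(0, 1)` by rejection;
#' unconnected edges are missing.
#'
#' @param counts Symmetric streamline count matrix.
#' @param target_fa Named compartment targets `c(left, right, inter)` in
#'   `(0, 1)`.
#' @param noise_sd Edge-level SD (default 0.08).
#' @param seed Optional integer seed.
#' @return Symmetric FA matrix with `NA` where counts are zero.
#' @export
sample_fa_edges <- function(counts, target_fa, noise_sd = 0.08, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("left", "right", "inter") %in% names(target_fa)))
  if (any(target_fa <= 0 | target_fa >= 1)) stop("FA targets must lie in (0, 1)")
  r <- nrow(counts)
  id <- seq_len(r)
  left <- id %% 2L == 1L
  fa <- matrix(NA_real_, r, r)
  ut <- upper.tri(counts)
  idx <- which(ut & counts > 0, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    li <- left[idx[, 1]]; lj <- left[idx[, 2]]
    comp <- ifelse(li != lj, "inter", ifelse(li, "left", "right"))
    mu <- target_fa[comp]
    vals <- stats::rnorm(nrow(idx), mu, noise_sd)
    bad <- which(vals <= 0 | vals >= 1)
    while (length(bad) > 0L) {
      vals[bad] <- stats::rnorm(length(bad), mu[bad], noise_sd)
      bad <- bad[vals[bad] <= 0 | vals[bad] >= 1]
    }
    fa[idx] <- vals
    fa[idx[, c(2, 1), drop = FALSE]] <- vals
  }
  fa
}

#' Sample regional time series with block-structured correlations
#'
#' Exact two-hemisphere factor construction: each hemisphere has a common
#' factor; the two factors share a component so that the within-left,
#' within-right and interhemispheric pairwise correlations equal
#' `tanh(target_z)`. Positive definiteness requires
#' `r_inter^2 <= r_left * r_right`; infeasible targets are repaired by
#' shrinking the interhemispheric correlation with a warning. Correlations
#' are clamped to `[0.01, 0.95]`.
#'
#' @param target_z Named Fisher-z compartment targets `c(left, right, inter)`.
#' @param n_timepoints Number of time points T.
#' @param n_regions Number of regions R (even; odd ids left hemisphere).
#' @param seed Optional integer seed.
#' @return `T x R` time-series matrix.
#' @export
sample_timeseries <- function(target_z, n_timepoints, n_regions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("left", "right", "inter") %in% names(target_z)))
  rr <- tanh(target_z)
  rr <- pmin(pmax(rr, 0), 0.95)  # factor model supports non-negative targets
  bound <- sqrt(rr["left"] * rr["right"])
  if (rr["inter"] > 0.999 * bound) {
    if (rr["inter"] > 1e-8) {
      warning("interhemispheric correlation target ", signif(rr["inter"], 3),
              " infeasible for block structure; shrunk to ", signif(0.999 * bound, 3))
    }
    rr["inter"] <- 0.999 * bound
  }
  rho_f <- if (bound > 0) rr["inter"] / bound else 0
  tt <- n_timepoints
  z_common <- stats::rnorm(tt)
  f_left <- sqrt(rho_f) * z_common + sqrt(1 - rho_f) * stats::rnorm(tt)
  f_right <- sqrt(rho_f) * z_common + sqrt(1 - rho_f) * stats::rnorm(tt)
  eps <- matrix(stats::rnorm(tt * n_regions), tt, n_regions)
  id <- seq_len(n_regions)
  left <- id %% 2L == 1L
  x <- matrix(0, tt, n_regions)
  x[, left] <- sqrt(rr["left"]) * f_left + sqrt(1 - rr["left"]) * eps[, left]
  x[, !left] <- sqrt(rr["right"]) * f_right + sqrt(1 - rr["right"]) * eps[, !left]
  x
}

subject_targets <- function(cfg, group, lesion, mu0) {
  lam <- cfg$lambda[[group]]
  # one latent factor per modality (EW, FA, FC), mutually independent, so
  # intermodal correlations are null by construction; the SC coherence
  # parameter governs the EW and FA loadings alike
  g_ew <- stats::rnorm(1)
  g_fa <- stats::rnorm(1)
  g_fc <- stats::rnorm(1)
  dev <- function(lambda, g) {
    sqrt(lambda) * g + sqrt(1 - lambda) * stats::rnorm(3)
  }
  comps <- c("left", "right", "inter")
  is_patient <- group != "control"

  ew <- mu0 * (1 + cfg$ew_rel_sd * dev(lam["SC"], g_ew))
  if (is_patient) ew["inter"] <- ew["inter"] * (1 + cfg$delta_ew_inter_patients)
  ew <- pmax(ew, 0.1 * mu0)

  fa <- cfg$mu_fa + cfg$fa_subject_sd * dev(lam["SC"], g_fa)
  if (group == "IDHwt") {
    ipsi <- if (lesion == "left") "left" else "right"
    fa[ipsi] <- fa[ipsi] + cfg$delta_fa_ipsi_idhwt
  }
  if (group == "IDHmut") {
    contra <- if (lesion == "left") "right" else "left"
    fa[contra] <- fa[contra] + cfg$delta_fa_contra_idhmut
  }
  fa <- pmin(pmax(fa, 0.02), 0.98)

  fc <- cfg$mu_fc + cfg$fc_subject_sd * dev(lam["FC"], g_fc)
  names(ew) <- names(fa) <- names(fc) <- comps
  list(EW = ew, FA = fa, FC = fc, g = c(EW = g_ew, FA = g_fa, FC = g_fc))
}

sample_truncated_age <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= 18 & draw < 80])
  }
  out[seq_len(n)]
}

#' Simulate a complete synthetic cohort
#'
#' Deterministic given `(config, seed)`: the master seed draws the
#' demographics and spawns one derived seed per subject, so subjects are
#' mutually independent and the cohort is bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return List of class `conn_cohort` with `subjects` (metadata table),
#'   `bundles` (named per-subject lists: `counts`, `fa`, `ts`, `truth`),
#'   `template` (see [sim_template()]), `config` and `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  config <- validate_sim_config(config)
  set.seed(as.integer(seed))
  tmpl <- sim_template(config)
  groups <- c(rep("control", config$n_control),
              rep("IDHmut", config$n_idhmut),
              rep("IDHwt", config$n_idhwt))
  ids <- c(sprintf("C%02d", seq_len(config$n_control)),
           sprintf("M%02d", seq_len(config$n_idhmut)),
           sprintf("W%02d", seq_len(config$n_idhwt)))
  n <- length(ids)
  age <- numeric(n)
  lesion <- character(n)
  sex <- character(n)
  for (grp in c("control", "IDHmut", "IDHwt")) {
    sel <- groups == grp
    age[sel] <- pmin(round(sample_truncated_age(sum(sel), config$age_mean[[grp]],
                                                config$age_sd[[grp]]), 1), 79.9)
    sex[sel] <- ifelse(stats::runif(sum(sel)) < config$male_prob[[grp]], "m", "f")
    lesion[sel] <- if (grp == "control") "none" else
      ifelse(stats::runif(sum(sel)) < config$lesion_left_prob[[grp]], "left", "right")
  }
  subjects <- validate_subjects(data.frame(
    subject_id = ids, group = groups, lesion_hemisphere = lesion,
    age = age, sex = sex, stringsAsFactors = FALSE))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  names(sub_seeds) <- ids
  bundles <- vector("list", n)
  names(bundles) <- ids
  for (i in seq_len(n)) {
    sid <- subjects$subject_id[i]
    set.seed(sub_seeds[[sid]])
    tr <- subject_targets(config, subjects$group[i],
                          subjects$lesion_hemisphere[i], tmpl$mu0)
    counts <- sample_counts(tmpl, tr$EW)
    fa <- sample_fa_edges(counts, tr$FA, config$fa_edge_sd)
    ts <- sample_timeseries(tr$FC, config$n_timepoints, config$n_regions)
    bundles[[sid]] <- list(counts = counts, fa = fa, ts = ts, truth = tr)
  }
  structure(list(subjects = subjects, bundles = bundles, template = tmpl,
                 config = config, seed = as.integer(seed)),
            class = "conn_cohort")
}
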