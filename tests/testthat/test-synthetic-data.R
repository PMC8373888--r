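test_that("the default configuration reproduces the study cohort structure", {
  cfg <- sim_config()
  expect_identical(cfg$n_regions, 246L)
  expect_identical(cfg$n_timepoints, 300L)
  expect_identical(c(cfg$n_control, cfg$n_idhmut, cfg$n_idhwt), c(27L, 15L, 14L))
  expect_error(sim_config(n_control = 2), ">= 4")
  expect_error(sim_config(mu_fa = c(left = 0.99, right = 0.5, inter = 0.5)),
               "inside \\(0, 1\\)")
  expect_error(sim_config(lesion_left_prob = c(IDHmut = 1.2, IDHwt = 0.5)),
               "\\[0, 1\\]")
})

test_that("simulated cohorts are deterministic given (config, seed)", {
  cfg <- sim_config(n_regions = 20, n_timepoints = 30,
                    n_control = 4, n_idhmut = 4, n_idhwt = 4)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$bundles, b$bundles)
  c2 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$bundles[[1]]$counts, c2$bundles[[1]]$counts))
})

test_that("cohort demographics respect group structure and bounds", {
  coh <- small_cohort(seed = 2)
  s <- coh$subjects
  expect_identical(as.integer(table(s$group)[c("control", "IDHmut", "IDHwt")]),
                   c(8L, 6L, 6L))
  expect_true(all(s$lesion_hemisphere[s$group == "control"] == "none"))
  expect_true(all(s$lesion_hemisphere[s$group != "control"] %in% c("left", "right")))
  expect_true(all(s$age >= 18 & s$age < 80))
})

test_that("count sampling matches its edge-weight targets via calibration", {
  cfg <- sim_config(n_regions = 60, n_timepoints = 30,
                    n_control = 4, n_idhmut = 4, n_idhwt = 4)
  tmpl <- sim_template(cfg)
  target <- tmpl$mu0 * c(1.15, 0.9, 0.8)
  names(target) <- names(tmpl$mu0)
  set.seed(77)
  devs <- replicate(20, {
    counts <- sample_counts(tmpl, target)
    ew <- edge_weight_matrix(counts)
    got <- hemispheric_means(ew, tmpl$template, default_atlas(60))$means
    (got - target) / target
  })
  expect_lt(max(abs(rowMeans(devs))), 0.03)
})

test_that("expected edge weights are invariant to uniform rate scaling", {
  cfg1 <- sim_config(n_regions = 40, intra_rate = 40, inter_rate = 30,
                     background_rate = 1)
  cfg2 <- sim_config(n_regions = 40, intra_rate = 80, inter_rate = 60,
                     background_rate = 2)
  expect_equal(sim_template(cfg1)$mu0, sim_template(cfg2)$mu0, tolerance = 1e-12)
})

test_that("the realized control mask retains nearly all template edges", {
  cfg <- sim_config(n_regions = 40, n_timepoints = 30,
                    n_control = 8, n_idhmut = 4, n_idhwt = 4)
  tmpl <- sim_template(cfg)
  n_template <- sum(tmpl$template[upper.tri(tmpl$template)])
  for (s in 1:10) {
    coh <- simulate_cohort(cfg, seed = 100 + s)
    ctrl <- coh$subjects$subject_id[coh$subjects$group == "control"]
    mask <- control_edge_mask(lapply(coh$bundles[ctrl], `[[`, "counts"))
    ut <- upper.tri(mask)
    retained <- sum(mask[ut] & tmpl$template[ut]) / n_template
    expect_gte(retained, 0.95)
  }
  # at the default control count a background edge (rate 1) survives the
  # all-controls rule with probability (1 - e^-1)^27 -- effectively never
  p_survive <- (1 - exp(-sim_config()$background_rate))^sim_config()$n_control
  expect_lt(p_survive, 1e-4)
})

test_that("FA edges follow their compartment targets and count support", {
  set.seed(31)
  counts <- random_counts(30, density = 0.5)
  target <- c(left = 0.42, right = 0.5, inter = 0.55)
  fa0 <- sample_fa_edges(counts, target, noise_sd = 0)
  expect_identical(is.na(fa0), counts == 0)  # missing exactly off the support
  atlas <- default_atlas(30)
  comp <- edge_compartments(atlas)
  ut <- upper.tri(counts) & counts > 0
  expect_true(all(fa0[ut & comp == "intra_left"] == 0.42))
  expect_true(all(fa0[ut & comp == "interhemispheric"] == 0.55))
  # with noise: all in (0,1), symmetric, compartment mean near target
  fa <- sample_fa_edges(counts, target, noise_sd = 0.08)
  vals <- fa[!is.na(fa)]
  expect_true(all(vals > 0 & vals < 1))
  expect_equal(fa, t(fa))
  hm <- hemispheric_means(fa, counts > 0, atlas)
  for (k in names(target)) {
    se <- 0.08 / sqrt(hm$n_edges[[k]])
    expect_lt(abs(hm$means[[k]] - target[[k]]), 4 * se)
  }
  expect_error(sample_fa_edges(counts, c(left = 1.2, right = 0.5, inter = 0.5)),
               "\\(0, 1\\)")
})

test_that("time series hit their block correlation structure", {
  set.seed(41)
  target <- c(left = atanh(0.4), right = atanh(0.3), inter = atanh(0.2))
  ts <- sample_timeseries(target, n_timepoints = 4000, n_regions = 20)
  expect_identical(dim(ts), c(4000L, 20L))
  fc <- fc_matrix(ts)
  atlas <- default_atlas(20)
  full <- matrix(TRUE, 20, 20); diag(full) <- FALSE
  hm <- hemispheric_means(fc, full, atlas)
  # sampling SE of mean z across correlated edges is below ~0.03 at T = 4000
  expect_lt(abs(hm$means[["left"]] - target[["left"]]), 0.06)
  expect_lt(abs(hm$means[["right"]] - target[["right"]]), 0.06)
  expect_lt(abs(hm$means[["inter"]] - target[["inter"]]), 0.06)
  # null targets give (near) independent series
  ts0 <- sample_timeseries(c(left = 0, right = 0, inter = 0), 500, 10)
  fc0 <- fc_matrix(ts0)
  expect_lt(mean(abs(fc0[upper.tri(fc0)])), 0.1)
  # infeasible interhemispheric target is repaired with a warning
  expect_warning(
    sample_timeseries(c(left = atanh(0.05), right = atanh(0.05),
                        inter = atanh(0.6)), 50, 8),
    "infeasible")
})

test_that("recovered compartment means track the stored truth targets", {
  # means are taken over the template support (the edges the all-controls
  # mask retains at the study's control count) so the check isolates
  # generator fidelity from mask sampling noise
  cfg <- sim_config(n_regions = 60, n_timepoints = 150,
                    n_control = 6, n_idhmut = 4, n_idhwt = 4)
  atlas <- default_atlas(60)
  dev_fa <- dev_fc <- dev_ew <- numeric(0)
  for (s in 1:5) {
    coh <- simulate_cohort(cfg, seed = 200 + s)
    tmpl_mask <- coh$template$template
    for (sid in coh$subjects$subject_id) {
      b <- coh$bundles[[sid]]
      truth <- b$truth
      ew <- hemispheric_means(edge_weight_matrix(b$counts), tmpl_mask, atlas)$means
      fa <- hemispheric_means(fa_connectivity(b$fa), tmpl_mask, atlas)$means
      fc <- hemispheric_means(fc_matrix(b$ts), tmpl_mask, atlas)$means
      dev_fa <- c(dev_fa, unname(fa - truth$FA))
      dev_fc <- c(dev_fc, unname(fc - truth$FC))
      dev_ew <- c(dev_ew, unname((ew - truth$EW) / truth$EW))
    }
  }
  # unbiased to within a few measurement SEs; spreads bounded by the
  # generator's own noise model (FA: edge noise / sqrt(edges); FC: finite-T
  # correlation noise; EW: Poisson + calibration approximation)
  expect_lt(abs(mean(dev_fa)), 0.005)
  expect_lt(stats::sd(dev_fa), 0.02)
  expect_lt(abs(mean(dev_fc)), 0.03)
  expect_lt(stats::sd(dev_fc), 0.1)
  expect_lt(abs(mean(dev_ew)), 0.03)
  expect_lt(stats::sd(dev_ew), 0.1)
})

test_that("planted group effects shift the expected compartment targets", {
  cfg <- sim_config(n_regions = 20, n_timepoints = 30,
                    n_control = 4, n_idhmut = 4, n_idhwt = 4,
                    ew_rel_sd = 0, fa_subject_sd = 0, fc_subject_sd = 0)
  coh <- simulate_cohort(cfg, seed = 9)
  s <- coh$subjects
  tmpl <- coh$template
  for (i in seq_len(nrow(s))) {
    tr <- coh$bundles[[s$subject_id[i]]]$truth
    if (s$group[i] == "control") {
      expect_equal(unname(tr$EW["inter"]), unname(tmpl$mu0["inter"]),
                   tolerance = 1e-12)
      expect_equal(unname(tr$FA), unname(cfg$mu_fa), tolerance = 1e-12)
    } else {
      expect_equal(unname(tr$EW["inter"]),
                   unname(tmpl$mu0["inter"]) * 0.85, tolerance = 1e-12)
      ipsi <- s$lesion_hemisphere[i]
      contra <- setdiff(c("left", "right"), ipsi)
      if (s$group[i] == "IDHwt") {
        expect_equal(unname(tr$FA[ipsi]), unname(cfg$mu_fa[ipsi]) - 0.03,
                     tolerance = 1e-12)
        expect_equal(unname(tr$FA[contra]), unname(cfg$mu_fa[contra]),
                     tolerance = 1e-12)
      } else {
        expect_equal(unname(tr$FA[contra]), unname(cfg$mu_fa[contra]) + 0.03,
                     tolerance = 1e-12)
      }
    }
  }
})
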