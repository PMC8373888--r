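# shared fixtures and independent oracles

# random symmetric non-negative count matrix with zero diagonal
random_counts <- function(r, max_count = 20, density = 0.6) {
  m <- matrix(0L, r, r)
  ut <- upper.tri(m)
  n <- sum(ut)
  vals <- ifelse(stats::runif(n) < density,
                 stats::rpois(n, max_count / 4), 0L)
  m[ut] <- as.integer(vals)
  m + t(m)
}

# brute-force edge weight from the definition, element by element
ew_bruteforce <- function(counts) {
  r <- nrow(counts)
  s <- sapply(seq_len(r), function(i) sum(counts[i, ]))
  out <- matrix(NA_real_, r, r)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    if (i != j) {
      d <- (s[i] + s[j]) / 2
      out[i, j] <- if (d > 0) counts[i, j] / d else 0
    }
  }
  out
}

# closed-form first-order partial correlation (oracle for k = 1)
pcor_closed_form <- function(x, y, z) {
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# small synthetic cohort for structural tests (fast)
small_cohort <- function(seed = 42, r = 40, t = 60,
                         n_control = 8, n_idhmut = 6, n_idhwt = 6) {
  simulate_cohort(sim_config(n_regions = r, n_timepoints = t,
                             n_control = n_control, n_idhmut = n_idhmut,
                             n_idhwt = n_idhwt),
                  seed = seed)
}

# summary-style table with a planted per-modality latent factor structure,
# bypassing the generator: used to test the coherence machinery in isolation
planted_summary_table <- function(n, lambda_sc, lambda_fc, seed,
                                  group = "control") {
  set.seed(seed)
  comps <- if (group == "control") c("left", "right", "inter") else
    c("ipsi", "contra", "inter")
  tab <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                    group = group,
                    age = stats::runif(n, 20, 75),
                    stringsAsFactors = FALSE)
  for (mod in c("EW", "FA", "FC")) {
    lam <- if (mod == "FC") lambda_fc else lambda_sc
    g <- stats::rnorm(n)
    for (cc in comps) {
      tab[[paste(mod, cc, sep = "_")]] <-
        sqrt(lam) * g + sqrt(1 - lam) * stats::rnorm(n)
    }
  }
  tab
}
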