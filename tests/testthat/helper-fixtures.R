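# Fixtures built in code, shared across test files.

# A tiny cohort for fast end-to-end checks.
tiny_cohort <- function(n = 12, seed = 42, ...) {
  simulate_cohort(sim_config(n_participants = n, n_volumes = 60, seed = seed, ...))
}

# A complete battery (no missing cells) with known latent structure.
complete_battery <- function(n = 40, seed = 1) {
  cfg <- sim_config(n_participants = n, missing_block_rate = 0,
                    missing_item_rate = 0, seed = seed)
  set.seed(seed)
  latent <- data.frame(prospective = rnorm(n), retrospective = rnorm(n),
                       row.names = sprintf("sub-%03d", seq_len(n)))
  simulate_questionnaires(cfg, latent)$battery
}

# Columns with exact sample moments: unit variances, correlation rho.
exact_corr_pair <- function(n = 20, rho = 0.5) {
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x))
  y <- rho * x + sqrt(1 - rho^2) * scale(e)[, 1]
  cbind(x = x, y = y)
}

# Profiles with id rownames from a symmetric random generator.
random_profiles <- function(n, n_edges = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n_edges), n, n_edges)
  rownames(m) <- sprintf("sub-%03d", seq_len(n))
  m
}

expect_binomial_coverage <- function(k, n_rep, alpha = 0.05) {
  # 0.05 must lie inside the exact (Clopper-Pearson) 95% CI of k/n_rep,
  # i.e. the exact binomial test must not reject.
  expect_gt(stats::binom.test(k, n_rep, alpha)$p.value, 0.05,
            label = sprintf("binom.test p for %d/%d rejections", k, n_rep))
}
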