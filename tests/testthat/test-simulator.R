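test_that("interaction matrix draw honors sparsity, tier scaling and seed", {
  B_h <- draw_interaction_matrix(20, 0.05, "high", seed = 3)
  expect_equal(sum(B_h != 0), 20)
  expect_lt(max(Mod(eigen(B_h)$values)), 1)
  B_l <- draw_interaction_matrix(20, 0.05, "low", seed = 3)
  B_m <- draw_interaction_matrix(20, 0.05, "medium", seed = 3)
  # shared seed: tiers differ only by the scale factor
  expect_equal(B_l, 0.1 * B_h, tolerance = 1e-12)
  expect_equal(B_m, 0.5 * B_h, tolerance = 1e-12)
  # byte-for-byte reproducibility
  expect_identical(B_h, draw_interaction_matrix(20, 0.05, "high", seed = 3))
  expect_error(draw_interaction_matrix(4, 0.01, "high", seed = 1),
               "at least 1")
})

test_that("scenario wiring: zeros and heterogeneity switch as designed", {
  cfgs <- lapply(1:4, function(s) sim_config(s, 5, 5, seed = 2))
  expect_equal(cfgs[[1]]$zero_profile, rep(0, 20))
  expect_equal(cfgs[[2]]$zero_profile, rep(0, 20))
  expect_equal(cfgs[[3]]$zero_profile, default_zero_profile)
  expect_false(cfgs[[1]]$heterogeneity)
  expect_true(cfgs[[2]]$heterogeneity)
  expect_false(cfgs[[3]]$heterogeneity)
  expect_true(cfgs[[4]]$heterogeneity)
})

test_that("taxa with zero-probability 1 are absent everywhere", {
  sim <- quick_sim(4, n = 15, T = 6, seed = 17)
  df <- as.data.frame(sim$panel)
  always_zero <- names(which(sim$truth$zero_profile == 1))
  expect_gt(length(always_zero), 0)
  for (tx in always_zero) {
    expect_true(all(df$count[df$taxon == tx] == 0))
  }
})

test_that("with B = 0 and no zeros, counts match the Poisson moment oracle", {
  cfg <- sim_config(1, n_subjects = 60, n_times = 10, seed = 29)
  sim <- simulate_panel(cfg, B_true = matrix(0, 20, 20))
  df <- as.data.frame(sim$panel)
  means <- tapply(df$count, df$taxon, mean)
  mu <- exp(cfg$b0)
  se <- sqrt(mu / (60 * 11))
  expect_true(all(abs(means - mu) < 3.5 * se))
  # chi-square GOF: counts are Poisson(exp(b0_m)) for most taxa
  pvals <- vapply(seq_along(mu), function(m) {
    y <- df$count[df$taxon == sprintf("taxon_%02d", m)]
    brk <- unique(stats::qpois(seq(0.125, 0.875, 0.125), mu[m]))
    obs <- table(cut(y, c(-1, brk, Inf)))
    expc <- diff(c(0, stats::ppois(c(brk, Inf), mu[m]))) * length(y)
    keep <- expc > 1
    suppressWarnings(stats::chisq.test(obs[keep], p = expc[keep] /
                                         sum(expc[keep]))$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 18)
})

test_that("empirical structural-zero fractions match the profile", {
  cfg <- sim_config(4, n_subjects = 500, n_times = 2, seed = 37)
  sim <- simulate_panel(cfg, B_true = matrix(0, 20, 20))
  frac <- colMeans(sim$truth$mask)
  p <- cfg$zero_profile
  se <- sqrt(p * (1 - p) / 500)
  expect_true(all(abs(frac - p) <= 3 * se + 1e-12))
})

test_that("zero-profile jitter is clamped, centred and optional", {
  cfg <- sim_config(3, 30, 5, seed = 51)
  expect_identical(perturb_zero_profile(cfg, 0), cfg)
  cfg_j <- perturb_zero_profile(cfg, 0.15)
  sim <- simulate_panel(cfg_j, B_true = matrix(0, 20, 20))
  df <- as.data.frame(sim$panel)
  # per-taxon zero fraction over many subjects ~ mean of clamped p_mt;
  # for interior probabilities the time-average stays near p_m
  interior <- which(cfg$zero_profile > 0.3 & cfg$zero_profile < 0.7)
  zf <- tapply(df$count == 0, df$taxon, mean)[interior]
  expect_true(all(abs(zf - cfg$zero_profile[interior]) < 0.12))
})

test_that("simulation is reproducible and panels are valid", {
  s1 <- quick_sim(2, n = 6, T = 5, seed = 61)
  s2 <- quick_sim(2, n = 6, T = 5, seed = 61)
  expect_identical(as.data.frame(s1$panel), as.data.frame(s2$panel))
  expect_identical(s1$truth$B_true, s2$truth$B_true)
  expect_s3_class(s1$panel, "longitudinal_panel")
  # T + 1 observations per subject (baseline + T transitions)
  expect_equal(unique(table(s1$panel$subject)), 6 * 20)
})
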