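test_that("conditional mixture log-likelihood matches term-by-term oracle", {
  # degenerate mixtures
  expect_equal(zip_loglik(0, eta = 1, p = 1), 0)
  expect_equal(zip_loglik(3, eta = 1, p = 1), -Inf)
  y <- c(0, 2, 5); eta <- log(c(1.5, 2, 5))
  expect_equal(zip_loglik(y, eta, p = 0),
               sum(dpois(y, exp(eta), log = TRUE)))
  # brute-force mixture density oracle on a random small case
  set.seed(3)
  y <- rpois(20, 3) * rbinom(20, 1, 0.7)
  eta <- rnorm(20, 1, 0.3); p <- runif(20, 0.1, 0.6)
  direct <- sum(vapply(seq_along(y), function(i) {
    if (y[i] == 0) log(p[i] + (1 - p[i]) * dpois(0, exp(eta[i])))
    else log((1 - p[i]) * dpois(y[i], exp(eta[i])))
  }, numeric(1)))
  expect_equal(zip_loglik(y, eta, p), direct, tolerance = 1e-12)
  expect_error(zip_loglik(1, eta = Inf, p = 0), "non-finite")
})

test_that("penalized objective follows the -2 loglik + l1 form", {
  expect_equal(penalized_objective(-10), 20)
  expect_equal(penalized_objective(-10, D = matrix(0.5, 1, 1), mu1 = 2), 21)
  # l1 homogeneity: doubling coefficients doubles the penalty part
  D <- matrix(c(0.5, -1, 0, 2), 2, 2)
  base <- penalized_objective(0, D = D, mu1 = 3)
  expect_equal(penalized_objective(0, D = 2 * D, mu1 = 3), 2 * base)
})

test_that("dispersion estimate floors at 1 and detects overdispersion", {
  expect_equal(estimate_dispersion(c(2, 3), c(2, 3), k = 1), 1)
  set.seed(42)
  mu <- rep(5, 400)
  y_pois <- rpois(400, mu)
  expect_lt(abs(estimate_dispersion(y_pois, mu, k = 1) - 1), 0.15)
  y_nb <- rnbinom(400, size = 2, mu = 5)  # variance mu + mu^2/2
  expect_gt(estimate_dispersion(y_nb, mu, k = 1), 1.5)
})

test_that("Laplace marginal reduces to the conditional at zero variance and
           matches numerical integration", {
  set.seed(9)
  eta <- rnorm(8, 1.2, 0.4)
  y <- rpois(8, exp(eta))
  subj <- rep(1L, 8)
  l0 <- laplace_marginal(y, eta, subj, sigma_a = 0, sigma_b = 0, n = 1)
  expect_equal(l0$loglik, zip_loglik(y, eta, 0), tolerance = 1e-12)
  expect_equal(unname(l0$modes[1, ]), c(0, 0))
  # single-subject Poisson-only toy with sigma_b > 0: adaptive quadrature
  # is the reference; a well-informed posterior makes Laplace accurate
  # while a 2-node Gauss-Hermite rule remains visibly cruder
  set.seed(9)
  eta <- rnorm(40, 3, 0.3)
  y <- rpois(40, exp(eta))
  for (s2 in c(0.05, 0.2)) {
    lap <- laplace_marginal(y, eta, rep(1L, 40), sigma_a = 0,
                            sigma_b = s2, n = 1)$loglik
    ref <- direct_marginal_poisson(y, eta, s2)
    expect_lt(abs(lap - ref), 1e-4)
    expect_gt(abs(gh_marginal_poisson(y, eta, s2, 2) - ref),
              abs(lap - ref))
  }
})

test_that("Laplace marginal decreases as the data move away from the mode", {
  # 1-subject toy: marginal loglik is largest when the fixed predictor is
  # unbiased and decreases monotonically as a bias is added
  set.seed(10)
  eta <- rep(log(8), 10)
  y <- rpois(10, exp(eta))
  shifts <- c(0, 0.4, 0.8, 1.2)
  ll <- vapply(shifts, function(s) {
    laplace_marginal(y, eta + s + mean(y / 8 - 1), rep(1L, 10),
                     sigma_a = 0, sigma_b = 0.05, n = 1)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) < 0))
})

test_that("unpenalized no-zero no-heterogeneity fit collapses to the
           IRLS Poisson GLM", {
  set.seed(21)
  sim <- quick_sim(1, n = 10, T = 8, seed = 31, M = 4)
  # keep only taxa with no zeros so the mixture part is inert
  keep <- names(which(tapply(sim$panel$count > 0, sim$panel$taxon, all)))
  expect_gte(length(keep), 2)
  panel <- longitudinal_panel(
    as.data.frame(sim$panel)[sim$panel$taxon %in% keep, ])
  fit <- fit_zipar(panel, lambda = 0,
                   control = zipar_control(random_effects = "none",
                                           tol = 1e-8, max_em_iter = 10))
  des <- lagged_design(panel)
  for (m in seq_along(keep)) {
    X <- cbind(des$lag[, -m, drop = FALSE], proj = des$y0log[des$subj, m])
    oracle <- suppressWarnings(
      glm.fit(cbind(1, X), des$y[, m], family = poisson()))
    est <- unname(c(fit$C[m, 1], fit$B[m, -m], fit$pi[m]))
    expect_equal(est, unname(coef(oracle)), tolerance = 1e-6)
  }
})

test_that("a huge penalty shrinks every penalized coefficient to zero", {
  sim <- quick_sim(1, n = 8, T = 6, seed = 77, M = 5)
  fit <- fit_zipar(sim$panel, lambda = 1e4,
                   control = zipar_control(random_effects = "none",
                                           max_em_iter = 5))
  expect_true(all(fit$B == 0))
  # the projection coefficient is unpenalized and the intercept survives
  expect_true(any(fit$C[, 1] != 0))
})

test_that("structural-zero responsibilities follow the subject-level
           closed form", {
  sim <- quick_sim(4, n = 10, T = 8, seed = 13, M = 8)
  fit <- fit_zipar(sim$panel, control = fast_control())
  des <- fit$design
  for (m in which(!fit$all_zero)) {
    y <- des$y[, m]
    z <- fit$responsibilities[, m]
    expect_true(all(z >= 0 & z <= 1))
    # a subject with any positive count cannot be structural: z = 0 on
    # all of its rows; an all-zero subject is structural: z = 1
    az <- tapply(y, des$subj, function(v) all(v == 0))
    expect_true(all(z[!az[des$subj]] == 0))
    expect_true(all(z[az[des$subj]] == 1))
    # and the population zero probability tracks the all-zero fraction
    expect_equal(unname(fit$p_subject[1, m]), mean(az), tolerance = 0.05)
  }
})

test_that("relabeling taxa permutes the interaction matrix identically", {
  sim <- quick_sim(3, n = 10, T = 8, seed = 19, M = 6)
  fit1 <- fit_zipar(sim$panel, control = fast_control())
  df <- as.data.frame(sim$panel)
  relabel <- setNames(sprintf("zz_%s", rev(attr(sim$panel, "taxa"))),
                      attr(sim$panel, "taxa"))
  df$taxon <- unname(relabel[df$taxon])
  fit2 <- fit_zipar(longitudinal_panel(df), control = fast_control())
  perm <- match(relabel[rownames(fit1$B)], rownames(fit2$B))
  expect_equal(unname(fit2$B[perm, perm]), unname(fit1$B),
               tolerance = 1e-8)
})

test_that("the penalized EM objective is monotone non-increasing at fixed
           penalty", {
  sim <- quick_sim(4, n = 12, T = 8, seed = 23, M = 10)
  des <- lagged_design(sim$panel)
  # fit one taxon at a fixed penalty and inspect the recorded objective
  m1 <- which(colSums(des$y) > 0)[1]
  y <- des$y[, m1]
  X <- cbind(des$lag, proj = des$y0log[des$subj, m1])
  ft <- ziparnet:::fit_taxon_zip(y, X, c(rep(1, ncol(des$lag)), 0),
                                 des$subj, length(des$subjects),
                                 matrix(0, length(des$subjects), 0),
                                 zipar_control(tol = 1e-6,
                                               max_em_iter = 40),
                                 lambda_fixed = 0.02)
  q <- ft$q_trace
  expect_gt(length(q), 1)
  viol <- diff(q) / pmax(abs(q[-length(q)]), 1)
  expect_true(all(viol < 1e-6))
})

test_that("BIC recomputes from loglik and parameter count, and a singleton
           grid returns that point", {
  sim <- quick_sim(1, n = 8, T = 6, seed = 41, M = 5)
  sel <- select_penalty_bic(sim$panel, grid = 0.05, shared = TRUE,
                            control = fast_control())
  ok <- !sel$fit$all_zero
  expect_true(all(sel$lambda[ok] == 0.05))
  fit <- sel$fit
  l <- 0
  for (m in which(ok)) {
    k_bic <- fit$k[m] + 2L + (if (any(fit$design$y[, m] == 0)) l + 1L else 0L)
    expect_equal(fit$bic[m],
                 -2 * fit$loglik[m] + k_bic * log(nrow(fit$design$y)),
                 tolerance = 1e-9)
  }
})

test_that("fit serialization round-trips coefficient matrices", {
  sim <- quick_sim(1, n = 8, T = 6, seed = 43, M = 5)
  fit <- fit_zipar(sim$panel, control = fast_control())
  d <- withr::local_tempdir()
  write_fit(fit, d, seed = 43)
  back <- read_fit(d)
  expect_equal(unname(back$B), unname(fit$B), tolerance = 1e-12)
  expect_equal(back$meta$method_tag, "zipar")
  expect_equal(back$meta$seed, 43)
})
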