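test_that("MNSES matches hand arithmetic and handles degenerate sd", {
  expect_equal(mnses(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_equal(mnses(c(2, 4), c(1, 2), c(1, 2)), 1.0)
  # zero sd with zero residual (0/0 cells) are excluded from the average
  expect_equal(mnses(c(0, 4), c(0, 2), c(0, 2)), 1)
  expect_error(mnses(c(1, 4), c(0, 2), c(0, 2)), "zero predictive")
})

test_that("selection metrics agree with a brute-force confusion matrix", {
  truth <- matrix(0, 20, 20)
  set.seed(12); truth[sample(400, 20)] <- rnorm(20)
  # perfect selection
  m <- selection_metrics(truth != 0, truth)
  expect_equal(m$tpr, 1); expect_equal(m$fpr, 0)
  expect_equal(m$mcc, 1); expect_equal(m$f_score, 1)
  # empty selection with true edges present
  m0 <- selection_metrics(matrix(FALSE, 20, 20), truth)
  expect_equal(m0$tpr, 0); expect_equal(m0$f_score, 0)
  # random mask vs brute force
  sel <- matrix(runif(400) < 0.1, 20, 20)
  m1 <- selection_metrics(sel, truth)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in 1:20) for (j in 1:20) {
    s <- sel[i, j]; t <- truth[i, j] != 0
    if (s && t) tp <- tp + 1 else if (s && !t) fp <- fp + 1
    else if (!s && t) fn <- fn + 1 else tn <- tn + 1
  }
  expect_equal(unname(m1$counts), c(tp, fp, tn, fn))
  expect_equal(sum(m1$counts), 400)
  expect_equal(m1$tpr, tp / (tp + fn))
  expect_equal(m1$fpr, fp / (fp + tn))
  expect_equal(m1$mcc, (tp * tn - fp * fn) /
                 sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  expect_equal(m1$f_score, tp / (tp + (fp + fn) / 2))
  expect_error(selection_metrics(sel[1:3, 1:3], truth), "shapes")
})

test_that("zero-proportion CV follows the by-time definition", {
  # two time points with zero proportions 0.2 and 0.4 for taxon g1
  rows <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(subject = paste0("s", i), time = 0:1, taxon = "g1",
               count = c(ifelse(i <= 2, 0, 5), ifelse(i <= 4, 0, 5)),
               stringsAsFactors = FALSE)
  }))
  rows2 <- rows; rows2$taxon <- "g2"; rows2$count <- 3  # never zero
  p <- longitudinal_panel(rbind(rows, rows2))
  cv <- zero_proportion_cv(p)
  g1 <- cv[cv$taxon == "g1", ]
  expect_equal(g1$mean_zero_prop, 0.3)
  expect_equal(g1$sd, sd(c(0.2, 0.4)))
  expect_equal(g1$cv, sd(c(0.2, 0.4)) / 0.3, tolerance = 1e-12)
  expect_true(is.na(cv$cv[cv$taxon == "g2"]))
  # constant zero proportion across time gives CV 0: the same two
  # subjects are zero at both time points
  rows3 <- rows
  rows3$count <- ifelse(rows3$subject %in% c("s1", "s2"), 0, 5)
  cv3 <- zero_proportion_cv(longitudinal_panel(rows3))
  expect_equal(cv3$cv, 0)
})

test_that("study runner is seeded, order-invariant and degenerate-safe", {
  ctrl <- fast_control()
  r1 <- run_simulation_study(1, 6, 5, "high", "poisson", n_reps = 2,
                             seed = 3, n_taxa = 6, control = ctrl)
  r2 <- run_simulation_study(1, 6, 5, "high", "poisson", n_reps = 2,
                             seed = 3, n_taxa = 6, control = ctrl)
  expect_identical(r1$mnses, r2$mnses)
  # n_reps = 1: IQR collapses onto the single value
  s1 <- summarize_study(r1[r1$replicate == 1, ])
  expect_equal(s1$mnses_q1, s1$mnses_median)
  expect_equal(s1$mnses_q3, s1$mnses_median)
  # summaries invariant to replicate execution order
  perm <- r1[sample.int(nrow(r1)), ]
  expect_equal(summarize_study(perm)$mnses_median,
               summarize_study(r1)$mnses_median)
})

test_that("TPR rises with effect tier at matched seeds", {
  ctrl <- fast_control()
  res <- run_simulation_study(1, 15, 8, c("low", "medium", "high"),
                              "zipar", n_reps = 4, seed = 9,
                              control = ctrl)
  s <- summarize_study(res)
  tpr <- setNames(s$tpr_mean, s$tier)
  expect_lte(tpr[["low"]], tpr[["medium"]] + 1e-9)
  expect_lte(tpr[["medium"]], tpr[["high"]] + 1e-9)
})
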