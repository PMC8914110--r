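test_that("long-format parsing validates and indexes deterministically", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\ttime\ttaxon\tcount",
               "s1\t0\tg1\t10", "s1\t1\tg1\t0", "s1\t2\tg1\t5"), f)
  p <- read_long_counts(f)
  expect_s3_class(p, "longitudinal_panel")
  expect_equal(attr(p, "subjects"), "s1")
  expect_equal(attr(p, "taxa"), "g1")
  expect_equal(nrow(p), 3L)
  expect_equal(p$count, c(10, 0, 5))

  writeLines(c("subject\ttime\ttaxon\tcount", "s1\t0\tg1\t-1",
               "s1\t1\tg1\t2"), f)
  expect_error(read_long_counts(f), "negative abundance")

  writeLines(c("subject\ttime\tcount", "s1\t0\t1"), f)
  expect_error(read_long_counts(f), "missing required column")
})

test_that("panel invariants reject duplicates, single-timepoint and gaps", {
  df <- toy_panel_df()
  expect_s3_class(longitudinal_panel(df), "longitudinal_panel")
  expect_error(longitudinal_panel(rbind(df, df[1, ])), "duplicate")
  expect_error(longitudinal_panel(df[df$time == 0, ]), "fewer than 2")
  gap <- df[df$subject != "s1" | df$time != 1, ]
  expect_error(longitudinal_panel(gap), "irregular")
})

test_that("write -> read round-trips a simulated panel exactly", {
  sim <- quick_sim(3, n = 4, T = 4, seed = 11, M = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_long_counts(sim$panel, f)
  back <- read_long_counts(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$panel))
  # idempotence of a second cycle
  write_long_counts(back, f)
  expect_equal(as.data.frame(read_long_counts(f)), as.data.frame(back))
})

test_that("absolute abundances scale relative abundances by load x density", {
  expect_equal(absolute_from_relative(c(0.5, 0.5), 100, 1.1), c(55, 55))
  expect_equal(absolute_from_relative(c(1, 0), 7, 2), c(14, 0))
  set.seed(1)
  x <- rexp(30); rel <- x / sum(x)
  out <- absolute_from_relative(rel, 1e5, 1.1)
  expect_equal(sum(out), 1.1e5, tolerance = 1e-9)
  expect_error(absolute_from_relative(c(0.6, 0.6), 10), "sum to 1")
  expect_error(absolute_from_relative(c(1.2, -0.2), 10), "\\[0, 1\\]")
})

test_that("taxa filtering applies prevalence and mean-abundance rules", {
  # taxon 'rare' present in 4 samples, 'tiny' at 0.05% mean rel abundance
  base <- expand.grid(subject = paste0("s", 1:4), time = 0:4,
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    s <- base$subject[i]; t <- base$time[i]
    data.frame(subject = s, time = t,
               taxon = c("big", "rare", "tiny"),
               count = c(10000, if (i <= 4) 50 else 0, 5),
               stringsAsFactors = FALSE)
  }))
  p <- longitudinal_panel(rows)
  fl <- filter_taxa(p, min_mean_rel_abund = 0.001,
                    min_prevalence_samples = 5)
  expect_setequal(fl$removed, c("rare", "tiny"))
  expect_equal(attr(fl$panel, "taxa"), "big")
  # thresholds 0/0 are the identity filter
  fl0 <- filter_taxa(p, 0, 0)
  expect_length(fl0$removed, 0)
  expect_equal(as.data.frame(fl0$panel), as.data.frame(p))
  # order independence
  perm <- rows[sample.int(nrow(rows)), ]
  fl2 <- filter_taxa(longitudinal_panel(perm), 0.001, 5)
  expect_setequal(fl2$removed, fl$removed)
})

test_that("covariate tables must be complete and unique", {
  df <- data.frame(subject = c("s1", "s2"), age = c(30, 40))
  expect_silent(ziparnet:::validate_covariates(df, c("s1", "s2")))
  expect_error(ziparnet:::validate_covariates(df, c("s1", "s3")),
               "missing for subject")
  df$age[1] <- NA
  expect_error(ziparnet:::validate_covariates(df), "missing values")
})
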