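# helper: build an edge_set directly (bypassing the bootstrap) so graph
# summaries can be tested against closed forms
make_edge_set <- function(edges_df, taxa) {
  all_pairs <- expand.grid(source = taxa, target = taxa,
                           stringsAsFactors = FALSE)
  all_pairs$estimate <- 0; all_pairs$ci_low <- -1; all_pairs$ci_high <- 1
  key <- paste(all_pairs$source, all_pairs$target)
  if (nrow(edges_df) > 0) {
    k2 <- paste(edges_df$source, edges_df$target)
    idx <- match(k2, key)
    all_pairs$estimate[idx] <- edges_df$estimate
    all_pairs$ci_low[idx] <- edges_df$estimate - 0.01
    all_pairs$ci_high[idx] <- edges_df$estimate + 0.01
  }
  all_pairs$sign <- sign(all_pairs$estimate)
  all_pairs$informative <- all_pairs$ci_low > 0 | all_pairs$ci_high < 0
  structure(all_pairs, n_taxa = length(taxa), taxa = taxa,
            n_bootstrap = 100L, ci_level = 0.95, n_failed = 0L,
            class = c("edge_set", "data.frame"))
}

test_that("network summary: empty set and star graph closed forms", {
  taxa <- paste0("t", 1:5)
  empty <- make_edge_set(data.frame(), taxa)
  s0 <- summarize_network(empty)
  expect_equal(s0$n_informative_edges, 0)
  expect_equal(unname(s0$informative_percentage), 0)
  expect_true(all(s0$edge_bins == 0))

  # star: hub t1 -> each leaf
  star <- make_edge_set(data.frame(source = "t1",
                                   target = paste0("t", 2:5),
                                   estimate = c(0.05, 0.2, 0.3, 0.7)),
                        taxa)
  s <- summarize_network(star)
  expect_equal(s$n_informative_edges, 4)
  expect_equal(unname(s$edge_bins), c(1, 1, 1, 1))
  expect_equal(unname(s$degree["t1"]), 4)
  expect_equal(unname(s$average_neighbor_degree["t2"]), 4)
  expect_equal(unname(s$average_neighbor_degree["t1"]), 1)
  expect_equal(unname(s$informative_percentage), 100 * 4 / 25)
})

test_that("bin counts and degrees match brute force and igraph", {
  set.seed(14)
  taxa <- paste0("g", 1:8)
  df <- expand.grid(source = taxa, target = taxa,
                    stringsAsFactors = FALSE)
  df <- df[runif(nrow(df)) < 0.25, ]
  df$estimate <- rnorm(nrow(df), 0, 0.4)
  es <- make_edge_set(df, taxa)
  s <- summarize_network(es)
  a <- abs(es$estimate[es$informative])
  expect_equal(unname(s$edge_bins),
               c(sum(a < 0.1), sum(a >= 0.1 & a < 0.25),
                 sum(a >= 0.25 & a < 0.5), sum(a >= 0.5)))
  expect_equal(sum(s$edge_bins), s$n_informative_edges)
  # igraph as independent oracle for degree / average neighbor degree
  inf <- es[es$informative & es$source != es$target, ]
  g <- igraph::graph_from_data_frame(inf[, 1:2], directed = FALSE,
                                     vertices = taxa)
  g <- igraph::simplify(g)
  deg_i <- igraph::degree(g)
  self_loop <- with(es[es$informative, ], source == target)
  selfs <- unique(es$source[es$informative][self_loop])
  expected_deg <- deg_i[taxa] + as.numeric(taxa %in% selfs)
  expect_equal(unname(s$degree[taxa]), unname(expected_deg))
  knn_i <- suppressWarnings(igraph::knn(g)$knn)
  # igraph knn ignores the self-loop increment; compare on vertices
  # without informative self-edges
  plain <- setdiff(taxa, selfs)
  plain <- plain[!plain %in% selfs &
                   !vapply(plain, function(v)
                     any(igraph::neighbors(g, v)$name %in% selfs), TRUE)]
  expect_equal(s$average_neighbor_degree[plain], knn_i[plain],
               tolerance = 1e-12)
})

test_that("graph export round-trips and GraphML is well-formed XML", {
  taxa <- paste0("x", 1:4)
  es <- make_edge_set(data.frame(source = c("x1", "x2"),
                                 target = c("x2", "x3"),
                                 estimate = c(0.4, -0.2)), taxa)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_graph(es, f, "edgelist", informative_only = FALSE)
  back <- read_edge_list(f)
  expect_equal(back$estimate, es$estimate)
  expect_equal(sum(back$informative), 2)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  es1 <- make_edge_set(data.frame(source = "x1", target = "x2",
                                  estimate = 0.4), taxa)
  export_graph(es1, f1, "edgelist")
  expect_length(readLines(f1), 2L)  # header + one edge

  fg <- withr::local_tempfile(fileext = ".graphml")
  export_graph(es, fg, "graphml")
  doc <- xml2::read_xml(fg)  # errors if malformed
  expect_equal(xml2::xml_name(doc), "graphml")
})

test_that("bootstrap edge selection is deterministic and CI-consistent", {
  sim <- quick_sim(1, n = 14, T = 8, seed = 71, M = 5)
  ctrl <- fast_control()
  es1 <- bootstrap_edges(sim$panel, n_boot = 12, seed = 5, control = ctrl)
  es2 <- bootstrap_edges(sim$panel, n_boot = 12, seed = 5, control = ctrl)
  expect_identical(as.data.frame(es1), as.data.frame(es2))
  expect_true(all(es1$ci_low <= es1$estimate + 1e-12))
  expect_true(all(es1$ci_high >= es1$estimate - 1e-12))
  inf <- es1[es1$informative, ]
  expect_true(all(inf$ci_low > 0 | inf$ci_high < 0))
  expect_error(bootstrap_edges(sim$panel, n_boot = 0), "at least 1")
})

test_that("strong true edges are recovered; null edges are rarely selected", {
  ctrl <- fast_control()
  hits <- 0; n_meta <- 6
  null_rate <- numeric(n_meta)
  # a single strong off-diagonal interaction (taxon 3 -> taxon 1)
  B_true <- matrix(0, 5, 5)
  B_true[1, 3] <- 0.6
  for (r in seq_len(n_meta)) {
    sim <- NULL
    for (k in 0:10) {
      sim <- tryCatch(
        simulate_panel(sim_config(1, 30, 10, n_taxa = 5,
                                  seed = 300 + 17 * r + k),
                       B_true = B_true),
        error = function(e) NULL)
      if (!is.null(sim)) break
    }
    es <- bootstrap_edges(sim$panel, n_boot = 25, seed = r, control = ctrl)
    Binf <- matrix(es$informative,
                   attr(es, "n_taxa"), attr(es, "n_taxa"))
    # edge_set is column-major in B[m, j]
    if (Binf[1, 3]) hits <- hits + 1
    null_rate[r] <- mean(Binf[B_true == 0])
  }
  expect_gte(hits, n_meta - 1)
  expect_lte(mean(null_rate), 0.10)
})
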