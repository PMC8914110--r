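#' Bootstrap selection of informative interactions
#'
#' Resamples subjects (whole trajectories, preserving within-subject
#' dependence) with replacement, refits the model on each replicate, and
#' forms percentile confidence intervals for every entry of the
#' interaction matrix. An interaction is informative when its interval
#' excludes zero. Penalties are kept fixed at the values tuned on the
#' original data unless \code{retune = TRUE}.
#'
#' @inheritParams fit_zipar
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed; replicate streams derive from it, so a fixed
#'   seed gives an identical edge set.
#' @param ci_level confidence level (default 0.95).
#' @param retune re-tune the penalty by BIC inside every replicate.
#' @param max_fail_frac abort when more than this fraction of replicate
#'   fits fail (default 0.2).
#' @param boot_control fitter control for the replicate refits; the
#'   default relaxes the original control (tolerance 1e-3, at most 15 EM
#'   cycles, no exact marginal) since interval endpoints do not need deep
#'   convergence.
#' @return an \code{edge_set}: a data.frame over all M^2 ordered taxon
#'   pairs with columns source (predictor taxon j), target (response taxon
#'   m), estimate (original \eqn{\hat B_{mj}}), ci_low, ci_high, sign,
#'   informative; attributes n_bootstrap, ci_level, n_taxa, n_failed.
#'   Intervals are widened, when necessary, to contain the original
#'   estimate.
#' @export
bootstrap_edges <- function(panel, covariates = NULL, zero_cols = NULL,
                            ar_cols = NULL, n_boot = 100, seed = 1,
                            ci_level = 0.95, retune = FALSE,
                            control = zipar_control(),
                            max_fail_frac = 0.2, boot_control = NULL) {
  if (n_boot < 1) stop("n_boot must be at least 1 to form an interval",
                       call. = FALSE)
  if (is.null(boot_control)) {
    boot_control <- control
    boot_control$tol <- max(control$tol, 1e-3)
    boot_control$max_em_iter <- min(control$max_em_iter, 15L)
    boot_control$exact_marginal <- FALSE
  }
  fit0 <- fit_zipar(panel, covariates, zero_cols, ar_cols,
                    control = control)
  taxa <- fit0$taxa
  M <- length(taxa)
  subjects <- fit0$subjects
  df <- as.data.frame(panel)
  chunks <- split(df, df$subject)
  lam <- if (retune) NULL else ifelse(is.na(fit0$lambda), 0, fit0$lambda)

  boots <- array(NA_real_, c(n_boot, M, M))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    pick <- sample(subjects, length(subjects), replace = TRUE)
    parts <- lapply(seq_along(pick), function(k) {
      d <- chunks[[pick[k]]]
      d$subject <- sprintf("bs%03d_%s", k, pick[k])
      d
    })
    bpanel <- longitudinal_panel(do.call(rbind, parts))
    bcov <- if (!is.null(covariates)) {
      cc <- covariates[match(pick, covariates$subject), , drop = FALSE]
      cc$subject <- sprintf("bs%03d_%s", seq_along(pick), pick)
      cc
    } else NULL
    Bb <- tryCatch(
      fit_zipar(bpanel, bcov, zero_cols, ar_cols, lambda = lam,
                control = boot_control)$B,
      error = function(e) NULL)
    if (is.null(Bb)) {
      n_failed <- n_failed + 1L
      next
    }
    boots[b, , ] <- Bb
  }
  if (n_failed > max_fail_frac * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap fits failed; aborting",
         call. = FALSE)
  }
  alpha <- (1 - ci_level) / 2
  lo <- apply(boots, c(2, 3), stats::quantile, probs = alpha,
              na.rm = TRUE, names = FALSE)
  hi <- apply(boots, c(2, 3), stats::quantile, probs = 1 - alpha,
              na.rm = TRUE, names = FALSE)
  est <- fit0$B
  lo <- pmin(lo, est)
  hi <- pmax(hi, est)
  edges <- data.frame(
    source = rep(taxa, each = M),   # predictor taxon j (column of B)
    target = rep(taxa, times = M),  # response taxon m (row of B)
    estimate = as.vector(est),      # column-major: B[m, j] varies m first
    ci_low = as.vector(lo),
    ci_high = as.vector(hi),
    stringsAsFactors = FALSE)
  edges$sign <- sign(edges$estimate)
  edges$informative <- edges$ci_low > 0 | edges$ci_high < 0
  structure(edges, n_bootstrap = n_boot, ci_level = ci_level,
            n_taxa = M, taxa = taxa, n_failed = n_failed,
            seed = seed, fit = fit0,
            class = c("edge_set", "data.frame"))
}

#' @export
print.edge_set <- function(x, ...) {
  cat("Bootstrap interaction edge set\n")
  cat(sprintf("  taxa: %d   candidate effects: %d   informative: %d\n",
              attr(x, "n_taxa"), nrow(x), sum(x$informative)))
  cat(sprintf("  bootstrap resamples: %d (failed: %d)   CI level: %.2f\n",
              attr(x, "n_bootstrap"), attr(x, "n_failed"),
              attr(x, "ci_level")))
  invisible(x)
}

#' Graph summary statistics of an informative edge set
#'
#' Bins the informative interaction strengths at thresholds 0.1, 0.25 and
#' 0.5 on \eqn{|\hat B_{mj}|}, splits by sign, and computes vertex degrees
#' (undirected, a reciprocal pair counted once) with the per-vertex
#' average neighbor degree; directed in/out degrees are also reported.
#'
#' @param edges an \code{edge_set}.
#' @return a \code{network_summary} list: n_taxa, n_informative_edges,
#'   edge_bins, informative_percentage (of M^2 candidates),
#'   positive_negative_counts, degree (per vertex), in_degree, out_degree,
#'   degree_histogram, average_neighbor_degree (per vertex).
#' @export
summarize_network <- function(edges) {
  stopifnot(inherits(edges, "edge_set"))
  taxa <- attr(edges, "taxa")
  M <- attr(edges, "n_taxa")
  inf <- edges[edges$informative, , drop = FALSE]
  n_inf <- nrow(inf)
  a <- abs(inf$estimate)
  bins <- c(`|B|<0.1` = sum(a < 0.1),
            `0.1<=|B|<0.25` = sum(a >= 0.1 & a < 0.25),
            `0.25<=|B|<0.5` = sum(a >= 0.25 & a < 0.5),
            `|B|>=0.5` = sum(a >= 0.5))
  pos_neg <- c(positive = sum(inf$estimate > 0),
               negative = sum(inf$estimate < 0))

  # undirected simple adjacency: m~j if either direction is informative
  adj <- matrix(FALSE, M, M, dimnames = list(taxa, taxa))
  if (n_inf > 0) {
    ii <- cbind(match(inf$target, taxa), match(inf$source, taxa))
    adj[ii] <- TRUE
    adj <- adj | t(adj)
  }
  diag_self <- diag(adj)
  diag(adj) <- FALSE
  degree <- rowSums(adj) + diag_self  # self-interaction counts once
  neigh_deg <- vapply(seq_len(M), function(v) {
    nb <- which(adj[v, ])
    if (length(nb) == 0) NA_real_ else mean(degree[nb])
  }, numeric(1))
  in_deg <- tabulate(match(inf$target, taxa), nbins = M)
  out_deg <- tabulate(match(inf$source, taxa), nbins = M)

  structure(list(n_taxa = M,
                 n_informative_edges = n_inf,
                 edge_bins = bins,
                 informative_percentage = 100 * n_inf / M^2,
                 positive_negative_counts = pos_neg,
                 degree = stats::setNames(degree, taxa),
                 in_degree = stats::setNames(in_deg, taxa),
                 out_degree = stats::setNames(out_deg, taxa),
                 degree_histogram = table(factor(degree,
                                                 levels = 0:max(degree, 0))),
                 average_neighbor_degree = stats::setNames(neigh_deg, taxa)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Interaction network summary\n")
  cat(sprintf("  taxa: %d   informative interactions: %d (%.2f%% of %d)\n",
              x$n_taxa, x$n_informative_edges, x$informative_percentage,
              x$n_taxa^2))
  cat("  effect-size bins: ",
      paste(names(x$edge_bins), x$edge_bins, sep = "=", collapse = "  "),
      "\n", sep = "")
  cat(sprintf("  positive/negative: %d/%d\n",
              x$positive_negative_counts[["positive"]],
              x$positive_negative_counts[["negative"]]))
  invisible(x)
}

#' Write a network summary as JSON
#' @param summary a \code{network_summary}.
#' @param path output file.
#' @export
write_network_json <- function(summary, path) {
  stopifnot(inherits(summary, "network_summary"))
  obj <- unclass(summary)
  obj$degree_histogram <- as.list(obj$degree_histogram)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Export an edge set as an edge list or GraphML
#'
#' Directed graph over all taxa; edge weight is the estimated interaction,
#' with sign and informative attributes, node degree attribute, and stable
#' (sorted) node ordering. The edge list contains only informative edges
#' by default.
#'
#' @param edges an \code{edge_set}.
#' @param path output file.
#' @param format \code{"edgelist"} (TSV) or \code{"graphml"}.
#' @param informative_only restrict to informative edges (default TRUE).
#' @export
export_graph <- function(edges, path, format = c("edgelist", "graphml"),
                         informative_only = TRUE) {
  stopifnot(inherits(edges, "edge_set"))
  format <- match.arg(format)
  sel <- if (informative_only) edges[edges$informative, , drop = FALSE]
  else as.data.frame(edges)
  if (format == "edgelist") {
    utils::write.table(sel, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    taxa <- sort(attr(edges, "taxa"))
    g <- igraph::graph_from_data_frame(
      sel[, c("source", "target", "estimate", "sign", "informative")],
      directed = TRUE, vertices = data.frame(name = taxa))
    igraph::V(g)$degree <- igraph::degree(g, mode = "all")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an exported edge list back into an edge set
#'
#' @param path a TSV written by [export_graph()] with
#'   \code{format = "edgelist"}.
#' @param taxa optional taxon universe (defaults to taxa present).
#' @export
read_edge_list <- function(path, taxa = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("source", "target", "estimate", "ci_low", "ci_high", "sign",
            "informative")
  stopifnot(all(need %in% names(df)))
  if (is.null(taxa)) taxa <- sort(unique(c(df$source, df$target)))
  structure(df[, need], n_taxa = length(taxa), taxa = taxa,
            n_bootstrap = NA_integer_, ci_level = NA_real_,
            n_failed = NA_integer_,
            class = c("edge_set", "data.frame"))
}
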