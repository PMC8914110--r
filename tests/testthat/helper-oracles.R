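# Independent oracle utilities shared across tests.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen-decomposition of the
# Jacobi matrix), for checking Laplace-approximate integrals.
gauss_hermite <- function(k) {
  if (k == 1) return(list(nodes = 0, weights = sqrt(pi)))
  j <- sqrt(seq_len(k - 1) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- j
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- j
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# marginal log-likelihood of a Poisson model with a single N(0, s2) random
# intercept, integrated by k-node Gauss-Hermite quadrature
gh_marginal_poisson <- function(y, eta, s2, k) {
  gh <- gauss_hermite(k)
  b <- sqrt(2 * s2) * gh$nodes
  vals <- vapply(b, function(bb) {
    sum(stats::dpois(y, exp(eta + bb), log = TRUE))
  }, numeric(1))
  m <- max(vals)
  log(sum(gh$weights / sqrt(pi) * exp(vals - m))) + m
}

# the same integral by direct adaptive quadrature (the reference oracle;
# fixed-node Gauss-Hermite under-resolves sharp posteriors)
direct_marginal_poisson <- function(y, eta, s2) {
  lp <- function(bb) {
    sum(stats::dpois(y, exp(eta + bb), log = TRUE)) +
      stats::dnorm(bb, 0, sqrt(s2), log = TRUE)
  }
  shift <- -lp(0)
  f <- function(b) vapply(b, function(bb) exp(lp(bb) + shift), numeric(1))
  log(stats::integrate(f, -3, 3, rel.tol = 1e-12)$value) - shift
}

# small deterministic long-format panel for I/O tests
toy_panel_df <- function() {
  expand.grid(subject = c("s1", "s2"), time = 0:3,
              taxon = c("gA", "gB"), stringsAsFactors = FALSE) |>
    (\(d) { d$count <- seq_len(nrow(d)) %% 7; d })()
}

# a quick simulated panel used by several suites
quick_sim <- function(scenario = 1, n = 12, T = 8, seed = 5, M = 20) {
  for (k in 0:10) {
    out <- tryCatch(
      simulate_panel(sim_config(scenario, n, T, n_taxa = M, seed = seed + k)),
      error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("quick_sim failed to produce a stable panel")
}

fast_control <- function(...) {
  zipar_control(tol = 1e-3, max_em_iter = 60, ...)
}
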