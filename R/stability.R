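#' Community stability from an interaction matrix
#'
#' Computes the full spectrum of the taxon-taxon interaction matrix
#' \code{B}, its spectral radius (the maximum eigenvalue modulus), the
#' squared radius, and the stationarity verdict: a log-linear Poisson AR(1)
#' community has a strict-sense stationary distribution when every
#' eigenvalue of \code{B} lies strictly inside the unit circle. A smaller
#' radius means the community returns to its stationary distribution
#' faster and is less reactive — i.e. more stable; both the return rate
#' and the reactivity are bounded by the spectral radius.
#'
#' @param B square numeric interaction matrix (rows = response taxon).
#' @param label optional community label carried into comparisons.
#' @return object of class \code{stability_report} with fields
#'   \code{eigenvalues} (complex), \code{spectral_radius},
#'   \code{max_eigenvalue_squared}, \code{is_stationary} (strict
#'   inequality), and \code{margin} = 1 - radius.
#' @export
stability_report <- function(B, label = NULL) {
  if (!is.matrix(B) || nrow(B) != ncol(B)) {
    stop("B must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(B))) stop("B contains non-finite entries",
                               call. = FALSE)
  ev <- eigen(B, only.values = TRUE)$values
  radius <- max(Mod(ev))
  structure(list(label = label,
                 eigenvalues = ev,
                 spectral_radius = radius,
                 max_eigenvalue_squared = radius^2,
                 is_stationary = radius < 1,
                 margin = 1 - radius,
                 n_taxa = nrow(B)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Community stability report",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  taxa: %d\n  spectral radius: %.4f (squared %.4f)\n",
              x$n_taxa, x$spectral_radius, x$max_eigenvalue_squared))
  cat(sprintf("  stationary: %s   margin to unit circle: %.4f\n",
              if (x$is_stationary) "yes" else "NO", x$margin))
  invisible(x)
}

#' Rank communities by stability
#'
#' Orders stability reports by squared spectral radius, ascending: the
#' community with the smallest radius is the most stable (its perturbed
#' abundances are pulled back to the stationary mean fastest). Exact ties
#' are flagged.
#'
#' @param ... two or more \code{stability_report} objects (or one list of
#'   them).
#' @return a \code{stability_comparison}: a data.frame with one row per
#'   community (label, radius, squared radius, stationary flag, rank;
#'   rank 1 = most stable) plus a \code{ties} attribute.
#' @export
compare_stability <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "stability_report")) {
    reports <- reports[[1L]]
  }
  stopifnot(length(reports) >= 2L,
            all(vapply(reports, inherits, TRUE, "stability_report")))
  labs <- vapply(seq_along(reports), function(i) {
    lb <- reports[[i]]$label
    if (is.null(lb)) paste0("community_", i) else lb
  }, character(1))
  sq <- vapply(reports, `[[`, numeric(1), "max_eigenvalue_squared")
  out <- data.frame(label = labs,
                    spectral_radius = sqrt(sq),
                    max_eigenvalue_squared = sq,
                    is_stationary = vapply(reports, `[[`, TRUE,
                                           "is_stationary"),
                    stringsAsFactors = FALSE)
  out$rank <- rank(sq, ties.method = "min")
  out$more_stable_than_next <- c(diff(sort(sq)) > 0, NA)[order(order(sq))]
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "ties") <- anyDuplicated(sq) > 0
  class(out) <- c("stability_comparison", "data.frame")
  out
}

#' Write a stability report as JSON
#'
#' Spectrum serialized as [re, im] pairs, plus radius, verdict and margin.
#'
#' @param report a \code{stability_report}.
#' @param path output file.
#' @export
write_stability_json <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  obj <- list(label = report$label,
              eigenvalues = lapply(report$eigenvalues,
                                   function(z) c(Re(z), Im(z))),
              spectral_radius = report$spectral_radius,
              max_eigenvalue_squared = report$max_eigenvalue_squared,
              is_stationary = report$is_stationary,
              margin = report$margin,
              n_taxa = report$n_taxa)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
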