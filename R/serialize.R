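#' Serialize a fit to a directory of delimited matrices
#'
#' Writes the coefficient matrices as TSV files (A.tsv, B.tsv, C.tsv,
#' pi.tsv, phi.tsv, sigma.tsv) plus a meta.json with penalties,
#' convergence flags, BIC, package version and an optional seed, so a fit
#' directory is self-describing and re-loadable.
#'
#' @param fit a \code{zipar_fit} or \code{baseline_fit}.
#' @param dir output directory (created if needed).
#' @param seed optional seed to record.
#' @export
write_fit <- function(fit, dir, seed = NULL) {
  stopifnot(inherits(fit, c("zipar_fit", "baseline_fit")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(as.data.frame(x), file.path(dir, f), sep = "\t",
                       quote = FALSE, col.names = NA, fileEncoding = "UTF-8")
  }
  wt(fit$B, "B.tsv")
  wt(fit$C, "C.tsv")
  is_zip <- inherits(fit, "zipar_fit")
  if (is_zip) {
    wt(fit$A, "A.tsv")
    wt(cbind(pi = fit$pi), "pi.tsv")
    wt(cbind(phi = fit$phi), "phi.tsv")
    wt(cbind(sigma_a = fit$sigma_a, sigma_b = fit$sigma_b), "sigma.tsv")
  } else {
    wt(cbind(residual_scale = fit$residual_scale), "sigma.tsv")
  }
  meta <- list(method_tag = if (is_zip) "zipar" else fit$method_tag,
               taxa = fit$taxa, subjects = fit$subjects,
               lambda = as.list(fit$lambda),
               bic = as.list(fit$bic),
               converged = if (is_zip) as.list(fit$converged) else NULL,
               all_zero = as.list(fit$all_zero),
               version = as.character(utils::packageVersion("ziparnet")),
               seed = seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a serialized fit directory
#'
#' @param dir a directory written by [write_fit()].
#' @return list of coefficient matrices and the metadata.
#' @export
read_fit <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    as.matrix(utils::read.table(p, header = TRUE, sep = "\t",
                                row.names = 1, check.names = FALSE))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  list(B = rd("B.tsv"), C = rd("C.tsv"), A = rd("A.tsv"),
       pi = rd("pi.tsv"), phi = rd("phi.tsv"), sigma = rd("sigma.tsv"),
       meta = meta)
}
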