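#' Longitudinal absolute-abundance panels
#'
#' A longitudinal panel holds absolute abundances \eqn{Y_{imt}} for subjects
#' \eqn{i = 1..n}, taxa \eqn{m = 1..M} and integer time indices
#' \eqn{t = 0, 1, 2, \ldots} in tidy long format (one row per
#' subject/time/taxon). Time 0 is the baseline observation used as the lag
#' and projection anchor; the autoregressive model treats times
#' \eqn{t \ge 1} as responses.
#'
#' @param data a data.frame with columns \code{subject}, \code{time},
#'   \code{taxon}, \code{count} and optionally \code{group}.
#' @return an object of class \code{longitudinal_panel}: the validated
#'   data.frame with attributes \code{subjects} and \code{taxa} (both in
#'   lexicographic order) and \code{has_group}.
#'
#' @details Validation enforces: non-negative abundances, unique
#'   (subject, time, taxon) triples, at least two time points per subject
#'   (an AR(1) model needs one transition), and unit-spaced integer time
#'   indices within subject. Irregularly spaced series are rejected with an
#'   error rather than silently modeled; abundances may be non-integer
#'   (qPCR-scaled values) and are only rounded at model-fitting time.
#' @export
longitudinal_panel <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("subject", "time", "taxon", "count")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("panel has no rows", call. = FALSE)
  data$subject <- as.character(data$subject)
  data$taxon <- as.character(data$taxon)
  data$time <- as.integer(data$time)
  data$count <- as.numeric(data$count)
  if (anyNA(data$time) || anyNA(data$count)) {
    stop("panel contains missing time or count values", call. = FALSE)
  }
  if (any(data$count < 0)) {
    stop("negative abundance found; counts must be >= 0", call. = FALSE)
  }
  if (any(data$time < 0)) {
    stop("negative time index found", call. = FALSE)
  }
  key <- paste(data$subject, data$time, data$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, time, taxon) triples in panel", call. = FALSE)
  }
  has_group <- "group" %in% names(data)
  if (has_group) data$group <- as.character(data$group)

  # per-subject time structure: >= 2 points, unit-spaced integers
  by_subj <- split(data$time, data$subject)
  for (s in names(by_subj)) {
    tt <- sort(unique(by_subj[[s]]))
    if (length(tt) < 2L) {
      stop("subject '", s, "' has fewer than 2 time points", call. = FALSE)
    }
    if (any(diff(tt) != 1L)) {
      stop("subject '", s, "' has irregularly spaced time indices; ",
           "the model assumes equally spaced unit steps", call. = FALSE)
    }
  }

  keep <- c(required, if (has_group) "group")
  data <- data[order(data$subject, data$time, data$taxon), keep,
               drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            subjects = sort(unique(data$subject)),
            taxa = sort(unique(data$taxon)),
            has_group = has_group,
            class = c("longitudinal_panel", "data.frame"))
}

#' @export
print.longitudinal_panel <- function(x, ...) {
  cat("Longitudinal abundance panel\n")
  cat(sprintf("  subjects: %d   taxa: %d   records: %d\n",
              length(attr(x, "subjects")), length(attr(x, "taxa")),
              nrow(x)))
  tt <- tapply(x$time, x$subject, function(v) length(unique(v)))
  cat(sprintf("  time points per subject: %d-%d\n", min(tt), max(tt)))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$count == 0)))
  invisible(x)
}

#' Read a long-format abundance table
#'
#' Reads a delimited text file with header columns \code{subject},
#' \code{time}, \code{taxon}, \code{count} and optionally \code{group},
#' and returns a validated [longitudinal_panel()].
#'
#' @param path path to a delimited text file.
#' @param sep field separator (tab by default).
#' @export
read_long_counts <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  longitudinal_panel(df)
}

#' Write a panel as delimited text
#'
#' @param panel a [longitudinal_panel()].
#' @param path output path; written UTF-8 with a header line.
#' @param sep field separator.
#' @export
write_long_counts <- function(panel, path, sep = "\t") {
  stopifnot(inherits(panel, "longitudinal_panel"))
  utils::write.table(as.data.frame(panel), path, sep = sep,
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a wide abundance matrix to a panel
#'
#' Convenience converter for one-subject-per-matrix input: each matrix has
#' rows = time points (0, 1, ...) and columns = taxa.
#'
#' @param mats named list of numeric matrices, one per subject, with taxon
#'   column names shared across subjects.
#' @param group optional named character vector of group labels per subject.
#' @export
panel_from_matrices <- function(mats, group = NULL) {
  stopifnot(is.list(mats), length(mats) > 0L, !is.null(names(mats)))
  rows <- lapply(names(mats), function(s) {
    m <- mats[[s]]
    stopifnot(is.matrix(m), !is.null(colnames(m)))
    df <- data.frame(subject = s,
                     time = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
                     taxon = rep(colnames(m), each = nrow(m)),
                     count = as.vector(m),
                     stringsAsFactors = FALSE)
    if (!is.null(group)) df$group <- unname(group[s])
    df
  })
  longitudinal_panel(do.call(rbind, rows))
}

#' Scale relative abundances to absolute abundances
#'
#' Converts a per-sample relative-abundance vector into absolute abundances
#' by multiplying by the total microbial load per gram (e.g. a qPCR
#' measurement of universal 16S rRNA copies) and the sample density in
#' g/cm^3, so the output sums to \code{load * density}.
#'
#' @param rel_abund numeric vector of relative abundances in [0, 1] summing
#'   to 1 (tolerance 1e-6).
#' @param total_load_per_gram positive total load per gram of sample.
#' @param density_g_per_cm3 positive sample density (default 1.1).
#' @return numeric vector of absolute abundances.
#' @export
absolute_from_relative <- function(rel_abund, total_load_per_gram,
                                   density_g_per_cm3 = 1.1) {
  if (!is.numeric(rel_abund) || any(rel_abund < 0) || any(rel_abund > 1)) {
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(rel_abund) - 1) > 1e-6) {
    stop("relative abundances must sum to 1 (got ",
         format(sum(rel_abund)), ")", call. = FALSE)
  }
  if (total_load_per_gram <= 0 || density_g_per_cm3 <= 0) {
    stop("total load and density must be positive", call. = FALSE)
  }
  rel_abund * total_load_per_gram * density_g_per_cm3
}

#' Filter rare and sparsely observed taxa
#'
#' Removes taxa whose mean relative abundance over all samples falls below
#' \code{min_mean_rel_abund}, or that are present (abundance > 0) in fewer
#' than \code{min_prevalence_samples} samples. When the panel carries a
#' \code{group} column both rules are applied within each group and a taxon
#' is dropped if it fails in any group; otherwise they apply globally.
#'
#' @param panel a [longitudinal_panel()].
#' @param min_mean_rel_abund minimum mean relative abundance (default 0.001,
#'   i.e. 0.1\%).
#' @param min_prevalence_samples minimum number of samples with nonzero
#'   abundance (default 5).
#' @return list with elements \code{panel} (filtered) and \code{removed}
#'   (character vector of removed taxon ids).
#' @export
filter_taxa <- function(panel, min_mean_rel_abund = 0.001,
                        min_prevalence_samples = 5) {
  stopifnot(inherits(panel, "longitudinal_panel"))
  df <- as.data.frame(panel)
  sample_id <- paste(df$subject, df$time, sep = "\r")
  totals <- tapply(df$count, sample_id, sum)
  rel <- df$count / pmax(as.numeric(totals[sample_id]), .Machine$double.eps)
  grp <- if (isTRUE(attr(panel, "has_group"))) df$group else rep("all", nrow(df))

  fails <- character(0)
  for (g in unique(grp)) {
    in_g <- grp == g
    mean_rel <- tapply(rel[in_g], df$taxon[in_g], mean)
    prev <- tapply(df$count[in_g] > 0, df$taxon[in_g], sum)
    bad <- names(mean_rel)[mean_rel < min_mean_rel_abund |
                             prev < min_prevalence_samples]
    fails <- union(fails, bad)
  }
  keep <- !(df$taxon %in% fails)
  if (!any(keep)) stop("all taxa removed by filtering: empty panel",
                       call. = FALSE)
  list(panel = longitudinal_panel(df[keep, , drop = FALSE]),
       removed = sort(fails))
}

#' Read a per-subject covariate table
#'
#' One row per subject; a \code{subject} column plus numeric covariates.
#' Missing values are rejected rather than imputed.
#'
#' @param path delimited text file.
#' @param sep field separator.
#' @export
read_covariates <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_covariates(df)
}

validate_covariates <- function(df, subjects = NULL) {
  if (!"subject" %in% names(df)) {
    stop("covariate table needs a 'subject' column", call. = FALSE)
  }
  df$subject <- as.character(df$subject)
  if (anyDuplicated(df$subject)) {
    stop("covariate table has duplicated subjects", call. = FALSE)
  }
  num_cols <- setdiff(names(df), "subject")
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      stop("covariate '", cc, "' is not numeric", call. = FALSE)
    }
  }
  if (anyNA(df)) stop("covariate table contains missing values; ",
                      "refusing to impute", call. = FALSE)
  if (!is.null(subjects)) {
    absent <- setdiff(subjects, df$subject)
    if (length(absent) > 0L) {
      stop("covariates missing for subject(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  df
}
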