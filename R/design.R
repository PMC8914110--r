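#' Build the lagged autoregressive design from a panel
#'
#' Transforms a longitudinal panel into the regression layout of the
#' log-linear AR(1) model: for every subject and every time \eqn{t \ge 1}
#' the response is the abundance vector at \eqn{t} and the predictors are
#' the log-transformed abundances \eqn{\tilde Y_{i(t-1)} = \log(Y_{i(t-1)} +
#' c)} at the previous time, with the subject's anchor-time log abundance
#' kept separately for the baseline (Chamberlain-type) projection term.
#'
#' @param panel a [longitudinal_panel()].
#' @param pseudo_count positive constant added before the log transform
#'   (default 1), so zero counts map to a zero predictor.
#' @param anchor_time time index used as the projection anchor; default is
#'   each subject's first observed time.
#' @return a list with components \code{y} (N x M response matrix over the
#'   N transition rows), \code{lag} (N x M lagged log-abundance matrix),
#'   \code{y0log} (n x M anchor log abundances), \code{subj} (integer
#'   subject index per row), \code{time}, \code{subjects}, \code{taxa}.
#' @export
lagged_design <- function(panel, pseudo_count = 1, anchor_time = NULL) {
  stopifnot(inherits(panel, "longitudinal_panel"), pseudo_count > 0)
  taxa <- attr(panel, "taxa")
  subjects <- attr(panel, "subjects")
  M <- length(taxa)
  df <- as.data.frame(panel)

  y_list <- list(); lag_list <- list(); subj_idx <- integer(0)
  time_idx <- integer(0)
  y0log <- matrix(0, length(subjects), M,
                  dimnames = list(subjects, taxa))
  kept <- logical(length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    d <- df[df$subject == s, , drop = FALSE]
    tt <- sort(unique(d$time))
    if (length(tt) < 2L) {
      warning("subject '", s, "' has a single time point; excluded")
      next
    }
    kept[si] <- TRUE
    # wide matrix, absent (time, taxon) cells treated as zero abundance
    Y <- matrix(0, length(tt), M, dimnames = list(tt, taxa))
    Y[cbind(match(d$time, tt), match(d$taxon, taxa))] <- d$count
    anchor <- if (is.null(anchor_time)) tt[1] else anchor_time
    if (!anchor %in% tt) {
      stop("anchor time ", anchor, " not observed for subject '", s, "'",
           call. = FALSE)
    }
    y0log[si, ] <- log(Y[match(anchor, tt), ] + pseudo_count)
    y_list[[length(y_list) + 1L]] <- Y[-1L, , drop = FALSE]
    lag_list[[length(lag_list) + 1L]] <-
      log(Y[-nrow(Y), , drop = FALSE] + pseudo_count)
    subj_idx <- c(subj_idx, rep(si, length(tt) - 1L))
    time_idx <- c(time_idx, tt[-1L])
  }
  if (!any(kept)) stop("no subject has two or more time points",
                       call. = FALSE)
  list(y = do.call(rbind, y_list),
       lag = do.call(rbind, lag_list),
       y0log = y0log,
       subj = subj_idx,
       time = time_idx,
       subjects = subjects,
       taxa = taxa,
       pseudo_count = pseudo_count)
}

# Per-subject covariate design matrices for the zero (W) and AR (Z) parts.
# Returns n x l / n x q matrices WITHOUT the intercept column; intercepts
# are handled by the fitters.
covariate_design <- function(covariates, subjects, zero_cols = NULL,
                             ar_cols = NULL) {
  if (is.null(covariates)) {
    return(list(W = matrix(0, length(subjects), 0),
                Z = matrix(0, length(subjects), 0)))
  }
  covariates <- validate_covariates(covariates, subjects)
  rows <- match(subjects, covariates$subject)
  pick <- function(cols) {
    if (is.null(cols)) cols <- setdiff(names(covariates), "subject")
    missing_c <- setdiff(cols, names(covariates))
    if (length(missing_c) > 0L) {
      stop("unknown covariate column(s): ", paste(missing_c, collapse = ", "),
           call. = FALSE)
    }
    as.matrix(covariates[rows, cols, drop = FALSE])
  }
  list(W = pick(zero_cols), Z = pick(ar_cols))
}

# deterministic substream seed below 2^31, derived from a master seed and a
# stream index so replicate order / parallel layout never changes results
derive_seed <- function(seed, k) {
  ((as.double(seed) %% 65011) * 33029 + as.double(k) * 2663 + 1) %% 2147483647
}
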