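#' Penalized Poisson autoregression baseline
#'
#' Per-taxon l1-penalized log-link Poisson regression of the abundance at
#' time t on the lagged log abundances of all taxa and time-independent
#' covariates — no zero-inflation and no random effects. The penalty is
#' tuned per taxon by BIC over a glmnet path unless fixed.
#'
#' @inheritParams fit_zipar
#' @param lambda \code{NULL} for BIC tuning, or a fixed penalty (scalar or
#'   length-M; 0 means unpenalized, solved by IRLS).
#' @return an object of class \code{baseline_fit} with \code{method_tag
#'   "poisson"}: interaction matrix \code{B}, covariate matrix \code{C}
#'   (first column the intercept), per-taxon BIC and selected penalty.
#' @export
fit_poisson_ar <- function(panel, covariates = NULL, ar_cols = NULL,
                           lambda = NULL, control = zipar_control()) {
  des <- lagged_design(panel, control$pseudo_count, control$anchor_time)
  cov_des <- covariate_design(covariates, des$subjects, NULL, ar_cols)
  fit_baseline_design(des, cov_des, lambda, control, method = "poisson")
}

#' Penalized log-normal multivariate autoregression baseline
#'
#' Per-taxon l1-penalized linear (Gaussian) regression of the
#' log-transformed abundance \eqn{\log(Y_{imt}+1)} on the lagged log
#' abundances and covariates — the classical MAR(1) community model fit on
#' the log scale. Residual variance is estimated on the selected support by
#' the unbiased estimator.
#'
#' @inheritParams fit_poisson_ar
#' @return a \code{baseline_fit} with \code{method_tag "mar"} and per-taxon
#'   \code{residual_scale} (residual standard deviation on the log scale).
#' @export
fit_mar <- function(panel, covariates = NULL, ar_cols = NULL,
                    lambda = NULL, control = zipar_control()) {
  des <- lagged_design(panel, control$pseudo_count, control$anchor_time)
  cov_des <- covariate_design(covariates, des$subjects, NULL, ar_cols)
  fit_baseline_design(des, cov_des, lambda, control, method = "mar")
}

fit_baseline_design <- function(des, cov_des, lambda, control, method) {
  taxa <- des$taxa; M <- length(taxa)
  N <- nrow(des$y)
  Z <- cov_des$Z; q <- ncol(Z)
  Zrow <- if (q > 0) Z[des$subj, , drop = FALSE] else NULL
  if (!is.null(lambda)) lambda <- rep_len(lambda, M)

  B <- matrix(0, M, M, dimnames = list(taxa, taxa))
  C <- matrix(0, M, q + 1,
              dimnames = list(taxa, c("(Intercept)", colnames(Z))))
  residual_scale <- stats::setNames(rep(NA_real_, M), taxa)
  lambda_sel <- stats::setNames(rep(NA_real_, M), taxa)
  bic <- stats::setNames(numeric(M), taxa)
  all_zero <- stats::setNames(rep(FALSE, M), taxa)

  for (m in seq_len(M)) {
    if (method == "poisson") {
      y_m <- des$y[, m]
    } else {
      y_m <- log(des$y[, m] + des$pseudo_count)
    }
    if (all(des$y[, m] == 0)) {
      all_zero[m] <- TRUE
      if (method == "mar") residual_scale[m] <- 0
      next
    }
    lag_cols <- if (control$include_self) seq_len(M) else
      setdiff(seq_len(M), m)
    X <- cbind(des$lag[, lag_cols, drop = FALSE], Zrow)
    pf <- rep(1, ncol(X))
    res <- fit_baseline_taxon(y_m, X, pf, method, control,
                              lambda_fixed = if (is.null(lambda)) NULL
                              else lambda[m])
    B[m, lag_cols] <- res$beta[seq_along(lag_cols)]
    C[m, 1] <- res$a0
    if (q > 0) C[m, -1] <- res$beta[length(lag_cols) + seq_len(q)]
    lambda_sel[m] <- res$lambda
    bic[m] <- res$bic
    if (method == "mar") residual_scale[m] <- res$residual_scale
  }

  structure(list(taxa = taxa, subjects = des$subjects,
                 B = B, C = C, intercepts = C[, 1],
                 residual_scale = residual_scale,
                 method_tag = method, lambda = lambda_sel, bic = bic,
                 all_zero = all_zero, design = des,
                 Zrow = Zrow, control = control),
            class = "baseline_fit")
}

fit_baseline_taxon <- function(y, X, pf, method, control, lambda_fixed) {
  N <- length(y)
  fam <- if (method == "poisson") "poisson" else "gaussian"
  if (!is.null(lambda_fixed) && lambda_fixed == 0) {
    if (method == "poisson") {
      f0 <- irls_poisson(X, y, rep(1, N), numeric(N))
      a0 <- f0$a0; beta <- f0$beta
    } else {
      Xi <- cbind(1, X)
      cf <- drop(solve(crossprod(Xi) + diag(1e-10, ncol(Xi)),
                       crossprod(Xi, y)))
      a0 <- cf[1L]; beta <- cf[-1L]
    }
    k <- 1L + sum(beta != 0)
    return(c(baseline_gof(y, X, a0, beta, method, k, N),
             list(a0 = a0, beta = beta, lambda = 0)))
  }
  gfit <- tryCatch(
    suppressWarnings(
      glmnet::glmnet(X, y, family = fam, penalty.factor = pf,
                   lambda = if (!is.null(lambda_fixed))
                     lambda_fixed * c(8, 4, 2, 1) else NULL,
                   nlambda = control$nlambda,
                   lambda.min.ratio = control$lambda_min_ratio,
                   standardize = FALSE, thresh = 1e-10)),
    error = function(e) NULL)
  if (is.null(gfit)) {
    a0 <- if (method == "poisson") log(max(mean(y), 1e-8)) else mean(y)
    beta <- numeric(ncol(X))
    return(c(baseline_gof(y, X, a0, beta, method, 1L, N),
             list(a0 = a0, beta = beta, lambda = Inf)))
  }
  if (!is.null(lambda_fixed)) {
    j <- length(gfit$lambda)
  } else {
    ks <- 1L + apply(gfit$beta != 0, 2, sum)
    bics <- vapply(seq_along(gfit$lambda), function(jj) {
      a0j <- as.numeric(gfit$a0[jj]); bj <- as.numeric(gfit$beta[, jj])
      baseline_gof(y, X, a0j, bj, method, ks[jj], N)$bic
    }, numeric(1))
    cand <- which(bics <= min(bics) + 1e-9)
    j <- cand[which.max(gfit$lambda[cand])]
  }
  a0 <- as.numeric(gfit$a0[j]); beta <- as.numeric(gfit$beta[, j])
  if (control$relax) {
    sel <- which(beta != 0)
    Xs <- X[, sel, drop = FALSE]
    ref <- tryCatch({
      if (method == "poisson") {
        irls_poisson(Xs, y, rep(1, N), numeric(N))
      } else {
        Xi <- cbind(1, Xs)
        cf <- drop(solve(crossprod(Xi) + diag(1e-10, ncol(Xi)),
                         crossprod(Xi, y)))
        list(a0 = cf[1L], beta = cf[-1L])
      }
    }, error = function(e) NULL)
    if (!is.null(ref) && all(is.finite(c(ref$a0, ref$beta)))) {
      a0 <- ref$a0
      beta[] <- 0
      if (length(sel)) beta[sel] <- ref$beta
    }
  }
  c(baseline_gof(y, X, a0, beta, method, 1L + sum(beta != 0), N),
    list(a0 = a0, beta = beta, lambda = gfit$lambda[j]))
}

baseline_gof <- function(y, X, a0, beta, method, k, N) {
  eta <- a0 + drop(X %*% beta)
  if (method == "poisson") {
    mu <- exp(pmin(eta, 300))
    cg <- if (all(abs(y - round(y)) < 1e-8)) lgamma(y + 1) else 0
    ll <- sum(y * pmin(eta, 300) - mu - cg)
    list(bic = -2 * ll + k * log(N), residual_scale = NA_real_)
  } else {
    rss <- sum((y - eta)^2)
    s2 <- rss / N
    ll <- -N / 2 * (log(2 * pi * max(s2, 1e-300)) + 1)
    list(bic = -2 * ll + (k + 1) * log(N),
         residual_scale = sqrt(rss / max(N - k, 1)))
  }
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Penalized %s autoregression baseline\n",
              if (x$method_tag == "mar") "log-normal (MAR)" else "Poisson"))
  cat(sprintf("  taxa: %d   subjects: %d   nonzero interactions: %d\n",
              length(x$taxa), length(x$subjects), sum(x$B != 0)))
  invisible(x)
}

#' Fitted moments for a baseline fit
#'
#' For the Poisson baseline, mean \eqn{\mu} and variance \eqn{\mu} (plain
#' Poisson, no dispersion scaling). For the MAR baseline the fitted normal
#' model on \eqn{\log(Y+c)} is mapped back to the count scale either by
#' the plugin back-transform \eqn{\hat y = e^{\hat m} - c} scored with the
#' Poisson-type variance \eqn{\hat\sigma^2 = \hat y} (default; the common
#' yardstick across the count models), or by the log-normal mean/variance
#' formulas (\code{backtransform = "lognormal"}); the log-scale moments
#' are returned alongside.
#'
#' @param fit a \code{baseline_fit}.
#' @param backtransform count-scale mapping for the MAR baseline.
#' @param ... unused.
#' @export
fitted_moments.baseline_fit <- function(fit,
                                        backtransform = c("plugin",
                                                          "lognormal"),
                                        ...) {
  backtransform <- match.arg(backtransform)
  des <- fit$design
  M <- length(fit$taxa)
  q <- ncol(fit$C) - 1L
  eta <- des$lag %*% t(fit$B)
  if (q > 0) eta <- eta + fit$Zrow %*% t(fit$C[, -1, drop = FALSE])
  eta <- sweep(eta, 2, -fit$C[, 1])
  if (fit$method_tag == "poisson") {
    mu <- exp(pmin(eta, 300))
    mu[, fit$all_zero] <- 0
    list(mean = mu, sd = sqrt(mu), observed = des$y)
  } else {
    s2 <- matrix(rep(fit$residual_scale^2, each = nrow(eta)), nrow(eta), M)
    mean_log <- pmin(eta, 300)
    if (backtransform == "plugin") {
      mean_ct <- pmax(exp(mean_log) - des$pseudo_count, 0)
      var_ct <- pmax(mean_ct, 1)  # at least one organism of spread
    } else {
      mean_ct <- exp(mean_log + s2 / 2) - des$pseudo_count
      var_ct <- (exp(s2) - 1) * exp(2 * mean_log + s2)
    }
    mean_ct[, fit$all_zero] <- 0
    var_ct[, fit$all_zero] <- 0
    list(mean = mean_ct, sd = sqrt(var_ct), observed = des$y,
         mean_log = mean_log,
         sd_log = sqrt(s2), observed_log = log(des$y + des$pseudo_count))
  }
}
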