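#' Control parameters for the zero-inflated Poisson AR fitter
#'
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change between EM iterations.
#' @param max_em_iter maximum number of EM iterations per taxon.
#' @param pseudo_count constant added inside the log transform of lagged
#'   abundances.
#' @param dispersion \code{"quasi_poisson"} estimates a per-taxon dispersion
#'   from Pearson residuals (floored at 1); \code{"poisson"} fixes it at 1.
#' @param nlambda,lambda_min_ratio shape of the automatic penalty path used
#'   for BIC tuning (passed to \code{glmnet}).
#' @param lambda_grid optional shared penalty grid (decreasing) used for all
#'   taxa instead of the automatic per-taxon path.
#' @param penalty_zero l1 penalty weight for zero-part covariate
#'   coefficients (the zero-part intercept is never penalized).
#' @param random_effects \code{"auto"} estimates the AR-part
#'   random-intercept variance by profile Laplace likelihood; \code{"none"}
#'   fixes it at zero (no heterogeneity).
#' @param zero_random_effect include a subject random intercept in the
#'   structural-zero logistic part (default FALSE: the zero probability is
#'   population-level given covariates; a subject-level intercept makes the
#'   per-subject zero probabilities saturate towards 0/1, which changes the
#'   meaning of the fitted mixture moments).
#' @param var_floor,var_ceiling bounds for the random-intercept variances;
#'   a variance at the floor is treated as exactly zero. The ceiling
#'   (default 1, a log-scale SD of 1, i.e. subject means varying by a
#'   factor of ~7 at 2 SD) is an identifiability constraint: without it
#'   the AR random intercept can drive a subject's fitted mean to zero
#'   and impersonate structural absence, which belongs to the logistic
#'   part.
#' @param relax debias the selected coefficients by an unpenalized refit
#'   on the BIC-selected support (relaxed lasso, default TRUE). Selection
#'   is unchanged; predictions lose the shrinkage bias, which otherwise
#'   dominates the squared standardized residuals of strong interactions.
#' @param include_self keep the response taxon's own lagged abundance as a
#'   predictor (the diagonal of B). Default FALSE: with it free, a
#'   zero-naive autoregression can memorize subject-constant zero runs
#'   through self-excitation instead of modeling cross-taxon dynamics, and
#'   estimated interaction networks are self-loop free.
#' @param anchor_time baseline time index for the projection term; default
#'   is each subject's first observation.
#' @param exact_marginal if TRUE (default) the reported log-likelihood and
#'   BIC use the full two-dimensional Laplace-approximate marginal; if
#'   FALSE the cheaper conditional approximation used during tuning.
#' @export
zipar_control <- function(tol = 1e-4, max_em_iter = 200, pseudo_count = 1,
                          dispersion = c("quasi_poisson", "poisson"),
                          nlambda = 20, lambda_min_ratio = 0.01,
                          lambda_grid = NULL, penalty_zero = 0,
                          random_effects = c("auto", "none"),
                          zero_random_effect = FALSE,
                          var_floor = 1e-8, var_ceiling = 1,
                          include_self = FALSE, relax = TRUE,
                          anchor_time = NULL, exact_marginal = TRUE) {
  stopifnot(tol > 0, max_em_iter >= 1, pseudo_count > 0, penalty_zero >= 0,
            var_floor > 0, var_ceiling > var_floor)
  list(tol = tol, max_em_iter = max_em_iter, pseudo_count = pseudo_count,
       dispersion = match.arg(dispersion), nlambda = nlambda,
       lambda_min_ratio = lambda_min_ratio, lambda_grid = lambda_grid,
       penalty_zero = penalty_zero,
       random_effects = match.arg(random_effects),
       zero_random_effect = isTRUE(zero_random_effect),
       var_floor = var_floor, var_ceiling = var_ceiling,
       include_self = isTRUE(include_self), relax = isTRUE(relax),
       anchor_time = anchor_time, exact_marginal = exact_marginal)
}

#' Conditional zero-inflated Poisson log-likelihood
#'
#' Log-likelihood of observations under the two-part mixture at fixed
#' linear predictors: a zero has density \eqn{p + (1-p) e^{-\mu}}, a
#' positive count has density \eqn{(1-p) \, \mathrm{Pois}(y; \mu)}. For
#' non-integer abundances the factorial term is dropped (continuous
#' quasi-likelihood); for integer counts the exact Poisson mass is used.
#'
#' @param y non-negative responses.
#' @param eta linear predictor, \eqn{\mu = e^{\eta}}.
#' @param p structural-zero probabilities in [0, 1] (scalar or vector).
#' @return the summed log-likelihood.
#' @export
zip_loglik <- function(y, eta, p = 0) {
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor in zip_loglik; parameters: ",
         "range(eta) = ", paste(range(eta), collapse = ", "), call. = FALSE)
  }
  p <- rep_len(p, length(y))
  mu <- exp(eta)
  is0 <- y == 0
  ll <- numeric(length(y))
  ll[is0] <- log(p[is0] + (1 - p[is0]) * exp(-mu[is0]))
  if (any(!is0)) {
    yp <- y[!is0]
    cg <- if (all(abs(yp - round(yp)) < 1e-8)) lgamma(yp + 1) else 0
    ll[!is0] <- log1p(-p[!is0]) + yp * eta[!is0] - mu[!is0] - cg
  }
  sum(ll)
}

#' Objective combining fit and l1 penalties
#'
#' \eqn{Q = -2 \log L + \sum_m ( \mu_{1m} \|D_m\|_1 + \mu_{2m} \|A_m\|_1 )},
#' the quantity monitored for EM convergence.
#'
#' @param loglik log-likelihood value.
#' @param D matrix (or vector) of autoregressive-part coefficients subject
#'   to penalty \code{mu1} (per row when a matrix).
#' @param A matrix (or vector) of zero-part coefficients subject to
#'   penalty \code{mu2}.
#' @param mu1,mu2 non-negative penalty weights (scalar or per-row).
#' @export
penalized_objective <- function(loglik, D = NULL, A = NULL, mu1 = 0,
                                mu2 = 0) {
  pen <- 0
  l1_rows <- function(x) {
    if (is.null(x)) return(0)
    x <- as.matrix(x)
    rowSums(abs(x))
  }
  if (!is.null(D)) pen <- pen + sum(rep_len(mu1, nrow(as.matrix(D))) *
                                      l1_rows(D))
  if (!is.null(A)) pen <- pen + sum(rep_len(mu2, nrow(as.matrix(A))) *
                                      l1_rows(A))
  -2 * loglik + pen
}

#' Quasi-Poisson dispersion estimate
#'
#' Pearson chi-square over residual degrees of freedom, computed on
#' observations weighted by their probability of not being a structural
#' zero, and floored at 1 so the variance model never deflates below
#' Poisson.
#'
#' @param y responses.
#' @param mu fitted means.
#' @param weights non-structural-zero weights (1 - E-step responsibility).
#' @param k number of estimated mean parameters.
#' @export
estimate_dispersion <- function(y, mu, weights = 1, k = 1) {
  w <- rep_len(weights, length(y))
  df <- sum(w) - k
  if (df <= 0) {
    warning("non-positive residual degrees of freedom; dispersion set to 1")
    return(1)
  }
  x2 <- sum(w * (y - mu)^2 / pmax(mu, .Machine$double.eps))
  max(x2 / df, 1)
}

#' Laplace-approximate marginal log-likelihood for one taxon
#'
#' Integrates the subject-level random intercepts of the zero part
#' (\code{sigma_a}) and the autoregressive part (\code{sigma_b}) out of the
#' conditional mixture likelihood by a per-subject Laplace approximation:
#' an inner quasi-Newton search finds the joint mode of the random effects
#' and a log-determinant curvature correction accounts for their posterior
#' spread. Variances at or below \code{var_floor} are treated as exactly
#' zero, so with both variances at zero the function returns the plain
#' conditional log-likelihood at zero random effects.
#'
#' The structural-zero state is time-independent, so the mixture acts at
#' the subject level: an all-zero subject contributes
#' \eqn{p + (1-p) e^{-\sum_t \mu_t}} and a subject with any positive count
#' contributes \eqn{(1-p) \prod_t \mathrm{Pois}(y_t; \mu_t)}.
#'
#' @param y responses over all transition rows of the taxon.
#' @param eta fixed-effect linear predictor per row (log mean without the
#'   random intercept).
#' @param subj integer subject index per row (1..n).
#' @param sigma_a,sigma_b random-intercept variances.
#' @param alpha_eta per-subject fixed-effect logit of the structural-zero
#'   probability (scalar or length-n); \code{-Inf} means no zero inflation.
#' @param n number of subjects.
#' @param init optional n x 2 matrix of starting values for the modes.
#' @param var_floor variances below this are fixed at zero.
#' @return list with \code{loglik}, per-subject \code{modes} (n x 2), and
#'   per-subject contributions \code{by_subject}.
#' @export
laplace_marginal <- function(y, eta, subj, sigma_a = 0, sigma_b = 0,
                             alpha_eta = -Inf, n = max(subj), init = NULL,
                             var_floor = 1e-8) {
  stopifnot(length(y) == length(eta), length(subj) == length(y))
  alpha_eta <- rep_len(alpha_eta, n)
  act_a <- sigma_a > var_floor
  act_b <- sigma_b > var_floor
  modes <- matrix(0, n, 2, dimnames = list(NULL, c("a", "b")))
  if (!is.null(init)) {
    modes <- as.matrix(init)
    dimnames(modes) <- list(NULL, c("a", "b"))
  }

  az <- as.vector(rowsum(y, subj, reorder = TRUE)) == 0  # all-zero subjects
  p_subj <- stats::plogis(alpha_eta)

  cond_ll <- function(i, a, b) {
    r <- subj == i
    p <- stats::plogis(alpha_eta[i] + a)
    mu <- exp(pmin(eta[r] + b, 300))
    if (az[i]) {
      log(p + (1 - p) * exp(-sum(mu)))
    } else {
      yp <- y[r]
      cg <- if (all(abs(yp - round(yp)) < 1e-8)) lgamma(yp + 1) else
        numeric(length(yp))
      log1p(-min(p, 1 - 1e-12)) +
        sum(yp * (eta[r] + b) - mu - cg)
    }
  }
  by_subject <- numeric(n)

  if (!act_a && act_b) {
    # fast path: only the AR-part intercept is active; vectorised damped
    # Newton on the subject-level mixture likelihood
    b <- modes[, "b"]
    for (it in 1:60) {
      mu <- exp(pmin(eta + b[subj], 300))
      s_mu <- as.vector(rowsum(mu, subj, reorder = TRUE))
      zeta <- ifelse(az, p_subj / (p_subj + (1 - p_subj) * exp(-s_mu)), 0)
      s_y <- as.vector(rowsum(y, subj, reorder = TRUE))
      g <- s_y - (1 - zeta) * s_mu - b / sigma_b
      h <- pmax((1 - zeta) * s_mu * ifelse(az, pmax(1 - zeta * s_mu, 0.05),
                                           1), 1e-8) + 1 / sigma_b
      step <- pmin(pmax(g / h, -1), 1)
      b <- b + step
      if (max(abs(step)) < 1e-9) break
    }
    mu <- exp(pmin(eta + b[subj], 300))
    s_mu <- as.vector(rowsum(mu, subj, reorder = TRUE))
    zeta <- ifelse(az, p_subj / (p_subj + (1 - p_subj) * exp(-s_mu)), 0)
    h <- pmax((1 - zeta) * s_mu * ifelse(az, pmax(1 - zeta * s_mu, 0.05),
                                         1), 1e-8) + 1 / sigma_b
    cg <- if (all(abs(y - round(y)) < 1e-8)) lgamma(y + 1) else
      numeric(length(y))
    pois_rows <- y * (eta + b[subj]) - mu - cg
    s_pois <- as.vector(rowsum(pois_rows, subj, reorder = TRUE))
    ll_subj <- ifelse(az,
                      log(p_subj + (1 - p_subj) * exp(-s_mu)),
                      log1p(-pmin(p_subj, 1 - 1e-12)) + s_pois)
    by_subject <- ll_subj - b^2 / (2 * sigma_b) -
      0.5 * log(pmax(sigma_b * h, 1e-300))
    modes[, "b"] <- b
    return(list(loglik = sum(by_subject), modes = modes,
                by_subject = by_subject))
  }

  for (i in seq_len(n)) {
    if (!act_a && !act_b) {
      by_subject[i] <- cond_ll(i, 0, 0)
      next
    }
    free <- c(act_a, act_b)
    obj <- function(u) {
      a <- if (act_a) u[[1L]] else 0
      b <- if (act_b) u[[length(u)]] else 0
      -(cond_ll(i, a, b) -
          (if (act_a) a^2 / (2 * sigma_a) else 0) -
          (if (act_b) b^2 / (2 * sigma_b) else 0))
    }
    start <- modes[i, free]
    opt <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    if (opt$convergence != 0) {
      opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead")
      if (opt2$value < opt$value) opt <- opt2
    }
    u <- opt$par
    modes[i, free] <- u
    H <- stats::optimHess(u, obj)
    S <- diag(c(if (act_a) sigma_a else NULL,
                if (act_b) sigma_b else NULL), nrow = sum(free))
    det_sh <- det(S %*% H)
    if (!is.finite(det_sh) || det_sh <= 0) det_sh <- 1
    by_subject[i] <- -opt$value - 0.5 * log(det_sh)
  }
  list(loglik = sum(by_subject), modes = modes, by_subject = by_subject)
}

# ---- internal per-taxon EM machinery -------------------------------------

# vectorised Newton for the AR-part random-intercept modes: maximises
# sum_t w_t (y_t * (eta_t + b) - exp(eta_t + b)) - b^2 / (2 sigma2) per
# subject. Concave in b; damped Newton with step cap.
newton_b_modes <- function(y, eta, w, subj, n, sigma2, b = numeric(n)) {
  wy <- as.vector(rowsum(w * y, subj, reorder = TRUE))
  idx <- sort(unique(subj))
  bb <- b[idx]
  for (it in 1:40) {
    s_mu <- as.vector(rowsum(w * exp(eta + bb[match(subj, idx)]), subj))
    g <- wy - s_mu - bb / sigma2
    h <- s_mu + 1 / sigma2
    step <- g / h
    step <- pmin(pmax(step, -2), 2)
    bb <- bb + step
    if (max(abs(g / h)) < 1e-10) break
  }
  b[idx] <- bb
  s_mu <- as.vector(rowsum(w * exp(eta + bb[match(subj, idx)]), subj))
  list(b = b, hess = s_mu + 1 / sigma2)
}

# vectorised Newton for the zero-part modes on aggregated Bernoulli
# pseudo-data (S successes out of TT trials per subject)
newton_a_modes <- function(S, TT, la, sigma2, a = numeric(length(S))) {
  for (it in 1:40) {
    p <- stats::plogis(la + a)
    g <- S - TT * p - a / sigma2
    h <- TT * p * (1 - p) + 1 / sigma2
    step <- pmin(pmax(g / h, -2), 2)
    a <- a + step
    if (max(abs(step)) < 1e-10) break
  }
  p <- stats::plogis(la + a)
  list(a = a, hess = TT * p * (1 - p) + 1 / sigma2)
}

# profile Laplace log-likelihood in log sigma2 for the AR part, modes
# refound at each candidate variance (weighted complete-data likelihood)
profile_sigma_b <- function(y, eta, w, subj, n, var_floor, var_ceiling,
                            b = numeric(n), lrt_keep = 2.706) {
  prof <- function(ls2) {
    s2 <- exp(ls2)
    nb <- newton_b_modes(y, eta, w, subj, n, s2, b)
    bb <- nb$b
    ll <- sum(w * (y * (eta + bb[subj]) - exp(eta + bb[subj])))
    sum_b2 <- sum(bb^2)
    ll - sum_b2 / (2 * s2) - 0.5 * sum(log(pmax(s2 * nb$hess, 1e-300)))
  }
  lo <- log(var_floor); hi <- log(var_ceiling)
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 0.02)
  # boundary safeguard: a positive variance must beat sigma2 = 0 by the
  # 5% critical value of the 0.5*chi2_0 + 0.5*chi2_1 mixture, otherwise
  # the random intercept is dropped (the profile MLE at a boundary is
  # positive with high probability even when the true variance is zero)
  if (2 * (opt$objective - prof(lo)) < lrt_keep) return(var_floor)
  exp(opt$maximum)
}

profile_sigma_a <- function(S, TT, la, var_floor, var_ceiling,
                            a = numeric(length(S)), lrt_keep = 2.706) {
  prof <- function(ls2) {
    s2 <- exp(ls2)
    na_ <- newton_a_modes(S, TT, la, s2, a)
    aa <- na_$a
    p <- stats::plogis(la + aa)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(S * log(p) + (TT - S) * log(1 - p))
    ll - sum(aa^2) / (2 * s2) - 0.5 * sum(log(pmax(s2 * na_$hess, 1e-300)))
  }
  lo <- log(var_floor); hi <- log(var_ceiling)
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 0.02)
  if (2 * (opt$objective - prof(lo)) < lrt_keep) return(var_floor)
  exp(opt$maximum)
}

# own IRLS for the unpenalized weighted log-link Poisson subproblem (used
# when the l1 penalty is exactly zero; glmnet handles all penalized cases)
irls_poisson <- function(X, y, w, offset, maxit = 100, tol = 1e-12) {
  Xi <- cbind(1, X)
  beta <- c(log(max(sum(w * y) / max(sum(w), 1e-12), 1e-8)),
            numeric(ncol(X)))
  for (it in seq_len(maxit)) {
    eta <- offset + drop(Xi %*% beta)
    mu <- exp(pmin(eta, 30))
    ww <- w * mu
    z <- eta - offset + (y - mu) / pmax(mu, 1e-12)
    fit <- tryCatch(
      solve(crossprod(Xi, Xi * ww) + diag(1e-10, ncol(Xi)),
            crossprod(Xi, ww * z)),
      error = function(e) NULL)
    if (is.null(fit)) break
    new_beta <- drop(fit)
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  list(a0 = beta[1L], beta = beta[-1L])
}

# weighted logistic IRLS on subject-aggregated responsibilities with offset
irls_binomial <- function(W, S, TT, offset, maxit = 60) {
  Wi <- cbind(1, W)
  alpha <- c(stats::qlogis(pmin(pmax(sum(S) / sum(TT), 1e-6), 1 - 1e-6)),
             numeric(ncol(W)))
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(Wi %*% alpha) + offset)
    g <- crossprod(Wi, S - TT * p)
    h <- crossprod(Wi, Wi * (TT * p * (1 - p))) + diag(1e-9, ncol(Wi))
    step <- drop(solve(h, g))
    step <- pmin(pmax(step, -4), 4)
    alpha <- alpha + step
    if (max(abs(step)) < 1e-10) break
  }
  alpha
}

# One taxon's EM fit. X carries [lagged log abundances | AR covariates |
# baseline projection column]; pf is the glmnet penalty.factor (0 for the
# projection column). W is the n x l zero-part covariate matrix without
# intercept. With force_p0 the zero part is switched off (plain penalized
# Poisson AR with random intercept), used for the per-taxon BIC comparison
# that lets the mixture collapse to Poisson when zeros carry no signal.
fit_taxon_zip <- function(y, X, pf, subj, n, W, control,
                          lambda_fixed = NULL, force_p0 = FALSE) {
  N <- length(y)
  is0 <- y == 0
  # structural absence is time-independent, so only subjects observed at
  # zero throughout can carry posterior structural-zero mass
  az_set <- sort(unique(subj))
  az_flag <- as.vector(rowsum(y, subj, reorder = TRUE)) == 0
  az <- logical(n); az[az_set] <- az_flag
  rows_az <- az[subj]
  any0 <- any(az) && !force_p0
  l <- ncol(W)
  use_re <- control$random_effects == "auto"
  floor2 <- control$var_floor

  # --- initial values ------------------------------------------------------
  # structural state is subject-level and hard: a subject observed at zero
  # throughout is structural (for any taxon abundant enough to matter,
  # P(all-zero | present) = exp(-sum mu) is negligible); its rows carry no
  # weight in the AR part, so unpenalized coefficients cannot learn to
  # separate masked from present subjects
  z <- numeric(N)
  if (any0) z[rows_az] <- 1
  w <- 1 - z
  init <- tryCatch(suppressWarnings({
    g0 <- glmnet::glmnet(X, y, family = "poisson", weights = w,
                         alpha = 0, lambda = 1 / N, standardize = FALSE)
    list(a0 = as.numeric(g0$a0), beta = as.numeric(g0$beta[, 1L]))
  }), error = function(e) NULL)
  if (is.null(init)) {
    init <- list(a0 = log(max(sum(w * y) / max(sum(w), 1), 1e-4)),
                 beta = numeric(ncol(X)))
  }
  a0 <- init$a0; beta <- init$beta
  alpha <- c(if (any0) stats::qlogis(min(max(mean(az), 1e-4), 1 - 1e-4))
             else -20, numeric(l))
  use_re_a <- use_re && control$zero_random_effect
  sigma_a <- if (any0 && use_re_a) 0.1 else floor2
  sigma_b <- if (use_re) 0.1 else floor2
  a_modes <- numeric(n); b_modes <- numeric(n)
  Wi <- cbind(1, W)

  # estimate the subject heterogeneity before any interaction enters the
  # model: on an interaction-free mean the profile likelihood sees the full
  # between-subject variation, and the resulting random-intercept offset
  # prevents subject-patterned cross-lags from absorbing it during
  # penalty selection
  if (use_re) {
    mu0 <- max(sum(w * y) / max(sum(w), 1e-8), 1e-8)
    eta0 <- rep(log(mu0), N)
    sigma_b <- profile_sigma_b(y, eta0, w, subj, n, floor2,
                               control$var_ceiling)
    if (sigma_b > floor2) {
      b_modes <- newton_b_modes(y, eta0, w, subj, n, sigma_b)$b
    }
  }

  lam_grid <- NULL
  lambda_sel <- if (!is.null(lambda_fixed)) lambda_fixed else NA_real_
  lam_locked <- !is.null(lambda_fixed)
  prev_j <- -1L
  phi_cur <- 1
  floor_runs_a <- 0L; floor_runs_b <- 0L
  q_trace <- numeric(0)
  converged <- FALSE
  k_sel <- 1L
  iter <- 0L

  for (iter in seq_len(control$max_em_iter)) {
    old_par <- c(alpha, a0, beta, sigma_a, sigma_b)

    # --- E step: subject-level structural-zero responsibilities -----------
    eta <- a0 + drop(X %*% beta) + b_modes[subj]
    if (anyNA(eta)) {
      stop("non-finite linear predictor in EM; model diverged",
           call. = FALSE)
    }
    # transient coordinate-descent overshoot is clamped, not fatal; the
    # debiased refit restores a finite fit
    eta <- pmin(eta, 30)
    p_subj <- stats::plogis(drop(Wi %*% alpha) + a_modes)
    z_subj <- as.numeric(az)

    # --- M step, zero part (one Bernoulli trial per subject) --------------
    if (any0) {
      S_full <- z_subj
      ones <- rep(1, n)
      if (control$penalty_zero > 0 && l > 0) {
        gz <- glmnet::glmnet(W, cbind(1 - S_full, S_full),
                             family = "binomial", offset = a_modes,
                             lambda = control$penalty_zero,
                             standardize = FALSE)
        alpha <- c(as.numeric(gz$a0), as.numeric(gz$beta[, 1L]))
      } else {
        alpha <- irls_binomial(W, S_full, ones, a_modes)
      }
      la <- drop(Wi %*% alpha)
      if (use_re_a && floor_runs_a < 2L && iter <= 10L) {
        sigma_a <- profile_sigma_a(S_full, ones, la, floor2,
                                   control$var_ceiling, a_modes)
        floor_runs_a <- if (sigma_a <= floor2) floor_runs_a + 1L else 0L
      }
      if (sigma_a > floor2) {
        a_modes <- newton_a_modes(S_full, ones, la, sigma_a, a_modes)$a
      } else a_modes <- numeric(n)
      p_subj <- stats::plogis(la + a_modes)
    }

    # --- M step, AR part ---------------------------------------------------
    off <- b_modes[subj]
    if (!is.null(lambda_fixed) && lambda_fixed == 0) {
      fit0 <- irls_poisson(X, y, w, off)
      a0 <- fit0$a0; beta <- fit0$beta
      lambda_sel <- 0
      k_sel <- 1L + sum(beta != 0)
    } else {
      gfit <- tryCatch(suppressWarnings({
        if (lam_locked) {
          glmnet::glmnet(X, y, family = "poisson", weights = w,
                         offset = off, penalty.factor = pf,
                         lambda = lambda_sel * c(8, 4, 2, 1),
                         standardize = FALSE, thresh = 1e-8, maxit = 300000)
        } else if (is.null(lam_grid)) {
          glmnet::glmnet(X, y, family = "poisson", weights = w,
                         offset = off, penalty.factor = pf,
                         nlambda = control$nlambda,
                         lambda.min.ratio = control$lambda_min_ratio,
                         lambda = control$lambda_grid,
                         standardize = FALSE, thresh = 1e-8, maxit = 300000)
        } else {
          glmnet::glmnet(X, y, family = "poisson", weights = w,
                         offset = off, penalty.factor = pf,
                         lambda = lam_grid, standardize = FALSE,
                         thresh = 1e-8, maxit = 300000)
        }
      }), error = function(e) NULL)
      if (is.null(gfit)) {
        # degenerate weighted data: fall back to intercept-only
        a0 <- log(max(sum(w * y) / max(sum(w), 1e-8), 1e-8))
        beta <- numeric(ncol(X))
        lambda_sel <- if (is.null(lambda_fixed)) Inf else lambda_fixed
        k_sel <- 1L
      } else if (any(!is.finite(as.numeric(gfit$beta[, ncol(gfit$beta)])))) {
        a0 <- log(max(sum(w * y) / max(sum(w), 1e-8), 1e-8))
        beta <- numeric(ncol(X))
        lambda_sel <- if (is.null(lambda_fixed)) Inf else lambda_fixed
        k_sel <- 1L
      } else {
        if (is.null(lam_grid)) lam_grid <- gfit$lambda
        if (lam_locked) {
          j <- length(gfit$lambda)
          a0 <- as.numeric(gfit$a0[j]); beta <- as.numeric(gfit$beta[, j])
          k_sel <- 1L + sum(beta != 0)
        } else {
          # BIC over the path using the conditional mixture likelihood
          eta_path <- a0_path_eta(gfit, X, off)
          ll_path <- mixture_ll_path(y, eta_path, w)
          k_path <- 1L + apply(gfit$beta != 0, 2, sum) + 2L +
            (if (any0) l + 1L else 0L)
          # dispersion-scaled (quasi-likelihood) BIC: under quasi-Poisson
          # variance phi*mu the deviance differences are inflated by phi
          bic_path <- -2 * ll_path / phi_cur + k_path * log(N)
          lam_vec <- gfit$lambda[seq_along(bic_path)]
          cand <- which(bic_path <= min(bic_path) + 1e-9)
          j <- cand[which.max(lam_vec[cand])]  # ties -> sparser
          a0 <- as.numeric(gfit$a0[j]); beta <- as.numeric(gfit$beta[, j])
          lambda_sel <- gfit$lambda[j]
          k_sel <- 1L + sum(beta != 0)
          # once the BIC choice repeats, freeze the penalty so the EM
          # solves a fixed objective from here on
          if ((j == prev_j && iter >= 3L) || iter >= 8L) {
            lam_locked <- TRUE
          }
          prev_j <- j
        }
      }
    }

    # --- random-effect variance and modes, AR part -------------------------
    eta_fix <- a0 + drop(X %*% beta)
    if (use_re && floor_runs_b < 2L && iter <= 10L) {
      sigma_b <- profile_sigma_b(y, eta_fix, w, subj, n, floor2,
                                 control$var_ceiling, b_modes)
      floor_runs_b <- if (sigma_b <= floor2) floor_runs_b + 1L else 0L
    }
    if (sigma_b > floor2) {
      b_modes <- newton_b_modes(y, eta_fix, w, subj, n, sigma_b, b_modes)$b
    } else b_modes <- numeric(n)

    # --- convergence monitoring -------------------------------------------
    eta <- eta_fix + b_modes[subj]
    ll_cond <- zip_subject_ll(y, eta, p_subj, subj, az) -
      sum(b_modes^2) / (2 * max(sigma_b, floor2)) -
      sum(a_modes^2) / (2 * max(sigma_a, floor2))
    mu1 <- if (is.finite(lambda_sel)) 2 * N * lambda_sel else 0
    q_trace <- c(q_trace,
                 penalized_objective(ll_cond, D = matrix(beta, 1),
                                     A = if (any0 && l > 0)
                                       matrix(alpha[-1L], 1) else NULL,
                                     mu1 = mu1, mu2 = 2 * n *
                                       control$penalty_zero))
    if (control$dispersion == "quasi_poisson") {
      mu_it <- exp(pmin(eta, 300))
      dfw <- sum(w) - k_sel
      phi_cur <- if (dfw > 0) {
        max(sum(w * (y - mu_it)^2 / pmax(mu_it, 1e-12)) / dfw, 1)
      } else 1
    }
    new_par <- c(alpha, a0, beta, sigma_a, sigma_b)
    if (max(abs(new_par - old_par)) < control$tol) {
      converged <- TRUE
      break
    }
    # stall detection: a flat penalized objective over several cycles
    # (e.g. the variance and responsibilities trading off) counts as
    # converged for all practical purposes
    nq <- length(q_trace)
    if (nq >= 4) {
      rel <- abs(diff(q_trace[(nq - 3):nq])) / pmax(abs(q_trace[nq]), 1)
      if (all(rel < 3e-7)) {
        converged <- TRUE
        break
      }
    }
  }

  # relaxed-lasso debiasing: unpenalized weighted refit on the selected
  # support (selection unchanged)
  if (control$relax && is.finite(lambda_sel) && lambda_sel > 0) {
    sel <- which(beta != 0)
    ref <- tryCatch(irls_poisson(X[, sel, drop = FALSE], y, w,
                                 b_modes[subj]),
                    error = function(e) NULL)
    if (!is.null(ref) && all(is.finite(c(ref$a0, ref$beta)))) {
      eta_new <- ref$a0 + b_modes[subj] +
        (if (length(sel)) drop(X[, sel, drop = FALSE] %*% ref$beta) else 0)
      if (max(eta_new) < 30) {
        a0 <- ref$a0
        beta[] <- 0
        if (length(sel)) beta[sel] <- ref$beta
        if (sigma_b > floor2) {
          b_modes <- newton_b_modes(y, a0 + drop(X %*% beta), w, subj, n,
                                    sigma_b, b_modes)$b
        }
        eta <- a0 + drop(X %*% beta) + b_modes[subj]
      }
    }
  }

  mu <- exp(eta)
  phi <- if (control$dispersion == "quasi_poisson") {
    estimate_dispersion(y, mu, w, k_sel)
  } else 1
  list(a0 = a0, beta = beta, alpha = alpha, sigma_a = sigma_a,
       sigma_b = sigma_b, a_modes = a_modes, b_modes = b_modes,
       p_subj = p_subj, z = z, phi = phi, lambda = lambda_sel,
       k = k_sel, converged = converged, n_iter = iter,
       q_trace = q_trace, eta_fix = a0 + drop(X %*% beta),
       alpha_eta = drop(Wi %*% alpha), any0 = any0, az = az, N = N)
}

# helper: linear predictors over a whole glmnet path (N x nlambda);
# glmnet can return a truncated path on non-convergence, so dimensions
# are taken from the coefficient matrix
a0_path_eta <- function(gfit, X, off) {
  eta <- as.matrix(X %*% gfit$beta)
  a0 <- as.numeric(gfit$a0)[seq_len(ncol(eta))]
  eta + matrix(a0, nrow(eta), ncol(eta), byrow = TRUE) + off
}

# sum a row quantity into a full-length per-subject vector
rowsum_full <- function(x, subj, n) {
  out <- numeric(n)
  rs <- rowsum(x, subj, reorder = TRUE)
  out[as.integer(rownames(rs))] <- rs
  out
}

# subject-level mixture log-likelihood (no factorial terms; used for
# monitoring and penalty tuning where only differences matter)
zip_subject_ll <- function(y, eta, p_subj, subj, az) {
  n <- length(p_subj)
  eta <- pmin(eta, 300)
  mu <- exp(eta)
  s_mu <- rowsum_full(mu, subj, n)
  s_pois <- rowsum_full(y * eta - mu, subj, n)
  p_c <- pmin(p_subj, 1 - 1e-12)
  ll <- ifelse(az,
               log(p_subj + (1 - p_subj) * exp(-pmin(s_mu, 500))),
               log1p(-p_c) + s_pois)
  present <- tabulate(subj, nbins = n) > 0
  sum(ll[present])
}

# penalty-path log-likelihood used for BIC selection. Under the hard
# subject-level classification the structural subjects' contribution
# log(p_hat) does not depend on the AR coefficients, so selection is
# driven by the responsibility-weighted Poisson likelihood of present
# subjects; without this, coefficients that suppress the predicted mean
# of masked subjects would be rewarded and false selections inflate.
mixture_ll_path <- function(y, eta_path, w) {
  eta_path <- pmin(eta_path, 300)
  as.vector(crossprod(w * y, eta_path) - crossprod(w, exp(eta_path)))
}

#' Fit the zero-inflated Poisson autoregressive mixed-effects model
#'
#' Fits, taxon by taxon, a two-part model for longitudinal absolute
#' abundances: a logistic component for structural zeros (with optional
#' subject-level covariates and a subject random intercept) and a log-link
#' Poisson autoregressive component whose linear predictor combines the
#' lagged log abundances of all taxa (the interaction matrix \code{B}),
#' time-independent covariates (\code{C}), an unpenalized baseline
#' projection coefficient per taxon, and a subject random intercept.
#' Estimation is by an EM algorithm that treats the structural-zero labels
#' as missing data, integrates the random intercepts by Laplace
#' approximation, and solves the l1-penalized weighted regression
#' subproblems by coordinate descent, with the penalty tuned per taxon by
#' BIC unless fixed via \code{lambda}.
#'
#' @param panel a [longitudinal_panel()] (already filtered).
#' @param covariates optional per-subject covariate data.frame with a
#'   \code{subject} column.
#' @param zero_cols,ar_cols covariate column names used in the zero part
#'   (\code{W}) and the autoregressive part (\code{Z}); default: all
#'   covariate columns for both.
#' @param lambda penalty for the autoregressive part: \code{NULL} (default)
#'   tunes per taxon by BIC over an automatic path; a single number or a
#'   length-M vector fixes it (0 means unpenalized).
#' @param control a [zipar_control()] list.
#' @return an object of class \code{zipar_fit}; see Details.
#' @details The returned fit contains the coefficient matrices \code{A}
#'   (zero part, M x (l+1)), \code{B} (interactions, rows = response taxon),
#'   \code{C} (AR covariates, M x (q+1) including intercept), the projection
#'   coefficients \code{pi}, dispersions \code{phi}, random-intercept
#'   variances \code{sigma_a}/\code{sigma_b}, per-subject fitted
#'   structural-zero probabilities and random-effect modes, E-step
#'   responsibilities, per-taxon Laplace log-likelihoods, BIC, selected
#'   penalties, and convergence flags. Taxa observed as all-zero are
#'   flagged and given a degenerate fit (p = 1, zero interaction row).
#' @export
fit_zipar <- function(panel, covariates = NULL, zero_cols = NULL,
                      ar_cols = NULL, lambda = NULL,
                      control = zipar_control()) {
  des <- lagged_design(panel, control$pseudo_count, control$anchor_time)
  cov_des <- covariate_design(covariates, des$subjects, zero_cols, ar_cols)
  fit_zipar_design(des, cov_des, lambda, control)
}

# core fitter on a pre-built design (shared with the bootstrap loop)
fit_zipar_design <- function(des, cov_des, lambda = NULL,
                             control = zipar_control()) {
  taxa <- des$taxa; M <- length(taxa)
  subjects <- des$subjects; n <- length(subjects)
  N <- nrow(des$y)
  W <- cov_des$W; Z <- cov_des$Z
  l <- ncol(W); q <- ncol(Z)
  Zrow <- if (q > 0) Z[des$subj, , drop = FALSE] else NULL
  if (!is.null(lambda)) lambda <- rep_len(lambda, M)

  A <- matrix(0, M, l + 1,
              dimnames = list(taxa, c("(Intercept)", colnames(W))))
  B <- matrix(0, M, M, dimnames = list(taxa, taxa))
  C <- matrix(0, M, q + 1,
              dimnames = list(taxa, c("(Intercept)", colnames(Z))))
  pi_coef <- stats::setNames(numeric(M), taxa)
  phi <- stats::setNames(rep(1, M), taxa)
  sigma_a <- stats::setNames(numeric(M), taxa)
  sigma_b <- stats::setNames(numeric(M), taxa)
  lambda_sel <- stats::setNames(rep(NA_real_, M), taxa)
  loglik <- stats::setNames(numeric(M), taxa)
  bic <- stats::setNames(numeric(M), taxa)
  kpar <- stats::setNames(rep(1L, M), taxa)
  converged <- stats::setNames(rep(TRUE, M), taxa)
  n_iter <- stats::setNames(integer(M), taxa)
  all_zero <- stats::setNames(rep(FALSE, M), taxa)
  p_subject <- matrix(0, n, M, dimnames = list(subjects, taxa))
  a_modes <- matrix(0, n, M, dimnames = list(subjects, taxa))
  b_modes <- matrix(0, n, M, dimnames = list(subjects, taxa))
  zresp <- matrix(0, N, M, dimnames = list(NULL, taxa))
  eta_fix <- matrix(0, N, M, dimnames = list(NULL, taxa))
  q_traces <- vector("list", M); names(q_traces) <- taxa


  for (m in seq_len(M)) {
    y_m <- des$y[, m]
    if (all(y_m == 0)) {
      all_zero[m] <- TRUE
      A[m, 1] <- 20  # p = 1 on the logit scale, effectively
      p_subject[, m] <- 1
      zresp[des$y[, m] == 0, m] <- 1
      loglik[m] <- 0  # zeros are certain under p = 1
      bic[m] <- 0
      next
    }
    lag_cols <- if (control$include_self) seq_len(M) else
      setdiff(seq_len(M), m)
    X <- cbind(des$lag[, lag_cols, drop = FALSE],
               Zrow,
               proj = des$y0log[des$subj, m])
    pf <- c(rep(1, length(lag_cols)), rep(1, q), 0)  # projection free
    ft <- fit_taxon_zip(y_m, X, pf, des$subj, n, W, control,
                        lambda_fixed = if (is.null(lambda)) NULL
                        else lambda[m])
    A[m, ] <- ft$alpha
    B[m, lag_cols] <- ft$beta[seq_along(lag_cols)]
    C[m, 1] <- ft$a0
    if (q > 0) C[m, -1] <- ft$beta[length(lag_cols) + seq_len(q)]
    pi_coef[m] <- ft$beta[length(ft$beta)]
    phi[m] <- ft$phi
    sigma_a[m] <- if (ft$sigma_a <= control$var_floor) 0 else ft$sigma_a
    sigma_b[m] <- if (ft$sigma_b <= control$var_floor) 0 else ft$sigma_b
    lambda_sel[m] <- ft$lambda
    kpar[m] <- ft$k
    converged[m] <- ft$converged
    n_iter[m] <- ft$n_iter
    p_subject[, m] <- ft$p_subj
    a_modes[, m] <- ft$a_modes
    b_modes[, m] <- ft$b_modes
    zresp[, m] <- ft$z
    eta_fix[, m] <- ft$eta_fix
    q_traces[[m]] <- ft$q_trace

    if (control$exact_marginal) {
      lm_ <- laplace_marginal(y_m, ft$eta_fix, des$subj,
                              sigma_a = sigma_a[m], sigma_b = sigma_b[m],
                              alpha_eta = if (ft$any0) ft$alpha_eta else -Inf,
                              n = n,
                              init = cbind(ft$a_modes, ft$b_modes),
                              var_floor = control$var_floor)
      loglik[m] <- lm_$loglik
    } else {
      loglik[m] <- zip_subject_ll(y_m, ft$eta_fix + ft$b_modes[des$subj],
                                  ft$p_subj, des$subj, ft$az)
    }
    k_bic <- ft$k + 2L + (if (ft$any0) l + 1L else 0L)
    bic[m] <- -2 * loglik[m] + k_bic * log(ft$N)
  }

  structure(list(taxa = taxa, subjects = subjects,
                 A = A, B = B, C = C, pi = pi_coef, phi = phi,
                 sigma_a = sigma_a, sigma_b = sigma_b,
                 lambda = lambda_sel, k = kpar,
                 loglik = loglik, bic = bic,
                 converged = converged, n_iter = n_iter,
                 all_zero = all_zero,
                 p_subject = p_subject, a_modes = a_modes,
                 b_modes = b_modes, responsibilities = zresp,
                 eta_fix = eta_fix, design = des, control = control),
            class = "zipar_fit")
}

#' @export
print.zipar_fit <- function(x, ...) {
  cat("Zero-inflated Poisson AR mixed-effects fit\n")
  cat(sprintf("  taxa: %d (%d all-zero)   subjects: %d   transitions: %d\n",
              length(x$taxa), sum(x$all_zero), length(x$subjects),
              nrow(x$design$y)))
  cat(sprintf("  nonzero interactions: %d of %d\n",
              sum(x$B != 0), length(x$B)))
  cat(sprintf("  converged: %d/%d taxa   total BIC: %.1f\n",
              sum(x$converged), length(x$taxa), sum(x$bic)))
  cat(sprintf("  spectral radius of B: %.3f\n",
              max(Mod(eigen(x$B, only.values = TRUE)$values))))
  invisible(x)
}

#' Fitted mixture moments of a zero-inflated Poisson AR fit
#'
#' Returns, for every transition cell, the fitted mean and standard
#' deviation under the estimated mixture: \eqn{\hat y = (1-p)\mu} and
#' \eqn{\mathrm{Var} = (1-p)(\phi \mu + p \mu^2)} with \eqn{\mu} evaluated
#' at the subject's random-effect mode.
#'
#' @param fit a \code{zipar_fit}.
#' @param ... method-specific options.
#' @return list with N x M matrices \code{mean} and \code{sd}, and the
#'   observed response matrix \code{observed}.
#' @export
fitted_moments <- function(fit, ...) {
  UseMethod("fitted_moments")
}

#' @export
fitted_moments.zipar_fit <- function(fit, ...) {
  des <- fit$design
  M <- length(fit$taxa)
  mu <- exp(fit$eta_fix + fit$b_modes[des$subj, , drop = FALSE])
  # for cells classified structural the conditional-on-present mean is not
  # identified (their own-lag history is all zero); impute the taxon's
  # weighted mean fitted abundance among present cells as the
  # counterfactual present-state mean
  z <- fit$responsibilities
  for (m in seq_len(M)) {
    st <- z[, m] >= 0.5
    if (any(st) && !all(st)) {
      mu[st, m] <- sum((1 - z[!st, m]) * mu[!st, m]) /
        sum(1 - z[!st, m])
    }
  }
  p <- fit$p_subject[des$subj, , drop = FALSE]
  mu[, fit$all_zero] <- 0
  mean_ <- (1 - p) * mu
  var_ <- (1 - p) * (rep(fit$phi, each = nrow(mu)) * mu + p * mu^2)
  list(mean = mean_, sd = sqrt(var_), observed = des$y)
}

#' Tune the autoregressive penalty by BIC
#'
#' Runs the EM fitter over a penalty grid and reports the per-taxon
#' BIC-selected penalty (ties broken toward the sparser, larger penalty)
#' together with the BIC path.
#'
#' @param panel a [longitudinal_panel()].
#' @param covariates optional covariate table.
#' @param grid decreasing vector of candidate penalties; \code{NULL} lets
#'   each taxon use its automatic path.
#' @param shared if TRUE all taxa share \code{grid}; per-taxon automatic
#'   paths otherwise.
#' @param ... passed to [fit_zipar()].
#' @param control a [zipar_control()].
#' @export
select_penalty_bic <- function(panel, covariates = NULL, grid = NULL,
                               shared = !is.null(grid),
                               control = zipar_control(), ...) {
  if (is.null(grid) && shared) {
    stop("a shared grid requires 'grid'", call. = FALSE)
  }
  if (!is.null(grid)) {
    if (length(grid) == 0) stop("empty penalty grid", call. = FALSE)
    control$lambda_grid <- sort(grid, decreasing = TRUE)
  }
  fit <- fit_zipar(panel, covariates, control = control, ...)
  list(lambda = fit$lambda, bic = fit$bic, fit = fit)
}
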