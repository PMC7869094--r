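#' Hierarchical (parametric empirical Bayes) model over subject DCMs
#'
#' Places a group-level GLM over selected first-level parameters: each
#' subject's posterior mean for the selected parameters is treated as data
#' with its posterior covariance, plus an isotropic between-subject
#' component, so that `theta_s ~ N(beta %*% X[s, ], C_s + gamma I)`.  The
#' group coefficients `beta` (one per parameter and covariate) receive a
#' zero-mean shrinkage prior and are estimated in closed form conditional
#' on the between-subject variance, whose log-precision is MAP-estimated
#' under a weakly informative Gaussian prior.
#'
#' @param subject_posteriors list of [gaussian_belief()] objects with
#'   named means (e.g., from [dcm_fit()]).
#' @param X subjects x covariates design matrix; column 1 should be the
#'   group mean (intercept).  Further columns (e.g., per-condition TMRs)
#'   are mean-centered automatically so the intercept keeps its group-mean
#'   interpretation.
#' @param params character vector (or indices) of first-level parameters
#'   to model; defaults to all B-matrix (modulation) parameters.
#' @param beta_prior_var prior variance of each group coefficient
#'   (scalar or length `k * ncol(X)`).
#' @param gamma between-subject variance; `NULL` (default) estimates it,
#'   a number fixes it (0 = none).
#' @param lambda_prior_mean,lambda_prior_var prior moments of the
#'   between-subject log-precision.
#' @param center_covariates mean-center columns 2..ncol(X).
#' @return Object of class `"peb_model"` with the group posterior `beta`
#'   (a [gaussian_belief()] with free energy), the prior, and bookkeeping.
#' @export
peb_fit <- function(subject_posteriors, X, params = NULL,
                    beta_prior_var = 1 / 16, gamma = NULL,
                    lambda_prior_mean = 0, lambda_prior_var = 16,
                    center_covariates = TRUE) {
  ns <- length(subject_posteriors)
  if (ns < 2) stop("need at least 2 subjects")
  X <- as.matrix(X)
  if (nrow(X) != ns) stop("rows of X must equal the number of subjects")
  if (qr(X)$rank < ncol(X)) stop("design matrix X is rank deficient")
  if (center_covariates && ncol(X) > 1)
    X[, -1] <- scale(X[, -1, drop = FALSE], center = TRUE, scale = FALSE)
  nm_all <- names(subject_posteriors[[1]]$mean)
  if (is.null(params))
    params <- grep("^B\\.", nm_all, value = TRUE)
  if (is.numeric(params)) params <- nm_all[params]
  if (!length(params)) stop("no parameters selected")
  k <- length(params)
  idx <- match(params, nm_all)
  if (anyNA(idx)) stop("selected parameters missing from subject posteriors")
  for (s in subject_posteriors)
    if (!all(params %in% names(s$mean)))
      stop("selected parameters must be identical across subjects")
  M <- t(vapply(subject_posteriors, function(s) s$mean[idx], numeric(k)))
  Cs <- lapply(subject_posteriors, function(s)
    as.matrix(s$cov)[idx, idx, drop = FALSE])
  ncov <- ncol(X)
  covnames <- colnames(X) %||%
    c("mean", if (ncov > 1) paste0("cov", seq_len(ncov - 1)))
  K <- k * ncov
  bnames <- as.vector(vapply(covnames, function(cn) paste(cn, params,
                                                          sep = ":"),
                             character(k)))
  pv <- rep(beta_prior_var, length.out = K)

  fit_given_gamma <- function(g) {
    H <- matrix(0, K, K)
    b <- numeric(K)
    qsum <- 0
    ldet <- 0
    for (s in seq_len(ns)) {
      W <- chol2inv(chol(Cs[[s]] + diag(g, k)))
      ldet <- ldet - logdet_chol(W)         # + logdet of (Cs + gI)
      xs <- X[s, ]
      H <- H + kronecker(tcrossprod(xs), W)
      Wm <- W %*% M[s, ]
      b <- b + as.vector(kronecker(xs, Wm))
      qsum <- qsum + drop(M[s, ] %*% Wm)
    }
    Hp <- H + diag(1 / pv, K)
    R <- chol(Hp)
    mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
    lz <- -ns * k / 2 * log(2 * pi) - 0.5 * ldet -
      0.5 * sum(log(pv)) - sum(log(diag(R))) -
      0.5 * (qsum - drop(mu %*% Hp %*% mu))
    list(F = lz, mu = mu, Hp = Hp)
  }

  if (is.null(gamma)) {
    obj <- function(lambda)
      fit_given_gamma(exp(-lambda))$F -
        (lambda - lambda_prior_mean) ^ 2 / (2 * lambda_prior_var)
    opt <- stats::optimize(obj, c(-10, 12), maximum = TRUE, tol = 1e-4)
    lambda <- opt$maximum
    gamma <- exp(-lambda)
  } else {
    lambda <- if (gamma > 0) -log(gamma) else Inf
  }
  fit <- fit_given_gamma(gamma)
  Fpen <- fit$F - if (is.finite(lambda))
    (lambda - lambda_prior_mean) ^ 2 / (2 * lambda_prior_var) else 0
  beta <- gaussian_belief(mean = stats::setNames(fit$mu, bnames),
                          cov = chol2inv(chol(fit$Hp)),
                          free_energy = Fpen)
  prior <- gaussian_belief(mean = stats::setNames(rep(0, K), bnames),
                           cov = diag(pv, K))
  structure(list(beta = beta, prior = prior, X = X, gamma = gamma,
                 lambda = lambda, params = params, covariates = covnames,
                 n_subjects = ns, k = k, free_energy = Fpen),
            class = "peb_model")
}

#' @export
print.peb_model <- function(x, ...) {
  cat(sprintf(
    "PEB model: %d subjects, %d parameters x %d covariates, F = %.2f\n",
    x$n_subjects, x$k, length(x$covariates), x$free_energy))
  cat(sprintf("  between-subject variance: %.4g\n", x$gamma))
  invisible(x)
}

#' Analytic evidence and posterior of a model with a reduced prior
#'
#' Bayesian model reduction: given the prior and posterior of a full
#' model, computes the posterior and change in log evidence that direct
#' inversion under a different (nested) prior would have produced, using
#' Gaussian algebra only - no refitting.
#'
#' @param full_prior,full_posterior [gaussian_belief()] objects from the
#'   full model.
#' @param reduced_prior [gaussian_belief()]; typically equal to the full
#'   prior except for entries "switched off" (mean 0, variance ~1e-8).
#' @return Object of class `"reduced_model"`: `posterior` (a
#'   [gaussian_belief()]), `delta_F` (log evidence of reduced minus full),
#'   and `free_energy` (absolute, when the full posterior carries one).
#' @export
bayesian_model_reduction <- function(full_prior, full_posterior,
                                     reduced_prior) {
  p <- length(full_prior$mean)
  if (length(full_posterior$mean) != p || length(reduced_prior$mean) != p)
    stop("priors and posterior must share one parameter space")
  P0 <- chol2inv(chol(full_prior$cov))
  P1 <- chol2inv(chol(reduced_prior$cov))
  P <- chol2inv(chol(full_posterior$cov))
  Pn <- P + P1 - P0
  Rn <- tryCatch(chol(Pn), error = function(e)
    stop("non-nested priors: reduced posterior precision not positive ",
         "definite"))
  m0 <- full_prior$mean; m1 <- reduced_prior$mean; m <- full_posterior$mean
  bn <- drop(P %*% m + P1 %*% m1 - P0 %*% m0)
  mn <- backsolve(Rn, backsolve(Rn, bn, transpose = TRUE))
  dF <- 0.5 * (logdet_chol(P) + logdet_chol(P1) - logdet_chol(P0) -
                 2 * sum(log(diag(Rn)))) +
    0.5 * (drop(mn %*% Pn %*% mn) - drop(m %*% P %*% m) -
             drop(m1 %*% P1 %*% m1) + drop(m0 %*% P0 %*% m0))
  post <- gaussian_belief(mean = stats::setNames(mn, names(m)),
                          cov = chol2inv(Rn),
                          free_energy = if (!is.null(
                            full_posterior$free_energy))
                            full_posterior$free_energy + dF else NULL)
  structure(list(posterior = post, delta_F = dF,
                 free_energy = post$free_energy %||% dF),
            class = "reduced_model")
}

# reduced prior with the masked-off entries pinned to zero
reduced_prior_for_mask <- function(prior, off_idx, off_var = 1e-8) {
  cov <- as.matrix(prior$cov)
  mean <- prior$mean
  if (length(off_idx)) {
    cov[off_idx, ] <- 0
    cov[, off_idx] <- 0
    diag(cov)[off_idx] <- off_var
    mean[off_idx] <- 0
  }
  gaussian_belief(mean = mean, cov = cov)
}

#' Greedy search over reduced group models
#'
#' Starting from the full PEB model (all group parameters "switched on"),
#' iteratively switches off the single parameter whose removal most
#' increases the free energy, until no single removal increases it.  It
#' then takes the 8 candidate parameters with the smallest absolute
#' evidence contribution (the least decisive ones, measured by the free-
#' energy change of switching each off alone in the full model) and scores
#' all 2^8 = 256 on/off combinations of those parameters (others held at
#' their terminal state) by Bayesian model reduction.  With fewer than 8
#' candidates, all 2^k combinations are scored (with a message).
#'
#' @param peb a fitted [peb_fit()] model.
#' @param candidates indices (or names) of switchable group parameters;
#'   default: all of them.
#' @param off_var prior variance representing "switched off".
#' @param enumerate_k number of parameters in the terminal enumeration.
#' @return Object of class `"model_set"`: `models` (list with `mask`
#'   (logical vector over group parameters), `free_energy`, `delta_F`),
#'   plus the full `prior` and `posterior` needed to reconstruct reduced
#'   posteriors, and the terminal greedy mask.
#' @export
greedy_search <- function(peb, candidates = NULL, off_var = 1e-8,
                          enumerate_k = 8) {
  prior <- peb$prior
  posterior <- peb$beta
  K <- length(prior$mean)
  if (is.null(candidates)) candidates <- seq_len(K)
  if (is.character(candidates))
    candidates <- match(candidates, names(prior$mean))
  if (anyNA(candidates)) stop("unknown candidate parameters")

  v <- diag(as.matrix(prior$cov))          # current prior variances
  Cp <- as.matrix(posterior$cov)           # current posterior covariance
  m <- unname(posterior$mean)
  on <- rep(TRUE, K)

  # free-energy change of switching parameter i off alone, given the
  # current (m, Cp, v) state; rank-one identity
  dF_off <- function(i) {
    ci <- 1 / off_var - 1 / v[i]
    den <- 1 + ci * Cp[i, i]
    0.5 * log(v[i] / off_var) - 0.5 * log(den) -
      0.5 * ci * m[i] ^ 2 / den
  }

  # decisiveness of each candidate in the full model
  full_dF <- vapply(candidates, dF_off, numeric(1))

  repeat {
    live <- candidates[on[candidates]]
    if (!length(live)) break
    dfs <- vapply(live, dF_off, numeric(1))
    best <- which.max(dfs)
    if (dfs[best] <= 0) break
    i <- live[best]
    ci <- 1 / off_var - 1 / v[i]
    den <- 1 + ci * Cp[i, i]
    m <- m - (ci * m[i] / den) * Cp[, i]
    Cp <- Cp - (ci / den) * tcrossprod(Cp[, i])
    v[i] <- off_var
    on[i] <- FALSE
  }

  kk <- min(enumerate_k, length(candidates))
  if (kk < enumerate_k)
    message("fewer than ", enumerate_k, " candidate parameters; ",
            "enumerating all 2^", kk, " combinations")
  uncertain <- candidates[order(abs(full_dF))][seq_len(kk)]

  base_mask <- on
  combos <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), kk)))
  models <- vector("list", nrow(combos))
  for (mi in seq_len(nrow(combos))) {
    mask <- base_mask
    mask[uncertain] <- combos[mi, ]
    off_idx <- which(!mask)
    rp <- reduced_prior_for_mask(prior, off_idx, off_var)
    rm <- bayesian_model_reduction(prior, posterior, rp)
    models[[mi]] <- list(mask = mask, free_energy = rm$free_energy,
                         delta_F = rm$delta_F)
  }
  structure(list(models = models, prior = prior, posterior = posterior,
                 candidates = candidates, terminal_mask = base_mask,
                 enumerated = uncertain, off_var = off_var,
                 param_names = names(prior$mean)),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("model set: %d reduced models over %d group parameters\n",
              length(x$models), length(x$param_names)))
  cat(sprintf("  greedy search pruned %d of %d candidates; %d enumerated\n",
              sum(!x$terminal_mask[x$candidates]), length(x$candidates),
              length(x$enumerated)))
  invisible(x)
}

#' Bayesian model average over a set of reduced models
#'
#' Weights each model by the softmax of its free energy, averages the
#' Gaussian posteriors by their mixture moments, and reports per-parameter
#' posterior probabilities `Pp` (summed weight of the models in which the
#' parameter is switched on).  Parameters with `Pp` below the threshold
#' are flagged as discounted.
#'
#' @param models a `"model_set"` from [greedy_search()], or a plain list
#'   of `"reduced_model"` objects (which carry their posteriors).
#' @param threshold retention threshold on `Pp`.
#' @return Object of class `"bma_result"`: `mean`, `cov`, `pp`,
#'   `retained` (names with `Pp >= threshold`), `weights`.
#' @export
bayesian_model_average <- function(models, threshold = 0.95) {
  if (inherits(models, "model_set")) {
    set <- models
    Fs <- vapply(set$models, function(mm) mm$free_energy, numeric(1))
    w <- exp(Fs - max(Fs))
    w <- w / sum(w)
    K <- length(set$prior$mean)
    mean_acc <- numeric(K)
    cov_acc <- matrix(0, K, K)
    pp <- numeric(K)
    for (mi in seq_along(set$models)) {
      mm <- set$models[[mi]]
      if (w[mi] > 1e-12) {
        rp <- reduced_prior_for_mask(set$prior, which(!mm$mask),
                                     set$off_var)
        post <- bayesian_model_reduction(set$prior, set$posterior,
                                         rp)$posterior
        mean_acc <- mean_acc + w[mi] * post$mean
        cov_acc <- cov_acc + w[mi] * (as.matrix(post$cov) +
                                        tcrossprod(post$mean))
      }
      pp <- pp + w[mi] * mm$mask
    }
    cov_acc <- cov_acc - tcrossprod(mean_acc)
    nm <- set$param_names
  } else {
    if (!length(models)) stop("empty model list")
    Fs <- vapply(models, function(mm) mm$free_energy, numeric(1))
    w <- exp(Fs - max(Fs))
    w <- w / sum(w)
    K <- length(models[[1]]$posterior$mean)
    nm <- names(models[[1]]$posterior$mean)
    mean_acc <- numeric(K)
    cov_acc <- matrix(0, K, K)
    pp <- numeric(K)
    for (mi in seq_along(models)) {
      post <- models[[mi]]$posterior
      mask <- models[[mi]]$mask %||% rep(TRUE, K)
      mean_acc <- mean_acc + w[mi] * post$mean
      cov_acc <- cov_acc + w[mi] * (as.matrix(post$cov) +
                                      tcrossprod(post$mean))
      pp <- pp + w[mi] * mask
    }
    cov_acc <- cov_acc - tcrossprod(mean_acc)
  }
  names(mean_acc) <- nm
  names(pp) <- nm
  structure(list(mean = mean_acc, cov = cov_acc, pp = pp,
                 retained = nm[pp >= threshold], weights = w,
                 threshold = threshold), class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("Bayesian model average over %d models\n", length(x$weights)))
  cat(sprintf("  %d of %d parameters retained at Pp >= %.2f\n",
              length(x$retained), length(x$pp), x$threshold))
  invisible(x)
}

#' Human-readable table of group parameters after model averaging
#'
#' One row per group parameter: covariate, parameter, connection strength
#' (model-averaged posterior mean) and posterior probability, in the style
#' of a connectivity-modulation results table.
#'
#' @param bma a [bayesian_model_average()] result.
#' @param sort_by_pp order rows by decreasing posterior probability.
#' @return Data frame with `covariate`, `parameter`, `strength`, `Pp`.
#' @export
bma_table <- function(bma, sort_by_pp = TRUE) {
  nm <- names(bma$pp)
  parts <- regmatches(nm, regexpr(":", nm), invert = TRUE)
  covariate <- vapply(parts, `[`, "", 1)
  parameter <- vapply(parts, function(z) if (length(z) > 1) z[2] else z[1],
                      "")
  out <- data.frame(covariate = covariate, parameter = parameter,
                    strength = unname(bma$mean), Pp = unname(bma$pp))
  if (sort_by_pp) out <- out[order(-out$Pp, -abs(out$strength)), ]
  rownames(out) <- NULL
  out
}
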