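#' Gaussian belief over a parameter vector
#'
#' Container for a (prior or posterior) multivariate Gaussian, optionally
#' with the free energy attained by the fit that produced it.
#'
#' @param mean named parameter vector.
#' @param cov covariance matrix (symmetric positive semidefinite).
#' @param free_energy free energy in nats (posteriors only).
#' @param ... further fields stored on the object (accuracy, iteration
#'   traces, ...).
#' @return Object of class `"gaussian_belief"`.
#' @export
gaussian_belief <- function(mean, cov, free_energy = NULL, ...) {
  mean <- drop(mean)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == length(mean)))
    stop("covariance dimensions must match the mean")
  if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov))))
    stop("covariance must be symmetric")
  structure(c(list(mean = mean, cov = (cov + t(cov)) / 2,
                   free_energy = free_energy), list(...)),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("Gaussian belief over %d parameters%s\n", length(x$mean),
              if (!is.null(x$free_energy))
                sprintf(", F = %.2f nats", x$free_energy) else ""))
  invisible(x)
}

#' Observation-noise model for variational Laplace
#'
#' Independent Gaussian noise with one log-precision hyperparameter per
#' group of observations (e.g., per region).  No autoregressive structure:
#' sparse temporal sampling leaves scans conditionally independent.
#'
#' @param groups factor/vector assigning each observation to a precision
#'   component.
#' @param lambda0 prior mean of each log-precision.
#' @param lambda_var prior variance of each log-precision.
#' @param fixed_precision if non-`NULL`, a known precision (scalar or
#'   per-observation vector); hyperparameters are then not estimated.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(groups, lambda0 = 0, lambda_var = 16,
                        fixed_precision = NULL) {
  groups <- as.integer(factor(groups))
  if (!is.null(fixed_precision) && any(fixed_precision <= 0))
    stop("precisions must be positive")
  structure(list(groups = groups, n_groups = max(groups),
                 lambda0 = lambda0, lambda_var = lambda_var,
                 fixed = fixed_precision), class = "noise_model")
}

logdet_chol <- function(M) 2 * sum(log(diag(chol(M))))

# Laplace free energy given current linearization.
# e: residual, J: jacobian, w: per-observation precision,
# d: theta - prior mean, P0/C0: prior precision/covariance,
# lam terms: optional hyperparameter contribution.
vl_free_energy_terms <- function(e, J, w, d, P0, ldetC0, lam = NULL) {
  n <- length(e)
  H <- crossprod(J * w, J) + P0
  Cp <- chol2inv(chol(H))
  ldetCp <- -logdet_chol(H)
  JtWJ <- H - P0
  accuracy <- -0.5 * sum(w * e ^ 2) + 0.5 * sum(log(w)) -
    n / 2 * log(2 * pi) - 0.5 * sum(Cp * JtWJ)
  complexity <- 0.5 * (sum(Cp * P0) + drop(t(d) %*% P0 %*% d) -
                         length(d) + ldetC0 - ldetCp)
  F <- accuracy - complexity
  lambda_complexity <- 0
  if (!is.null(lam)) {
    lambda_complexity <- 0.5 * (sum(lam$cl / lam$var) +
                                  sum((lam$lambda - lam$l0) ^ 2 / lam$var) -
                                  length(lam$lambda) +
                                  sum(log(lam$var)) - sum(log(lam$cl)))
    F <- F - lambda_complexity
  }
  list(F = F, accuracy = accuracy, complexity = complexity,
       lambda_complexity = lambda_complexity, H = H, Cp = Cp)
}

#' Fit a nonlinear-Gaussian model by variational Laplace
#'
#' Iterative Gauss-Newton ascent on the variational free energy with
#' Levenberg-Marquardt regularization, alternating parameter updates with
#' Newton updates of the noise log-precision hyperparameters.  Returns the
#' posterior mode, Laplace covariance, and the converged free energy; the
#' free energy is non-decreasing across accepted steps.
#'
#' @param f prediction function: maps a parameter vector to a numeric
#'   vector of predicted observations.
#' @param y observed data vector.
#' @param prior a [gaussian_belief()] over the parameters.
#' @param noise a [noise_model()] for the observations.
#' @param jacobian optional function `(theta, step)` returning the
#'   Jacobian of `f`; by default central finite differences on `f`.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol convergence tolerance on `|dF|` in nats.
#' @param tol_count consecutive small-|dF| iterations required.
#' @param fd_step finite-difference step in parameter space.
#' @param fd finite-difference scheme for the default Jacobian:
#'   `"central"` (two-sided, default) or `"forward"` (one-sided; half the
#'   cost, adequate for Gauss-Newton steps on smooth models).
#' @param verbose print the free-energy trace.
#' @return A [gaussian_belief()] posterior with fields `free_energy`,
#'   `accuracy`, `complexity`, `lambda` (posterior log-precisions),
#'   `trace` (free energy per accepted iteration), and `converged`.
#' @export
variational_laplace <- function(f, y, prior, noise,
                                jacobian = NULL, max_iter = 64,
                                tol = 0.01, tol_count = 3, fd_step = 1e-4,
                                fd = c("central", "forward"),
                                verbose = FALSE) {
  fd <- match.arg(fd)
  theta <- prior$mean
  p <- length(theta)
  C0 <- prior$cov
  P0 <- chol2inv(chol(C0))
  ldetC0 <- logdet_chol(C0)
  if (!all(is.finite(y))) stop("data must be finite")
  n <- length(y)
  if (is.null(jacobian))
    jacobian <- if (fd == "central") {
      function(th, step) {
        J <- matrix(0, n, p)
        for (i in seq_len(p)) {
          tp <- th; tp[i] <- tp[i] + step
          tm <- th; tm[i] <- tm[i] - step
          J[, i] <- (f(tp) - f(tm)) / (2 * step)
        }
        J
      }
    } else {
      function(th, step) {
        J <- matrix(0, n, p)
        f0 <- f(th)
        for (i in seq_len(p)) {
          tp <- th; tp[i] <- tp[i] + step
          J[, i] <- (f(tp) - f0) / step
        }
        J
      }
    }
  groups <- noise$groups
  fixed <- !is.null(noise$fixed)
  lambda <- rep(noise$lambda0, noise$n_groups)
  weights <- function(lambda) {
    if (fixed) rep(noise$fixed, length.out = n) else exp(lambda)[groups]
  }
  lam_terms <- function(lambda, wR_sum, ng) {
    if (fixed) return(NULL)
    cl <- 1 / (0.5 * wR_sum / pmax(ng, 1) * ng + 1 / noise$lambda_var)
    # cl: Laplace variance of each log-precision (expected curvature)
    list(lambda = lambda, l0 = noise$lambda0,
         var = rep(noise$lambda_var, length(lambda)), cl = cl)
  }

  mu <- f(theta)
  if (length(mu) != n) stop("prediction length does not match data")
  e <- y - mu
  J <- jacobian(theta, fd_step)
  w <- weights(lambda)
  ng <- tabulate(groups, noise$n_groups)

  update_lambda <- function(lambda, e, J, Cp) {
    if (fixed) return(lambda)
    w <- weights(lambda)
    R <- e ^ 2 + rowSums((J %*% Cp) * J)
    for (it in 1:8) {
      w <- weights(lambda)
      sR <- as.numeric(tapply(w * R, factor(groups, seq_len(noise$n_groups)),
                              sum, default = 0))
      gd <- 0.5 * (ng - sR) - (lambda - noise$lambda0) / noise$lambda_var
      hs <- 0.5 * sR + 1 / noise$lambda_var
      step <- gd / hs
      step <- pmax(pmin(step, 2), -2)
      lambda <- lambda + step
      if (max(abs(step)) < 1e-4) break
    }
    lambda
  }

  wR_group <- function(lambda, e, J, Cp) {
    w <- weights(lambda)
    R <- e ^ 2 + rowSums((J %*% Cp) * J)
    as.numeric(tapply(w * R, factor(groups, seq_len(noise$n_groups)), sum,
                      default = 0))
  }

  ft <- vl_free_energy_terms(e, J, w, theta - prior$mean, P0, ldetC0,
                             if (fixed) NULL else
                               lam_terms(lambda, wR_group(lambda, e, J,
                                                          diag(1e-8, p)),
                                         ng))
  F <- ft$F
  trace <- F
  nu <- 0
  small <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    J <- jacobian(theta, fd_step)
    w <- weights(lambda)
    H <- crossprod(J * w, J) + P0
    g <- drop(crossprod(J, w * e)) - drop(P0 %*% (theta - prior$mean))
    accepted <- FALSE
    scale <- mean(diag(H))
    for (try in 1:8) {
      Hreg <- H + nu * scale * diag(p)
      delta <- tryCatch(solve(Hreg, g), error = function(err) {
        nu <<- max(nu * 10, 1e-4)
        NULL
      })
      if (is.null(delta)) next
      theta_new <- theta + delta
      mu_new <- tryCatch(f(theta_new), error = function(err) NULL)
      if (!is.null(mu_new) && all(is.finite(mu_new))) {
        e_new <- y - mu_new
        lambda_new <- update_lambda(lambda, e_new, J,
                                    chol2inv(chol(H)))
        w_new <- weights(lambda_new)
        ft_new <- vl_free_energy_terms(
          e_new, J, w_new, theta_new - prior$mean, P0, ldetC0,
          if (fixed) NULL else
            lam_terms(lambda_new,
                      wR_group(lambda_new, e_new, J, chol2inv(chol(H))), ng))
        if (is.finite(ft_new$F) && ft_new$F > F - 1e-12) {
          theta <- theta_new; e <- e_new; lambda <- lambda_new
          F <- ft_new$F; ft <- ft_new
          nu <- nu / 2
          if (nu < 1e-8) nu <- 0
          accepted <- TRUE
          break
        }
      }
      nu <- max(nu * 10, 1e-4)
    }
    trace <- c(trace, F)
    if (verbose)
      message(sprintf("iter %2d: F = %.4f%s", iter, F,
                      if (accepted) "" else " (no step accepted)"))
    dF <- abs(diff(utils::tail(trace, 2)))
    small <- if (length(dF) && dF < tol) small + 1L else 0L
    if (small >= tol_count) { converged <- TRUE; break }
    if (!accepted) { converged <- TRUE; break }  # regularized local optimum
  }
  if (!converged)
    warning("variational Laplace did not converge; returning best-so-far")
  # final curvature at the mode
  J <- jacobian(theta, fd_step)
  w <- weights(lambda)
  ftf <- vl_free_energy_terms(e, J, w, theta - prior$mean, P0, ldetC0,
                              if (fixed) NULL else
                                lam_terms(lambda,
                                          wR_group(lambda, e, J,
                                                   chol2inv(chol(crossprod(
                                                     J * w, J) + P0))), ng))
  names(theta) <- names(prior$mean)
  gaussian_belief(mean = theta, cov = ftf$Cp, free_energy = ftf$F,
                  accuracy = ftf$accuracy, complexity = ftf$complexity,
                  lambda = lambda, trace = trace, converged = converged,
                  residuals = e)
}

#' Free energy (evidence bound) of a belief given data and predictions
#'
#' `F = expected log-likelihood - KL(posterior || prior)`, the quantity
#' maximized by [variational_laplace()].  The expected log-likelihood
#' (accuracy) penalizes residuals under the noise model; the KL term
#' (complexity) penalizes deviation of the posterior from the prior.
#'
#' @param y data vector.
#' @param prediction model prediction at the posterior mean.
#' @param belief posterior [gaussian_belief()].
#' @param prior prior [gaussian_belief()].
#' @param noise a [noise_model()]; hyperparameters at their prior mean (or
#'   fixed precision).
#' @param jacobian optional Jacobian matrix at the posterior mean, for the
#'   curvature correction of the expected log-likelihood; defaults to
#'   zero (no correction).
#' @return List with `free_energy`, `accuracy`, `complexity`.
#' @export
free_energy <- function(y, prediction, belief, prior, noise,
                        jacobian = NULL) {
  if (length(y) != length(prediction)) stop("mismatched dimensions")
  if (length(belief$mean) != length(prior$mean))
    stop("mismatched parameter dimensions")
  n <- length(y)
  w <- if (!is.null(noise$fixed)) rep(noise$fixed, length.out = n)
       else exp(rep(noise$lambda0, noise$n_groups))[noise$groups]
  if (is.null(jacobian)) jacobian <- matrix(0, n, length(belief$mean))
  P0 <- chol2inv(chol(prior$cov))
  e <- y - prediction
  JtWJ <- crossprod(jacobian * w, jacobian)
  accuracy <- -0.5 * sum(w * e ^ 2) + 0.5 * sum(log(w)) -
    n / 2 * log(2 * pi) - 0.5 * sum(belief$cov * JtWJ)
  d <- belief$mean - prior$mean
  complexity <- 0.5 * (sum(belief$cov * P0) + drop(t(d) %*% P0 %*% d) -
                         length(d) + logdet_chol(prior$cov) -
                         logdet_chol(belief$cov))
  list(free_energy = accuracy - complexity, accuracy = accuracy,
       complexity = complexity)
}
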