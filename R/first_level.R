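#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF: a gamma density (shape `peak1`, unit rate) minus
#' 1/`ratio` of a gamma density (shape `peak2`) for the late undershoot,
#' scaled to approximately unit peak.
#'
#' @param t time in seconds (vectorized; zero before stimulus onset).
#' @param peak1,peak2 gamma shape parameters (delay of response and of
#'   undershoot, in seconds).
#' @param ratio response : undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak1 = 6, peak2 = 16, ratio = 6) {
  h <- ifelse(t <= 0, 0,
              stats::dgamma(t, shape = peak1, rate = 1) -
                stats::dgamma(t, shape = peak2, rate = 1) / ratio)
  h / max(stats::dgamma(peak1 - 1 + 1e-9, shape = peak1, rate = 1), 1e-12)
}

#' Build a sparse-sampled GLM design matrix
#'
#' Each stimulus is modeled as a delta function at its onset, convolved
#' with the canonical HRF on a fine time grid, then sampled at the volume
#' acquisition times.  Motion covariates and per-run intercepts are
#' appended as covariates of no interest.
#'
#' @param events data frame with columns `onset` (s, session time),
#'   `condition` (factor/character), and optionally `run`.
#' @param acquisition_times volume acquisition times in seconds (session
#'   time), strictly increasing.
#' @param motion optional matrix of motion covariates (one row per scan).
#' @param runs optional integer vector assigning each scan to a run;
#'   per-run intercepts are added when present.
#' @return A list of class `"design_matrix"` with `X` (scans x regressors),
#'   `condition_cols`, `nuisance_cols`, and `acquisition_times`.  Because
#'   stimuli are delta functions, the convolution on a fine grid reduces to
#'   evaluating the HRF at (scan time - onset), which is done exactly.
#' @export
build_design <- function(events, acquisition_times, motion = NULL,
                         runs = NULL) {
  if (any(diff(acquisition_times) <= 0))
    stop("acquisition times must be strictly increasing")
  if (nrow(events) > 0 &&
      (any(events$onset < 0) ||
       any(events$onset > max(acquisition_times))))
    stop("event onsets outside the acquisition window")
  conds <- if (nrow(events)) sort(unique(as.character(events$condition)))
           else character(0)
  nscan <- length(acquisition_times)
  Xc <- matrix(0, nscan, length(conds),
               dimnames = list(NULL, conds))
  for (cn in conds) {
    on <- events$onset[as.character(events$condition) == cn]
    col <- numeric(nscan)
    for (o in on) col <- col + canonical_hrf(acquisition_times - o)
    Xc[, cn] <- col
  }
  Xn <- NULL
  if (!is.null(runs)) {
    runs <- as.integer(factor(runs))
    Xr <- stats::model.matrix(~ 0 + factor(runs))
    colnames(Xr) <- paste0("run", seq_len(ncol(Xr)))
    Xn <- Xr
  } else {
    Xn <- matrix(1, nscan, 1, dimnames = list(NULL, "intercept"))
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    Xn <- cbind(Xn, motion)
  }
  X <- cbind(Xc, Xn)
  structure(list(X = X, condition_cols = conds,
                 nuisance_cols = colnames(Xn),
                 acquisition_times = acquisition_times),
            class = "design_matrix")
}

#' GLM t statistics for a contrast, per region
#'
#' Ordinary least squares fit of each region's timeseries on the design,
#' with `t = c'b / se(c'b)`.  With zero residual variance the t value is
#' capped at a large finite value and a warning is raised.
#'
#' @param Y scans x regions matrix (or vector) of timeseries.
#' @param design a `"design_matrix"` from [build_design()] or a plain
#'   matrix.
#' @param contrast numeric contrast vector over the design columns; it may
#'   also be given over the condition columns only, in which case nuisance
#'   columns receive zero weight.
#' @return Data frame with `region`, `estimate`, `t`, `df`, `p`.
#' @export
glm_contrast <- function(Y, design, contrast) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (length(contrast) == length(if (inherits(design, "design_matrix"))
                                 design$condition_cols else integer(0)))
    contrast <- c(contrast, rep(0, ncol(X) - length(contrast)))
  if (length(contrast) != ncol(X))
    stop("contrast length does not match design columns")
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  beta[is.na(beta)] <- 0
  fit <- X %*% beta
  res <- Y - fit
  df <- nrow(X) - qrX$rank
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res ^ 2) / df
  XtXi <- chol2inv(qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank),
                             drop = FALSE])
  # map back to full column order (pivoting)
  cvar <- numeric(1)
  piv <- qrX$pivot[seq_len(qrX$rank)]
  cfull <- contrast[piv]
  cvar <- drop(t(cfull) %*% XtXi %*% cfull)
  est <- drop(t(contrast) %*% beta)
  # numerically exact fits: residual variance at rounding-error scale
  tiny <- 1e-16 * pmax(colMeans(Y ^ 2), 1e-300)
  se <- sqrt(pmax(sigma2 * cvar, 0))
  tval <- ifelse(se > 0, est / se, 0)
  zerovar <- sigma2 <= tiny & abs(est) > 1e-12
  if (any(zerovar)) {
    warning("zero residual variance; t capped at 1e6 (df = ", df, ")")
    tval[zerovar] <- sign(est[zerovar]) * 1e6
    se[zerovar] <- 0
  }
  data.frame(region = colnames(Y) %||% paste0("V", seq_len(ncol(Y))),
             estimate = est, t = tval, df = df,
             p = 2 * stats::pt(-abs(tval), df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal eigenvariate of a multivoxel region
#'
#' First right-singular-vector summary of a voxels x scans matrix, scaled
#' to unit variance, with the sign chosen so the summary correlates
#' positively with the voxel-mean timeseries.
#'
#' @param Y voxels x scans matrix.
#' @return Numeric summary timeseries (length = scans) with unit variance.
#' @export
principal_eigenvariate <- function(Y) {
  Y <- as.matrix(Y)
  s <- svd(scale(t(Y), center = TRUE, scale = FALSE), nu = 1, nv = 0)
  ev <- s$u[, 1]
  m <- colMeans(Y)
  if (stats::sd(m) > 0 && stats::cor(ev, m) < 0) ev <- -ev
  as.numeric(ev / stats::sd(ev))
}

#' Canonical variate analysis of a multivariate response
#'
#' Tests for linear association between the span of the design contrast
#' and a multivariate (e.g., multivoxel) response, after projecting out
#' the remaining (nuisance) design columns.  Significance of the canonical
#' correlations uses Bartlett's chi-square approximation to Wilks' lambda.
#'
#' @param Y scans x voxels response matrix.
#' @param X scans x regressors design matrix.
#' @param contrast matrix (or vector) whose columns span the subspace of
#'   interest in design-column space.
#' @return A list of class `"cva_result"` with `correlations` (nonincreasing,
#'   in \[0,1\]), `chi_square`, `df`, `p_value`.
#' @export
cva <- function(Y, X, contrast) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  cmat <- as.matrix(contrast)
  if (nrow(cmat) != ncol(X)) stop("contrast rows must match design columns")
  n <- nrow(Y)
  if (ncol(Y) >= n) stop("more response dimensions than observations")
  X1 <- X %*% cmat                       # subspace of interest
  # project out the null-space-of-interest part of the design
  c0 <- diag(ncol(X)) - cmat %*% MASS_ginv(cmat)
  X0 <- X %*% c0
  keep <- colSums(abs(X0)) > 1e-10
  if (any(keep)) {
    X0 <- X0[, keep, drop = FALSE]
    R0 <- diag(n) - X0 %*% MASS_ginv(X0)
    Y <- R0 %*% Y
    X1 <- R0 %*% X1
  }
  cc <- stats::cancor(X1, Y)
  r <- pmin(pmax(cc$cor, 0), 1)
  p <- qr(X1)$rank
  q <- qr(Y)$rank
  lambda <- prod(1 - r ^ 2)
  chi <- -(n - 1 - (p + q + 1) / 2) * log(max(lambda, 1e-300))
  df <- p * q
  structure(list(correlations = r, chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE)),
            class = "cva_result")
}

# Moore-Penrose pseudoinverse (small matrices only)
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Combine independent p-values with Fisher's method
#'
#' @param p_values vector of independent p-values.
#' @return A list with `chi_square` (`-2 * sum(log(p))`), `df` (`2k`), and
#'   the combined `p_value`.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("no p-values supplied")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  chi <- -2 * sum(log(pmax(p_values, 1e-300)))
  df <- 2L * length(p_values)
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Select region voxels by combined group and subject thresholds
#'
#' Reproduces a two-stage timeseries-selection rule: voxels must survive a
#' family-wise-error-corrected group threshold (functional mask) and an
#' uncorrected subject-level threshold; when no voxel in the region
#' survives, the subject threshold is relaxed in steps of `step` until at
#' least one voxel does.
#'
#' @param group_p vector of group-level FWE-corrected p-values per voxel.
#' @param subject_p vector of subject-level uncorrected p-values per voxel.
#' @param group_alpha group-level threshold (default 0.05).
#' @param subject_alpha initial subject-level threshold (default 0.05).
#' @param step relaxation increment for the subject threshold.
#' @return A list with `voxels` (indices of retained voxels) and
#'   `subject_alpha_used`.
#' @export
select_voxels <- function(group_p, subject_p, group_alpha = 0.05,
                          subject_alpha = 0.05, step = 0.05) {
  if (length(group_p) != length(subject_p))
    stop("group and subject p-value vectors must match")
  mask <- group_p < group_alpha
  if (!any(mask)) stop("no voxels survive the group-level threshold")
  alpha <- subject_alpha
  repeat {
    vox <- which(mask & subject_p < alpha)
    if (length(vox)) return(list(voxels = vox, subject_alpha_used = alpha))
    alpha <- alpha + step
    if (alpha > 1 + step) stop("no voxels survive any subject threshold")
  }
}
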