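#' Specification of the free parameters of a DCM
#'
#' Defines which entries of the A/B/C matrices and which hemodynamic
#' constants are free when inverting the model.  The default is the fully
#' connected model: all extrinsic connections and self log-scalings in A,
#' modulation of every intrinsic and extrinsic connection by difficulty
#' and by the task-by-difficulty interaction in B, driving weights for all
#' four inputs in C, and per-region log-scalings of transit time `tau` and
#' signal decay `kappa`.
#'
#' @param regions region labels (see [dcm_regions()]).
#' @param b_inputs inputs allowed to modulate connections.
#' @param a_mask logical regions x regions matrix of enabled A entries
#'   (diagonal = self log-scalings); default all `TRUE`.
#' @param b_masks named list of logical masks per modulatory input;
#'   default all `TRUE`.
#' @param c_mask logical regions x inputs matrix of enabled driving
#'   weights; default all `TRUE`.
#' @param hemo_free character subset of `c("tau", "kappa")` with free
#'   per-region log-scalings.
#' @return Object of class `"dcm_model_spec"` with a fixed parameter
#'   packing order and names.
#' @export
dcm_model_spec <- function(regions = dcm_regions(),
                           b_inputs = c("difficulty", "interaction"),
                           a_mask = NULL, b_masks = NULL, c_mask = NULL,
                           hemo_free = c("tau", "kappa")) {
  n <- length(regions)
  inputs <- dcm_input_names()
  if (!all(b_inputs %in% inputs)) stop("unknown modulatory input")
  if (is.null(a_mask)) a_mask <- matrix(TRUE, n, n)
  if (is.null(b_masks))
    b_masks <- stats::setNames(replicate(length(b_inputs),
                                         matrix(TRUE, n, n),
                                         simplify = FALSE), b_inputs)
  if (is.null(c_mask)) c_mask <- matrix(TRUE, n, length(inputs))
  nm <- character(0)
  # A: off-diagonals then self log-scalings
  off <- which(a_mask & row(a_mask) != col(a_mask))
  nm <- c(nm, sprintf("A.%s<-%s", regions[row(a_mask)[off]],
                      regions[col(a_mask)[off]]))
  self <- which(diag(a_mask))
  nm <- c(nm, sprintf("A.%s.self", regions[self]))
  bidx <- list()
  for (b in b_inputs) {
    mask <- b_masks[[b]]
    idx <- which(mask)
    bidx[[b]] <- idx
    lab <- ifelse(row(mask)[idx] == col(mask)[idx],
                  sprintf("B.%s.%s.self", b, regions[row(mask)[idx]]),
                  sprintf("B.%s.%s<-%s", b, regions[row(mask)[idx]],
                          regions[col(mask)[idx]]))
    nm <- c(nm, lab)
  }
  cidx <- which(c_mask)
  nm <- c(nm, sprintf("C.%s.%s", inputs[col(c_mask)[cidx]],
                      regions[row(c_mask)[cidx]]))
  for (hp in hemo_free) nm <- c(nm, sprintf("hemo.%s.%s", hp, regions))
  structure(list(regions = regions, inputs = inputs, b_inputs = b_inputs,
                 a_mask = a_mask, b_masks = b_masks, c_mask = c_mask,
                 hemo_free = hemo_free,
                 a_off = off, a_self = self, b_idx = bidx, c_idx = cidx,
                 names = nm, n_par = length(nm)),
            class = "dcm_model_spec")
}

#' Unpack a parameter vector into a [dcm_params()] object
#'
#' @param theta parameter vector in the packing order of
#'   [dcm_model_spec()].
#' @param spec the model specification.
#' @param hemo_base baseline hemodynamic constants; free `tau`/`kappa`
#'   entries are multiplied by `exp(theta)`.
#' @param te echo time (s).
#' @return A [dcm_params()] object.
#' @export
theta_to_params <- function(theta, spec, hemo_base = NULL, te = 0.03) {
  n <- length(spec$regions)
  if (length(theta) != spec$n_par) stop("theta has wrong length")
  if (is.null(hemo_base)) hemo_base <- hemo_params(n)
  pos <- 0L
  take <- function(k) {
    out <- theta[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  A <- matrix(0, n, n)
  A[spec$a_off] <- take(length(spec$a_off))
  diag(A)[spec$a_self] <- take(length(spec$a_self))
  B <- stats::setNames(replicate(length(spec$b_inputs), matrix(0, n, n),
                                 simplify = FALSE), spec$b_inputs)
  for (b in spec$b_inputs) B[[b]][spec$b_idx[[b]]] <-
    take(length(spec$b_idx[[b]]))
  C <- matrix(0, n, length(spec$inputs))
  C[spec$c_idx] <- take(length(spec$c_idx))
  hemo <- hemo_base
  for (hp in spec$hemo_free) hemo[, hp] <- hemo[, hp] * exp(take(n))
  dcm_params(A = A, B = B, C = C, hemo = hemo, te = te,
             regions = spec$regions)
}

#' Shrinkage priors over DCM parameters
#'
#' Weakly informative, stability-preserving zero-mean Gaussian priors:
#' extrinsic A entries N(0, 1/64) Hz, self log-scalings N(0, 1/256),
#' modulations N(0, 1/4) (a prior SD of 0.5 accommodates disinhibition of
#' the magnitude reported for difficulty effects without destabilizing
#' the self-connections), driving weights N(0, 1), hemodynamic
#' log-scalings N(0, 1/256).
#'
#' @param spec a [dcm_model_spec()].
#' @param a_off_var,a_self_var,b_var,c_var,hemo_var prior variances per
#'   parameter class.
#' @return A [gaussian_belief()] prior.
#' @export
dcm_priors <- function(spec, a_off_var = 1 / 64, a_self_var = 1 / 256,
                       b_var = 1 / 4, c_var = 1, hemo_var = 1 / 256) {
  v <- c(rep(a_off_var, length(spec$a_off)),
         rep(a_self_var, length(spec$a_self)),
         rep(b_var, sum(lengths(spec$b_idx))),
         rep(c_var, length(spec$c_idx)),
         rep(hemo_var, length(spec$hemo_free) * length(spec$regions)))
  m <- stats::setNames(rep(0, spec$n_par), spec$names)
  gaussian_belief(mean = m, cov = diag(v, spec$n_par))
}

# residual-forming projector of the confound space (run intercepts plus
# any motion covariates)
confound_projector <- function(run, confounds = NULL) {
  lev <- unique(run)
  X0 <- vapply(lev, function(r) as.numeric(run == r), numeric(length(run)))
  if (!is.null(confounds)) X0 <- cbind(X0, as.matrix(confounds))
  diag(length(run)) - X0 %*% MASS_ginv(X0)
}

#' Fit a DCM to one subject's region timeseries by variational Laplace
#'
#' Run intercepts and any motion covariates are projected out of both the
#' data and the model prediction before computing residuals, and the
#' noise model carries one log-precision per region.  The finite-
#' difference Jacobian drives Gauss-Newton ascent on the free energy.
#'
#' @param ts an `"roi_timeseries"` (or scans x regions matrix with a
#'   `run` argument).
#' @param inputs a [dcm_inputs()] object matching the timeseries.
#' @param spec a [dcm_model_spec()]; defaults to the fully connected model
#'   over the timeseries regions.
#' @param priors a [gaussian_belief()] prior; defaults to [dcm_priors()].
#' @param confounds optional scans x k matrix of nuisance covariates.
#' @param run run assignment per scan (taken from `ts` when it is an
#'   `"roi_timeseries"`).
#' @param max_iter,tol Gauss-Newton iteration cap and `|dF|` tolerance.
#' @param fd finite-difference scheme for the Jacobian (`"central"` or
#'   `"forward"`; see [variational_laplace()]).
#' @param verbose print the free-energy trace.
#' @return A [gaussian_belief()] posterior with attributes `spec` and
#'   `regions`; parameter names follow `spec$names`.
#' @export
dcm_fit <- function(ts, inputs, spec = NULL, priors = NULL,
                    confounds = NULL, run = NULL, max_iter = 64,
                    tol = 0.01, fd = c("central", "forward"),
                    verbose = FALSE) {
  if (inherits(ts, "roi_timeseries")) {
    Y <- ts$data
    run <- ts$run
    regions <- ts$regions
  } else {
    Y <- as.matrix(ts)
    if (is.null(run)) run <- rep(1L, nrow(Y))
    regions <- colnames(Y) %||% dcm_regions(ncol(Y))
  }
  if (is.null(spec)) spec <- dcm_model_spec(regions = regions)
  if (is.null(priors)) priors <- dcm_priors(spec)
  R0 <- confound_projector(run, confounds)
  yv <- as.vector(R0 %*% Y)
  n <- length(spec$regions)
  predict_fn <- function(theta) {
    params <- theta_to_params(theta, spec)
    as.vector(R0 %*% integrate_and_sample(params, inputs)$data)
  }
  noise <- noise_model(groups = rep(seq_len(n), each = nrow(Y)))
  post <- variational_laplace(predict_fn, yv, priors, noise,
                              max_iter = max_iter, tol = tol, fd = fd,
                              verbose = verbose)
  attr(post, "spec") <- spec
  attr(post, "regions") <- spec$regions
  post
}

#' Write a fitted posterior to JSON
#'
#' @param post a [gaussian_belief()] posterior from [dcm_fit()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_posterior_json <- function(post, path) {
  jsonlite::write_json(
    list(parameters = as.list(post$mean),
         covariance = unname(as.matrix(post$cov)),
         free_energy = post$free_energy,
         lambda = post$lambda,
         trace = post$trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a posterior written by [write_posterior_json()]
#'
#' @param path JSON file path.
#' @return A [gaussian_belief()].
#' @export
read_posterior_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gaussian_belief(mean = unlist(x$parameters), cov = x$covariance,
                  free_energy = x$free_energy, lambda = x$lambda,
                  trace = x$trace)
}
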