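#' Region labels of the auditory-cortex network
#'
#' Left and right core (Te1.0), posteromedial belt (Te1.1), anterolateral
#' belt (Te1.2), and higher auditory cortex (Te3).
#'
#' @param n_regions 8 for the bilateral network, 4 for the left hemisphere
#'   only.
#' @return Character vector of region labels.
#' @export
dcm_regions <- function(n_regions = 8) {
  full <- c("lTe1.0", "lTe1.1", "lTe1.2", "lTe3",
            "rTe1.0", "rTe1.1", "rTe1.2", "rTe3")
  if (n_regions == 8) full else full[seq_len(n_regions)]
}

#' Input names of the task design
#'
#' Driving/modulatory inputs: all trials, the task main effect, the
#' difficulty main effect, and the task-by-difficulty interaction.  Only
#' difficulty and the interaction modulate connections; all four may drive.
#' @return Character vector of the four input names.
#' @export
dcm_input_names <- function() c("trials", "task", "difficulty", "interaction")

#' Per-region hemodynamic (balloon model) constants
#'
#' Canonical values: signal decay `kappa` = 0.64/s, feedback rate `gamma` =
#' 0.32/s, transit time `tau` = 2 s, stiffness exponent `alpha` = 0.32,
#' resting oxygen extraction `E0` = 0.4, resting venous volume fraction
#' `V0` = 0.04, intra/extravascular ratio `epsilon` = 1.
#'
#' @param n_regions number of regions (rows).
#' @param kappa,gamma,tau,alpha,E0,V0,epsilon scalar or per-region values.
#' @return Matrix `n_regions` x 7 with named columns.
#' @export
hemo_params <- function(n_regions = 8, kappa = 0.64, gamma = 0.32, tau = 2,
                        alpha = 0.32, E0 = 0.4, V0 = 0.04, epsilon = 1) {
  h <- cbind(kappa = rep(kappa, length.out = n_regions),
             gamma = rep(gamma, length.out = n_regions),
             tau = rep(tau, length.out = n_regions),
             alpha = rep(alpha, length.out = n_regions),
             E0 = rep(E0, length.out = n_regions),
             V0 = rep(V0, length.out = n_regions),
             epsilon = rep(epsilon, length.out = n_regions))
  if (any(h[, c("kappa", "gamma", "tau", "V0", "epsilon")] <= 0) ||
      any(h[, "E0"] <= 0) || any(h[, "E0"] >= 1) ||
      any(h[, "alpha"] <= 0) || any(h[, "alpha"] >= 1))
    stop("hemodynamic constants out of range")
  h
}

#' Generative-model parameters (A/B/C matrices plus hemodynamics)
#'
#' The neural model is `dz/dt = Abar(u) z + C u`.  Off-diagonal entries of
#' `Abar(u)` are `A[i,k] + sum_j u_j B_j[i,k]` (extrinsic coupling, Hz);
#' diagonal entries are parameterized as log-scalings of a -0.5 Hz
#' baseline, `-0.5 * exp(A[i,i] + sum_j u_j B_j[i,i])`, so self-connections
#' remain negative for all inputs and negative modulation values mean
#' disinhibition (slower decay, higher gain).
#'
#' @param A square coupling matrix; diagonal entries are the self
#'   log-scalings (unitless), off-diagonals extrinsic rates in Hz.
#' @param B named list of modulation matrices, one per modulatory input
#'   (`"difficulty"`, `"interaction"`); same self/off-diagonal convention.
#' @param C driving-input weight matrix, regions x inputs (columns in
#'   [dcm_input_names()] order).
#' @param hemo per-region hemodynamic constants from [hemo_params()].
#' @param te echo time in seconds, used by the BOLD observation equation.
#' @param regions region labels.
#' @return Object of class `"dcm_params"`.
#' @export
dcm_params <- function(A = NULL, B = NULL, C = NULL, hemo = NULL, te = 0.03,
                       regions = dcm_regions()) {
  n <- length(regions)
  inputs <- dcm_input_names()
  if (is.null(A)) A <- matrix(0, n, n)
  if (is.null(B))
    B <- list(difficulty = matrix(0, n, n),
              interaction = matrix(0, n, n))
  if (is.null(C)) C <- matrix(0, n, length(inputs))
  if (!all(dim(A) == c(n, n))) stop("A must be ", n, " x ", n)
  for (bm in B) if (!all(dim(bm) == c(n, n))) stop("B matrices must match A")
  if (!all(dim(C) == c(n, length(inputs)))) stop("C must be regions x inputs")
  if (is.null(hemo)) hemo <- hemo_params(n)
  if (!all(is.finite(A)) || !all(vapply(B, function(x) all(is.finite(x)),
                                        TRUE)) || !all(is.finite(C)))
    stop("non-finite parameters")
  dimnames(A) <- list(regions, regions)
  B <- lapply(B, function(bm) { dimnames(bm) <- list(regions, regions); bm })
  dimnames(C) <- list(regions, inputs)
  rownames(hemo) <- regions
  structure(list(A = A, B = B, C = C, hemo = hemo, te = te,
                 regions = regions, inputs = inputs),
            class = "dcm_params")
}

#' @export
print.dcm_params <- function(x, ...) {
  cat(sprintf("DCM parameters: %d regions, inputs: %s; modulatory: %s\n",
              length(x$regions), paste(x$inputs, collapse = ", "),
              paste(names(x$B), collapse = ", ")))
  cat(sprintf("  nonzero A off-diagonals: %d, nonzero B entries: %d\n",
              sum(x$A[row(x$A) != col(x$A)] != 0),
              sum(vapply(x$B, function(b) sum(b != 0), 0))))
  invisible(x)
}

# full m-input modulation list (zero matrices for driving-only inputs)
expand_B <- function(params) {
  n <- length(params$regions)
  lapply(params$inputs, function(nm)
    if (!is.null(params$B[[nm]])) params$B[[nm]] else matrix(0, n, n))
}

# effective coupling matrix at input u
coupling_at <- function(params, u) {
  Bfull <- expand_B(params)
  M <- params$A
  for (j in seq_along(u)) M <- M + u[j] * Bfull[[j]]
  diag(M) <- -0.5 * exp(diag(M))
  M
}

#' Neural state derivative of the bilinear model
#'
#' @param z neural state vector (one per region).
#' @param u input vector (length = number of inputs).
#' @param params a [dcm_params()] object.
#' @return `dz/dt` in Hz.
#' @export
neural_derivative <- function(z, u, params) {
  if (length(z) != length(params$regions)) stop("z has wrong length")
  if (length(u) != length(params$inputs)) stop("u has wrong length")
  unname(drop(coupling_at(params, u) %*% z + params$C %*% u))
}

#' Hemodynamic state derivative (balloon model)
#'
#' States: vasodilatory signal `s`, blood inflow `f`, venous volume `v`,
#' deoxyhemoglobin content `q`.  `ds/dt = z - kappa s - gamma (f - 1)`;
#' `df/dt = s`; `tau dv/dt = f - v^(1/alpha)`; `tau dq/dt =
#' f (1 - (1-E0)^(1/f)) / E0 - v^(1/alpha) q / v`.
#'
#' @param h state vector `c(s, f, v, q)` (f, v, q positive).
#' @param z neural input (scalar).
#' @param hemo named vector/one-row matrix of hemodynamic constants
#'   (columns of [hemo_params()]).
#' @return `dh/dt` as a length-4 vector.
#' @export
hemo_derivative <- function(h, z, hemo = hemo_params(1)[1, ]) {
  hemo <- drop(hemo)
  s <- h[1]; f <- h[2]; v <- h[3]; q <- h[4]
  if (f <= 0 || v <= 0 || q <= 0) stop("f, v, q must be positive")
  fv <- v ^ (1 / hemo["alpha"])
  Ef <- 1 - (1 - hemo["E0"]) ^ (1 / f)
  unname(c(z - hemo["kappa"] * s - hemo["gamma"] * (f - 1),
           s,
           (f - fv) / hemo["tau"],
           (f * Ef / hemo["E0"] - fv * q / v) / hemo["tau"]))
}

#' BOLD observation equation
#'
#' `y = V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v))` in percent signal
#' change, with `k1 = 4.3 * 40.3 * E0 * TE`, `k2 = epsilon * 25 * E0 * TE`,
#' `k3 = 1 - epsilon` (classical coefficients for 3 T).
#'
#' @param h state vector `c(s, f, v, q)` or a matrix with those columns.
#' @param hemo hemodynamic constants (as in [hemo_derivative()]).
#' @param te echo time in seconds.
#' @return BOLD signal in percent.
#' @export
bold_observation <- function(h, hemo = hemo_params(1)[1, ], te = 0.03) {
  hemo <- drop(hemo)
  if (is.null(dim(h))) h <- matrix(h, 1)
  v <- h[, 3]; q <- h[, 4]
  k1 <- 4.3 * 40.3 * hemo[["E0"]] * te
  k2 <- hemo[["epsilon"]] * 25 * hemo[["E0"]] * te
  k3 <- 1 - hemo[["epsilon"]]
  drop(100 * hemo[["V0"]] *
         (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v)))
}

#' Build the input set (fine-grid regressors) for a DCM
#'
#' Converts an event table into piecewise-constant inputs on the
#' integration grid, one block per run.  Events are boxcars of their
#' stated duration.  Coding: `trials` = 1 during any stimulus; `task` =
#' +1/2 for speech-in-noise, -1/2 for figure-ground; `difficulty` = +1/2
#' for the hard (60%-threshold) conditions, -1/2 for the easy (90%)
#' conditions; `interaction` = product of the two codings.  Onsets and
#' acquisition times are snapped to the integration grid.
#'
#' @param events data frame with columns `run`, `onset` (s, within-run),
#'   `duration` (s), `condition` (one of `"SFG-60"`, `"SFG-90"`,
#'   `"SPIN-60"`, `"SPIN-90"`).
#' @param acquisition_times data frame with columns `run` and `time`
#'   (within-run volume onset times, s), or `NULL` to place one volume per
#'   8 s trial at 4.64 s (sparse sampling).
#' @param run_dur run duration in seconds.
#' @param dt integration step in seconds (at most 0.1).
#' @return Object of class `"dcm_inputs"`: per-run input matrices `u`
#'   (inputs x steps), per-run `sample_steps`, `dt`, and bookkeeping.
#' @export
dcm_inputs <- function(events, acquisition_times = NULL, run_dur = 192,
                       dt = 0.05) {
  if (dt > 0.1) stop("fine step must be at most 0.1 s")
  runs <- sort(unique(events$run))
  if (is.null(acquisition_times)) {
    acquisition_times <- do.call(rbind, lapply(runs, function(r) {
      nt <- floor(run_dur / 8)
      data.frame(run = r, time = (seq_len(nt) - 1) * 8 + 4.64)
    }))
  }
  code <- function(cond) {
    task <- ifelse(grepl("^SPIN", cond), 0.5, -0.5)
    diff <- ifelse(grepl("-60$", cond), 0.5, -0.5)
    cbind(trials = 1, task = task, difficulty = diff,
          interaction = task * diff)
  }
  nT <- round(run_dur / dt)
  u <- list(); sample_steps <- list()
  for (r in runs) {
    ev <- events[events$run == r, , drop = FALSE]
    ur <- matrix(0, 4, nT, dimnames = list(dcm_input_names(), NULL))
    if (nrow(ev)) {
      cd <- code(as.character(ev$condition))
      for (i in seq_len(nrow(ev))) {
        a <- round(ev$onset[i] / dt) + 1L
        b <- min(round((ev$onset[i] + ev$duration[i]) / dt), nT)
        if (b >= a) ur[, a:b] <- ur[, a:b] + cd[i, ]
      }
    }
    at <- acquisition_times$time[acquisition_times$run == r]
    u[[as.character(r)]] <- ur
    sample_steps[[as.character(r)]] <- as.integer(round(at / dt))
  }
  structure(list(u = u, sample_steps = sample_steps, dt = dt,
                 runs = runs, run_dur = run_dur,
                 acquisition_times = acquisition_times,
                 input_names = dcm_input_names()),
            class = "dcm_inputs")
}

# pure-R RK4 reference integrator for one run (slow; used for cross-checks)
integrate_run_r <- function(params, ur, sample_steps, dt) {
  n <- length(params$regions)
  Bfull <- expand_B(params)
  x <- rep(0, 5 * n)                      # z, s, log f, log v, log q
  deriv <- function(x, M, Cu) {
    z <- x[1:n]; s <- x[n + 1:n]
    f <- exp(x[2 * n + 1:n]); v <- exp(x[3 * n + 1:n])
    q <- exp(x[4 * n + 1:n])
    h <- params$hemo
    fv <- exp(x[3 * n + 1:n] / h[, "alpha"])
    Ef <- 1 - (1 - h[, "E0"]) ^ (1 / f)
    c(M %*% z + Cu,
      z - h[, "kappa"] * s - h[, "gamma"] * (f - 1),
      s / f,
      (f - fv) / (h[, "tau"] * v),
      (f * Ef / h[, "E0"] / q - fv / v) / h[, "tau"])
  }
  bold <- function(x) {
    v <- exp(x[3 * n + 1:n]); q <- exp(x[4 * n + 1:n])
    h <- params$hemo
    k1 <- 4.3 * 40.3 * h[, "E0"] * params$te
    k2 <- h[, "epsilon"] * 25 * h[, "E0"] * params$te
    k3 <- 1 - h[, "epsilon"]
    100 * h[, "V0"] * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
  }
  nT <- ncol(ur)
  Y <- matrix(0, length(sample_steps), n)
  isamp <- 1L
  while (isamp <= length(sample_steps) && sample_steps[isamp] == 0) {
    Y[isamp, ] <- bold(x); isamp <- isamp + 1L
  }
  ulast <- rep(NA_real_, nrow(ur))
  M <- NULL; Cu <- NULL
  for (step in seq_len(nT)) {
    uk <- ur[, step]
    if (!identical(uk, ulast)) {
      M <- params$A
      for (j in seq_along(uk)) M <- M + uk[j] * Bfull[[j]]
      diag(M) <- -0.5 * exp(diag(M))
      Cu <- drop(params$C %*% uk)
      ulast <- uk
    }
    k1 <- deriv(x, M, Cu)
    k2 <- deriv(x + dt / 2 * k1, M, Cu)
    k3 <- deriv(x + dt / 2 * k2, M, Cu)
    k4 <- deriv(x + dt * k3, M, Cu)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(x)) || sum(x ^ 2) > 1e12)
      stop("unstable integration in R reference integrator")
    while (isamp <= length(sample_steps) && sample_steps[isamp] == step) {
      Y[isamp, ] <- bold(x); isamp <- isamp + 1L
    }
  }
  Y
}

#' Integrate the joint model and sample BOLD at acquisition times
#'
#' Integrates the neural + hemodynamic system over each run with a
#' fixed-step 4th-order Runge-Kutta scheme (each run starts from rest) and
#' returns the predicted BOLD signal only at the sparse acquisition times.
#'
#' @param params a [dcm_params()] object.
#' @param inputs a [dcm_inputs()] object.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation, slow; for cross-checks).
#' @return Object of class `"roi_timeseries"`: list with `data` (scans x
#'   regions matrix), `run` (run of each scan), `regions`, `tr` (3.36 s),
#'   `scan_period` (8 s), `acquisition_times`.
#' @export
integrate_and_sample <- function(params, inputs, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  Bfull <- expand_B(params)
  out <- lapply(seq_along(inputs$runs), function(ri) {
    key <- as.character(inputs$runs[ri])
    if (engine == "cpp")
      dcm_integrate_cpp(params$A, Bfull, params$C, inputs$u[[key]],
                        params$hemo, inputs$dt,
                        inputs$sample_steps[[key]], params$te)
    else
      integrate_run_r(params, inputs$u[[key]], inputs$sample_steps[[key]],
                      inputs$dt)
  })
  data <- do.call(rbind, out)
  colnames(data) <- params$regions
  run <- rep(inputs$runs, vapply(out, nrow, 0L))
  structure(list(data = data, run = run, regions = params$regions,
                 tr = 3.36, scan_period = 8,
                 acquisition_times = inputs$acquisition_times),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI timeseries: %d scans x %d regions, %d run(s)\n",
              nrow(x$data), ncol(x$data), length(unique(x$run))))
  invisible(x)
}
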