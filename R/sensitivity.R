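# Latin-hypercube / partial-rank-correlation sensitivity screen: samples
# model parameters, runs the reduced simulator at each point and ranks each
# parameter's monotone influence on the final global curvature.

#' Parameter space for the sensitivity screen
#'
#' @param ranges named list of `c(min, max)` ranges; recognised names for
#'   [run_sensitivity()] are `k_cont`, `F_ECMs`, `F_ECMc`, `k_memb`,
#'   `k_adhL`, `k_adhB`, `k_adhA`, `k_ecm`, `k_vol`
#' @param n_samples number of Latin-hypercube samples (at least
#'   `length(ranges) + 2`)
#' @param seed RNG seed for the sampling permutations
#' @return an object of class `parameter_space`
#' @export
parameter_space <- function(ranges, n_samples = 60L, seed = 1L) {
  stopifnot(is.list(ranges), length(ranges) >= 1, !is.null(names(ranges)))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] >= r[2])
      stop("range for ", nm, " must be c(min, max) with min < max")
  }
  if (n_samples < length(ranges) + 2)
    stop("n_samples must be at least n_parameters + 2")
  structure(list(ranges = ranges, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)), class = "parameter_space")
}

#' Default parameter space of the curvature screen
#'
#' Seven mechanical parameters spanning the contractility level, both ECM
#' prestrain levels and the main stiffnesses, centred on the package
#' defaults.
#'
#' @param n_samples,seed passed to [parameter_space()]
#' @return a `parameter_space`
#' @export
default_parameter_space <- function(n_samples = 60L, seed = 1L) {
  parameter_space(list(
    k_cont = c(0, 9), F_ECMs = c(0, 2), F_ECMc = c(0, 8),
    k_memb = c(15, 35), k_adhL = c(10, 30), k_ecm = c(20, 60),
    k_vol = c(2, 12)), n_samples = n_samples, seed = seed)
}

#' Latin hypercube sample of a parameter space
#'
#' Each parameter's `n_samples` values occupy distinct equal-probability
#' strata of its range, randomly permuted across rows; reproducible by the
#' space's seed.
#'
#' @param space a [parameter_space()]
#' @return `n_samples` x `n_parameters` matrix with named columns
#' @export
lhs_sample <- function(space) {
  stopifnot(inherits(space, "parameter_space"))
  p <- length(space$ranges)
  old_seed <- .Random.seed_exists()
  set.seed(space$seed)
  U <- lhs::randomLHS(space$n_samples, p)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out <- vapply(seq_len(p), function(j) {
    r <- space$ranges[[j]]
    r[1] + U[, j] * (r[2] - r[1])
  }, numeric(space$n_samples))
  out <- matrix(out, nrow = space$n_samples)
  colnames(out) <- names(space$ranges)
  out
}

#' Partial rank correlation coefficients
#'
#' For each parameter, rank-transforms all columns, removes (by linear
#' regression on ranks) the influence of the remaining parameters from both
#' the parameter and the output, and reports the correlation of the two
#' residual vectors, with a bootstrap confidence interval. PRCC lies in
#' [-1, 1] and is invariant under monotone transforms of any column.
#'
#' @param samples matrix of parameter samples (columns = parameters)
#' @param outputs numeric output vector, one value per sample row
#' @param n_boot bootstrap replicates for the confidence intervals
#' @param conf confidence level
#' @return data frame of class `sensitivity_report`: parameter, prcc, lower,
#'   upper
#' @export
prcc <- function(samples, outputs, n_boot = 500L, conf = 0.95) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(outputs), nrow(samples) >= ncol(samples) + 2)
  cs <- apply(samples, 2, function(x) stats::sd(x) == 0)
  if (any(cs))
    stop("constant parameter column(s): ",
         paste(colnames(samples)[cs], collapse = ", "))
  if (stats::sd(outputs) == 0) stop("constant output column")
  nm <- colnames(samples)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(samples)))

  prcc_one <- function(R, ry, j) {
    others <- R[, -j, drop = FALSE]
    if (ncol(others)) {
      X <- cbind(1, others)
      rj <- stats::lm.fit(X, R[, j])$residuals
      ro <- stats::lm.fit(X, ry)$residuals
    } else {
      rj <- R[, j] - mean(R[, j])
      ro <- ry - mean(ry)
    }
    if (stats::sd(rj) == 0 || stats::sd(ro) == 0) return(0)
    stats::cor(rj, ro)
  }
  all_prcc <- function(idx) {
    R <- apply(samples[idx, , drop = FALSE], 2, rank)
    ry <- rank(outputs[idx])
    vapply(seq_len(ncol(R)), function(j) prcc_one(R, ry, j), numeric(1))
  }
  est <- all_prcc(seq_along(outputs))
  boot <- matrix(NA_real_, n_boot, length(est))
  old_seed <- .Random.seed_exists()
  set.seed(20260925L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(outputs), replace = TRUE)
    boot[b, ] <- tryCatch(all_prcc(idx), error = function(e) rep(NA_real_, length(est)))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  a <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  structure(data.frame(parameter = nm, prcc = est,
                       lower = ci[1, ], upper = ci[2, ]),
            class = c("sensitivity_report", "data.frame"))
}

#' Run the curvature sensitivity screen
#'
#' Draws a Latin hypercube over the parameter space, runs the contractility
#' scenario at each point on a small tissue with a fixed short horizon, and
#' returns the PRCC of every parameter against the final global curvature.
#' Runs that blow up are excluded with a warning, provided they are fewer
#' than `max_failure_rate` of the total.
#'
#' @param space a [parameter_space()]; recognised parameter names are mapped
#'   onto the scenario (contractility level, prestrain tensions) and energy
#'   parameters (stiffnesses)
#' @param cfg tissue used for every run (default: the mini preset)
#' @param sim simulation settings (default: a fixed 8000-step horizon)
#' @param dp damping parameters
#' @param max_failure_rate tolerated fraction of failed runs
#' @return list of class `sensitivity_result`: `report` (the [prcc()]
#'   table), `samples`, `outputs`, `failed` (indices)
#' @export
run_sensitivity <- function(space = default_parameter_space(),
                            cfg = tissue_config(preset = "mini"),
                            sim = sim_config(max_steps = 8000L,
                                             convergence_window = 8000L),
                            dp = damping_params(),
                            max_failure_rate = 0.1) {
  X <- lhs_sample(space)
  outputs <- rep(NA_real_, nrow(X))
  for (r in seq_len(nrow(X))) {
    prm <- as.list(X[r, ])
    ep <- energy_params()
    if (!is.null(prm$k_memb)) ep$e_memb$k <- prm$k_memb
    if (!is.null(prm$k_adhL)) ep$e_adhL$k <- prm$k_adhL
    if (!is.null(prm$k_adhB)) ep$e_adhB$k <- prm$k_adhB
    if (!is.null(prm$k_adhA)) ep$e_adhA$k <- prm$k_adhA
    if (!is.null(prm$k_ecm)) ep$e_ecm$k <- prm$k_ecm
    if (!is.null(prm$k_vol)) ep$k_vol <- prm$k_vol
    ep$e_cont$k <- if (!is.null(prm$k_cont)) prm$k_cont else 0
    ps <- prestrain_spec(F_ECMs = if (!is.null(prm$F_ECMs)) prm$F_ECMs else 0,
                         F_ECMc = if (!is.null(prm$F_ECMc)) prm$F_ECMc else 0)
    outputs[r] <- tryCatch({
      st <- build_tissue(cfg, ep)
      st <- apply_prestrain(st, ps, ep)
      traj <- run_simulation(st, ep, dp, sim)
      traj$curvature[length(traj$curvature)]
    }, error = function(e) NA_real_)
  }
  failed <- which(!is.finite(outputs))
  if (length(failed) / nrow(X) > max_failure_rate)
    stop(length(failed), " of ", nrow(X), " runs failed")
  if (length(failed)) {
    warning(length(failed), " run(s) failed and were excluded")
    keep <- setdiff(seq_len(nrow(X)), failed)
  } else keep <- seq_len(nrow(X))
  rep_ <- prcc(X[keep, , drop = FALSE], outputs[keep])
  structure(list(report = rep_, samples = X, outputs = outputs,
                 failed = failed), class = "sensitivity_result")
}
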