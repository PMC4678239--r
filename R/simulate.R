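SECONDS_PER_HOUR <- 3600

#' Sampling specification
#'
#' Regular sampling grid for simulated or clinical time courses: a horizon in
#' hours and a density in samples per hour, optionally including t = 0.
#'
#' @param horizon_h horizon in hours (> 0).
#' @param density samples per hour (>= 1); sample times are k/density hours
#'   for k = 1..horizon_h*density, plus t0 when included.
#' @param include_t0 include the t = 0 sample (default `TRUE`).
#' @return an object of class `kin_sampling`.
#' @export
sampling_spec <- function(horizon_h, density = 6, include_t0 = TRUE) {
  stopifnot(horizon_h > 0, density >= 1)
  n <- horizon_h * density
  if (abs(n - round(n)) > 1e-9)
    stop("horizon_h * density must be an integer number of samples")
  structure(list(horizon_h = horizon_h, density = density,
                 include_t0 = isTRUE(include_t0)),
            class = "kin_sampling")
}

#' Sample times of a grid, in hours
#' @param spec a `kin_sampling`.
#' @return strictly increasing numeric vector of times (hours).
#' @export
sample_times <- function(spec) {
  k <- seq_len(round(spec$horizon_h * spec$density))
  t <- k / spec$density
  if (spec$include_t0) t <- c(0, t)
  t
}

new_trajectory <- function(times, values, output_names) {
  colnames(values) <- output_names
  structure(list(times = times, values = values, output_names = output_names),
            class = "kin_trajectory")
}

#' Simulate a kinetic model on a sampling grid
#'
#' Integrates the model with a stiff-capable solver (deSolve's `lsoda`,
#' using the package's compiled mass-action kernel) from its initial state
#' under constant stimulus switched on at t = 0, and returns the designated
#' outputs at the grid's sample times. Time is integrated in seconds
#' internally; the grid is expressed in hours. Tiny negative solver
#' overshoots are clipped to zero in the reported values only.
#'
#' @param model a `kin_model`.
#' @param spec a `kin_sampling`; default is the model's default horizon at
#'   6 samples per hour.
#' @param rtol,atol relative/absolute integrator tolerances (atol in nM).
#' @param outputs which species to report: `"declared"` (the model's
#'   output_names) or `"all"` states (used by conservation checks).
#' @param stimulus optional stimulus override (nM).
#' @return a `kin_trajectory`: times (hours) and a matrix of sampled
#'   concentrations (nM), one column per reported species.
#' @export
simulate_model <- function(model, spec = NULL, rtol = 1e-8, atol = 1e-10,
                           outputs = c("declared", "all"), stimulus = NULL) {
  stopifnot(inherits(model, "kin_model"))
  outputs <- match.arg(outputs)
  if (is.null(spec)) spec <- sampling_spec(model$default_horizon_h, 6)
  u <- if (is.null(stimulus)) model$stimulus else stimulus
  t_h <- sample_times(spec)
  t_s <- t_h * SECONDS_PER_HOUR
  solve_times <- if (t_s[1] == 0) t_s else c(0, t_s)
  sol <- deSolve::lsoda(
    y = unname(model$initial_state), times = solve_times,
    func = "kin_derivs", dllname = "kinfault", initfunc = "kin_init",
    parms = pack_network(model, u = u), rtol = rtol, atol = atol,
    maxsteps = 50000
  )
  if (nrow(sol) < length(solve_times) || anyNA(sol)) {
    t_fail <- sol[nrow(sol), 1] / SECONDS_PER_HOUR
    xn <- sqrt(sum(sol[nrow(sol), -1]^2, na.rm = TRUE))
    stop(sprintf("integration failed at t = %.4g h (state norm %.4g nM)",
                 t_fail, xn))
  }
  vals <- sol[, -1, drop = FALSE]
  if (t_s[1] != 0) vals <- vals[-1, , drop = FALSE]
  colnames(vals) <- model$state_names
  keep <- if (outputs == "declared") model$output_names else model$state_names
  vals <- vals[, keep, drop = FALSE]
  vals[vals < 0] <- 0
  new_trajectory(t_h, vals, keep)
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat(sprintf("<kin_trajectory> %d samples over [%g, %g] h; outputs: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$output_names, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.kin_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, x$values, check.names = FALSE)
}

#' Write a trajectory to CSV
#'
#' Header `time_h,<output1>,...`; values at full precision.
#' @param traj a `kin_trajectory`.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#' @param path CSV file as written by [write_trajectory()].
#' @return a `kin_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_h")
    stop("expected first column 'time_h' in ", path)
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop("times must be strictly increasing")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m) || any(!is.finite(m)))
    stop("trajectory contains missing or non-finite values")
  new_trajectory(df$time_h, m, names(df)[-1])
}
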