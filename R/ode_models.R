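#' Endothelial cell growth (logistic)
#'
#' Solves dNe/dt = lambda_e_g * Ne * (1 - Ne/theta_e) from `n0` at the first
#' requested time, using the analytic logistic solution.
#'
#' @param p [growth_params()]
#' @param n0 initial cell number at `times[1]`
#' @param times output times (h), strictly increasing
#' @return an [ang_series()] of cell numbers
#' @export
endothelial_growth <- function(p, n0, times) {
  stopifnot(inherits(p, "growth_params"), n0 >= 0)
  tt <- times - times[1]
  if (p$lambda_e_g == 0 || n0 == 0) {
    v <- rep(n0, length(tt))
  } else {
    e <- exp(p$lambda_e_g * tt)
    v <- p$theta_e * n0 * e / (p$theta_e + n0 * (e - 1))
  }
  ang_series(times, v)
}

#' Tumor cell growth (exponential)
#'
#' Solves dNT/dt = lambda_T_g * NT from `n0` at the first requested time.
#'
#' @inheritParams endothelial_growth
#' @return an [ang_series()] of cell numbers
#' @export
tumor_growth <- function(p, n0, times) {
  stopifnot(inherits(p, "growth_params"), n0 >= 0)
  ang_series(times, n0 * exp(p$lambda_T_g * (times - times[1])))
}

#' Integral of the cell trajectory over an interval
#'
#' Closed-form integral of the logistic (endothelial) or exponential
#' (tumor) cell number over `[t0, t1]`, given the cell number `n_a` at
#' `t0`. Vectorized over `n_a`, `t0`, `t1` and the rate.
#'
#' @keywords internal
#' @noRd
cell_integral <- function(kind, rate, theta, n_a, dt) {
  if (kind == "logistic") {
    ifelse(rate == 0, n_a * dt,
           (theta / rate) * log((theta + n_a * (exp(rate * dt) - 1)) / theta))
  } else {
    ifelse(rate == 0, n_a * dt, n_a * (exp(rate * dt) - 1) / rate)
  }
}

#' Advance the cell number over an interval (closed form)
#' @keywords internal
#' @noRd
cell_advance <- function(kind, rate, theta, n_a, dt) {
  if (kind == "logistic") {
    e <- exp(rate * dt)
    theta * n_a * e / (theta + n_a * (e - 1))
  } else {
    n_a * exp(rate * dt)
  }
}

#' VEGF concentration trajectory with media resets
#'
#' Integrates the VEGF kinetics between media replacements. In
#' `"consumption"` mode d\[VEGF\]/dt = -lambda_e_c * Ne(t) * \[VEGF\]; in
#' `"production"` mode d\[VEGF\]/dt = lambda_T_p * NT(t) * (1 -
#' \[VEGF\]/theta_V). At each reset time the state jumps to the baseline
#' concentration; the value recorded at a reset time is the pre-reset
#' value. The cell trajectory is supplied as a function of time (hours),
#' typically the calibrated growth-model solution.
#'
#' Integration uses `deSolve::lsoda` (adaptive, rtol 1e-8) piecewise
#' between resets, so reset discontinuities never cross an integrator
#' step.
#'
#' @param mode `"production"` or `"consumption"`
#' @param cells function of time returning the cell number, or an
#'   [ang_series()] (interpolated linearly)
#' @param k [vegf_kinetics_params()]
#' @param v0 initial concentration (pg/mL) at `times[1]`
#' @param times output times (h), strictly increasing
#' @param reset_times media replacement times (h), sorted
#' @return an [ang_series()] of concentrations (pg/mL)
#' @export
vegf_trajectory <- function(mode = c("production", "consumption"),
                            cells, k, v0, times, reset_times = numeric()) {
  mode <- match.arg(mode)
  stopifnot(inherits(k, "vegf_kinetics_params"), v0 >= 0)
  if (inherits(cells, "ang_series")) {
    s <- cells
    cells <- function(t) approx(s$time_h, s$value, xout = t, rule = 2)$y
  }
  stopifnot(is.function(cells))
  reset_times <- sort(reset_times)
  reset_times <- reset_times[reset_times > times[1] &
                               reset_times <= max(times)]

  deriv <- if (mode == "consumption") {
    function(t, y, parms) list(-k$lambda_e_c * cells(t) * y)
  } else {
    function(t, y, parms) {
      list(k$lambda_T_p * cells(t) * (1 - y / k$theta_V))
    }
  }

  bounds <- unique(c(times[1], reset_times, max(times)))
  out_t <- numeric(0)
  out_v <- numeric(0)
  v <- v0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    if (b <= a) next
    # report at requested times in (a, b]; pre-reset value at b
    want <- times[times > a & times <= b]
    grid <- sort(unique(c(a, want, b)))
    sol <- deSolve::lsoda(y = c(V = v), times = grid, func = deriv,
                          rtol = 1e-10, atol = 1e-12)
    vals <- sol[, "V"]
    keep <- grid %in% want
    out_t <- c(out_t, grid[keep])
    out_v <- c(out_v, vals[keep])
    v <- if (b %in% reset_times) k$baseline else vals[length(vals)]
  }
  if (times[1] < min(c(out_t, Inf))) {
    out_t <- c(times[1], out_t)
    out_v <- c(v0, out_v)
  }
  ang_series(out_t, pmax(out_v, 0))
}

#' Daily ELISA measurement model (closed form)
#'
#' The measured daily VEGF concentrations implied by the kinetics: starting
#' from the baseline concentration after each media replacement, the
#' concentration evolves for 24 h under the production or consumption ODE
#' with the growth-model cell trajectory, and the pre-reset value is
#' recorded. Uses the analytic solution of the linear-in-\[VEGF\] kinetics,
#' so it is vectorized over parameter vectors (`lambda`, `theta_V`) for
#' grid sweeps.
#'
#' @param mode `"production"` or `"consumption"`
#' @param gp [growth_params()]
#' @param n0 cell number at time 0
#' @param lambda production (pg/(mL h cell)) or consumption (1/(h cell))
#'   rate; may be a vector
#' @param theta_V VEGF carrying capacity (pg/mL); may be a vector
#'   (recycled against `lambda`); ignored in consumption mode
#' @param baseline post-reset concentration (pg/mL)
#' @param n_days number of daily measurements
#' @param v0 concentration at time 0 (defaults to `baseline`)
#' @return a matrix with one row per parameter set and `n_days` columns of
#'   measured concentrations (pg/mL); a vector if a single parameter set
#' @export
elisa_daily_series <- function(mode = c("production", "consumption"),
                               gp, n0, lambda, theta_V = NULL,
                               baseline = 1100, n_days = 7, v0 = baseline) {
  mode <- match.arg(mode)
  stopifnot(inherits(gp, "growth_params"), n0 >= 0)
  if (mode == "production") {
    stopifnot(!is.null(theta_V))
    np <- max(length(lambda), length(theta_V))
    lambda <- rep_len(lambda, np); theta_V <- rep_len(theta_V, np)
    kind <- "exponential"; rate <- gp$lambda_T_g; theta <- Inf
  } else {
    np <- length(lambda)
    kind <- "logistic"; rate <- gp$lambda_e_g; theta <- gp$theta_e
  }
  out <- matrix(NA_real_, np, n_days)
  n_a <- n0
  v <- rep_len(v0, np)
  for (d in seq_len(n_days)) {
    I <- cell_integral(kind, rate, theta, n_a, 24)
    if (mode == "production") {
      v <- theta_V + (v - theta_V) * exp(-(lambda / theta_V) * I)
    } else {
      v <- v * exp(-lambda * I)
    }
    out[, d] <- v
    n_a <- cell_advance(kind, rate, theta, n_a, 24)
    v <- rep_len(baseline, np)
  }
  if (np == 1L) drop(out) else out
}
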