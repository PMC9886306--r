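#' Scenario result container
#'
#' Bundles a calibration scenario's posterior, maximum-likelihood
#' parameters, best-fit model output, per-day relative errors and
#' provenance (inputs and configuration needed to reproduce the run).
#'
#' @keywords internal
new_scenario_result <- function(scenario, posterior, mle, fitted, errors,
                                provenance, extra = list()) {
  structure(c(list(scenario = scenario, posterior = posterior,
                   mle = mle, fitted = fitted, errors = errors,
                   provenance = provenance), extra),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: %s>\n", x$scenario))
  cat("MLE parameters:\n")
  print(unlist(x$mle))
  if (!is.null(x$errors) && nrow(x$errors)) {
    cat("relative errors (%):\n")
    print(x$errors, row.names = FALSE)
  }
  invisible(x)
}

#' Scenario 1: calibration of tumor and endothelial cell growth
#'
#' Fits the exponential tumor growth rate and the logistic endothelial
#' growth rate and carrying capacity to hemocytometer counts by
#' minimizing the summed squared misfit. The first time point initializes
#' each model; the later points are the calibration data. Grid posteriors
#' around the least-squares optimum are attached for uncertainty
#' inspection.
#'
#' @param counts_T,counts_E tumor and endothelial [ang_series()] counts
#' @param n_grid grid points per dimension for the attached posteriors
#' @param span half-width of the posterior grid, as a fraction of the MLE
#' @return a `scenario_result` with `mle` holding a [growth_params()]
#' @export
scenario1_growth <- function(counts_T, counts_E, n_grid = 41,
                             span = 0.5) {
  stopifnot(nrow(counts_T) >= 2, nrow(counts_E) >= 2)
  tT <- counts_T$time_h - counts_T$time_h[1]
  tE <- counts_E$time_h - counts_E$time_h[1]
  n0_T <- counts_T$value[1]; n0_e <- counts_E$value[1]
  yT <- counts_T$value[-1]; yE <- counts_E$value[-1]

  if (length(unique(round(counts_T$value, 8))) == 1 ||
      length(unique(round(counts_E$value, 8))) == 1)
    warning("constant counts: likelihood is flat in the growth rate")

  sse_T <- function(lam) sum((yT - n0_T * exp(lam * tT[-1]))^2)
  lam_T <- optimize(sse_T, c(0, 0.5), tol = 1e-10)$minimum

  sse_E <- function(par) {
    lam <- par[1]; th <- exp(par[2])
    e <- exp(lam * tE[-1])
    sum((yE - th * n0_e * e / (th + n0_e * (e - 1)))^2)
  }
  opt <- optim(c(0.03, log(2 * max(counts_E$value))), sse_E,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  lam_E <- opt$par[1]; theta_E <- exp(opt$par[2])

  gp <- growth_params(lambda_e_g = max(lam_E, 0), theta_e = theta_E,
                      lambda_T_g = max(lam_T, 0))
  fit_T <- tumor_growth(gp, n0_T, counts_T$time_h)
  fit_E <- endothelial_growth(gp, n0_e, counts_E$time_h)
  errors <- data.frame(
    day = c(counts_T$time_h / 24, counts_E$time_h / 24),
    series = rep(c("tumor", "endothelial"),
                 c(nrow(counts_T), nrow(counts_E))),
    error_pct = c(relative_error(fit_T$value, counts_T$value),
                  relative_error(fit_E$value, counts_E$value)))

  lo <- function(x) max(x * (1 - span), 1e-8)
  hi <- function(x) max(x * (1 + span), 1e-6)
  sig_T <- max(sqrt(sse_T(lam_T) / length(yT)), 1e-9 * max(yT))
  post_T <- quadrature_posterior(
    function(m) sse_T(m[1]),
    lower = c(lambda_T_g = lo(lam_T)),
    upper = c(lambda_T_g = hi(lam_T)),
    n_grid = n_grid, sigma = sig_T, n_points = length(yT))
  sig_E <- max(sqrt(sse_E(opt$par) / length(yE)), 1e-9 * max(yE))
  post_E <- quadrature_posterior(
    function(m) sse_E(c(m[1], log(m[2]))),
    lower = c(lambda_e_g = lo(lam_E), theta_e = theta_E * (1 - span)),
    upper = c(lambda_e_g = hi(lam_E), theta_e = theta_E * (1 + span)),
    n_grid = n_grid, sigma = sig_E, n_points = length(yE))

  new_scenario_result(
    "scenario1_growth",
    list(tumor = post_T, endothelial = post_E),
    list(growth = gp, n0_T = n0_T, n0_e = n0_e),
    list(tumor = fit_T, endothelial = fit_E),
    errors,
    list(n_grid = n_grid, span = span))
}

#' Scenario 2: calibration of VEGF production and consumption
#'
#' Naive grid quadrature for the VEGF production rate, consumption rate
#' and carrying capacity against the daily ELISA series of the tumor
#' (production) and endothelial (consumption) plates. An initial
#' least-squares point centers the grid (`n_grid` values per parameter,
#' spanning `mle * (1 +/- span)`); the calibrated growth models supply
#' the cell-number inputs. Gaussian fits of the marginals are attached.
#'
#' @param elisa_T,elisa_E daily VEGF [ang_series()] for the tumor and
#'   endothelial plates
#' @param growth_fit result of [scenario1_growth()], or a list with
#'   elements `growth`, `n0_T`, `n0_e`
#' @param n_grid grid values per parameter (default 100, the full sweep)
#' @param span half-width of the grid as a fraction of the initial
#'   least-squares point
#' @param sigma likelihood standard deviation (pg/mL); defaults to 5% of
#'   the mean measured concentration
#' @return a `scenario_result`; `mle` holds the grid argmax as a
#'   [vegf_kinetics_params()], `gaussian_fit` the moment-matched
#'   marginals
#' @export
scenario2_vegf <- function(elisa_T, elisa_E, growth_fit, n_grid = 100,
                           span = 0.5, sigma = NULL) {
  mle_in <- if (inherits(growth_fit, "scenario_result"))
    growth_fit$mle else growth_fit
  gp <- mle_in$growth; n0_T <- mle_in$n0_T; n0_e <- mle_in$n0_e
  stopifnot(inherits(gp, "growth_params"))
  n_days <- nrow(elisa_T)
  stopifnot(nrow(elisa_E) == n_days)
  yT <- elisa_T$value; yE <- elisa_E$value
  baseline <- 1100

  mis_prod <- function(lam, th) {
    v <- elisa_daily_series("production", gp, n0_T, lambda = lam,
                            theta_V = th, baseline = baseline,
                            n_days = n_days)
    if (is.matrix(v)) rowSums(sweep(v, 2, yT)^2) else sum((v - yT)^2)
  }
  mis_cons <- function(lam) {
    v <- elisa_daily_series("consumption", gp, n0_e, lambda = lam,
                            baseline = baseline, n_days = n_days)
    if (is.matrix(v)) rowSums(sweep(v, 2, yE)^2) else sum((v - yE)^2)
  }

  # initial least-squares point (log-scale for conditioning)
  op <- optim(log(c(1.7e-3, 4000)),
              function(p) mis_prod(exp(p[1]), exp(p[2])),
              method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  lam_p0 <- exp(op$par[1]); th_0 <- exp(op$par[2])
  oc <- optimize(function(lg) mis_cons(exp(lg)), c(log(1e-9), log(1e-4)))
  lam_c0 <- exp(oc$minimum)

  if (is.null(sigma)) sigma <- 0.05 * mean(c(yT, yE))
  misfit_fn <- function(m)
    mis_prod(m[, 1], m[, 3]) + mis_cons(m[, 2])
  post <- quadrature_posterior(
    misfit_fn,
    lower = c(lambda_T_p = lam_p0 * (1 - span),
              lambda_e_c = lam_c0 * (1 - span),
              theta_V = th_0 * (1 - span)),
    upper = c(lambda_T_p = lam_p0 * (1 + span),
              lambda_e_c = lam_c0 * (1 + span),
              theta_V = th_0 * (1 + span)),
    n_grid = n_grid, sigma = sigma, n_points = 2 * n_days,
    vectorized = TRUE)

  mle <- post$mle
  on_edge <- mle <= c(lam_p0 * (1 - span), lam_c0 * (1 - span),
                      th_0 * (1 - span)) * (1 + 1e-12) |
    mle >= c(lam_p0 * (1 + span), lam_c0 * (1 + span),
             th_0 * (1 + span)) * (1 - 1e-12)
  if (any(on_edge))
    warning("posterior mode on the grid boundary; widen the sweep")

  kin <- vegf_kinetics_params(lambda_T_p = mle[["lambda_T_p"]],
                              lambda_e_c = mle[["lambda_e_c"]],
                              theta_V = mle[["theta_V"]],
                              baseline = baseline)
  fit_T <- ang_series(elisa_T$time_h,
                      elisa_daily_series("production", gp, n0_T,
                                         kin$lambda_T_p, kin$theta_V,
                                         baseline, n_days))
  fit_E <- ang_series(elisa_E$time_h,
                      elisa_daily_series("consumption", gp, n0_e,
                                         kin$lambda_e_c,
                                         baseline = baseline,
                                         n_days = n_days))
  errors <- data.frame(
    day = rep(elisa_T$time_h / 24, 2),
    series = rep(c("tumor_vegf", "endothelial_vegf"), each = n_days),
    error_pct = c(relative_error(fit_T$value, yT),
                  relative_error(fit_E$value, yE)))

  new_scenario_result(
    "scenario2_vegf", post, list(kinetics = kin),
    list(tumor = fit_T, endothelial = fit_E), errors,
    list(n_grid = n_grid, span = span, sigma = sigma,
         lsq = c(lambda_T_p = lam_p0, lambda_e_c = lam_c0,
                 theta_V = th_0)),
    extra = list(gaussian_fit = fit_gaussian(post)))
}

#' Scenario 3: calibration of the global stalk cell divide time
#'
#' Metropolis-Hastings calibration of the reduced single-sprout model
#' against mean sprout lengths over time. Parameters are the stalk divide
#' time, the VEGF force coefficient (which does not alter the
#' division-limited length and therefore has a flat posterior), and the
#' likelihood standard deviation treated as a hyperparameter. The implied
#' posterior-mean elongation rate `2R / (d_sc + g_sc)` is attached.
#'
#' @param length_data [ang_series()] of mean sprout lengths (um) with
#'   times in hours since sprouting began
#' @param params [abm_params()] (supplies `g_sc` and `R`)
#' @param n_steps MH proposals
#' @param seed RNG seed (mandatory)
#' @param prior_d_sc,prior_f_v,prior_sigma uniform prior bounds
#' @param proposal_sd per-parameter random-walk proposal sd
#' @return a `scenario_result` with `implied_rate` (um/h), the posterior
#'   chain and the Gaussian fit of `d_sc`
#' @export
scenario3_sprout_length <- function(length_data, params = abm_params(),
                                    n_steps = 20000, seed = 1,
                                    prior_d_sc = c(1, 10),
                                    prior_f_v = c(0, 2),
                                    prior_sigma = c(1, 400),
                                    proposal_sd = c(0.25, 0.1, 20)) {
  stopifnot(nrow(length_data) >= 3)
  tt <- length_data$time_h
  yy <- length_data$value
  n <- length(yy)
  sse <- function(d_sc)
    sum((yy - sprout_length_closed(tt, d_sc, params$g_sc, params$R))^2)
  log_post <- function(m)
    log_likelihood(sse(m[1]), m[3], n)
  init <- c(d_sc = mean(prior_d_sc), f_v = mean(prior_f_v),
            sigma = mean(prior_sigma))
  post <- metropolis_hastings(log_post, init, proposal_sd, n_steps,
                              seed = seed,
                              lower = c(prior_d_sc[1], prior_f_v[1],
                                        prior_sigma[1]),
                              upper = c(prior_d_sc[2], prior_f_v[2],
                                        prior_sigma[2]))
  # crude split-chain check on d_sc
  d <- post$support[, "d_sc"]
  h1 <- d[seq_len(length(d) %/% 2)]
  h2 <- d[-seq_len(length(d) %/% 2)]
  W <- mean(c(var(h1), var(h2)))
  B <- var(c(mean(h1), mean(h2))) * length(h1)
  psrf <- sqrt(max((length(h1) - 1) / length(h1) + B / (W * length(h1)),
                   0))
  if (is.finite(psrf) && psrf > 1.1)
    warning(sprintf("chain may not have converged (split-Rhat %.2f)",
                    psrf))
  rate <- mean(2 * params$R / (d + params$g_sc))
  mle <- post$mle
  fit <- ang_series(tt, sprout_length_closed(tt, mle[["d_sc"]],
                                             params$g_sc, params$R))
  errors <- data.frame(day = tt / 24, series = "sprout_length",
                       error_pct = relative_error(fit$value, yy))
  new_scenario_result(
    "scenario3_sprout_length", post,
    list(d_sc = mle[["d_sc"]], f_v = mle[["f_v"]],
         sigma = mle[["sigma"]]),
    fit, errors,
    list(n_steps = n_steps, seed = seed, g_sc = params$g_sc,
         R = params$R),
    extra = list(implied_rate = rate,
                 gaussian_fit = fit_gaussian(post)))
}

#' Density profile of a cell snapshot
#'
#' Rasterizes a snapshot and sums the mask along the vessel-length (y)
#' axis, yielding the vascular density over distance from the parent
#' vessel.
#'
#' @param cells snapshot data.frame
#' @param domain `c(Lx, Ly)` (um)
#' @param pixel pixel size (um)
#' @return integer density profile
#' @export
density_from_snapshot <- function(cells, domain, pixel = 2.254) {
  vascular_density(snapshot_mask(cells, domain, pixel), axis = 2)
}

#' Scenario 4: calibration of the distance between new tip cells
#'
#' One-dimensional naive quadrature over `d_tip`: each candidate runs the
#' full hybrid model from day 0 (the ABM cannot be initialized
#' mid-course), renders the vasculature at the calibration days, and
#' compares density profiles to the data beyond the exclusion band near
#' the parent vessel (15 voxels, > 35 um, where migratory endothelial
#' cells corrupt the data). The best-fit run also records the later
#' prediction day.
#'
#' @param density_data named list of density profiles (or
#'   [binary_mask()]s, reduced with [vascular_density()]), keyed by day
#'   (e.g. `"3"`, `"5"`, `"7"`)
#' @param scene a [platform_scene()]
#' @param params,fparams model parameters
#' @param days_cal days used for calibration
#' @param day_pred later day predicted by evolving the best fit
#' @param prior `c(lower, upper)` uniform prior on `d_tip` (um)
#' @param n_grid quadrature points
#' @param exclude_px voxels adjacent to the parent vessel excluded from
#'   the misfit
#' @param grid_spacing field element size (um)
#' @param pixel image pixel size (um)
#' @return a `scenario_result` with the `d_tip` posterior, Gaussian fit
#'   and per-day relative errors
#' @export
scenario4_density <- function(density_data, scene, params, fparams,
                              days_cal = c(3, 5), day_pred = 7,
                              prior = c(150, 350), n_grid = 64,
                              exclude_px = 15, grid_spacing = 10,
                              pixel = 2.254) {
  days_all <- sort(unique(c(days_cal, day_pred)))
  prof_data <- lapply(density_data, function(d)
    if (inherits(d, "binary_mask")) vascular_density(d, axis = 2)
    else as.numeric(d))
  cache <- new.env(parent = emptyenv())

  forward <- function(d_tip) {
    key <- sprintf("%.10g", d_tip)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sim <- simulate_angiogenesis(scene, params, fparams,
                                 t_end = max(days_all) * 24,
                                 record_times = days_all * 24,
                                 grid_spacing = grid_spacing,
                                 d_tip = d_tip)
    prof <- lapply(sim$snapshots, density_from_snapshot,
                   domain = scene$domain, pixel = pixel)
    names(prof) <- as.character(days_all)
    cache[[key]] <- prof
    prof
  }

  misfit <- function(m) {
    prof <- forward(m[1])
    s <- 0
    for (d in as.character(days_cal)) {
      dm <- prof[[d]]; dd <- prof_data[[d]]
      n <- min(length(dm), length(dd))
      keep <- seq_len(n) > exclude_px
      s <- s + sum((dd[seq_len(n)][keep] - dm[seq_len(n)][keep])^2)
    }
    s
  }

  ref <- unlist(prof_data[as.character(days_cal)])
  sigma <- max(0.05 * mean(ref[ref > 0]), 1e-6)
  n_points <- sum(vapply(prof_data[as.character(days_cal)], length, 0L))
  post <- quadrature_posterior(misfit, c(d_tip = prior[1]),
                               c(d_tip = prior[2]), n_grid = n_grid,
                               sigma = sigma, n_points = n_points)
  mle <- post$mle[["d_tip"]]
  best <- forward(mle)
  errors <- do.call(rbind, lapply(as.character(days_all), function(d) {
    dm <- best[[d]]; dd <- prof_data[[d]]
    n <- min(length(dm), length(dd))
    keep <- seq_len(n) > exclude_px & dd[seq_len(n)] > 0
    data.frame(day = as.numeric(d),
               series = if (as.numeric(d) %in% days_cal)
                 "calibration" else "prediction",
               error_pct = mean(relative_error(dm[seq_len(n)][keep],
                                               dd[seq_len(n)][keep])))
  }))
  new_scenario_result(
    "scenario4_density", post, list(d_tip = mle), best, errors,
    list(prior = prior, n_grid = n_grid, exclude_px = exclude_px,
         days_cal = days_cal, day_pred = day_pred,
         grid_spacing = grid_spacing, pixel = pixel),
    extra = list(gaussian_fit = fit_gaussian(post)))
}

skeleton_neighbor_counts <- function(m) {
  nb <- zs_neighbors(m * 1L)
  Reduce(`+`, nb)
}

#' Trace skeleton pixels into ordered paths
#'
#' Orders the pixels of each connected skeleton component into a path,
#' starting from the endpoint closest to the parent vessel (smallest x)
#' and repeatedly stepping to the nearest unvisited neighbor. Intended
#' for simple, sparsely-branched skeletons such as individual sprouts.
#'
#' @param skel a [binary_mask()] skeleton
#' @return list of n x 2 matrices of positions (um)
#' @export
trace_skeleton <- function(skel) {
  m <- unclass(skel) != 0
  sp <- mask_spacing(skel)
  lab <- label_components(m)
  ncount <- skeleton_neighbor_counts(m)
  paths <- list()
  for (comp in seq_len(max(lab))) {
    idx <- which(lab == comp, arr.ind = TRUE)
    if (nrow(idx) < 2) next
    ends <- idx[ncount[idx] == 1, , drop = FALSE]
    start <- if (nrow(ends)) ends[which.min(ends[, 1]), ]
    else idx[which.min(idx[, 1]), ]
    visited <- matrix(FALSE, nrow(m), ncol(m))
    path <- matrix(start, 1, 2)
    visited[start[1], start[2]] <- TRUE
    cur <- start
    repeat {
      di <- pmax(cur[1] - 1, 1):pmin(cur[1] + 1, nrow(m))
      dj <- pmax(cur[2] - 1, 1):pmin(cur[2] + 1, ncol(m))
      cand <- expand.grid(i = di, j = dj)
      ok <- m[as.matrix(cand)] & !visited[as.matrix(cand)]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) break
      d2 <- (cand$i - cur[1])^2 + (cand$j - cur[2])^2
      nxt <- as.numeric(cand[which.min(d2), ])
      path <- rbind(path, nxt)
      visited[nxt[1], nxt[2]] <- TRUE
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- cbind((path[, 1] - 0.5) * sp,
                                         (path[, 2] - 0.5) * sp)
  }
  paths
}

#' Initialize a sprout network from a skeleton
#'
#' Places chain cells at one-cell-diameter arc spacing along each traced
#' skeleton path, anchoring at the end nearest the parent vessel; the
#' tip direction is the end tangent of the path (the imposed VEGF
#' gradient direction for local calibration).
#'
#' @param skel day-3 [binary_mask()] skeleton
#' @param params [abm_params()]
#' @return a [sprout_network()]
#' @export
init_network_from_skeleton <- function(skel, params = abm_params()) {
  paths <- trace_skeleton(skel)
  if (!length(paths)) stop("no skeleton paths to initialize from")
  net <- sprout_network()
  step <- 2 * params$R
  for (p in paths) {
    seg <- diff(p)
    lens <- sqrt(rowSums(seg^2))
    arc <- c(0, cumsum(lens))
    total <- arc[length(arc)]
    ss <- unique(c(seq(0, total, by = step), total))
    pts <- cbind(approx(arc, p[, 1], xout = ss)$y,
                 approx(arc, p[, 2], xout = ss)$y)
    net <- add_sprout(net, pts[1, ])
    k <- length(net$chains)
    ch <- net$chains[[k]]
    if (nrow(pts) > 1) {
      d <- diff(pts)
      dl <- sqrt(rowSums(d^2))
      keep <- dl > 1e-9
      ch$seg_dir <- d[keep, , drop = FALSE] / dl[keep]
      ch$seg_len <- dl[keep]
      ch$dir <- ch$seg_dir[nrow(ch$seg_dir), ]
    }
    net$chains[[k]] <- ch
  }
  net
}

#' Centerline mask of a sprout network
#'
#' Draws each chain's polyline into pixels, giving the model-side
#' centerline directly comparable to a skeletonized data mask.
#'
#' @param network a [sprout_network()]
#' @param dim mask dimensions `c(nx, ny)`
#' @param spacing pixel size (um)
#' @return a [binary_mask()]
#' @export
network_centerline_mask <- function(network, dim, spacing = 2.254) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (ch in network$chains) {
    pos <- chain_positions(ch)
    if (nrow(pos) == 1) {
      pts <- pos
    } else {
      seg <- diff(pos)
      lens <- sqrt(rowSums(seg^2))
      arc <- c(0, cumsum(lens))
      ss <- unique(c(seq(0, arc[length(arc)], by = spacing / 2),
                     arc[length(arc)]))
      pts <- cbind(approx(arc, pos[, 1], xout = ss)$y,
                   approx(arc, pos[, 2], xout = ss)$y)
    }
    i <- pmin(pmax(ceiling(pts[, 1] / spacing), 1), dim[1])
    j <- pmin(pmax(ceiling(pts[, 2] / spacing), 1), dim[2])
    m[cbind(i, j)] <- TRUE
  }
  binary_mask(m, spacing)
}

#' Scenario 5: local stalk cell divide time from vessel centerlines
#'
#' Initializes the ABM from a day-3 skeleton (chain cells along the
#' traced centerline, growth direction imposed by each branch's end
#' tangent, no new tip activation) and calibrates the local stalk divide
#' time against the bidirectional mean centerline distances at the later
#' days, with misfit `sum_days (mean_MD - mean_DM)^2`. Aborts when the
#' initialized centerline fails to reproduce the day-3 skeleton (Dice of
#' the 1x-dilated centerlines below 0.8).
#'
#' @param day3_skeleton day-3 [binary_mask()] skeleton
#' @param later_skeletons named list of skeletons keyed by day (e.g.
#'   `"5"`, `"7"`)
#' @param params [abm_params()]
#' @param prior `c(lower, upper)` uniform prior on the local divide time
#'   (h)
#' @param n_grid quadrature points
#' @return a `scenario_result` with the `d_sc_local` posterior and the
#'   predicted centerline masks at the data days
#' @export
scenario5_local <- function(day3_skeleton, later_skeletons,
                            params = abm_params(), prior = c(2, 30),
                            n_grid = 15) {
  stopifnot(any(unclass(day3_skeleton) != 0), length(later_skeletons) >= 1)
  sp <- mask_spacing(day3_skeleton)
  dims <- dim(day3_skeleton)
  net0 <- init_network_from_skeleton(day3_skeleton, params)

  init_mask <- network_centerline_mask(net0, dims, sp)
  brush <- matrix(1L, 3, 3)
  d_init <- binary_mask(EBImage::dilate(unclass(init_mask) * 1L,
                                        brush) > 0, sp)
  d_data <- binary_mask(EBImage::dilate(unclass(day3_skeleton) * 1L,
                                        brush) > 0, sp)
  dc <- dice(d_init, d_data)
  if (dc < 0.8)
    stop(sprintf("initialization centerline Dice %.2f < 0.8", dc))

  days <- as.numeric(names(later_skeletons))
  forward <- function(d_loc) {
    net <- net0
    out <- list()
    t_cur <- 0
    for (i in order(days)) {
      t_target <- (days[order(days)][i] - 3) * 24
      nsteps <- round((t_target - t_cur) / params$dt)
      for (s in seq_len(nsteps))
        net <- advance_sprouts(net, params, grad_fn = NULL,
                               dt = params$dt, d_sc = d_loc)
      t_cur <- t_target
      out[[as.character(days[order(days)][i])]] <-
        network_centerline_mask(net, dims, sp)
    }
    out
  }

  misfit <- function(m) {
    pred <- forward(m[1])
    s <- 0
    for (d in names(later_skeletons)) {
      cd <- centerline_distance(pred[[d]], later_skeletons[[d]])
      s <- s + (cd[["mean_a_to_b"]] - cd[["mean_b_to_a"]])^2
    }
    s
  }

  post <- quadrature_posterior(misfit, c(d_sc_local = prior[1]),
                               c(d_sc_local = prior[2]), n_grid = n_grid,
                               sigma = max(sp, 1), n_points =
                                 2 * length(later_skeletons))
  mle <- post$mle[["d_sc_local"]]
  best <- forward(mle)
  errors <- do.call(rbind, lapply(names(later_skeletons), function(d) {
    cd <- centerline_distance(best[[d]], later_skeletons[[d]])
    data.frame(day = as.numeric(d), series = "centerline_um",
               error_pct = NA_real_,
               mean_model_to_data = cd[["mean_a_to_b"]],
               mean_data_to_model = cd[["mean_b_to_a"]])
  }))
  new_scenario_result(
    "scenario5_local", post, list(d_sc_local = mle), best, errors,
    list(prior = prior, n_grid = n_grid, init_dice = dc),
    extra = list(gaussian_fit = fit_gaussian(post),
                 network_init = net0))
}

sample_truncated <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  trunc_n <- 0L
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= lower && v <= upper) break
      trunc_n <- trunc_n + 1L
    }
    out[i] <- v
  }
  attr(out, "truncated") <- trunc_n
  out
}

#' Propagate calibration uncertainty into density predictions
#'
#' Samples parameters from their Gaussian posterior fits and reruns the
#' hybrid model from day 0 for each draw. The 1-parameter case samples
#' only the tip spacing `d_tip`; the 4-parameter case additionally
#' samples the VEGF production and consumption rates (which scale the
#' field source/sink coefficients proportionally) and the stalk divide
#' time. Samples outside the admissible range are redrawn (truncation is
#' recorded).
#'
#' @param scene a [platform_scene()]
#' @param params,fparams model parameters at their MLEs
#' @param fits named list of `c(mean, sd)` for `d_tip`, and for the
#'   4-parameter case also `lambda_T_p`, `lambda_e_c`, `d_sc`
#' @param mode `"1param"` or `"4param"`
#' @param n_samples forward runs
#' @param seed RNG seed
#' @param days days at which profiles are recorded
#' @param grid_spacing,pixel resolutions (um)
#' @return list with per-day profile matrices (`n_samples` rows), their
#'   mean and 95% interval, per-day `total_uncertainty` (summed interval
#'   width), vascular fractions and the truncation count
#' @export
predict_with_uncertainty <- function(scene, params, fparams, fits,
                                     mode = c("1param", "4param"),
                                     n_samples = 100, seed = 1,
                                     days = c(3, 5, 7),
                                     grid_spacing = 10, pixel = 2.254) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  g <- function(nm) fits[[nm]]
  d_tip_s <- sample_truncated(n_samples, g("d_tip")[1], g("d_tip")[2],
                              2 * params$R + 1, Inf)
  trunc_n <- attr(d_tip_s, "truncated")
  if (mode == "4param") {
    lp <- sample_truncated(n_samples, g("lambda_T_p")[1],
                           g("lambda_T_p")[2], 0, Inf)
    lc <- sample_truncated(n_samples, g("lambda_e_c")[1],
                           g("lambda_e_c")[2], 0, Inf)
    ds <- sample_truncated(n_samples, g("d_sc")[1], g("d_sc")[2],
                           0.2, Inf)
    trunc_n <- trunc_n + attr(lp, "truncated") +
      attr(lc, "truncated") + attr(ds, "truncated")
  }
  profs <- vector("list", length(days))
  names(profs) <- as.character(days)
  fracs <- matrix(NA_real_, n_samples, length(days),
                  dimnames = list(NULL, as.character(days)))
  for (s in seq_len(n_samples)) {
    fp_s <- fparams
    p_s <- params
    if (mode == "4param") {
      fp_s$gamma_h <- fparams$gamma_h * lp[s] / g("lambda_T_p")[1]
      scale_c <- lc[s] / g("lambda_e_c")[1]
      fp_s$lambda_t_c <- fparams$lambda_t_c * scale_c
      fp_s$lambda_s_c <- fparams$lambda_s_c * scale_c
      fp_s$lambda_e_c <- fparams$lambda_e_c * scale_c
      p_s$d_sc <- ds[s]
    }
    sim <- simulate_angiogenesis(scene, p_s, fp_s,
                                 t_end = max(days) * 24,
                                 record_times = days * 24,
                                 grid_spacing = grid_spacing,
                                 d_tip = d_tip_s[s],
                                 d_sc = p_s$d_sc)
    for (di in seq_along(days)) {
      cells <- sim$snapshots[[di]]
      pr <- density_from_snapshot(cells, scene$domain, pixel)
      if (is.null(profs[[di]]))
        profs[[di]] <- matrix(NA_real_, n_samples, length(pr))
      profs[[di]][s, ] <- pr
      fracs[s, di] <- vascular_fraction(
        snapshot_mask(cells, scene$domain, pixel))
    }
  }
  summaries <- lapply(profs, function(p) {
    data.frame(position_px = seq_len(ncol(p)),
               mean = colMeans(p),
               lo = apply(p, 2, quantile, 0.025),
               hi = apply(p, 2, quantile, 0.975))
  })
  total_unc <- vapply(summaries, function(s) sum(s$hi - s$lo), 0)
  list(mode = mode, profiles = profs, summary = summaries,
       total_uncertainty = total_unc, fractions = fracs,
       truncated = trunc_n, seed = seed)
}

#' Prediction envelope from sampled centerline masks
#'
#' Per-pixel hit counts over the sampled runs and the thresholded
#' envelope masks (pixels covered by at least each threshold count).
#' Higher thresholds give nested subsets.
#'
#' @param runs list of same-shape [binary_mask()] centerlines
#' @param thresholds hit-count thresholds; the study thresholds 10, 50
#'   and 100 of 1000 runs give the 1%, 5% and 10% envelopes
#' @return list with the `counts` matrix and one mask per threshold
#' @export
prediction_envelope <- function(runs, thresholds = c(10, 50, 100)) {
  stopifnot(length(runs) >= 1)
  if (any(thresholds > length(runs)))
    stop("threshold exceeds the number of runs")
  dims <- dim(runs[[1]])
  counts <- matrix(0L, dims[1], dims[2])
  for (r in runs) {
    stopifnot(all(dim(r) == dims))
    counts <- counts + (unclass(r) != 0)
  }
  sp <- mask_spacing(runs[[1]])
  masks <- lapply(thresholds, function(th)
    binary_mask(counts >= th, sp))
  names(masks) <- paste0("ge", thresholds)
  list(counts = counts, masks = masks, thresholds = thresholds,
       n_runs = length(runs))
}
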