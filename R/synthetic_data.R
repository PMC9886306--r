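#' Synthetic-data configuration
#'
#' Ground-truth parameters, noise levels and geometry for the synthetic
#' emulations of the study's three data modalities: hemocytometer counts,
#' daily ELISA VEGF concentrations, and confocal-like image stacks.
#' Defaults are the calibrated study conditions: growth and kinetic rates
#' at their maximum-likelihood values, daily media resets to 1100 pg/mL,
#' 5% relative ELISA noise, counting noise of 5% CV, tumor seeding at the
#' areal analogue of 1e6 cells/mL, and confocal voxels of 2.254 um
#' in-plane by 4.28 um axially.
#'
#' @param growth [growth_params()] ground truth
#' @param kinetics [vegf_kinetics_params()] ground truth
#' @param abm [abm_params()] ground truth
#' @param n0_T,n0_e initial tumor and endothelial cell numbers (cells);
#'   defaults follow the seeding densities (30,000 and 10,000 cells/cm^2
#'   in a 3.8 cm^2 well)
#' @param count_cv multiplicative CV of hemocytometer counts
#' @param elisa_rel_sd ELISA noise sd as a fraction of each value
#' @param seeding_density_per_ml volumetric tumor seeding density
#' @param domain platform domain `c(Lx, Ly)` (um)
#' @param spacing_xy,spacing_z confocal voxel sizes (um)
#' @param n_slices z-slices per stack
#' @param blur_sigma_px optical blur sd (pixels)
#' @param read_sd Gaussian read-noise sd (intensity units)
#' @param shot_scale Poisson shot-noise scale (photons at intensity 1)
#' @param n_distractors planted single-pixel migratory-cell distractors
#' @return a `synth_config`
#' @export
synth_config <- function(growth = growth_params(),
                         kinetics = vegf_kinetics_params(),
                         abm = abm_params(),
                         n0_T = 1.14e5, n0_e = 3.5e4,
                         count_cv = 0.05, elisa_rel_sd = 0.05,
                         seeding_density_per_ml = 1e6,
                         domain = c(676.2, 3155.6),
                         spacing_xy = 2.254, spacing_z = 4.28,
                         n_slices = 10, blur_sigma_px = 1,
                         read_sd = 0.05, shot_scale = 50,
                         n_distractors = 50) {
  stopifnot(count_cv >= 0, elisa_rel_sd >= 0, read_sd >= 0,
            n0_T >= 0, n0_e >= 0)
  structure(list(growth = growth, kinetics = kinetics, abm = abm,
                 n0_T = n0_T, n0_e = n0_e, count_cv = count_cv,
                 elisa_rel_sd = elisa_rel_sd,
                 seeding_density_per_ml = seeding_density_per_ml,
                 domain = domain, spacing_xy = spacing_xy,
                 spacing_z = spacing_z, n_slices = n_slices,
                 blur_sigma_px = blur_sigma_px, read_sd = read_sd,
                 shot_scale = shot_scale,
                 n_distractors = n_distractors),
            class = "synth_config")
}

#' Synthetic hemocytometer counts
#'
#' Tumor (exponential) and endothelial (logistic) cell counts on days 1,
#' 2, 3, 5 and 7 with multiplicative lognormal counting noise of the
#' configured CV (mean-unbiased). Ground truth is returned alongside.
#'
#' @param cfg a [synth_config()]
#' @param seed RNG seed (mandatory)
#' @param days sampling days
#' @return list with `tumor`, `endothelial` (noisy [ang_series()]) and
#'   `truth` (noise-free series)
#' @export
gen_cell_counts <- function(cfg, seed, days = c(1, 2, 3, 5, 7)) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(seed))
  times <- days * 24
  tT <- tumor_growth(cfg$growth, cfg$n0_T, times)
  tE <- endothelial_growth(cfg$growth, cfg$n0_e, times)
  noisy <- function(s) {
    if (cfg$count_cv == 0) return(s)
    sdlog <- sqrt(log(1 + cfg$count_cv^2))
    ang_series(s$time_h,
               s$value * rlnorm(nrow(s), -sdlog^2 / 2, sdlog))
  }
  list(tumor = noisy(tT), endothelial = noisy(tE),
       truth = list(tumor = tT, endothelial = tE))
}

#' Synthetic daily ELISA VEGF series
#'
#' Daily VEGF concentrations over `n_days` from the production (tumor
#' plate) and consumption (endothelial plate) kinetics with media resets
#' to the baseline after each measurement, corrupted by additive Gaussian
#' noise with sd equal to `elisa_rel_sd` of each value.
#'
#' @param cfg a [synth_config()]
#' @param seed RNG seed (mandatory)
#' @param n_days number of daily measurements
#' @return list with `tumor`, `endothelial` (noisy [ang_series()]) and
#'   `truth`
#' @export
gen_elisa_series <- function(cfg, seed, n_days = 7) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(seed))
  k <- cfg$kinetics
  times <- 24 * seq_len(n_days)
  vp <- elisa_daily_series("production", cfg$growth, cfg$n0_T,
                           lambda = k$lambda_T_p, theta_V = k$theta_V,
                           baseline = k$baseline, n_days = n_days)
  vc <- elisa_daily_series("consumption", cfg$growth, cfg$n0_e,
                           lambda = k$lambda_e_c,
                           baseline = k$baseline, n_days = n_days)
  noisy <- function(v) {
    if (cfg$elisa_rel_sd == 0) return(ang_series(times, v))
    ang_series(times,
               pmax(v + rnorm(length(v), 0, cfg$elisa_rel_sd * v), 0),
               sd = cfg$elisa_rel_sd * v)
  }
  list(tumor = noisy(vp), endothelial = noisy(vc),
       truth = list(tumor = ang_series(times, vp),
                    endothelial = ang_series(times, vc)))
}

#' Synthetic platform scene
#'
#' Parent vessel along the long axis and tumor cells placed by a spatial
#' Poisson process at the areal analogue of the volumetric seeding
#' density (`density^(2/3)` cells per um^2), keeping a clearance strip
#' next to the vessel.
#'
#' @param cfg a [synth_config()]
#' @param seed RNG seed (mandatory)
#' @param clearance tumor-free strip next to the vessel (um)
#' @return a [platform_scene()]
#' @export
gen_platform_scene <- function(cfg, seed, clearance = 50) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(seed))
  areal <- (cfg$seeding_density_per_ml * 1e-12)^(2 / 3)  # cells / um^2
  Lx <- cfg$domain[1]; Ly <- cfg$domain[2]
  area <- max(Lx - clearance, 0) * Ly
  n <- rpois(1, areal * area)
  platform_scene(cfg$domain,
                 data.frame(x = runif(n, clearance, Lx),
                            y = runif(n, 0, Ly)))
}

#' Synthetic confocal image stack of a vessel snapshot
#'
#' Renders vessel cells as disks into `n_slices` z-slices with Gaussian
#' optical blur, Poisson-Gaussian noise, and planted single-pixel
#' "migratory cell" distractors. Vessels are generated in a thin 2D plane
#' replicated over the slices, matching the primarily in-plane growth of
#' the platform's sprouts. The noise-free ground-truth mask and its
#' skeleton are returned alongside.
#'
#' @param cfg a [synth_config()]
#' @param cells data.frame of vessel cells (`x`, `y`, optionally `R`)
#' @param seed RNG seed (mandatory)
#' @param domain image domain `c(Lx, Ly)` (um); defaults to `cfg$domain`
#' @return list with `stack` (3D array), `truth_mask`, `truth_skeleton`,
#'   `distractors` (pixel indices), `spacing_xy`, `spacing_z`
#' @export
gen_confocal_stack <- function(cfg, cells, seed, domain = cfg$domain) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(seed))
  sp <- cfg$spacing_xy
  dims <- c(ceiling(domain[1] / sp), ceiling(domain[2] / sp))
  R <- if ("R" %in% names(cells)) cells$R else cfg$abm$R
  truth <- if (nrow(cells))
    rasterize_disks(cells$x, cells$y, R, dims, sp)
  else binary_mask(matrix(FALSE, dims[1], dims[2]), sp)
  base <- unclass(truth) * 1
  k <- cfg$n_distractors
  distract <- integer(0)
  if (k > 0) {
    open <- which(base == 0)
    distract <- sample(open, min(k, length(open)))
    # bright nuclei: stay above the intensity threshold after blur
    base[distract] <- 4
  }
  if (cfg$blur_sigma_px > 0)
    base <- as.matrix(EBImage::gblur(base, sigma = cfg$blur_sigma_px))
  stack <- array(0, c(dims[1], dims[2], cfg$n_slices))
  for (z in seq_len(cfg$n_slices)) {
    sl <- base
    if (cfg$shot_scale > 0)
      sl <- rpois(length(sl), pmax(sl, 0) * cfg$shot_scale) /
        cfg$shot_scale
    sl <- sl + rnorm(length(sl), 0, cfg$read_sd)
    stack[, , z] <- sl
  }
  list(stack = stack, truth_mask = truth,
       truth_skeleton = skeletonize(truth),
       distractors = distract, spacing_xy = sp,
       spacing_z = cfg$spacing_z)
}
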