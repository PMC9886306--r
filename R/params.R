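#' Cell-growth parameters
#'
#' Parameters of the endothelial (logistic) and tumor (exponential) growth
#' laws. Rates are per hour; the carrying capacity is in cells.
#'
#' @param lambda_e_g endothelial growth rate (1/h)
#' @param theta_e endothelial carrying capacity (cells)
#' @param lambda_T_g tumor growth rate (1/h)
#' @return an object of class `growth_params`
#' @export
growth_params <- function(lambda_e_g = 3.7e-2, theta_e = 2.67e5,
                          lambda_T_g = 8.9e-3) {
  stopifnot(lambda_e_g >= 0, lambda_T_g >= 0, theta_e > 0)
  structure(list(lambda_e_g = lambda_e_g, theta_e = theta_e,
                 lambda_T_g = lambda_T_g),
            class = "growth_params")
}

#' VEGF kinetics parameters
#'
#' Rates of the VEGF production/consumption ODEs. Concentrations are pg/mL;
#' a 1 mL well volume is assumed so pg and pg/mL are interchangeable
#' (configurable through `well_volume_ml`).
#'
#' @param lambda_T_p VEGF production rate per tumor cell (pg/(mL h cell))
#' @param lambda_e_c VEGF consumption rate per endothelial cell (1/(h cell))
#' @param theta_V VEGF carrying capacity (pg/mL)
#' @param baseline post-media-replacement VEGF concentration (pg/mL)
#' @param well_volume_ml well volume used to convert pg to pg/mL
#' @return an object of class `vegf_kinetics_params`
#' @export
vegf_kinetics_params <- function(lambda_T_p = 1.7e-3, lambda_e_c = 8.9e-7,
                                 theta_V = 4035, baseline = 1100,
                                 well_volume_ml = 1) {
  stopifnot(lambda_T_p >= 0, lambda_e_c >= 0, theta_V > 0, baseline >= 0,
            well_volume_ml > 0)
  structure(list(lambda_T_p = lambda_T_p, lambda_e_c = lambda_e_c,
                 theta_V = theta_V, baseline = baseline,
                 well_volume_ml = well_volume_ml),
            class = "vegf_kinetics_params")
}

#' Agent-based model parameters
#'
#' Geometry and rate constants of the sprouting ABM. The cell diameter is
#' 2R = 10 um; the nuclear radius defaults to half the cytoplasmic radius.
#'
#' @param d_sc stalk cell divide time (h)
#' @param g_sc stalk cell growth time (h)
#' @param d_sc_local local stalk cell divide time (h), scenario-5 variant
#' @param f_v VEGF force coefficient (dimensionless)
#' @param d_tip minimum spacing between new tip cells (um)
#' @param R cytoplasmic cell radius (um)
#' @param R_N nuclear cell radius (um)
#' @param alpha_A VEGF activation threshold (normalized concentration)
#' @param sigma_H hypoxia nutrient threshold (normalized concentration)
#' @param shutoff_dist tumor VEGF-secretion shutoff distance (um)
#' @param dt agent time step (h)
#' @return an object of class `abm_params`
#' @export
abm_params <- function(d_sc = 3.96, g_sc = 1.04, d_sc_local = 10.86,
                       f_v = 0.61, d_tip = 243, R = 5, R_N = 2.5,
                       alpha_A = 0.05, sigma_H = 0.2, shutoff_dist = 40,
                       dt = 0.1) {
  stopifnot(d_sc > 0, g_sc > 0, d_sc_local > 0, f_v >= 0, d_tip > 0,
            R > 0, R_N > 0, R_N <= R, alpha_A >= 0, sigma_H >= 0,
            shutoff_dist >= 0, dt > 0, d_tip > 2 * R)
  structure(list(d_sc = d_sc, g_sc = g_sc, d_sc_local = d_sc_local,
                 f_v = f_v, d_tip = d_tip, R = R, R_N = R_N,
                 alpha_A = alpha_A, sigma_H = sigma_H,
                 shutoff_dist = shutoff_dist, dt = dt),
            class = "abm_params")
}

#' Continuum field parameters
#'
#' Diffusion coefficients and per-cell-type reaction rates of the
#' reaction-diffusion equations for nutrient and VEGF. Fields are stored
#' normalized to \[0, 1\]; `vegf_scale` converts to pg/mL when coupling to
#' ODE-calibrated rates.
#'
#' @param D_n,D_v nutrient and VEGF diffusion coefficients (um^2/h)
#' @param lambda_pq_c,lambda_h_c nutrient consumption rates of
#'   proliferative/quiescent and hypoxic tumor cells (1/h)
#' @param lambda_t_c,lambda_s_c,lambda_e_c VEGF consumption rates of tip,
#'   stalk and phalanx endothelial cells (1/h)
#' @param gamma_e nutrient production rate of looped endothelial cells (1/h)
#' @param gamma_h VEGF production rate of hypoxic/secreting tumor cells (1/h)
#' @param vegf_scale physical concentration (pg/mL) at normalized VEGF = 1
#' @return an object of class `field_params`
#' @export
field_params <- function(D_n = 1000, D_v = 1000,
                         lambda_pq_c = 0.1, lambda_h_c = 0.05,
                         lambda_t_c = 0.5, lambda_s_c = 0.5,
                         lambda_e_c = 0.5,
                         gamma_e = 1, gamma_h = 50, vegf_scale = 4035) {
  p <- list(D_n = D_n, D_v = D_v, lambda_pq_c = lambda_pq_c,
            lambda_h_c = lambda_h_c, lambda_t_c = lambda_t_c,
            lambda_s_c = lambda_s_c, lambda_e_c = lambda_e_c,
            gamma_e = gamma_e, gamma_h = gamma_h, vegf_scale = vegf_scale)
  stopifnot(all(unlist(p) >= 0))
  structure(p, class = "field_params")
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "angiocal", mustWork = TRUE)
}

#' In-study observation tables
#'
#' Fixed numeric tables from the microfluidic study that the calibration
#' scenarios consume as data: the observed/predicted sprout lengths by day
#' (`sprout_length_table`), the vascular-density calibration and prediction
#' errors by day (`density_error_table`), and the calibrated parameter
#' summary with maximum-likelihood values and Gaussian fits
#' (`calibrated_parameter_table`). The parameter table uses the
#' unit-consistent carrying-capacity assignment (theta_e in cells,
#' theta_V in pg/mL).
#'
#' @return a data.frame
#' @export
sprout_length_table <- function() {
  read.csv(fixture_path("sprout_length.csv"))
}

#' @rdname sprout_length_table
#' @export
density_error_table <- function() {
  read.csv(fixture_path("vascular_density_errors.csv"))
}

#' @rdname sprout_length_table
#' @export
calibrated_parameter_table <- function() {
  read.csv(fixture_path("calibrated_parameters.csv"))
}

#' Calibrated maximum-likelihood parameter set
#'
#' Convenience lookup of the calibrated MLE value (or Gaussian-fit mean and
#' sd) of one parameter from [calibrated_parameter_table()].
#'
#' @param parameter parameter name as in the table, e.g. `"d_sc"`
#' @return named numeric vector with elements `mle`, `fit_mean`, `fit_sd`
#' @export
calibrated_parameter <- function(parameter) {
  tab <- calibrated_parameter_table()
  row <- tab[tab$parameter == parameter, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown parameter: ", parameter)
  c(mle = row$mle, fit_mean = row$fit_mean, fit_sd = row$fit_sd)
}
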