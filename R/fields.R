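#' Gridded scalar field
#'
#' A 2D concentration field on a regular grid. The matrix is indexed
#' `[i, j]` with `i` along x and `j` along y; element centers sit at
#' `(i - 0.5) * spacing` (same convention in y). Fields are stored
#' normalized to \[0, 1\].
#'
#' @param values numeric matrix of concentrations (finite, >= 0)
#' @param spacing element size (um)
#' @return a `scalar_field` (matrix with a `spacing` attribute)
#' @export
scalar_field <- function(values, spacing) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)), all(values >= 0), spacing > 0)
  structure(values, spacing = spacing, class = c("scalar_field", "matrix"))
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field %dx%d, spacing %g um, range [%g, %g]>\n",
              nrow(x), ncol(x), attr(x, "spacing"), min(x), max(x)))
  invisible(x)
}

#' Field spacing accessor
#' @param x a `scalar_field`
#' @return element size in um
#' @export
field_spacing <- function(x) attr(x, "spacing")

#' Bilinear sample of a field at physical positions
#' @param f a `scalar_field`
#' @param x,y positions (um)
#' @return sampled values (edge values beyond the grid)
#' @export
field_at <- function(f, x, y) {
  h <- field_spacing(f)
  gi <- pmin(pmax(x / h + 0.5, 1), nrow(f))
  gj <- pmin(pmax(y / h + 0.5, 1), ncol(f))
  i0 <- pmin(floor(gi), nrow(f) - 1L); j0 <- pmin(floor(gj), ncol(f) - 1L)
  if (nrow(f) == 1L) i0 <- rep(1L, length(gi))
  if (ncol(f) == 1L) j0 <- rep(1L, length(gj))
  fx <- gi - i0; fy <- gj - j0
  i1 <- pmin(i0 + 1L, nrow(f)); j1 <- pmin(j0 + 1L, ncol(f))
  m <- unclass(f)
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i1, j0)] * fx * (1 - fy) +
    m[cbind(i0, j1)] * (1 - fx) * fy +
    m[cbind(i1, j1)] * fx * fy
}

#' Finite-difference gradient of a field at physical positions
#' @param f a `scalar_field`
#' @param x,y positions (um)
#' @return matrix with columns `gx`, `gy` (per um)
#' @export
field_gradient_at <- function(f, x, y) {
  h <- field_spacing(f)
  gx <- (field_at(f, x + h / 2, y) - field_at(f, x - h / 2, y)) / h
  gy <- (field_at(f, x, y + h / 2) - field_at(f, x, y - h / 2)) / h
  cbind(gx = gx, gy = gy)
}

#' Per-element volume fractions of each cell type
#'
#' Couples the agents to the continuum grid: each cell contributes its disk
#' area `pi * R^2` to the element containing its center, and the per-type
#' totals are divided by the element area. Total cell area is conserved.
#'
#' @param cells data.frame with columns `x`, `y` (um), `type` (one of
#'   `pq`, `h`, `e`, `t`, `s`, `looped`) and optionally `R` (um)
#' @param dim grid dimensions `c(nx, ny)`
#' @param spacing element size (um)
#' @param R default cell radius (um) when `cells$R` is absent
#' @return named list of fraction matrices, one per cell type
#' @export
compute_volume_fractions <- function(cells, dim, spacing, R = 5) {
  types <- c("pq", "h", "e", "t", "s", "looped")
  vf <- lapply(types, function(a) matrix(0, dim[1], dim[2]))
  names(vf) <- types
  if (nrow(cells) > 0) {
    rr <- if ("R" %in% names(cells)) cells$R else rep(R, nrow(cells))
    i <- pmin(pmax(floor(cells$x / spacing) + 1L, 1L), dim[1])
    j <- pmin(pmax(floor(cells$y / spacing) + 1L, 1L), dim[2])
    lin <- (j - 1L) * dim[1] + i
    area <- pi * rr^2 / spacing^2
    for (a in types) {
      sel <- cells$type == a
      if (!any(sel)) next
      m <- vf[[a]]
      agg <- rowsum(area[sel], lin[sel])
      m[as.integer(rownames(agg))] <- agg[, 1]
      vf[[a]] <- m
    }
  }
  vf
}

#' Assemble reaction coefficients from volume fractions
#'
#' Linear combinations coupling the agents to the continuum equations:
#' nutrient uptake `Lambda_n = lambda_pq_c * phi_pq + lambda_h_c * phi_h`,
#' nutrient production `Gamma_n = gamma_e * phi_looped`, VEGF consumption
#' `Lambda_v = lambda_t_c * phi_t + lambda_s_c * phi_s + lambda_e_c *
#' phi_e`, and VEGF production `Gamma_v = gamma_h * phi_h`.
#'
#' @param vf volume fractions from [compute_volume_fractions()]
#' @param p [field_params()]
#' @return named list of matrices `Lambda_n`, `Gamma_n`, `Lambda_v`,
#'   `Gamma_v`
#' @export
assemble_coefficients <- function(vf, p) {
  stopifnot(inherits(p, "field_params"))
  list(Lambda_n = p$lambda_pq_c * vf$pq + p$lambda_h_c * vf$h,
       Gamma_n = p$gamma_e * vf$looped,
       Lambda_v = p$lambda_t_c * vf$t + p$lambda_s_c * vf$s +
         p$lambda_e_c * vf$e,
       Gamma_v = p$gamma_h * vf$h)
}

laplacian_noflux <- function(m, h) {
  nx <- nrow(m); ny <- ncol(m)
  up <- m[c(1, seq_len(nx - 1)), , drop = FALSE]
  dn <- m[c(seq_len(nx - 1) + 1, nx), , drop = FALSE]
  lf <- m[, c(1, seq_len(ny - 1)), drop = FALSE]
  rt <- m[, c(seq_len(ny - 1) + 1, ny), drop = FALSE]
  (up + dn + lf + rt - 4 * m) / h^2
}

#' One explicit step of the reaction-diffusion equation
#'
#' Advances `df/dt = div(D grad f) - Lambda * f + Gamma * f * (1 - f)` by
#' one explicit finite-difference step with no-flux boundaries. The
#' logistic production term keeps a normalized field below one; with zero
#' reaction and no-flux boundaries total mass is conserved.
#'
#' @param field a `scalar_field`
#' @param D diffusion coefficient (um^2/h)
#' @param dt time step (h); must satisfy `dt <= spacing^2 / (4 D)`
#' @param Lambda,Gamma reaction coefficient matrices (or scalars)
#' @return the advanced `scalar_field`
#' @export
step_reaction_diffusion <- function(field, D, dt, Lambda = 0, Gamma = 0) {
  h <- field_spacing(field)
  dt_max <- h^2 / (4 * D)
  if (D > 0 && dt > dt_max + 1e-12)
    stop(sprintf("unstable step: dt = %g exceeds admissible dt = %g",
                 dt, dt_max))
  m <- unclass(field)
  out <- m + dt * (D * laplacian_noflux(m, h) - Lambda * m +
                     Gamma * m * (1 - m))
  scalar_field(pmax(out, 0), h)
}
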