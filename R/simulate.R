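#' Platform scene description
#'
#' Geometry of a simulated microfluidic platform: the rectangular domain
#' (um), the parent vessel running along the y axis at x = 0, and tumor
#' seed positions.
#'
#' @param domain `c(Lx, Ly)` in um; the study domain is
#'   676.2 x 3155.6 um^2
#' @param tumors data.frame with columns `x`, `y` (um)
#' @return a `platform_scene`
#' @export
platform_scene <- function(domain = c(676.2, 3155.6),
                           tumors = data.frame(x = numeric(),
                                               y = numeric())) {
  stopifnot(length(domain) == 2, all(domain > 0),
            all(c("x", "y") %in% names(tumors)))
  structure(list(domain = domain, tumors = tumors),
            class = "platform_scene")
}

parent_vessel_cells <- function(scene, R = 5) {
  y <- seq(R, scene$domain[2] - R, by = 2 * R)
  data.frame(x = rep(R, length(y)), y = y)
}

#' Simulate hybrid angiogenesis
#'
#' Runs the coupled agent/continuum model: secreting tumor cells source a
#' normalized VEGF field (reaction-diffusion, no-flux boundaries),
#' endothelial cells of the parent vessel activate into tips where the
#' local VEGF exceeds the activation threshold while respecting the
#' minimum tip spacing `d_tip`, sprouts elongate by division-limited
#' growth steered up the VEGF gradient, anastomoses loop sprouts
#' together, and tumor cells within the shutoff distance of vasculature
#' stop secreting. The run is deterministic for a fixed scene and
#' parameter set.
#'
#' @param scene a [platform_scene()]
#' @param params [abm_params()]
#' @param fparams [field_params()]
#' @param t_end simulated time (h)
#' @param record_times times (h) at which cell snapshots are stored
#' @param grid_spacing field element size (um)
#' @param d_tip,d_sc parameter overrides (um, h); default to `params`
#' @param allow_activation whether new tips may activate after the start
#' @param secretion_every interval (h) between secretion-flag updates
#' @param vegf_init initial normalized VEGF; a small trace level is
#'   required because the logistic production term amplifies rather than
#'   creates concentration
#' @return list with `snapshots` (one cell data.frame per record time,
#'   endothelial and sprout cells), `network`, `vegf` (final field),
#'   `tumors`, and `times`
#' @export
simulate_angiogenesis <- function(scene, params, fparams,
                                  t_end, record_times = t_end,
                                  grid_spacing = 10,
                                  d_tip = params$d_tip,
                                  d_sc = params$d_sc,
                                  allow_activation = TRUE,
                                  secretion_every = 1,
                                  vegf_init = 1e-3) {
  stopifnot(inherits(scene, "platform_scene"),
            inherits(params, "abm_params"),
            inherits(fparams, "field_params"), t_end > 0)
  dt <- params$dt
  h <- grid_spacing
  dims <- c(max(2L, ceiling(scene$domain[1] / h)),
            max(2L, ceiling(scene$domain[2] / h)))
  vegf <- scalar_field(matrix(vegf_init, dims[1], dims[2]), h)
  dt_sub_max <- 0.9 * h^2 / (4 * max(fparams$D_v, 1e-9))
  n_sub <- max(1L, ceiling(dt / dt_sub_max))
  dt_sub <- dt / n_sub

  vessel <- parent_vessel_cells(scene, params$R)
  tumors <- scene$tumors
  tumors$state <- if (nrow(tumors)) "quiescent" else character()
  tumors$secreting <- nrow(tumors) > 0
  net <- sprout_network()

  record_times <- sort(record_times)
  snapshots <- vector("list", length(record_times))
  names(snapshots) <- paste0("t", record_times)
  rec_i <- 1L

  snapshot_cells <- function() {
    sc <- network_cells(net, params$R, params$R_N)
    rbind(data.frame(chain = 0L, x = vessel$x, y = vessel$y,
                     phenotype = "e", R = params$R, R_N = params$R_N),
          sc)
  }

  fast_df <- function(x, y, type) {
    structure(list(x = x, y = y, type = type),
              class = "data.frame",
              row.names = seq_along(x))
  }

  net_xy <- function() {
    xs <- ys <- numeric(0); ph <- character(0)
    for (ch in net$chains) {
      pos <- chain_positions(ch)
      n <- nrow(pos)
      xs <- c(xs, pos[, 1]); ys <- c(ys, pos[, 2])
      p <- rep("s", n)
      p[n] <- if (ch$looped) "looped" else "t"
      ph <- c(ph, p)
    }
    list(x = xs, y = ys, ph = ph)
  }

  steps <- ceiling(t_end / dt)
  next_secretion <- 0
  for (s in seq_len(steps)) {
    t_now <- s * dt

    nc <- net_xy()

    if (nrow(tumors) && t_now >= next_secretion) {
      tumors <- update_secretion(
        tumors, fast_df(c(vessel$x, nc$x), c(vessel$y, nc$y), NULL),
        params$shutoff_dist)
      next_secretion <- t_now + secretion_every
    }

    agents <- fast_df(
      c(vessel$x, nc$x, tumors$x),
      c(vessel$y, nc$y, tumors$y),
      c(rep("e", nrow(vessel)), nc$ph,
        if (nrow(tumors)) ifelse(tumors$secreting, "h", "pq")))
    vf <- compute_volume_fractions(agents, dims, h, R = params$R)
    cf <- assemble_coefficients(vf, fparams)
    for (k in seq_len(n_sub))
      vegf <- step_reaction_diffusion(vegf, fparams$D_v, dt_sub,
                                      Lambda = cf$Lambda_v,
                                      Gamma = cf$Gamma_v)

    if (allow_activation) {
      # anchors keep counting as tip sites: a sprout's origin stays
      # occupied even after its tip migrates away from the vessel
      ax <- vapply(net$chains, function(ch) ch$anchor[1], 0)
      ay <- vapply(net$chains, function(ch) ch$anchor[2], 0)
      is_tip <- nc$ph == "t"
      tips <- fast_df(c(nc$x[is_tip], ax), c(nc$y[is_tip], ay), NULL)
      p_act <- params; p_act$d_tip <- d_tip
      idx <- activate_tips(vessel, vegf, tips, p_act)
      for (i in idx)
        net <- add_sprout(net, c(vessel$x[i] + params$R, vessel$y[i]),
                          c(1, 0))
    }

    grad_fn <- function(x, y) field_gradient_at(vegf, x, y)[1, ]
    net <- advance_sprouts(net, params, grad_fn, dt, d_sc = d_sc)
    net <- detect_anastomosis(net, 2 * params$R, time_h = t_now)

    while (rec_i <= length(record_times) &&
           t_now + dt / 2 >= record_times[rec_i]) {
      snapshots[[rec_i]] <- snapshot_cells()
      rec_i <- rec_i + 1L
    }
  }
  while (rec_i <= length(record_times)) {
    snapshots[[rec_i]] <- snapshot_cells()
    rec_i <- rec_i + 1L
  }
  list(times = record_times, snapshots = snapshots, network = net,
       vegf = vegf, tumors = tumors)
}

#' Rasterize a cell snapshot into a vessel mask
#'
#' Renders endothelial cells (vessel and sprouts) as filled disks at the
#' confocal pixel resolution, giving the model-side analogue of the
#' binarized vessel mask.
#'
#' @param cells snapshot data.frame (`x`, `y`, `R`)
#' @param domain `c(Lx, Ly)` in um
#' @param spacing pixel size (um)
#' @return a [binary_mask()]
#' @export
snapshot_mask <- function(cells, domain, spacing = 2.254) {
  dims <- c(ceiling(domain[1] / spacing), ceiling(domain[2] / spacing))
  R <- if ("R" %in% names(cells)) cells$R else 5
  rasterize_disks(cells$x, cells$y, R, dims, spacing)
}
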