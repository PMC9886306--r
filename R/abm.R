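#' Chemotactic potential gradient between two cells
#'
#' Piecewise potential shape driving tip-cell chemotaxis. For cell
#' separation `d_vec` with combined nuclear radius `R_N` and combined
#' cytoplasmic radius `R`, the scalar shape is
#' `R_N*|d|/R^2 - 2*|d|/R + 1` inside the nuclear zone (`|d| <= R_N`),
#' `(|d|/R)^2 - 2*|d|/R + 1` in the cytoplasmic zone (`R_N <= |d| <= R`),
#' and zero beyond `R`. The two branches agree at `|d| = R_N` and the outer
#' branch vanishes at `|d| = R`, so the potential is continuous with
#' bounded support. The gradient points against the unit VEGF gradient
#' (so the force `-f_v * grad_psi` points up-gradient); a zero VEGF
#' gradient returns the zero vector.
#'
#' @param d_vec displacement vector between the cells (um)
#' @param R_N combined nuclear radius (um)
#' @param R combined cytoplasmic radius (um), `R >= R_N`
#' @param vegf_gradient VEGF gradient vector at the tip
#' @return length-2 gradient vector
#' @export
vegf_potential_gradient <- function(d_vec, R_N, R, vegf_gradient) {
  stopifnot(R_N <= R, all(is.finite(vegf_gradient)))
  gn <- sqrt(sum(vegf_gradient^2))
  if (gn == 0) return(c(0, 0))
  nd <- sqrt(sum(d_vec^2))
  s <- if (nd <= R_N) {
    R_N * nd / R^2 - 2 * nd / R + 1
  } else if (nd <= R) {
    nd^2 / R^2 - 2 * nd / R + 1
  } else 0
  -s * vegf_gradient / gn
}

#' Chemotactic force on a tip cell
#'
#' `F = -f_v * grad_psi(d; R_N_i + R_N_j, R_i + R_j, [VEGF])`, linear in
#' the force coefficient. Cells are lists with elements `x`, `y`, `R`,
#' `R_N`. Coincident cells use the finite inner-branch limit at zero
#' separation.
#'
#' @param tip,neighbor cell lists (`x`, `y`, `R`, `R_N`)
#' @param f_v VEGF force coefficient
#' @param vegf_gradient VEGF gradient vector at the tip
#' @return length-2 force vector
#' @export
vegf_force <- function(tip, neighbor, f_v, vegf_gradient) {
  d <- c(tip$x - neighbor$x, tip$y - neighbor$y)
  -f_v * vegf_potential_gradient(d, tip$R_N + neighbor$R_N,
                                 tip$R + neighbor$R, vegf_gradient)
}

#' Tip-cell activation under VEGF and spacing constraints
#'
#' Selects candidate endothelial cells whose local VEGF exceeds the
#' activation threshold and which lie farther than `d_tip` from every
#' existing tip and every tip activated earlier in the same pass.
#' Candidates are processed in descending local VEGF, which makes the
#' selection deterministic.
#'
#' @param candidates data.frame with columns `x`, `y` of eligible cells
#' @param vegf local normalized VEGF at each candidate (or a
#'   `scalar_field`, sampled at the candidate positions)
#' @param existing_tips data.frame with columns `x`, `y` (may be empty)
#' @param params [abm_params()] (uses `alpha_A` and `d_tip`)
#' @return integer row indices of `candidates` that activate
#' @export
activate_tips <- function(candidates, vegf, existing_tips, params) {
  stopifnot(inherits(params, "abm_params"))
  if (nrow(candidates) == 0) return(integer())
  v <- if (inherits(vegf, "scalar_field"))
    field_at(vegf, candidates$x, candidates$y) else vegf
  elig <- which(v > params$alpha_A)
  elig <- elig[order(v[elig], decreasing = TRUE)]
  tips_x <- existing_tips$x; tips_y <- existing_tips$y
  out <- integer()
  for (i in elig) {
    if (length(tips_x) == 0 ||
        all((candidates$x[i] - tips_x)^2 + (candidates$y[i] - tips_y)^2 >
            params$d_tip^2)) {
      out <- c(out, i)
      tips_x <- c(tips_x, candidates$x[i])
      tips_y <- c(tips_y, candidates$y[i])
    }
  }
  sort(out)
}

#' Create an empty sprout network
#'
#' A sprout network holds one chain per sprout. Each chain is anchored at
#' its activation point on the parent vessel and is represented by unit
#' segment directions and segment lengths; cell positions are the running
#' sums of the segments. Elongation is division-limited: after each stalk
#' divide time `d_sc` a new zero-length segment is inserted at the tip and
#' grows to one cell diameter over the growth time `g_sc`, so chains can
#' never tear (the stiff limit of the cell-cell adhesion springs).
#'
#' @return a `sprout_network`
#' @export
sprout_network <- function() {
  structure(list(chains = list(),
                 anastomoses = data.frame(chain = integer(),
                                          target_chain = integer(),
                                          time_h = numeric())),
            class = "sprout_network")
}

#' @export
print.sprout_network <- function(x, ...) {
  cat(sprintf("<sprout_network: %d sprout(s), %d anastomosis event(s)>\n",
              length(x$chains), nrow(x$anastomoses)))
  invisible(x)
}

#' Add a sprout to a network
#'
#' @param network a [sprout_network()]
#' @param anchor activation point `c(x, y)` on the parent vessel (um)
#' @param direction initial outgrowth direction (normalized internally)
#' @return the updated network
#' @export
add_sprout <- function(network, anchor, direction = c(1, 0)) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) direction <- c(1, 0) else direction <- direction / nrm
  network$chains[[length(network$chains) + 1L]] <-
    list(anchor = anchor, seg_dir = matrix(numeric(), 0, 2),
         seg_len = numeric(), clock = 0, growing = FALSE,
         looped = FALSE, dir = direction)
  network
}

chain_positions <- function(ch) {
  n <- length(ch$seg_len)
  pos <- matrix(ch$anchor, n + 1L, 2, byrow = TRUE)
  if (n > 0) {
    pos[-1, 1] <- ch$anchor[1] + cumsum(ch$seg_dir[, 1] * ch$seg_len)
    pos[-1, 2] <- ch$anchor[2] + cumsum(ch$seg_dir[, 2] * ch$seg_len)
  }
  pos
}

chain_length <- function(ch) sum(ch$seg_len)

#' Cells of a sprout network
#'
#' Flattens the chains into a cell table: the anchor cell plus one cell
#' per segment. The distal cell of an unlooped chain is the tip; cells of
#' looped chains carry the `looped` phenotype.
#'
#' @param network a [sprout_network()]
#' @param R,R_N cell radii recorded in the table (um)
#' @return data.frame with columns `chain`, `x`, `y`, `phenotype`
#' @export
network_cells <- function(network, R = 5, R_N = 2.5) {
  out <- lapply(seq_along(network$chains), function(k) {
    ch <- network$chains[[k]]
    pos <- chain_positions(ch)
    n <- nrow(pos)
    ph <- rep("s", n)
    ph[n] <- if (ch$looped) "looped" else "t"
    data.frame(chain = k, x = pos[, 1], y = pos[, 2], phenotype = ph,
               R = R, R_N = R_N)
  })
  if (length(out) == 0)
    return(data.frame(chain = integer(), x = numeric(), y = numeric(),
                      phenotype = character(), R = numeric(),
                      R_N = numeric()))
  do.call(rbind, out)
}

#' Advance all sprouts by one time step
#'
#' Division-limited elongation: per chain, the division clock accumulates
#' while no daughter is growing; once it exceeds `d_sc` a zero-length tip
#' segment is inserted and grows at `2R/g_sc` until it reaches one cell
#' diameter. The growing tip segment is steered along the chemotactic
#' force direction (the unit VEGF gradient under the bounded potential);
#' with a zero gradient the previous direction is kept. Looped chains do
#' not advance. Sprout length is non-decreasing.
#'
#' @param network a [sprout_network()]
#' @param params [abm_params()]
#' @param grad_fn function `(x, y) -> c(gx, gy)` giving the VEGF gradient
#'   at the tip, or `NULL` for straight outgrowth
#' @param dt time step (h)
#' @param d_sc stalk divide time override (h); defaults to `params$d_sc`
#' @return the advanced network
#' @export
advance_sprouts <- function(network, params, grad_fn = NULL,
                            dt = params$dt, d_sc = params$d_sc) {
  stopifnot(dt > 0)
  two_R <- 2 * params$R
  for (k in seq_along(network$chains)) {
    ch <- network$chains[[k]]
    if (ch$looped) next
    tip <- chain_positions(ch)[length(ch$seg_len) + 1L, ]
    if (!is.null(grad_fn)) {
      g <- grad_fn(tip[1], tip[2])
      gn <- sqrt(sum(g^2))
      if (is.finite(gn) && gn > 0) ch$dir <- g / gn
    }
    # exact time accounting: leftover step time rolls into the next
    # phase so the division/growth cycle is exactly d_sc + g_sc
    t_rem <- dt
    while (t_rem > 1e-12) {
      if (ch$growing) {
        i <- length(ch$seg_len)
        ch$seg_dir[i, ] <- ch$dir
        need <- (two_R - ch$seg_len[i]) * params$g_sc / two_R
        take <- min(t_rem, need)
        ch$seg_len[i] <- ch$seg_len[i] + two_R * take / params$g_sc
        if (take >= need - 1e-12) {
          ch$seg_len[i] <- two_R
          ch$growing <- FALSE
          ch$clock <- 0
        }
        t_rem <- t_rem - take
      } else {
        need <- d_sc - ch$clock
        take <- min(t_rem, need)
        ch$clock <- ch$clock + take
        if (take >= need - 1e-12) {
          ch$seg_dir <- rbind(ch$seg_dir, ch$dir)
          ch$seg_len <- c(ch$seg_len, 0)
          ch$growing <- TRUE
        }
        t_rem <- t_rem - take
      }
    }
    network$chains[[k]] <- ch
  }
  network
}

#' Detect anastomosis (sprout fusion) events
#'
#' A tip within `contact_dist` of any cell of another chain fuses with it:
#' the event is recorded and the tip's chain switches to the looped
#' phenotype and stops advancing. Events are never removed, so the event
#' count is non-decreasing in time.
#'
#' @param network a [sprout_network()]
#' @param contact_dist contact distance (um)
#' @param time_h simulation time recorded with new events
#' @return the updated network
#' @export
detect_anastomosis <- function(network, contact_dist, time_h = NA_real_) {
  n <- length(network$chains)
  if (n < 2) return(network)
  pos <- lapply(network$chains, chain_positions)
  for (k in seq_len(n)) {
    ch <- network$chains[[k]]
    if (ch$looped) next
    tip <- pos[[k]][nrow(pos[[k]]), ]
    for (j in seq_len(n)) {
      if (j == k) next
      d2 <- (pos[[j]][, 1] - tip[1])^2 + (pos[[j]][, 2] - tip[2])^2
      if (any(d2 <= contact_dist^2)) {
        ch$looped <- TRUE
        network$anastomoses <- rbind(network$anastomoses,
                                     data.frame(chain = k,
                                                target_chain = j,
                                                time_h = time_h))
        break
      }
    }
    network$chains[[k]] <- ch
  }
  network
}

#' Update tumor VEGF secretion flags
#'
#' A tumor cell stops secreting VEGF when it lies within the shutoff
#' distance of the nearest vessel cell (a surrogate for nutrient delivery
#' by the new vasculature); the flag is recomputed from scratch each call,
#' so it would flip back if the vasculature regressed.
#'
#' @param tumors data.frame with columns `x`, `y` (and any others)
#' @param vessel_cells data.frame with columns `x`, `y` of all vessel
#'   cells (parent vessel plus sprouts)
#' @param shutoff_dist shutoff distance (um)
#' @return `tumors` with a logical `secreting` column
#' @export
update_secretion <- function(tumors, vessel_cells, shutoff_dist) {
  if (nrow(tumors) == 0) return(cbind(tumors, secreting = logical()))
  if (nrow(vessel_cells) == 0) {
    tumors$secreting <- TRUE
    return(tumors)
  }
  d2min <- vapply(seq_len(nrow(tumors)), function(i) {
    min((vessel_cells$x - tumors$x[i])^2 +
          (vessel_cells$y - tumors$y[i])^2)
  }, 0)
  tumors$secreting <- d2min > shutoff_dist^2
  tumors
}

#' Tumor cell state transitions
#'
#' Minimal nutrient-driven state machine: a tumor cell below the hypoxia
#' threshold `sigma_H` becomes hypoxic; a quiescent cell above it becomes
#' proliferative with probability linear in the local nutrient; necrotic
#' is absorbing. The calibration scenarios bypass this machinery through
#' the secretion-shutoff surrogate, but it is available for full
#' nutrient-coupled runs.
#'
#' @param tumors data.frame with columns `x`, `y`, `state`
#' @param nutrient a `scalar_field` of normalized nutrient
#' @param params [abm_params()]
#' @param dt time step (h)
#' @return `tumors` with updated `state`
#' @export
update_tumor_states <- function(tumors, nutrient, params, dt = params$dt) {
  if (nrow(tumors) == 0) return(tumors)
  sig <- field_at(nutrient, tumors$x, tumors$y)
  st <- tumors$state
  alive <- st != "necrotic"
  st[alive & sig < params$sigma_H] <- "hypoxic"
  back <- alive & st == "hypoxic" & sig >= params$sigma_H
  st[back] <- "quiescent"
  q <- which(st == "quiescent" & sig >= params$sigma_H)
  if (length(q)) {
    p <- pmin(pmax(sig[q], 0), 1) * dt
    st[q[runif(length(q)) < p]] <- "proliferative"
  }
  tumors$state <- st
  tumors
}

#' Closed-form division-limited sprout length
#'
#' Length of a single sprout whose elongation is driven purely by stalk
#' divisions: each cycle waits `d_sc`, then grows one cell diameter over
#' `g_sc`. Long-run rate is `2R / (d_sc + g_sc)`. Vectorized over `t`.
#'
#' @param t times since activation (h)
#' @param d_sc stalk divide time (h)
#' @param g_sc stalk growth time (h)
#' @param R cell radius (um)
#' @return sprout lengths (um)
#' @export
sprout_length_closed <- function(t, d_sc, g_sc, R = 5) {
  c_len <- d_sc + g_sc
  k <- floor(t / c_len)
  s <- t - k * c_len
  2 * R * (k + pmax(0, pmin((s - d_sc) / g_sc, 1)))
}

#' Reduced single-sprout model
#'
#' The scenario-3 forward model: one tip growing perpendicular to the
#' parent vessel on a reduced domain, with the VEGF field removed, so the
#' length trajectory depends only on the stalk division cycle. The
#' step-driven simulation and the closed form agree to within one cell
#' diameter.
#'
#' @param params [abm_params()]
#' @param t_end simulated time (h)
#' @param dt output/step resolution (h)
#' @param d_sc stalk divide time override (h)
#' @return an [ang_series()] of sprout length (um) over time
#' @export
simplified_sprout_model <- function(params, t_end, dt = params$dt,
                                    d_sc = params$d_sc) {
  stopifnot(t_end > 0)
  times <- seq(0, t_end, by = dt)
  net <- add_sprout(sprout_network(), c(0, 0), c(1, 0))
  lens <- numeric(length(times))
  for (i in seq_along(times)[-1]) {
    net <- advance_sprouts(net, params, grad_fn = NULL, dt = dt,
                           d_sc = d_sc)
    lens[i] <- chain_length(net$chains[[1]])
  }
  ang_series(times, lens)
}
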