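# Independent oracles used by the tests: deliberately naive
# implementations kept separate from the package's code paths.

# fixed-step RK4 integration of a scalar ODE dy/dt = f(t, y)
rk4_solve <- function(f, y0, t_end, n_steps = 10000) {
  h <- t_end / n_steps
  y <- y0; t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# all-pairs nearest-neighbor mean distance between two pixel sets (um)
brute_centerline_distance <- function(a, b, spacing) {
  pa <- which(unclass(a) != 0, arr.ind = TRUE)
  pb <- which(unclass(b) != 0, arr.ind = TRUE)
  near <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2)), 0)
  }
  c(mean(near(pa, pb)), mean(near(pb, pa))) * spacing
}

# reference Zhang-Suen thinning: plain per-pixel double loop
reference_zhang_suen <- function(mask) {
  m <- (unclass(mask) != 0) * 1L
  pad <- function(x) rbind(0L, cbind(0L, x, 0L), 0L)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- pad(m)
      del <- matrix(FALSE, nrow(m), ncol(m))
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(ncol(m))) {
          if (m[i, j] == 0) next
          ii <- i + 1; jj <- j + 1
          nb <- c(p[ii - 1, jj], p[ii - 1, jj + 1], p[ii, jj + 1],
                  p[ii + 1, jj + 1], p[ii + 1, jj], p[ii + 1, jj - 1],
                  p[ii, jj - 1], p[ii - 1, jj - 1])  # P2..P9
          B <- sum(nb)
          A <- sum(nb[c(1:8)] == 0 & nb[c(2:8, 1)] == 1)
          if (B < 2 || B > 6 || A != 1) next
          if (pass == 1) {
            if (nb[1] * nb[3] * nb[5] != 0) next
            if (nb[3] * nb[5] * nb[7] != 0) next
          } else {
            if (nb[1] * nb[3] * nb[7] != 0) next
            if (nb[1] * nb[5] * nb[7] != 0) next
          }
          del[i, j] <- TRUE
        }
      }
      if (any(del)) changed <- TRUE
      m[del] <- 0L
    }
    if (!changed) break
  }
  m
}

# small two-sprout scene used by the hybrid-model tests
tiny_scene <- function(seed = 5, n_tumors = 12,
                       domain = c(250, 500)) {
  set.seed(seed)
  platform_scene(domain,
                 data.frame(x = runif(n_tumors, domain[1] * 0.4,
                                      domain[1] * 0.95),
                            y = runif(n_tumors, 0, domain[2])))
}

# straight-line skeleton fixture in a small region
line_skeleton <- function(rows, col, dims = c(120, 120),
                          spacing = 2.254) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[rows, col] <- TRUE
  binary_mask(m, spacing)
}
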