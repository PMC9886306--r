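test_that("chemotactic potential is continuous, bounded and compactly
           supported", {
  R_N <- 2.5; R <- 5
  g <- c(1, 0)
  # zero exactly at |d| = R and beyond
  expect_equal(vegf_potential_gradient(c(R, 0), R_N, R, g), c(0, 0))
  expect_equal(vegf_potential_gradient(c(7.3, 1.2), R_N, R, g), c(0, 0))
  # branch agreement at |d| = R_N
  inner <- vegf_potential_gradient(c(R_N - 1e-9, 0), R_N, R, g)
  outer <- vegf_potential_gradient(c(R_N + 1e-9, 0), R_N, R, g)
  expect_equal(inner, outer, tolerance = 1e-6)
  shape <- R_N^2 / R^2 - 2 * R_N / R + 1
  expect_equal(inner[1], -shape, tolerance = 1e-6)
  # zero gradient gives the zero vector, not an error
  expect_equal(vegf_potential_gradient(c(1, 1), R_N, R, c(0, 0)),
               c(0, 0))
})

test_that("chemotactic force is linear in f_v and matches the composed
           formula", {
  tip <- list(x = 3, y = 0, R = 5, R_N = 2.5)
  nb <- list(x = 0, y = 0, R = 5, R_N = 2.5)
  g <- c(0.2, 0.5)
  expect_equal(vegf_force(tip, nb, 0, g), c(0, 0))
  f1 <- vegf_force(tip, nb, 0.61, g)
  f2 <- vegf_force(tip, nb, 1.22, g)
  expect_equal(f2, 2 * f1)
  # symbolic oracle: |d| = 3 <= combined R_N = 5, inner branch of the
  # combined-radius potential (R = 10), force along unit gradient
  s <- 5 * 3 / 10^2 - 2 * 3 / 10 + 1
  expect_equal(f1, 0.61 * s * g / sqrt(sum(g^2)), tolerance = 1e-12)
  # coincident cells: finite inner-branch limit
  expect_equal(vegf_force(nb, nb, 1, g), g / sqrt(sum(g^2)))
})

test_that("tip activation respects the VEGF threshold and spacing", {
  p <- abm_params(d_tip = 243, alpha_A = 0.05)
  none <- data.frame(x = numeric(), y = numeric())
  cand <- data.frame(x = c(0, 0), y = c(0, 100))
  expect_length(activate_tips(cand, c(0, 0), none, p), 0)
  # two eligible cells 100 um apart with d_tip = 243: exactly one
  expect_length(activate_tips(cand, c(0.2, 0.1), none, p), 1)
  # the higher-VEGF candidate wins, deterministically
  expect_equal(activate_tips(cand, c(0.1, 0.2), none, p), 2L)
  # mutually distant candidates all activate
  far <- data.frame(x = rep(0, 3), y = c(0, 300, 600))
  expect_equal(activate_tips(far, c(0.2, 0.2, 0.2), none, p), 1:3)
  # an existing tip blocks its neighborhood
  tips <- data.frame(x = 0, y = 50)
  expect_length(activate_tips(cand, c(0.2, 0.2), tips, p), 0)
})

test_that("division-limited elongation reproduces 2R/(d_sc + g_sc)", {
  p <- abm_params(d_sc = 3.96, g_sc = 1.04, dt = 0.1)
  expect_equal(2 * p$R / (p$d_sc + p$g_sc), 2.0)
  s <- simplified_sprout_model(p, t_end = 384)
  final <- s$value[nrow(s)]
  expect_lt(abs(final - 2.0 * 384), 2 * p$R)  # within one cell diameter
  expect_true(all(diff(s$value) >= 0))

  # division-count oracle at several times
  for (t in c(50, 123, 250)) {
    len <- sprout_length_closed(t, p$d_sc, p$g_sc, p$R)
    expect_lt(abs(len - 2 * p$R * floor(t / (p$d_sc + p$g_sc))),
              2 * p$R + 1e-9)
  }
  # rate strictly decreasing in d_sc
  r <- 2 * p$R / (c(3, 4, 5) + p$g_sc)
  expect_true(all(diff(r) < 0))
  # step simulation agrees with the closed form
  expect_equal(s$value, sprout_length_closed(s$time_h, p$d_sc, p$g_sc,
                                             p$R), tolerance = 1e-6)
  # determinism: same configuration, identical trajectory
  s2 <- simplified_sprout_model(p, t_end = 384)
  expect_identical(s$value, s2$value)
})

test_that("chains stay connected and tips follow the gradient", {
  p <- abm_params(dt = 0.1)
  net <- add_sprout(sprout_network(), c(0, 0), c(1, 0))
  grad <- function(x, y) c(1, 0.2)  # constant oblique gradient
  for (i in 1:600) net <- advance_sprouts(net, p, grad, p$dt)
  pos <- angiocal:::chain_positions(net$chains[[1]])
  gaps <- sqrt(rowSums(diff(pos)^2))
  expect_true(all(gaps <= 2 * p$R + 1e-9))
  expect_gt(pos[nrow(pos), 1], 0)  # positive mean x-velocity
  dirs <- diff(pos)
  expect_true(all(dirs[, 1] > 0))
})

test_that("anastomosis events are detected once and never removed", {
  p <- abm_params()
  # two chains: one tip steered into the other's cells
  net <- add_sprout(sprout_network(), c(0, 0), c(1, 0))
  net <- add_sprout(net, c(0, 14), c(1, 0))
  # grow chain 1 straight; chain 2 towards chain 1
  net$chains[[1]]$seg_dir <- matrix(c(1, 0), 4, 2, byrow = TRUE)
  net$chains[[1]]$seg_len <- rep(10, 4)
  net$chains[[2]]$seg_dir <- matrix(c(0.8, -0.6), 1, 2, byrow = TRUE)
  net$chains[[2]]$seg_len <- 10
  out <- detect_anastomosis(net, contact_dist = 10, time_h = 5)
  expect_equal(nrow(out$anastomoses), 1)
  expect_equal(out$anastomoses$chain, 2)
  expect_true(out$chains[[2]]$looped)
  cells <- network_cells(out)
  expect_true("looped" %in% cells$phenotype[cells$chain == 2])
  # farther apart than contact distance: no events
  far <- add_sprout(sprout_network(), c(0, 0), c(1, 0))
  far <- add_sprout(far, c(0, 200), c(1, 0))
  expect_equal(nrow(detect_anastomosis(far, 10)$anastomoses), 0)
  # count non-decreasing when run again
  out2 <- detect_anastomosis(out, contact_dist = 10, time_h = 6)
  expect_gte(nrow(out2$anastomoses), nrow(out$anastomoses))
})

test_that("secretion shutoff equals the brute-force nearest distance", {
  set.seed(2)
  tumors <- data.frame(x = runif(40, 0, 300), y = runif(40, 0, 300))
  vessel <- data.frame(x = runif(25, 0, 300), y = runif(25, 0, 300))
  out <- update_secretion(tumors, vessel, shutoff_dist = 40)
  for (i in seq_len(nrow(tumors))) {
    dmin <- sqrt(min((vessel$x - tumors$x[i])^2 +
                       (vessel$y - tumors$y[i])^2))
    expect_identical(out$secreting[i], dmin > 40)
  }
  # empty network: all secreting
  none <- update_secretion(tumors, vessel[0, ], 40)
  expect_true(all(none$secreting))
  # boundary: tumor just inside the shutoff distance stops secreting
  tb <- update_secretion(data.frame(x = 39.99, y = 0),
                         data.frame(x = 0, y = 0), 40)
  expect_false(tb$secreting)
})
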