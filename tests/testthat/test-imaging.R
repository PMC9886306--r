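test_that("projection and binarization filter small components", {
  empty <- array(0, c(20, 20, 5))
  m <- project_and_binarize(empty, intensity_thr = 0.5, min_area_px = 5)
  expect_equal(sum(m), 0)

  # a blob below the area threshold is removed, above it is kept
  st <- array(0, c(30, 30, 3))
  st[5:6, 5:6, ] <- 1          # 4 px blob
  st[15:20, 15:20, ] <- 1      # 36 px blob
  keep <- project_and_binarize(st, intensity_thr = 0.5,
                               min_area_px = 10)
  expect_equal(sum(keep), 36)
  both <- project_and_binarize(st, intensity_thr = 0.5,
                               min_area_px = 3)
  expect_equal(sum(both), 40)
  expect_error(project_and_binarize(st, n_slices = 9))
})

test_that("vessel survives thresholding while planted single-pixel
           distractors are removed", {
  set.seed(21)
  st <- array(0, c(60, 120, 4))
  st[28:33, 10:110, ] <- 1  # one vessel
  stray <- cbind(sample(setdiff(1:60, 26:35), 50, TRUE),
                 sample(1:120, 50, TRUE))
  for (k in 1:50) st[stray[k, 1], stray[k, 2], ] <- 1
  m <- project_and_binarize(st, intensity_thr = 0.5, min_area_px = 20)
  lab <- label_components(m)
  expect_equal(max(lab), 1)
  expect_gte(sum(m), 6 * 101)
})

test_that("8-connected labeling joins diagonal pixels", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE  # diagonal line
  m[5, 5] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(length(unique(lab[cbind(1:3, 1:3)])), 1)
})

test_that("density profile and fraction follow the counting identities", {
  set.seed(3)
  m <- binary_mask(matrix(runif(15 * 40) > 0.6, 15, 40), 2.254)
  prof <- vascular_density(m, axis = 2)
  # direct counting oracle
  for (i in seq_len(nrow(m)))
    expect_equal(prof[i], sum(unclass(m)[i, ]))
  expect_equal(sum(prof), sum(m))
  expect_equal(vascular_fraction(m), mean(unclass(m)))
  # identity: fraction equals mean profile over the transverse width
  expect_equal(vascular_fraction(m), mean(prof) / ncol(m))

  full <- binary_mask(matrix(TRUE, 7, 9), 1)
  expect_equal(unname(vascular_density(full, axis = 1)), rep(7, 9))
  expect_equal(vascular_fraction(full), 1)
  expect_equal(sum(vascular_density(binary_mask(matrix(FALSE, 3, 3), 1))),
               0)
})

test_that("Dice obeys its bounds, symmetry and closed forms", {
  a <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), 1)
  b <- binary_mask(matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2), 1)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  expect_equal(dice(binary_mask(matrix(FALSE, 2, 2), 1),
                    binary_mask(matrix(FALSE, 2, 2), 1)), 0)
  # A subset of B with |A| = |B|/2 gives 2/3
  B <- binary_mask(matrix(c(rep(TRUE, 4), rep(FALSE, 4)), 4, 2), 1)
  A <- binary_mask(matrix(c(rep(TRUE, 2), rep(FALSE, 6)), 4, 2), 1)
  expect_equal(dice(A, B), 2 / 3)
  set.seed(8)
  x <- binary_mask(matrix(runif(64) > 0.5, 8, 8), 1)
  y <- binary_mask(matrix(runif(64) > 0.5, 8, 8), 1)
  expect_equal(dice(x, y), dice(y, x))
  expect_true(dice(x, y) >= 0 && dice(x, y) <= 1)
  expect_error(dice(x, binary_mask(matrix(TRUE, 3, 3), 1)))
})

test_that("region selection applies both the Dice and overlap rules", {
  # 5 regions with constructed Dice/overlap {0.9, 0.6, 0.4, 0.55, 0.2}
  make_region <- function(k) {
    a <- matrix(FALSE, 10, 20); a[, 1:10] <- TRUE  # |A| = 100
    b <- matrix(FALSE, 10, 20)
    b[, 1:10][seq_len(k)] <- TRUE                  # k overlap px
    b[, 11:20][seq_len(100 - k)] <- TRUE           # |B| = 100
    list(binary_mask(a, 1), binary_mask(b, 1))
  }
  ks <- c(90, 60, 40, 55, 20)
  regions <- lapply(ks, make_region)
  sel <- select_regions(regions, dice_thr = 0.5)
  expect_equal(sel$min_dice, ks / 100)
  # cohort mean overlap is 0.53: regions 1, 2 and 4 pass both rules
  expect_equal(which(sel$selected), c(1, 2, 4))

  # identical over time: selected; empty second time point: rejected
  const <- list(regions[[1]][[1]], regions[[1]][[1]])
  gone <- list(regions[[1]][[1]], binary_mask(matrix(FALSE, 10, 20), 1))
  sel2 <- select_regions(list(const, gone), dice_thr = 0.5)
  expect_true(sel2$selected[1])
  expect_false(sel2$selected[2])
})

test_that("Zhang-Suen thinning matches the reference implementation", {
  # solid 3xN bar reduces to its middle row
  as_plain <- function(m) {
    m <- (unclass(m) != 0) * 1L
    attributes(m) <- list(dim = dim(m))
    m
  }
  bar <- matrix(FALSE, 7, 24); bar[3:5, 2:23] <- TRUE
  sk <- skeletonize(binary_mask(bar, 1))
  ref <- reference_zhang_suen(binary_mask(bar, 1))
  expect_equal(as_plain(sk), ref)
  expect_equal(unique(which(unclass(sk), arr.ind = TRUE)[, 1]), 4L)

  # a one-pixel line is already thin
  line <- matrix(FALSE, 5, 12); line[3, 2:11] <- TRUE
  expect_equal(unclass(skeletonize(binary_mask(line, 1))) != 0, line)

  # idempotence and agreement with the reference on a random blob
  set.seed(12)
  blob <- matrix(FALSE, 25, 25)
  blob[5:20, 5:20] <- matrix(runif(256) > 0.25, 16, 16)
  as_plain <- function(m) {
    m <- (unclass(m) != 0) * 1L
    attributes(m) <- list(dim = dim(m))
    m
  }
  skb <- skeletonize(binary_mask(blob, 1))
  expect_equal(as_plain(skb),
               reference_zhang_suen(binary_mask(blob, 1)))
  expect_equal(unclass(skeletonize(skb)), unclass(skb))
})

test_that("skeletonization preserves component count of the dilated
           mask", {
  set.seed(14)
  m <- matrix(FALSE, 40, 40)
  m[5:10, 5:30] <- TRUE
  m[25:30, 10:35] <- TRUE
  msk <- binary_mask(m, 1)
  sk <- skeletonize(msk, dilate = 1)
  brush <- matrix(1L, 3, 3)
  dil <- EBImage::dilate(unclass(msk) * 1L, brush) > 0
  expect_equal(max(label_components(sk)), max(label_components(dil)))
})

test_that("centerline distances match the brute-force oracle", {
  sp <- 2.254
  a <- line_skeleton(10:40, 20, dims = c(60, 60), spacing = sp)
  expect_equal(unname(centerline_distance(a, a)), c(0, 0))
  # parallel lines offset by 7 px
  b <- line_skeleton(10:40, 27, dims = c(60, 60), spacing = sp)
  expect_equal(unname(centerline_distance(a, b)), c(7, 7) * sp)

  set.seed(6)
  ra <- binary_mask(matrix(runif(900) > 0.95, 30, 30), sp)
  rb <- binary_mask(matrix(runif(900) > 0.95, 30, 30), sp)
  expect_equal(unname(centerline_distance(ra, rb)),
               brute_centerline_distance(ra, rb, sp), tolerance = 1e-10)
  expect_error(centerline_distance(a, binary_mask(matrix(FALSE, 60, 60),
                                                  sp)))
})

test_that("mask alignment recovers translations and is antisymmetric", {
  set.seed(10)
  base <- matrix(FALSE, 40, 40)
  base[15:25, 5:35] <- TRUE
  base[10:30, 18:20] <- TRUE
  a <- binary_mask(base, 1)
  shifted <- angiocal:::shift_matrix(base, 3, -2, FALSE)
  b <- binary_mask(shifted, 1)
  expect_equal(align_by_parent_vessel(a, a), c(0L, 0L))
  expect_equal(align_by_parent_vessel(a, b), c(-3L, 2L))
  expect_equal(align_by_parent_vessel(a, b),
               -align_by_parent_vessel(b, a))
})
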