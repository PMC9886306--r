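#' Binary vessel mask
#'
#' A 2D boolean grid with physical pixel spacing. Pixels are 0-based
#' row-major in concept; pixel centers sit at `(index - 0.5) * spacing`.
#'
#' @param values logical (or coercible) matrix
#' @param spacing pixel size (um); the confocal in-plane resolution is
#'   2.254 um
#' @return a `binary_mask` (logical matrix with a `spacing` attribute)
#' @export
binary_mask <- function(values, spacing = 2.254) {
  m <- as.matrix(values)
  storage.mode(m) <- "logical"
  stopifnot(spacing > 0)
  structure(m, spacing = spacing, class = c("binary_mask", "matrix"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, spacing %g um, %d foreground px>\n",
              nrow(x), ncol(x), attr(x, "spacing"), sum(x)))
  invisible(x)
}

mask_spacing <- function(m) {
  s <- attr(m, "spacing")
  if (is.null(s)) 2.254 else s
}

shift_matrix <- function(m, di, dj, fill = 0L) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  xs <- max(1, 1 + di):min(nx, nx + di)
  ys <- max(1, 1 + dj):min(ny, ny + dj)
  if (length(xs) && length(ys))
    out[xs, ys] <- m[xs - di, ys - dj]
  out
}

#' Rasterize cells as filled disks
#'
#' Marks every pixel whose center lies within radius `R` of a cell center.
#'
#' @param x,y cell centers (um)
#' @param R disk radius (um), scalar or per cell
#' @param dim mask dimensions `c(nx, ny)`
#' @param spacing pixel size (um)
#' @return a [binary_mask()]
#' @export
rasterize_disks <- function(x, y, R, dim, spacing = 2.254) {
  m <- matrix(FALSE, dim[1], dim[2])
  R <- rep_len(R, length(x))
  for (k in seq_along(x)) {
    i0 <- max(1L, floor((x[k] - R[k]) / spacing))
    i1 <- min(dim[1], ceiling((x[k] + R[k]) / spacing) + 1L)
    j0 <- max(1L, floor((y[k] - R[k]) / spacing))
    j1 <- min(dim[2], ceiling((y[k] + R[k]) / spacing) + 1L)
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    px <- (ii - 0.5) * spacing - x[k]
    py <- (jj - 0.5) * spacing - y[k]
    d2 <- outer(px^2, py^2, "+")
    m[ii, jj] <- m[ii, jj] | (d2 <= R[k]^2)
  }
  binary_mask(m, spacing)
}

#' 8-connected component labels of a mask
#'
#' @param mask a [binary_mask()] or logical matrix
#' @return integer matrix of component labels (0 = background)
#' @export
label_components <- function(mask) {
  m <- unclass(mask) != 0
  lab <- matrix(0L, nrow(m), ncol(m))
  fg <- which(m)
  if (length(fg) == 0) return(lab)
  id <- match(seq_len(length(m)), fg)   # linear index -> node id
  parent <- seq_along(fg)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nx <- nrow(m)
  offsets <- c(1L, nx, nx - 1L, nx + 1L)  # S, E, NE, SE in linear index
  ri <- ((fg - 1L) %% nx) + 1L
  ci <- ((fg - 1L) %/% nx) + 1L
  for (oi in seq_along(offsets)) {
    off <- offsets[oi]
    nb <- fg + off
    ok <- switch(oi,
                 ri < nx,                     # S
                 ci < ncol(m),                # E
                 ri > 1 & ci < ncol(m),       # NE
                 ri < nx & ci < ncol(m))      # SE
    ok <- ok & nb >= 1 & nb <= length(m)
    ok[ok] <- m[nb[ok]]
    a <- id[fg[ok]]; b <- id[nb[ok]]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(fg), find, 0L)
  lab[fg] <- match(roots, unique(roots))
  lab
}

#' Project an image stack and binarize with intensity and area thresholds
#'
#' Averages the signal over the first `n_slices` z-slices, thresholds the
#' projection at `intensity_thr`, and removes 8-connected components
#' smaller than `min_area_px` pixels — the step that filters out stray
#' migratory endothelial cells that are not part of maturing vessels.
#'
#' @param stack 3D numeric array `[x, y, z]` of intensities, or an
#'   `image_stack` from [gen_confocal_stack()]
#' @param n_slices number of z-slices averaged (default all, up to 10)
#' @param intensity_thr intensity threshold on the mean projection
#' @param min_area_px minimum component area kept (pixels)
#' @param spacing pixel size (um)
#' @return a [binary_mask()]
#' @export
project_and_binarize <- function(stack, n_slices = NULL,
                                 intensity_thr = 0.5, min_area_px = 20,
                                 spacing = 2.254) {
  if (is.list(stack) && !is.null(stack$stack)) {
    if (!is.null(stack$spacing_xy)) spacing <- stack$spacing_xy
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 1)
  if (is.null(n_slices)) n_slices <- min(dim(stack)[3], 10L)
  stopifnot(n_slices <= dim(stack)[3])
  proj <- apply(stack[, , seq_len(n_slices), drop = FALSE], c(1, 2), mean)
  m <- proj > intensity_thr
  if (min_area_px > 1 && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    m[lab > 0 & sizes[pmax(lab, 1)] < min_area_px] <- FALSE
  }
  binary_mask(m, spacing)
}

#' Vascular density profile
#'
#' Counts foreground pixels summed along the vessel-length axis, giving a
#' 1D density profile over the transverse positions.
#'
#' @param mask a [binary_mask()]
#' @param axis axis summed over (the vessel-length axis): 1 for rows,
#'   2 for columns
#' @return integer vector of per-position foreground counts
#' @export
vascular_density <- function(mask, axis = 2) {
  stopifnot(axis %in% c(1, 2))
  m <- unclass(mask) != 0
  if (axis == 1) colSums(m) else rowSums(m)
}

#' Vascular area fraction
#'
#' Foreground pixels divided by total pixels of the domain.
#'
#' @param mask a [binary_mask()]
#' @return scalar in \[0, 1\]
#' @export
vascular_fraction <- function(mask) mean(unclass(mask) != 0)

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; zero when both masks are empty.
#'
#' @param a,b same-shape [binary_mask()]s
#' @return scalar in \[0, 1\]
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  a <- unclass(a) != 0; b <- unclass(b) != 0
  tot <- sum(a) + sum(b)
  if (tot == 0) return(0)
  2 * sum(a & b) / tot
}

#' Overlap percentage of consecutive masks
#'
#' `|A n B| / |A|` with `A` the earlier mask; `NA` when `A` is empty.
#' @keywords internal
#' @noRd
overlap_fraction <- function(a, b) {
  a <- unclass(a) != 0; b <- unclass(b) != 0
  if (sum(a) == 0) return(NA_real_)
  sum(a & b) / sum(a)
}

#' Select longitudinally consistent regions
#'
#' Screens candidate regions (each a list of aligned masks over time) for
#' local calibration: a region is kept when the Dice score between every
#' pair of consecutive time points exceeds `dice_thr` and its mean overlap
#' percentage (intersection over the earlier mask) is above the cohort
#' mean. This favors angiogenic sprouts that grow in place over random
#' endothelial cell migration.
#'
#' @param regions list of regions; each region is a list of >= 2 masks
#' @param dice_thr Dice threshold (default 0.5)
#' @return data.frame with per-region `min_dice`, `mean_overlap` and
#'   logical `selected`
#' @export
select_regions <- function(regions, dice_thr = 0.5) {
  stats <- lapply(regions, function(ms) {
    stopifnot(length(ms) >= 2)
    dc <- ov <- numeric(length(ms) - 1)
    for (i in seq_len(length(ms) - 1)) {
      dc[i] <- dice(ms[[i]], ms[[i + 1]])
      ov[i] <- overlap_fraction(ms[[i]], ms[[i + 1]])
    }
    c(min_dice = min(dc), mean_overlap = mean(ov))
  })
  out <- as.data.frame(do.call(rbind, stats))
  out$region <- seq_along(regions)
  cohort <- mean(out$mean_overlap, na.rm = TRUE)
  out$selected <- !is.na(out$mean_overlap) &
    out$min_dice > dice_thr & out$mean_overlap >= cohort
  out[, c("region", "min_dice", "mean_overlap", "selected")]
}

zs_neighbors <- function(m) {
  list(P2 = shift_matrix(m, 1, 0),   # N  (towards smaller row drawn up)
       P3 = shift_matrix(m, 1, -1),  # NE
       P4 = shift_matrix(m, 0, -1),  # E
       P5 = shift_matrix(m, -1, -1), # SE
       P6 = shift_matrix(m, -1, 0),  # S
       P7 = shift_matrix(m, -1, 1),  # SW
       P8 = shift_matrix(m, 0, 1),   # W
       P9 = shift_matrix(m, 1, 1))   # NW
}

zs_pass <- function(m, second) {
  nb <- zs_neighbors(m)
  B <- Reduce(`+`, nb)
  seqn <- nb[c("P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P2")]
  A <- 0
  for (i in 1:8) A <- A + (seqn[[i]] == 0 & seqn[[i + 1]] == 1)
  if (!second) {
    c1 <- nb$P2 * nb$P4 * nb$P6 == 0
    c2 <- nb$P4 * nb$P6 * nb$P8 == 0
  } else {
    c1 <- nb$P2 * nb$P4 * nb$P8 == 0
    c2 <- nb$P2 * nb$P6 * nb$P8 == 0
  }
  del <- m == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
  m[del] <- 0L
  m
}

#' Zhang-Suen skeletonization
#'
#' Thins a vessel mask to a one-pixel-wide centerline with the two-pass
#' Zhang-Suen parallel thinning algorithm, after an optional dilation
#' (3x3 square structuring element) that bridges small gaps in the mask.
#' Thinning is idempotent: re-skeletonizing a skeleton is the identity.
#'
#' @param mask a [binary_mask()]
#' @param dilate number of 3x3 dilation iterations before thinning
#' @return a [binary_mask()] holding the skeleton
#' @export
skeletonize <- function(mask, dilate = 0) {
  sp <- mask_spacing(mask)
  m <- unclass(mask) * 1L
  storage.mode(m) <- "integer"
  if (dilate > 0) {
    brush <- matrix(1L, 3, 3)
    for (i in seq_len(dilate))
      m <- (EBImage::dilate(m, brush) > 0) * 1L
  }
  repeat {
    m1 <- zs_pass(m, second = FALSE)
    m2 <- zs_pass(m1, second = TRUE)
    if (identical(m2, m)) break
    m <- m2
  }
  binary_mask(m, sp)
}

#' Bidirectional mean centerline distance
#'
#' For every foreground pixel of skeleton `a`, the Euclidean distance (via
#' the exact Euclidean distance transform) to the nearest foreground pixel
#' of skeleton `b`, averaged over `a`'s pixels — and likewise with the
#' roles reversed. Reported in um using the masks' pixel spacing.
#'
#' @param a,b same-shape nonempty [binary_mask()] skeletons
#' @return named numeric vector `c(mean_a_to_b, mean_b_to_a)` (um)
#' @export
centerline_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("skeleton shapes differ")
  am <- unclass(a) != 0; bm <- unclass(b) != 0
  if (!any(am) || !any(bm)) stop("empty skeleton")
  sp <- mask_spacing(a)
  d_to_b <- EBImage::distmap(1 - bm)
  d_to_a <- EBImage::distmap(1 - am)
  c(mean_a_to_b = mean(d_to_b[am]) * sp,
    mean_b_to_a = mean(d_to_a[bm]) * sp)
}

#' Align two masks by integer-pixel translation
#'
#' Finds the integer shift `c(di, dj)` maximizing the foreground overlap
#' when the second mask is translated by that shift — the parent-vessel
#' periphery (the dominant foreground structure) anchors the optimum.
#' `align_by_parent_vessel(a, b)` equals `-align_by_parent_vessel(b, a)`
#' when the optimum is unique; ties break toward the smallest shift.
#'
#' @param mask_t1,mask_t2 same-shape [binary_mask()]s
#' @param max_shift search radius (pixels)
#' @return integer vector `c(di, dj)`
#' @export
align_by_parent_vessel <- function(mask_t1, mask_t2, max_shift = 20) {
  if (!all(dim(mask_t1) == dim(mask_t2))) stop("mask shapes differ")
  a <- unclass(mask_t1) != 0; b <- unclass(mask_t2) != 0
  if (!any(a) || !any(b)) stop("vessel not detected")
  best <- c(0L, 0L); best_ov <- -1; best_norm <- Inf
  for (di in -max_shift:max_shift) {
    for (dj in -max_shift:max_shift) {
      ov <- sum(a & shift_matrix(b, di, dj, FALSE))
      nrm <- di^2 + dj^2
      if (ov > best_ov || (ov == best_ov && nrm < best_norm)) {
        best <- c(di, dj); best_ov <- ov; best_norm <- nrm
      }
    }
  }
  best
}
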