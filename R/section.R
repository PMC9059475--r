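#' Cross-sectional properties of a 2D slice mask
#'
#' Computes area, centroid, centroidal second moments of area, principal
#' moments and axes, the farthest material distances from the two principal
#' axes, and the geometric bending coefficients \code{Imax/C1} and
#' \code{Imin/C2}. Each voxel contributes as a filled square (its own
#' \code{a^4/12} plus the parallel-axis term), which removes the
#' point-mass bias on thin walls. \code{C1}/\code{C2} are measured from the
#' principal axes to the farthest foreground voxel centre.
#'
#' @param slice_mask logical matrix (one z-slice).
#' @param spacing_um voxel spacing, micrometres.
#' @return A one-row \code{data.frame}: \code{area} (mm^2), centroid
#'   \code{cx, cy} (mm), \code{ixx, iyy, ixy, imax, imin} (mm^4),
#'   \code{theta} (rad), \code{c1, c2} (mm), \code{imax_over_c1,
#'   imin_over_c2} (mm^3).
#' @export
section_properties <- function(slice_mask, spacing_um) {
  idx <- which(slice_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) undefined_metric("empty slice")
  a <- spacing_um / 1000
  x <- idx[, 1] * a
  y <- idx[, 2] * a
  n <- nrow(idx)
  area <- n * a^2
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  self_i <- a^4 / 12
  ixx <- sum(dy^2) * a^2 + n * self_i     # moment about the x axis
  iyy <- sum(dx^2) * a^2 + n * self_i
  ixy <- sum(dx * dy) * a^2
  m <- matrix(c(ixx, -ixy, -ixy, iyy), 2, 2)
  eg <- eigen(m, symmetric = TRUE)
  imax <- eg$values[1]; imin <- eg$values[2]
  v1 <- eg$vectors[, 1]                    # axis direction with I = imax
  v2 <- eg$vectors[, 2]
  if (abs(ixy) < 1e-12 * max(abs(ixx), abs(iyy), 1e-300) &&
      abs(ixx - iyy) < 1e-9 * max(abs(ixx), abs(iyy), 1e-300)) {
    v1 <- c(1, 0); v2 <- c(0, 1)           # tie: axes default to the grid
  }
  theta <- atan2(v1[2], v1[1])
  # perpendicular distance of material from each principal axis
  c1 <- max(abs(dx * (-v1[2]) + dy * v1[1]))
  c2 <- max(abs(dx * (-v2[2]) + dy * v2[1]))
  if (c1 <= 0 || c2 <= 0) {
    c1 <- max(c1, a / 2); c2 <- max(c2, a / 2)  # single-row sections
  }
  data.frame(area = area, cx = cx, cy = cy, ixx = ixx, iyy = iyy, ixy = ixy,
             imax = imax, imin = imin, theta = theta, c1 = c1, c2 = c2,
             imax_over_c1 = imax / c1, imin_over_c2 = imin / c2)
}

#' Per-slice rigidity profile along the shaft
#'
#' One \code{\link{section_properties}} row per z-slice, using the voxels of
#' the requested labels (default the whole mineralized section, cortical +
#' trabecular). If a modulus is supplied, the flexural rigidity
#' \code{E * Imin} is attached per slice (N mm^2 with E in MPa).
#'
#' @param volume a \code{voxel_volume}.
#' @param bone_labels labels forming the section.
#' @param modulus elastic modulus in MPa, optional.
#' @param drop_empty drop slices with no section voxels (default) instead of
#'   erroring.
#' @return \code{data.frame} with a leading \code{z} column (mm).
#' @export
rigidity_profile <- function(volume, bone_labels = c(LBL_CORTICAL,
                                                     LBL_TRABECULAR),
                             modulus = NULL, drop_empty = TRUE) {
  z <- slice_z(volume)
  rows <- vector("list", length(z))
  for (k in seq_along(z)) {
    m <- matrix(volume$labels[, , k] %in% bone_labels,
                dim(volume$labels)[1], dim(volume$labels)[2])
    if (!any(m)) {
      if (!drop_empty) undefined_metric(sprintf("slice %d is empty", k))
      next
    }
    rows[[k]] <- cbind(z = z[k], section_properties(m, volume$spacing))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L)
    undefined_metric("fewer than 2 nonempty slices")
  out <- do.call(rbind, rows)
  if (!is.null(modulus)) out$flexural_rigidity <- modulus * out$imin
  rownames(out) <- NULL
  out
}
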