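#' Select the standard metaphyseal volume of interest
#'
#' Crops the slices whose centres lie in the half-open axial interval
#' \code{[growth_plate_z + offset, growth_plate_z + offset + extent)}. The
#' defaults implement the standard trabecular VOI: a 2 mm region starting
#' 1 mm below the growth plate.
#'
#' @param volume a \code{voxel_volume} carrying a growth-plate coordinate.
#' @param offset distance below the growth plate where the VOI starts, mm.
#' @param extent axial extent of the VOI, mm.
#' @return The cropped \code{voxel_volume}.
#' @export
select_voi <- function(volume, offset = 1, extent = 2) {
  if (is.na(volume$growth_plate_z))
    range_error("volume has no growth-plate coordinate")
  if (offset < 0 || extent <= 0)
    param_error("offset must be >= 0 and extent > 0")
  z0 <- volume$growth_plate_z + offset
  z1 <- z0 + extent
  z <- slice_z(volume)
  if (z0 < z[1] - 1e-9 || z1 > z[length(z)] + spacing_mm(volume) + 1e-9)
    range_error("VOI exceeds the volume extent")
  crop_z(volume, z0, z1)
}

# signed Euclidean distance to the phase boundary, voxel units: positive
# inside the mask, negative outside, zero halfway between voxel centres.
signed_distance <- function(mask) {
  d <- dim(mask)
  din <- sqrt(.edt_sq(as.vector(mask), d))        # distance to background
  dout <- sqrt(.edt_sq(as.vector(!mask), d))      # distance to foreground
  sd <- ifelse(as.vector(mask), din - 0.5, -(dout - 0.5))
  array(sd, dim = d)
}

# triangulated isosurface area of a binary phase, physical units (mm^2),
# from the signed distance field at the given offset (voxels; positive
# offsets dilate). The discrete EDT level sets are scalloped (boundaries of
# unions of balls around lattice points), which inflates triangulated areas
# by ~10%; a 1-voxel Gaussian smoothing of the signed field removes the
# scallops while leaving planar boundaries exact. Faces against the array
# boundary stay open.
phase_surface_area <- function(mask, spacing_um, offset_vox = 0,
                               smooth_sigma = 1) {
  d <- dim(mask)
  sdf <- signed_distance(mask)
  sdf <- pmax(pmin(sdf, max(d)), -max(d))
  if (smooth_sigma > 0)
    sdf <- array(.gauss_smooth3(as.vector(sdf), d, smooth_sigma,
                                as.integer(ceiling(3 * smooth_sigma))),
                 dim = d)
  if (offset_vox != 0) {
    # smoothing averages the scallops' divergent unit gradients, leaving
    # |grad| < 1 and stretching the level spacing; renormalizing by the
    # local gradient magnitude restores metric offsets (the zero level is
    # unaffected)
    g2 <- array(0, dim = d)
    for (ax in 1:3) {
      hi <- lo <- seq_len(d[ax])
      hi <- pmin(hi + 1L, d[ax]); lo <- pmax(lo - 1L, 1L)
      idx_hi <- switch(ax, list(hi, TRUE, TRUE), list(TRUE, hi, TRUE),
                       list(TRUE, TRUE, hi))
      idx_lo <- switch(ax, list(lo, TRUE, TRUE), list(TRUE, lo, TRUE),
                       list(TRUE, TRUE, lo))
      gr <- (do.call(`[`, c(list(sdf), idx_hi)) -
               do.call(`[`, c(list(sdf), idx_lo))) / (hi - lo)[
                 slice.index(sdf, ax)]
      g2 <- g2 + gr^2
    }
    sdf <- sdf / pmax(sqrt(g2), 0.2)
  }
  a_vox <- .isosurface_area(as.vector(sdf), d, -offset_vox)
  a_vox * (spacing_um / 1000)^2
}

#' Global trabecular metrics: bone volume fraction and surface density
#'
#' \code{bvtv} is the foreground voxel count over the reference voxel count;
#' \code{bstv} is the triangulated isosurface area of the phase divided by
#' the reference volume. The isosurface is extracted from the signed distance
#' field of the mask at the half-voxel boundary, and faces on the VOI
#' boundary are left open (excluded), matching the open-face convention of
#' scanner morphometry software.
#'
#' @param mask logical 3D array of the bone phase within the VOI.
#' @param spacing_um voxel spacing, micrometres.
#' @param total_voxels reference voxel count for TV (defaults to the full
#'   array; pass the compartment voxel count to restrict TV to, e.g., the
#'   endosteal envelope).
#' @return \code{list(bvtv, bstv)} with \code{bstv} in 1/mm.
#' @export
global_metrics <- function(mask, spacing_um, total_voxels = length(mask)) {
  if (length(mask) == 0L || total_voxels <= 0)
    range_error("empty VOI")
  bv <- sum(mask)
  tv_mm3 <- total_voxels * (spacing_um / 1000)^3
  bs_mm2 <- if (bv == 0) 0 else phase_surface_area(mask, spacing_um)
  list(bvtv = bv / total_voxels, bstv = bs_mm2 / tv_mm3)
}

#' Model-independent local thickness map
#'
#' Thickness at a voxel is the diameter of the largest sphere that is fully
#' inscribed in the phase and contains the voxel (maximal-sphere definition,
#' computed from the Euclidean distance transform with a half-voxel boundary
#' offset). The volume-weighted mean of this map over the trabecular phase is
#' Tb.Th; the same computation on the intra-VOI background gives Tb.Sp.
#'
#' @param mask logical 3D array of the phase.
#' @param spacing_um voxel spacing, micrometres.
#' @return \code{list(map, mean)}: thickness map in mm (0 outside the phase)
#'   and its mean over the phase.
#' @export
local_thickness <- function(mask, spacing_um) {
  if (!any(mask)) undefined_metric("empty phase: local thickness undefined")
  d <- dim(mask)
  dt <- sqrt(.edt_sq(as.vector(mask), d))
  dt <- pmin(dt, max(d))  # degenerate all-foreground arrays stay bounded
  th_vox <- .local_thickness_vox(dt, d)
  map <- array(th_vox * spacing_um / 1000, dim = d)
  list(map = map, mean = mean(map[mask]))
}

#' Trabecular number by the direct 3D model-independent convention
#'
#' \code{Tb.N = 1 / (Tb.Th + Tb.Sp)}.
#'
#' @param tb_th trabecular thickness, mm.
#' @param tb_sp trabecular separation, mm.
#' @return Tb.N in 1/mm.
#' @export
trabecular_number <- function(tb_th, tb_sp) {
  if (tb_th + tb_sp <= 0)
    undefined_metric("Tb.N undefined when Tb.Th + Tb.Sp is zero")
  1 / (tb_th + tb_sp)
}

#' Structure model index
#'
#' \code{SMI = 6 V S' / S^2}, where \code{S'} is the derivative of the
#' isosurface area under unit surface dilation, estimated by central
#' difference of the area at symmetric signed-distance offsets (the central
#' difference is exact for the quadratic area growth of ideal shapes). Ideal
#' plates, cylinders and spheres give approximately 0, 3 and 4.
#'
#' @param mask logical 3D array of the bone phase.
#' @param spacing_um voxel spacing, micrometres.
#' @param step_vox dilation half-step, voxels (default 1).
#' @return SMI (unitless).
#' @export
structure_model_index <- function(mask, spacing_um, step_vox = 1) {
  if (sum(mask) < 2) undefined_metric("SMI undefined for degenerate objects")
  v_vox <- sum(mask)
  s0 <- phase_surface_area(mask, 1000, 0)        # voxel units (spacing 1 mm)
  if (s0 <= 0) undefined_metric("SMI undefined for zero-surface objects")
  s_plus <- phase_surface_area(mask, 1000, step_vox)
  s_minus <- phase_surface_area(mask, 1000, -step_vox)
  s_prime <- (s_plus - s_minus) / (2 * step_vox)
  6 * v_vox * s_prime / s0^2
}

#' Mean cortical thickness over a diaphyseal range
#'
#' Local-thickness mean of the cortical label within the given axial
#' interval.
#'
#' @param volume a \code{voxel_volume}.
#' @param z_range half-open axial interval \code{c(z_min, z_max)}, mm;
#'   \code{NULL} uses the whole volume.
#' @return Ct.Th in mm.
#' @export
cortical_thickness <- function(volume, z_range = NULL) {
  v <- if (is.null(z_range)) volume else crop_z(volume, z_range[1], z_range[2])
  mask <- v$labels == LBL_CORTICAL
  if (!any(mask)) undefined_metric("no cortical voxels in range")
  local_thickness(mask, v$spacing)$mean
}

#' Full trabecular + cortical morphometry report
#'
#' Applies the standard VOI rule and computes the seven ASBMR indices:
#' BV/TV, BS/TV, Tb.N, Tb.Th, Tb.Sp (trabecular compartment within the VOI)
#' and Ct.Th over a diaphyseal range, plus SMI. TV is the trabecular
#' compartment (trabecular + marrow voxels) when marrow is labeled, else the
#' full VOI box.
#'
#' @param volume a labeled \code{voxel_volume} with growth-plate metadata.
#' @param voi_offset,voi_extent VOI rule, mm.
#' @param diaphysis_range axial interval for Ct.Th, mm; default the last 25%
#'   of the volume.
#' @return A one-row \code{data.frame} with columns \code{bvtv, bstv, tb_n,
#'   tb_th, tb_sp, smi, ct_th}.
#' @export
morphometry_report <- function(volume, voi_offset = 1, voi_extent = 2,
                               diaphysis_range = NULL) {
  voi <- select_voi(volume, voi_offset, voi_extent)
  bone <- voi$labels == LBL_TRABECULAR
  compartment <- bone | voi$labels == LBL_MARROW
  total <- if (any(voi$labels == LBL_MARROW)) sum(compartment) else length(bone)
  gm <- global_metrics(bone, voi$spacing, total)
  th <- local_thickness(bone, voi$spacing)$mean
  sp_mask <- compartment & !bone
  sep <- local_thickness(sp_mask, voi$spacing)$mean
  smi <- structure_model_index(bone, voi$spacing)
  if (is.null(diaphysis_range)) {
    z <- slice_z(volume)
    diaphysis_range <- c(z[length(z)] - 0.25 * (z[length(z)] - z[1]),
                         z[length(z)] + spacing_mm(volume))
  }
  ct <- cortical_thickness(volume, diaphysis_range)
  data.frame(bvtv = gm$bvtv, bstv = gm$bstv,
             tb_n = trabecular_number(th, sep), tb_th = th, tb_sp = sep,
             smi = smi, ct_th = ct)
}
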