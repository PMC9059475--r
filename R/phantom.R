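#' Parameters for a synthetic femur phantom
#'
#' Describes a distal-femur stand-in: a tapered cortical shell around a
#' metaphyseal trabecular lattice and a marrow-filled diaphysis, voxelized on
#' an isotropic grid. The trabecular compartment is a regular three-axis rod
#' lattice with seeded positional jitter, so thickness and spacing have
#' analytic ground truth. When \code{trabecular_target_bvtv} is given, the rod
#' spacing is calibrated (closed-form union volume of three orthogonal rod
#' families, solved for spacing) so that the voxel-counted BV/TV in the
#' standard VOI matches the target.
#'
#' @param voxel_spacing isotropic voxel spacing, micrometres.
#' @param shaft_length diaphyseal shaft length beyond the metaphysis, mm.
#' @param outer_radius_profile \code{data.frame(z, r)} of outer radius (mm)
#'   versus axial position (mm), interpolated linearly; \code{NULL} builds a
#'   default profile from \code{r_metaphysis}/\code{r_shaft}.
#' @param r_metaphysis,r_shaft outer radii (mm) used for the default profile.
#' @param cortical_thickness cortical wall thickness, mm.
#' @param trabecular_target_bvtv target trabecular bone volume fraction in
#'   \code{[0, 1)}; \code{NA} uses \code{strut_spacing} as given.
#' @param strut_thickness trabecular rod diameter, mm.
#' @param strut_spacing trabecular rod lattice pitch, mm (initial value;
#'   recalibrated when a BV/TV target is set).
#' @param growth_plate_position axial coordinate (mm) of the growth plate.
#' @param metaphysis_extent axial extent (mm) of the trabecular compartment
#'   beyond the growth plate.
#' @param jitter_frac positional jitter of each rod, as a fraction of the
#'   pitch.
#' @param include_marrow label non-bone interior voxels as marrow (3) rather
#'   than background.
#' @param seed integer seed controlling the jitter.
#' @return A validated \code{phantom_params} list.
#' @export
phantom_params <- function(voxel_spacing = 11.25,
                           shaft_length = 2.5,
                           outer_radius_profile = NULL,
                           r_metaphysis = 0.8,
                           r_shaft = 0.6,
                           cortical_thickness = 0.2,
                           trabecular_target_bvtv = 0.12,
                           strut_thickness = 0.06,
                           strut_spacing = 0.24,
                           growth_plate_position = 0.3,
                           metaphysis_extent = 3.2,
                           jitter_frac = 0.08,
                           include_marrow = TRUE,
                           seed = 1L) {
  if (voxel_spacing <= 0) param_error("voxel_spacing must be > 0")
  if (!is.na(trabecular_target_bvtv) &&
      (trabecular_target_bvtv < 0 || trabecular_target_bvtv >= 1))
    param_error("trabecular_target_bvtv must be in [0, 1)")
  total_length <- growth_plate_position + metaphysis_extent + shaft_length
  if (is.null(outer_radius_profile)) {
    zm <- growth_plate_position + metaphysis_extent
    outer_radius_profile <- data.frame(
      z = c(0, zm - 1, zm, total_length),
      r = c(r_metaphysis, r_metaphysis, r_shaft, r_shaft))
  }
  if (cortical_thickness >= min(outer_radius_profile$r))
    param_error("cortical_thickness must be smaller than the minimum outer radius")
  if (strut_thickness < 2 * voxel_spacing / 1000)
    param_error("strut_thickness must be at least 2 voxels")
  if (strut_spacing <= strut_thickness)
    param_error("strut_spacing must exceed strut_thickness")
  structure(list(voxel_spacing = voxel_spacing, shaft_length = shaft_length,
                 outer_radius_profile = outer_radius_profile,
                 cortical_thickness = cortical_thickness,
                 trabecular_target_bvtv = trabecular_target_bvtv,
                 strut_thickness = strut_thickness,
                 strut_spacing = strut_spacing,
                 growth_plate_position = growth_plate_position,
                 metaphysis_extent = metaphysis_extent,
                 jitter_frac = jitter_frac,
                 include_marrow = include_marrow,
                 total_length = total_length, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Genotype presets for WT/KO phantom cohorts
#'
#' The knockout preset encodes the contrast ratios of the study phenotype:
#' trabecular BV/TV at 0.25x the wild-type target, slightly thicker and much
#' sparser struts, an unchanged cortical wall, and a reduced diaphyseal outer
#' radius (smaller mid-shaft cross section). Elastic moduli (GPa, from
#' nanoindentation group means) are attached as the \code{moduli} attribute:
#' WT cortical El/Et exceed KO by 43%/51%, trabecular by 33%/25%, with
#' anisotropy ratios inside the observed ranges.
#'
#' @param genotype \code{"wt"} or \code{"ko"}.
#' @param voxel_spacing voxel spacing, micrometres.
#' @param seed integer seed; also drives the per-specimen anatomy scatter.
#' @param specimen_cv coefficient of variation of the per-specimen outer
#'   radii (biological size scatter within a genotype; 0 disables it).
#' @return \code{phantom_params} with a \code{moduli} attribute (GPa).
#' @export
phantom_presets <- function(genotype = c("wt", "ko"), voxel_spacing = 11.25,
                            seed = 1L, specimen_cv = 0.03) {
  genotype <- match.arg(genotype)
  set.seed(seed + 20000L)
  rf <- max(1 + rnorm(1, 0, specimen_cv), 0.85)
  if (genotype == "wt") {
    p <- phantom_params(voxel_spacing = voxel_spacing,
                        trabecular_target_bvtv = 0.12,
                        strut_thickness = 0.060,
                        r_shaft = 0.60 * rf, r_metaphysis = 0.80 * rf,
                        cortical_thickness = 0.2, seed = seed)
    moduli <- c(cortical_el = 10.0, cortical_et = 7.55,
                trabecular_el = 7.3, trabecular_et = 5.0)
  } else {
    p <- phantom_params(voxel_spacing = voxel_spacing,
                        trabecular_target_bvtv = 0.03,
                        strut_thickness = 0.066,
                        r_shaft = 0.49 * rf, r_metaphysis = 0.72 * rf,
                        cortical_thickness = 0.2, seed = seed)
    moduli <- c(cortical_el = 10.0 / 1.43, cortical_et = 7.55 / 1.51,
                trabecular_el = 7.3 / 1.33, trabecular_et = 5.0 / 1.25)
  }
  attr(p, "moduli") <- moduli
  attr(p, "genotype") <- genotype
  p
}

# Continuous solid fraction of a cubic lattice of three orthogonal rod
# families (diameter t, pitch s), by inclusion-exclusion: three cylinders
# minus three pairwise crossings plus the Steinmetz tricylinder core.
rod_lattice_fraction <- function(t, s) {
  r <- t / 2
  3 * pi * r^2 / s^2 - 3 * (16 / 3) * r^3 / s^3 + 8 * (2 - sqrt(2)) * r^3 / s^3
}

# Solve the pitch s for a requested solid fraction at fixed rod diameter.
calibrate_strut_spacing <- function(t, target) {
  lo <- t * 1.05
  if (rod_lattice_fraction(t, lo) < target)
    param_error("trabecular_target_bvtv unreachable at this strut_thickness")
  uniroot(function(s) rod_lattice_fraction(t, s) - target,
          lower = lo, upper = t * 200, tol = 1e-10)$root
}

# 2D mask of jittered lattice discs: coords u, v (mm, centred), pitch s,
# diameter t, per-disc jitter drawn from the supplied RNG-seeded matrix pair.
disc_lattice_mask <- function(u, v, s, t, jit_u, jit_v) {
  nu <- length(u); nv <- length(v)
  iu <- pmin(pmax(round(outer(u, rep(1, nv)) / s), 0L), nrow(jit_u) - 1L)
  iv <- pmin(pmax(round(outer(rep(1, nu), v) / s), 0L), ncol(jit_u) - 1L)
  idx <- iu + nrow(jit_u) * iv + 1L
  cu <- iu * s + jit_u[idx]
  cv <- iv * s + jit_v[idx]
  (outer(u, rep(1, nv)) - cu)^2 + (outer(rep(1, nu), v) - cv)^2 <= (t / 2)^2
}

#' Generate a synthetic femur phantom
#'
#' Builds the labeled voxel volume described by \code{\link{phantom_params}}:
#' a closed cortical ring in every slice, a trabecular rod lattice in the
#' metaphysis (growth plate to growth plate + metaphysis extent), and marrow
#' elsewhere inside the shell. Deterministic for a fixed seed.
#'
#' @param params a \code{phantom_params} object.
#' @return \code{list(volume, ground_truth)} where \code{ground_truth} holds
#'   the design BV/TV, rod thickness and pitch, expected separation, analytic
#'   per-slice section properties of the cortical ring, and (for presets) the
#'   tissue modulus map.
#' @export
make_femur_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  sp <- params$voxel_spacing / 1000  # mm
  t <- params$strut_thickness
  s <- params$strut_spacing
  target <- params$trabecular_target_bvtv
  if (!is.na(target) && target > 0)
    s <- calibrate_strut_spacing(t, target)

  nz <- as.integer(ceiling(params$total_length / sp))
  rmax <- max(params$outer_radius_profile$r)
  nxy <- as.integer(2 * ceiling(rmax / sp) + 5)
  xy <- (seq_len(nxy) - (nxy + 1) / 2) * sp          # centred coords, mm
  z <- (seq_len(nz) - 1) * sp
  rr2 <- outer(xy^2, xy^2, "+")

  # seeded per-rod jitter, one offset pair per rod in each of the 3 families
  rng <- local({set.seed(params$seed); NULL})
  set.seed(params$seed)
  jmax <- params$jitter_frac * s
  ncell_xy <- as.integer(ceiling((max(xy) - 0) / s)) + 2L
  ncell_z <- as.integer(ceiling(max(z) / s)) + 2L
  jit <- function(n1, n2) matrix(runif(n1 * n2, -jmax, jmax), n1, n2)
  jxy_u <- jit(2 * ncell_xy, 2 * ncell_xy); jxy_v <- jit(2 * ncell_xy, 2 * ncell_xy)
  jyz_u <- jit(2 * ncell_xy, ncell_z); jyz_v <- jit(2 * ncell_xy, ncell_z)
  jxz_u <- jit(2 * ncell_xy, ncell_z); jxz_v <- jit(2 * ncell_xy, ncell_z)

  # lattice masks; lattice coordinates are shifted to be nonnegative so that
  # cell indexing is stable
  u0 <- xy - min(xy)
  m_xy <- disc_lattice_mask(u0, u0, s, t, jxy_u, jxy_v)   # rods along z
  m_yz <- disc_lattice_mask(u0, z, s, t, jyz_u, jyz_v)    # rods along x
  m_xz <- disc_lattice_mask(u0, z, s, t, jxz_u, jxz_v)    # rods along y

  rprof <- approx(params$outer_radius_profile$z, params$outer_radius_profile$r,
                  xout = z, rule = 2)$y
  gp <- params$growth_plate_position
  meta_hi <- gp + params$metaphysis_extent
  ct <- params$cortical_thickness

  labels <- array(0L, dim = c(nxy, nxy, nz))
  for (k in seq_len(nz)) {
    ro <- rprof[k]; ri <- ro - ct
    sl <- matrix(0L, nxy, nxy)
    ring <- rr2 <= ro^2 & rr2 > ri^2
    interior <- rr2 <= ri^2
    sl[ring] <- LBL_CORTICAL
    if (z[k] >= gp && z[k] < meta_hi && !is.na(target) && target > 0) {
      trab <- (m_xy | outer(m_xz[, k], rep(TRUE, nxy)) |
                 outer(rep(TRUE, nxy), m_yz[, k])) & interior
      sl[trab] <- LBL_TRABECULAR
      sl[interior & !trab] <- if (params$include_marrow) LBL_MARROW else 0L
    } else {
      sl[interior] <- if (params$include_marrow) LBL_MARROW else 0L
    }
    labels[, , k] <- sl
  }

  vol <- voxel_volume(labels, params$voxel_spacing, c(min(xy), min(xy), 0), gp)
  ring_props <- data.frame(
    z = z, outer_radius = rprof, inner_radius = rprof - ct,
    area = pi * (rprof^2 - (rprof - ct)^2),
    i_ring = pi * (rprof^4 - (rprof - ct)^4) / 4)
  gt <- list(true_bvtv = if (is.na(target)) rod_lattice_fraction(t, s) else target,
             true_strut_thickness = t, true_strut_spacing = s,
             # pore inscribed-sphere diameter: cell-edge rods all lie at
             # perpendicular distance s/sqrt(2) from the cell centre
             true_separation = sqrt(2) * s - t,
             cortical_thickness = ct,
             section_properties_per_slice = ring_props,
             true_E_map = attr(params, "moduli"),
             genotype = attr(params, "genotype"))
  list(volume = vol, ground_truth = gt)
}

#' Generate a prismatic beam phantom with closed-form section properties
#'
#' Voxelizes a prism of constant cross section along z, as an analytic oracle
#' for section analysis and finite-element bending.
#'
#' @param section_shape one of \code{"circle"}, \code{"annulus"},
#'   \code{"square"}, \code{"ellipse"}.
#' @param dimensions named numeric: \code{r} (circle), \code{ro, ri}
#'   (annulus), \code{a} (square side), \code{a, b} (ellipse semi-axes), mm.
#' @param length prism length, mm.
#' @param spacing voxel spacing, micrometres.
#' @param label voxel label for the solid phase (default cortical).
#' @param angle in-plane rotation of the section, radians.
#' @return \code{list(volume, ground_truth)}; the ground truth holds the
#'   closed-form area and second moments of area (e.g. circle
#'   \code{I = pi r^4 / 4}).
#' @export
make_prism_phantom <- function(section_shape, dimensions, length, spacing,
                               label = LBL_CORTICAL, angle = 0) {
  if (any(unlist(dimensions) <= 0) || length <= 0 || spacing <= 0)
    param_error("dimensions, length and spacing must be positive")
  sp <- spacing / 1000
  dm <- as.list(dimensions)
  half <- switch(section_shape,
    circle = dm$r, annulus = dm$ro, square = dm$a / 2 * sqrt(2),
    ellipse = max(dm$a, dm$b),
    param_error(paste("unknown section shape:", section_shape)))
  nxy <- as.integer(2 * ceiling(half / sp) + 6)   # even
  # half-voxel lattice offset keeps shape boundaries off voxel centres
  # (otherwise an inclusive boundary adds a full voxel row to, e.g., a
  # square of side exactly a)
  xy <- (seq_len(nxy) - nxy / 2) * sp - sp / 2
  nz <- as.integer(round(length / sp))
  X <- outer(xy, rep(1, nxy)); Y <- outer(rep(1, nxy), xy)
  if (angle != 0) {
    Xr <- cos(angle) * X + sin(angle) * Y
    Yr <- -sin(angle) * X + cos(angle) * Y
    X <- Xr; Y <- Yr
  }
  mask <- switch(section_shape,
    circle = X^2 + Y^2 <= dm$r^2,
    annulus = {
      r2 <- X^2 + Y^2
      r2 <= dm$ro^2 & r2 > dm$ri^2
    },
    square = abs(X) <= dm$a / 2 & abs(Y) <= dm$a / 2,
    ellipse = (X / dm$a)^2 + (Y / dm$b)^2 <= 1)
  gt <- switch(section_shape,
    circle = list(area = pi * dm$r^2, imax = pi * dm$r^4 / 4,
                  imin = pi * dm$r^4 / 4, c1 = dm$r, c2 = dm$r),
    annulus = list(area = pi * (dm$ro^2 - dm$ri^2),
                   imax = pi * (dm$ro^4 - dm$ri^4) / 4,
                   imin = pi * (dm$ro^4 - dm$ri^4) / 4,
                   c1 = dm$ro, c2 = dm$ro),
    square = list(area = dm$a^2, imax = dm$a^4 / 12, imin = dm$a^4 / 12,
                  c1 = dm$a / 2, c2 = dm$a / 2),
    ellipse = {
      i_major <- pi * dm$a * dm$b^3 / 4  # about the long axis if a > b
      i_minor <- pi * dm$b * dm$a^3 / 4
      list(area = pi * dm$a * dm$b, imax = max(i_major, i_minor),
           imin = min(i_major, i_minor),
           c1 = if (i_minor > i_major) dm$a else dm$b,
           c2 = if (i_minor > i_major) dm$b else dm$a)
    })
  gt$shape <- section_shape
  gt$length <- nz * sp
  labels <- array(0L, dim = c(nxy, nxy, nz))
  sl <- matrix(0L, nxy, nxy)
  sl[mask] <- as.integer(label)
  labels[] <- rep(sl, nz)
  list(volume = voxel_volume(labels, spacing, c(min(xy), min(xy), 0)),
       ground_truth = gt)
}
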