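#' Force-indentation curve container
#'
#' @param depth indentation depth, nm (non-negative, increasing).
#' @param force measured force, nN.
#' @param probe_radius spherical probe radius, nm.
#' @param poisson_ratio sample Poisson's ratio (default 0.3 for bone).
#' @param frequency indentation frequency, Hz (optional).
#' @param orientation \code{"longitudinal"} or \code{"transverse"}.
#' @param compartment \code{"cortical"} or \code{"trabecular"}.
#' @return A \code{force_indentation_curve}.
#' @export
force_indentation_curve <- function(depth, force, probe_radius = 300,
                                    poisson_ratio = 0.3,
                                    frequency = NA_real_,
                                    orientation = c("longitudinal",
                                                    "transverse"),
                                    compartment = c("cortical",
                                                    "trabecular")) {
  if (length(depth) != length(force) || length(depth) < 10)
    param_error("depth and force must have equal length >= 10")
  if (probe_radius <= 0) param_error("probe_radius must be > 0")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    param_error("poisson_ratio must be in [0, 0.5)")
  structure(list(depth = as.numeric(depth), force = as.numeric(force),
                 probe_radius = probe_radius, poisson_ratio = poisson_ratio,
                 frequency = frequency,
                 orientation = match.arg(orientation),
                 compartment = match.arg(compartment)),
            class = "force_indentation_curve")
}

#' Hertz forward model for a rigid sphere on an elastic half-space
#'
#' \code{F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)}. With depth and
#' radius in nm and modulus in GPa the force comes out in nN.
#'
#' @param delta indentation depth, nm.
#' @param E elastic modulus, GPa.
#' @param nu Poisson's ratio.
#' @param R probe radius, nm.
#' @return Force, nN.
#' @export
hertz_force <- function(delta, E, nu, R) {
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * pmax(delta, 0)^1.5
}

#' Synthesize a Hertzian force-indentation curve
#'
#' Samples the spherical-contact forward model on a uniform depth grid, with a
#' flat pre-contact baseline of extent \code{contact_offset} and additive
#' Gaussian force noise.
#'
#' @param E true modulus, GPa.
#' @param nu Poisson's ratio.
#' @param R probe radius, nm.
#' @param depth_max maximum sampled depth, nm (the study design keeps
#'   indentation below 50 nm so the response stays in the infinitesimal
#'   elastic regime).
#' @param n_points samples on the depth grid.
#' @param noise_sd additive Gaussian force noise, nN.
#' @param contact_offset depth at which contact begins, nm.
#' @param seed integer seed for the noise.
#' @param ... metadata passed to \code{\link{force_indentation_curve}}.
#' @return A \code{force_indentation_curve} with a \code{ground_truth}
#'   attribute.
#' @export
synth_indentation_curve <- function(E, nu = 0.3, R = 300, depth_max = 50,
                                    n_points = 200, noise_sd = 0,
                                    contact_offset = 0, seed = 1L, ...) {
  if (depth_max <= 0) param_error("depth_max must be > 0")
  if (E <= 0) param_error("E must be > 0")
  depth <- seq(0, depth_max + contact_offset, length.out = n_points)
  force <- hertz_force(depth - contact_offset, E, nu, R)
  if (noise_sd > 0) {
    set.seed(seed)
    force <- force + rnorm(n_points, 0, noise_sd)
  }
  curve <- force_indentation_curve(depth, force, probe_radius = R,
                                   poisson_ratio = nu, ...)
  attr(curve, "ground_truth") <- list(E = E, contact_offset = contact_offset)
  curve
}

#' Synthesize a frequency sweep of indentation curves
#'
#' One curve per frequency, generated with modulus
#' \code{E(f) = a + b * log(f)}, the empirical log-frequency stiffening law
#' for hydrated bone at 1-100 Hz.
#'
#' @param a modulus at 1 Hz, GPa.
#' @param b stiffening slope, GPa per ln(Hz).
#' @param freqs frequencies, Hz.
#' @param seed integer seed.
#' @param ... forwarded to \code{\link{synth_indentation_curve}}.
#' @return List of \code{force_indentation_curve}, one per frequency.
#' @export
synth_frequency_sweep <- function(a, b, freqs = c(1, 5, 10, 50, 100),
                                  seed = 1L, ...) {
  if (any(freqs <= 0)) param_error("all frequencies must be > 0")
  E <- a + b * log(freqs)
  if (any(E <= 0))
    param_error("a + b*log(f) must be positive at every requested frequency")
  lapply(seq_along(freqs), function(i) {
    cv <- synth_indentation_curve(E[i], seed = seed + i - 1, ...)
    cv$frequency <- freqs[i]
    cv
  })
}

#' Load-displacement curve from a three-point bending test
#'
#' @param displacement mm, non-decreasing, starting at 0.
#' @param force N.
#' @param loading_rate mm/s (default 0.05, the protocol rate).
#' @param span support span, mm.
#' @return A \code{load_displacement_curve}.
#' @export
load_displacement_curve <- function(displacement, force, loading_rate = 0.05,
                                    span = 7) {
  if (length(displacement) != length(force) || length(displacement) < 20)
    param_error("displacement and force must have equal length >= 20")
  if (displacement[1] != 0) param_error("displacement must start at 0")
  if (any(diff(displacement) < 0)) data_error("displacement must be non-decreasing")
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force),
                 loading_rate = loading_rate, span = span),
            class = "load_displacement_curve")
}

#' Synthesize a three-point-bending load-displacement record
#'
#' Piecewise curve with a quadratic toe (apparatus/specimen engagement), a
#' linear elastic segment of the requested stiffness, post-yield hardening to
#' the ultimate load, a shallow post-peak decline, and a sharp drop at
#' fracture. The maximum slope of the noise-free curve equals
#' \code{stiffness}; the peak force equals \code{ultimate_load}.
#'
#' @param toe_extent toe region extent, mm.
#' @param stiffness elastic slope, N/mm.
#' @param yield_load load at yield, N.
#' @param ultimate_load peak load, N.
#' @param fracture_disp displacement at fracture, mm.
#' @param hardening_frac post-yield slope as a fraction of \code{stiffness}.
#' @param n_points samples on the uniform displacement grid.
#' @param noise_sd additive Gaussian force noise, N.
#' @param seed integer seed.
#' @return \code{load_displacement_curve} with a \code{ground_truth}
#'   attribute (stiffness, yield, ultimate, displacement at ultimate, work to
#'   fracture of the noise-free curve).
#' @export
synth_bending_curve <- function(toe_extent = 0.05, stiffness = 120,
                                yield_load = 15, ultimate_load = 25,
                                fracture_disp = 0.6, hardening_frac = 0.2,
                                n_points = 400, noise_sd = 0, seed = 1L) {
  if (stiffness <= 0) param_error("stiffness must be > 0")
  if (yield_load >= ultimate_load)
    param_error("yield_load must be below ultimate_load")
  if (toe_extent < 0) param_error("toe_extent must be >= 0")
  f_toe <- stiffness * toe_extent / 2          # end of quadratic toe
  d_yield <- toe_extent + (yield_load - f_toe) / stiffness
  if (d_yield <= toe_extent)
    param_error("yield_load too small for the requested toe")
  k2 <- hardening_frac * stiffness
  d_ult <- d_yield + (ultimate_load - yield_load) / k2
  if (fracture_disp <= d_ult)
    param_error("fracture_disp must exceed the displacement at ultimate load")

  shape <- function(d) {
    ifelse(d <= toe_extent & toe_extent > 0,
           stiffness * d^2 / (2 * max(toe_extent, 1e-12)),
    ifelse(d <= d_yield, f_toe + stiffness * (d - toe_extent),
    ifelse(d <= d_ult, yield_load + k2 * (d - d_yield),
           ultimate_load - 0.15 * stiffness * (d - d_ult))))
  }
  d_end <- fracture_disp * 1.05
  displacement <- seq(0, d_end, length.out = n_points)
  # place the curve breakpoints on the grid exactly so the sampled peak
  # equals the designed ultimate load; drop float near-duplicates, which
  # would make finite-difference slopes meaningless
  displacement <- sort(c(displacement, toe_extent, d_yield, d_ult,
                         fracture_disp))
  step <- d_end / (n_points - 1)
  displacement <- displacement[c(TRUE, diff(displacement) > step * 1e-6)]
  force <- shape(displacement)
  force[displacement > fracture_disp] <- 0.02 * ultimate_load
  force <- pmax(force, 0)
  # ground truth from the noise-free record
  pre <- displacement <= fracture_disp
  work <- sum(diff(displacement[pre]) *
                (head(force[pre], -1) + tail(force[pre], -1)) / 2)
  if (noise_sd > 0) {
    set.seed(seed)
    force <- pmax(force + rnorm(length(force), 0, noise_sd), 0)
  }
  curve <- load_displacement_curve(displacement, force)
  attr(curve, "ground_truth") <- list(
    stiffness = stiffness, yield_load = yield_load,
    ultimate_load = ultimate_load, ultimate_displacement = d_ult,
    fracture_disp = fracture_disp, work_to_fracture = work,
    elastic_window = c(toe_extent, d_yield))
  curve
}

#' Genotype presets for three-point-bending generator parameters
#'
#' Group means encoding the whole-bone mechanical contrast: WT maximum load
#' 27 N vs KO 18 N (50\% larger), yield and ultimate ~60\% larger in WT,
#' stiffness ~30\% larger, and fracture displacements chosen so the WT work
#' to fracture comes out ~40\% larger.
#'
#' @param genotype \code{"wt"} or \code{"ko"}.
#' @return Named list of \code{\link{synth_bending_curve}} arguments.
#' @export
bending_presets <- function(genotype = c("wt", "ko")) {
  genotype <- match.arg(genotype)
  if (genotype == "wt")
    list(toe_extent = 0.05, stiffness = 126, yield_load = 16,
         ultimate_load = 27, fracture_disp = 0.60)
  else
    list(toe_extent = 0.05, stiffness = 97, yield_load = 10,
         ultimate_load = 18, fracture_disp = 0.62)
}

#' Synthesize a cohort of bending curves for one genotype
#'
#' Per-specimen generator parameters are the genotype preset means scaled by
#' a seeded lognormal-like factor (\code{cv}), emulating biological scatter.
#'
#' @param genotype \code{"wt"} or \code{"ko"}.
#' @param n specimens.
#' @param seed integer seed.
#' @param cv per-specimen parameter coefficient of variation.
#' @param noise_sd force noise per curve, N.
#' @return List of \code{load_displacement_curve}s with ground truth
#'   attributes.
#' @export
synth_bending_cohort <- function(genotype, n = 7, seed = 1L, cv = 0.05,
                                 noise_sd = 0.1) {
  base <- bending_presets(genotype)
  lapply(seq_len(n), function(i) {
    set.seed(seed + 100L * i)
    f <- max(1 + rnorm(1, 0, cv), 0.8)
    do.call(synth_bending_curve,
            c(list(stiffness = base$stiffness * f,
                   yield_load = base$yield_load * f,
                   ultimate_load = base$ultimate_load * f,
                   fracture_disp = base$fracture_disp,
                   toe_extent = base$toe_extent,
                   noise_sd = noise_sd, seed = seed + 100L * i + 1L)))
  })
}

#' Synthesize a calcein double-label measurement set
#'
#' Emulates dynamic histomorphometry fields from a 7-day double-calcein
#' protocol: per-field interlabel distances with mean
#' \code{mar_true * interval}, and double-/single-labeled surface extents
#' consistent with the target mineralizing surface fraction.
#'
#' @param mar_true true mineral apposition rate, um/day.
#' @param msbs_true true MS/BS fraction in \code{[0, 1]}.
#' @param n_fields number of measurement fields.
#' @param interval days between calcein doses.
#' @param distances_per_field interlabel measurements per field.
#' @param noise_frac relative measurement noise.
#' @param seed integer seed.
#' @return A \code{histo_label_set}: pooled interlabel distances (um), a
#'   per-field surface table (mm), and the label interval.
#' @export
synth_calcein_dataset <- function(mar_true, msbs_true, n_fields = 20,
                                  interval = 7, distances_per_field = 10,
                                  noise_frac = 0.1, seed = 1L) {
  if (msbs_true < 0 || msbs_true > 1) param_error("msbs_true must be in [0, 1]")
  set.seed(seed)
  mu <- mar_true * interval
  distances <- pmax(rnorm(n_fields * distances_per_field, mu,
                          noise_frac * max(mu, 1e-12)), 0)
  bs <- rep(2.0, n_fields)  # mm of bone surface traced per field
  ms_f <- pmin(pmax(rnorm(n_fields, msbs_true,
                          noise_frac * msbs_true), 0), 1)
  sl <- 0.3 * ms_f * bs
  dl <- ms_f * bs - 0.5 * sl
  out <- histo_label_set(distances = distances,
                         fields = data.frame(dl_surface = dl, sl_surface = sl,
                                             total_bone_surface = bs),
                         interval = interval)
  attr(out, "ground_truth") <- list(mar = mar_true, ms_bs = msbs_true,
                                    bfr_bs = mar_true * msbs_true)
  out
}
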