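#' Detect the contact point of a force-indentation curve
#'
#' First pass: the contact offset is the first depth at which the force
#' exceeds the pre-contact baseline mean by \code{force_threshold_sd}
#' baseline standard deviations. The estimate is then refined by
#' back-extrapolation: the offset minimizing the residual of the
#' origin-constrained Hertz fit in a window around the threshold crossing.
#'
#' @param curve a \code{force_indentation_curve}.
#' @param force_threshold_sd threshold in baseline SD units.
#' @param baseline_frac fraction of the curve treated as candidate baseline.
#' @return Contact offset, nm.
#' @export
detect_contact_point <- function(curve, force_threshold_sd = 3,
                                 baseline_frac = 0.1) {
  f <- curve$force; d <- curve$depth
  nb <- max(5L, floor(length(f) * baseline_frac))
  base <- f[seq_len(nb)]
  thr <- mean(base) + force_threshold_sd * max(sd(base), 1e-6 * max(abs(f), 1))
  ix <- which(f > thr)
  if (length(ix) == 0L)
    data_error("no contact: force never exceeds the baseline threshold")
  i0 <- ix[1]
  lo <- d[1]                     # a zero-offset curve must be reachable
  hi <- d[min(i0 + 5L, length(d))]
  if (hi <= lo) return(d[i0])
  rss <- function(off) {
    dd <- d - off
    use <- dd > 0
    if (sum(use) < 3) return(Inf)
    x <- dd[use]^1.5; y <- f[use]
    slope <- sum(x * y) / sum(x * x)
    sum((y - slope * x)^2)
  }
  optimize(rss, c(lo, hi))$minimum
}

#' Fit the Hertzian spherical-contact model
#'
#' Linearized least squares of force on \code{depth^(3/2)} through the
#' origin, over the post-contact window capped at \code{depth_cap}
#' (infinitesimal-strain regime; 50 nm by default). The modulus follows from
#' \code{E = 3 F (1 - nu^2) / (4 sqrt(R delta^3))}, i.e. the inversion of
#' \code{F = (4/3) E / (1 - nu^2) sqrt(R) delta^(3/2)}. With nm and nN units
#' the modulus is in GPa.
#'
#' @param curve a \code{force_indentation_curve}.
#' @param depth_cap maximum post-contact depth used, nm.
#' @param contact_offset contact point, nm; \code{NULL} detects it (or uses 0
#'   when the curve has no pre-contact baseline).
#' @param detect detect the contact point before fitting.
#' @return \code{list(modulus_e, contact_offset, residual_rms, n_points,
#'   depth_window)}.
#' @export
fit_hertz <- function(curve, depth_cap = 50, contact_offset = NULL,
                      detect = FALSE) {
  if (is.null(contact_offset))
    contact_offset <- if (detect) detect_contact_point(curve) else 0
  dd <- curve$depth - contact_offset
  use <- dd > 0 & dd <= depth_cap
  if (sum(use) < 10)
    data_error("fewer than 10 usable post-contact samples below the depth cap")
  x <- dd[use]^1.5
  y <- curve$force[use]
  slope <- sum(x * y) / sum(x * x)
  if (slope <= 0) data_error("Hertz fit failed: nonpositive slope")
  e <- slope * 3 * (1 - curve$poisson_ratio^2) / (4 * sqrt(curve$probe_radius))
  list(modulus_e = e, contact_offset = contact_offset,
       residual_rms = sqrt(mean((y - slope * x)^2)), n_points = sum(use),
       depth_window = c(0, depth_cap))
}

#' Point inversion of the Hertz relation
#'
#' \code{E = 3 F (1 - nu^2) / (4 sqrt(R delta^3))} for a single
#' (depth, force) observation.
#'
#' @param force nN.
#' @param delta depth, nm.
#' @param nu Poisson's ratio.
#' @param R probe radius, nm.
#' @return Modulus, GPa.
#' @export
hertz_modulus <- function(force, delta, nu = 0.3, R = 300) {
  3 * force * (1 - nu^2) / (4 * sqrt(R * delta^3))
}

#' Summarize longitudinal/transverse moduli and anisotropy per group
#'
#' Groups Hertz fits by compartment (and any further grouping column, e.g.
#' genotype) and reports the mean and SD of the longitudinal (El) and
#' transverse (Et) moduli, group sizes, and the anisotropy ratio
#' \code{mean(El) / mean(Et)}.
#'
#' @param fits \code{data.frame} with columns \code{modulus},
#'   \code{orientation} (\code{"longitudinal"}/\code{"transverse"}),
#'   \code{compartment}, and optionally \code{group}.
#' @return \code{data.frame}, one row per compartment (x group).
#' @export
modulus_summary <- function(fits) {
  stopifnot(all(c("modulus", "orientation", "compartment") %in% names(fits)))
  if (nrow(fits) == 0L) undefined_metric("no fits to summarize")
  keys <- fits[, intersect(c("compartment", "group"), names(fits)),
               drop = FALSE]
  split_idx <- split(seq_len(nrow(fits)), keys, drop = TRUE)
  rows <- lapply(split_idx, function(ix) {
    sub <- fits[ix, ]
    el <- sub$modulus[sub$orientation == "longitudinal"]
    et <- sub$modulus[sub$orientation == "transverse"]
    if (length(el) == 0L || length(et) == 0L)
      undefined_metric("empty orientation cell in modulus summary")
    cbind(unique(sub[, names(keys), drop = FALSE])[1, , drop = FALSE],
          data.frame(mean_el = mean(el), sd_el = sd(el), n_el = length(el),
                     mean_et = mean(et), sd_et = sd(et), n_et = length(et),
                     anisotropy_ratio = mean(el) / mean(et)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logarithmic frequency-dependence fit of the dynamic modulus
#'
#' Least-squares fit of \code{E = a + b * log(f)} to (frequency, modulus)
#' points, the empirical stiffening law of hydrated bone over 1-100 Hz.
#'
#' @param frequency Hz, all positive.
#' @param modulus GPa.
#' @return \code{list(intercept_a, slope_b, r_squared)}.
#' @export
fit_log_frequency <- function(frequency, modulus) {
  if (any(frequency <= 0)) param_error("frequencies must be > 0")
  if (length(unique(frequency)) < 3)
    data_error("need at least 3 distinct frequencies")
  fit <- lm(modulus ~ log(frequency))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((modulus - mean(modulus))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(intercept_a = unname(coef(fit)[1]), slope_b = unname(coef(fit)[2]),
       r_squared = r2)
}
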