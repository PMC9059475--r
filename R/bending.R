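local_slopes <- function(d, f, width) {
  n <- length(d)
  width <- max(3L, as.integer(width))
  half <- width %/% 2
  slopes <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    dd <- d[lo:hi]; ff <- f[lo:hi]
    den <- sum((dd - mean(dd))^2)
    slopes[i] <- if (den > 0) sum((dd - mean(dd)) * (ff - mean(ff))) / den
    else 0
  }
  slopes
}

#' Identify the linear elastic region of a bending curve
#'
#' The initial toe slope reflects apparatus compliance and specimen
#' engagement, not the bone, and is disregarded: the window starts where the
#' moving-window slope first reaches \code{toe_fraction} of the running
#' maximum slope, and ends at the first sustained drop below that fraction
#' (yielding), before the force peak.
#'
#' @param curve a \code{load_displacement_curve}.
#' @param toe_fraction slope fraction bounding the linear segment.
#' @param window_width moving-slope window, samples; default 5% of the
#'   curve.
#' @return Integer index range \code{c(first, last)} of the elastic window.
#' @export
identify_elastic_region <- function(curve, toe_fraction = 0.8,
                                    window_width = NULL) {
  f <- curve$force; d <- curve$displacement
  fmax <- max(f)
  if (fmax <= 0) data_error("flat curve: no elastic region")
  peak <- which.max(f)
  if (peak < 5L) data_error("force peaks too early for slope analysis")
  if (is.null(window_width)) window_width <- max(5L, round(length(d) * 0.05))
  sl <- local_slopes(d[1:peak], f[1:peak], window_width)
  smax <- max(sl, na.rm = TRUE)
  if (smax <= 0) data_error("no rising segment found")
  ok <- sl >= toe_fraction * smax
  i_max <- which.max(sl)
  first <- i_max
  while (first > 1L && ok[first - 1L]) first <- first - 1L
  last <- i_max
  while (last < peak && ok[last + 1L]) last <- last + 1L
  c(first, last)
}

#' Extract whole-bone three-point-bending metrics
#'
#' Stiffness is the maximum moving-window slope within the elastic window
#' (the mean value of the maximum slope of the elastic portion); the yield
#' load is where the curve crosses a line of the elastic slope offset by
#' 0.2% of the span; the ultimate point is the last point before a force
#' drop exceeding \code{fracture_drop} of the peak between consecutive
#' samples (fracture); the work to fracture is the trapezoidal integral of
#' force over displacement up to that point.
#'
#' @param curve a \code{load_displacement_curve}.
#' @param toe_fraction,window_width passed to
#'   \code{\link{identify_elastic_region}}.
#' @param offset_frac yield offset as a fraction of the span.
#' @param fracture_drop fracture threshold, fraction of peak force.
#' @return \code{data.frame}: \code{stiffness} (N/mm), \code{yield_load},
#'   \code{ultimate_load}, \code{max_load} (N), \code{ultimate_displacement}
#'   (mm), \code{work_to_fracture} (N mm), window indices, and a
#'   \code{fracture_detected} flag.
#' @export
extract_metrics <- function(curve, toe_fraction = 0.8, window_width = NULL,
                            offset_frac = 0.002, fracture_drop = 0.5) {
  d <- curve$displacement; f <- curve$force
  if (any(diff(d) < 0)) data_error("displacement must be non-decreasing")
  win <- identify_elastic_region(curve, toe_fraction, window_width)
  # moving-window max slope; the stiffness pass uses half the elastic window
  # so that the max over windows is not dominated by noise
  stiff_width <- max(5L, (win[2] - win[1] + 1L) %/% 2L)
  sl <- local_slopes(d[win[1]:win[2]], f[win[1]:win[2]], stiff_width)
  stiffness <- max(sl, na.rm = TRUE)
  max_load <- max(f)
  peak <- which.max(f)

  # elastic line through the window, offset along displacement by 0.2% span
  i_ref <- win[1] - 1 + which.max(sl)
  d0 <- d[i_ref] - f[i_ref] / stiffness          # elastic line x-intercept
  offset <- offset_frac * curve$span
  line <- stiffness * (d - d0 - offset)
  below <- which(f < line & d > d0 + offset & seq_along(f) >= win[1])
  yield_load <- if (length(below) > 0) {
    i <- below[1]
    # interpolate the crossing between i-1 and i
    if (i > 1) {
      g1 <- f[i - 1] - line[i - 1]; g2 <- f[i] - line[i]
      w <- if (g1 != g2) g1 / (g1 - g2) else 0
      f[i - 1] + w * (f[i] - f[i - 1])
    } else f[i]
  } else max_load

  drops <- which(-diff(f) > fracture_drop * max_load)
  fracture_detected <- length(drops) > 0
  i_ult <- if (fracture_detected) drops[1] else length(f)
  work <- sum(diff(d[1:i_ult]) * (f[1:(i_ult - 1)] + f[2:i_ult]) / 2)

  data.frame(stiffness = stiffness, yield_load = min(yield_load, max_load),
             ultimate_load = f[i_ult], ultimate_displacement = d[i_ult],
             max_load = max_load, work_to_fracture = work,
             window_first = win[1], window_last = win[2],
             fracture_detected = fracture_detected)
}

#' WT/KO contrast of bending metrics
#'
#' Per-metric group means, SDs, percent difference of means, and unpaired
#' two-tailed Student's t-test p-values.
#'
#' @param metrics_a,metrics_b \code{data.frame}s of per-specimen metrics
#'   (rows = specimens), e.g. stacked \code{\link{extract_metrics}} outputs.
#' @param labels group labels for the output.
#' @return \code{data.frame}, one row per metric.
#' @export
group_contrast <- function(metrics_a, metrics_b, labels = c("wt", "ko")) {
  if (nrow(metrics_a) < 2 || nrow(metrics_b) < 2)
    data_error("need at least 2 specimens per group")
  cols <- intersect(c("stiffness", "yield_load", "ultimate_load",
                      "ultimate_displacement", "max_load",
                      "work_to_fracture"),
                    intersect(names(metrics_a), names(metrics_b)))
  rows <- lapply(cols, function(cl) {
    a <- metrics_a[[cl]]; b <- metrics_b[[cl]]
    tt <- ttest_unpaired(a, b)
    data.frame(metric = cl,
               mean_a = mean(a), sd_a = sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = sd(b), n_b = length(b),
               percent_difference = percent_difference(mean(a), mean(b)),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_a$", paste0("_", labels[1]), names(out))
  names(out) <- sub("_b$", paste0("_", labels[2]), names(out))
  out
}
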