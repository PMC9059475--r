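#' Write a force-indentation curve as CSV with a JSON metadata sidecar
#'
#' CSV columns carry units in the header (\code{depth_nm, force_nN}); probe
#' radius, Poisson's ratio, frequency, orientation and compartment go to
#' \code{<path>.json}.
#'
#' @param curve a \code{force_indentation_curve}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_indentation_csv <- function(curve, path) {
  write.csv(data.frame(depth_nm = curve$depth, force_nN = curve$force),
            path, row.names = FALSE)
  meta <- curve[c("probe_radius", "poisson_ratio", "frequency",
                  "orientation", "compartment")]
  meta <- meta[!vapply(meta, function(x) is.na(x)[1], logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a force-indentation curve written by \code{write_indentation_csv}
#' @param path CSV path (sidecar \code{<path>.json} is read if present).
#' @return A \code{force_indentation_curve}.
#' @export
read_indentation_csv <- function(path) {
  tab <- read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  force_indentation_curve(
    tab$depth_nm, tab$force_nN,
    probe_radius = if (is.null(meta$probe_radius)) 300 else meta$probe_radius,
    poisson_ratio = if (is.null(meta$poisson_ratio)) 0.3
    else meta$poisson_ratio,
    frequency = if (is.null(meta$frequency)) NA_real_
    else as.numeric(meta$frequency),
    orientation = if (is.null(meta$orientation)) "longitudinal"
    else meta$orientation,
    compartment = if (is.null(meta$compartment)) "cortical"
    else meta$compartment)
}

#' Write a load-displacement record as CSV (+ JSON sidecar)
#' @param curve a \code{load_displacement_curve}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_bending_csv <- function(curve, path) {
  write.csv(data.frame(displacement_mm = curve$displacement,
                       force_N = curve$force),
            path, row.names = FALSE)
  jsonlite::write_json(list(span_mm = curve$span,
                            rate_mm_per_s = curve$loading_rate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a load-displacement record written by \code{write_bending_csv}
#' @param path CSV path.
#' @return A \code{load_displacement_curve}.
#' @export
read_bending_csv <- function(path) {
  tab <- read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  load_displacement_curve(
    tab$displacement_mm, tab$force_N,
    loading_rate = if (is.null(meta$rate_mm_per_s)) 0.05
    else meta$rate_mm_per_s,
    span = if (is.null(meta$span_mm)) 7 else meta$span_mm)
}
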