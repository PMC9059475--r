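#' Labeled voxel volume
#'
#' Container for an isotropic labeled 3D grid standing in for a reconstructed
#' micro-CT scan. Labels are 0 = background, 1 = cortical bone,
#' 2 = trabecular bone, 3 = marrow. The z axis is the shaft axis; the z
#' coordinate of slice \code{k} (1-based) is
#' \code{origin[3] + (k - 1) * spacing / 1000} mm.
#'
#' @param labels integer 3D array with values in \code{0:3}.
#' @param spacing isotropic voxel spacing in micrometres.
#' @param origin numeric length-3 physical position (mm) of the first voxel
#'   centre.
#' @param growth_plate_z axial coordinate (mm) of the growth-plate plane, or
#'   \code{NA} if not applicable (e.g. beam phantoms).
#' @return An object of class \code{voxel_volume}.
#' @export
voxel_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         growth_plate_z = NA_real_) {
  if (length(dim(labels)) != 3L)
    param_error("labels must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    param_error("spacing must be a single positive value (micrometres)")
  rng <- range(labels)
  if (rng[1] < 0 || rng[2] > 3)
    param_error("labels must be in {0 background, 1 cortical, 2 trabecular, 3 marrow}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 growth_plate_z = as.numeric(growth_plate_z)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("voxel_volume: %d x %d x %d voxels at %.4g um\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  extent: %.3g x %.3g x %.3g mm\n",
              d[1] * x$spacing / 1000, d[2] * x$spacing / 1000,
              d[3] * x$spacing / 1000))
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = 4L)
  cat(sprintf("  voxels: background %d, cortical %d, trabecular %d, marrow %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  if (!is.na(x$growth_plate_z))
    cat(sprintf("  growth plate at z = %.3g mm\n", x$growth_plate_z))
  invisible(x)
}

spacing_mm <- function(volume) volume$spacing / 1000

#' z coordinates (mm) of all slice centres
#' @noRd
slice_z <- function(volume) {
  volume$origin[3] + (seq_len(dim(volume$labels)[3]) - 1) * spacing_mm(volume)
}

#' Crop a volume to a half-open z interval
#'
#' Keeps the slices whose centre lies in \code{[z_min, z_max)} (mm).
#' @noRd
crop_z <- function(volume, z_min, z_max) {
  z <- slice_z(volume)
  keep <- which(z >= z_min - 1e-9 & z < z_max - 1e-9)
  if (length(keep) == 0L)
    range_error("z interval contains no slices")
  voxel_volume(volume$labels[, , keep, drop = FALSE], volume$spacing,
               c(volume$origin[1:2], z[keep[1]]), volume$growth_plate_z)
}

#' Write a labeled volume as MetaImage (.mha)
#'
#' Single-file MetaImage with an uncompressed 8-bit payload, readable by
#' ITK-based tools. A JSON sidecar is not needed: spacing, origin and the
#' growth-plate coordinate travel in the header (the latter as a private
#' \code{GrowthPlateZ} tag).
#'
#' @param volume a \code{voxel_volume}.
#' @param path output file path (conventionally \code{.mha}).
#' @return \code{path}, invisibly.
#' @export
write_volume_mha <- function(volume, path) {
  d <- dim(volume$labels)
  sp <- spacing_mm(volume)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", sp, sp, sp),
    sprintf("Offset = %.9g %.9g %.9g", volume$origin[1], volume$origin[2],
            volume$origin[3]),
    if (!is.na(volume$growth_plate_z))
      sprintf("GrowthPlateZ = %.9g", volume$growth_plate_z),
    "ElementType = MET_UCHAR",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.raw(as.vector(volume$labels)), con)
  invisible(path)
}

#' Read a MetaImage (.mha) labeled volume
#'
#' Supports the uncompressed single-file 8-bit layout written by
#' \code{\link{write_volume_mha}}.
#' @param path file path.
#' @return a \code{voxel_volume}.
#' @export
read_volume_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  get <- function(key) {
    row <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (length(row) == 0L) return(NULL)
    strsplit(sub("^[^=]*= *", "", row[1]), " +")[[1]]
  }
  d <- as.integer(get("DimSize"))
  sp <- as.numeric(get("ElementSpacing"))[1] * 1000
  org <- as.numeric(get("Offset"))
  gp <- get("GrowthPlateZ")
  gp <- if (is.null(gp)) NA_real_ else as.numeric(gp)
  if (!identical(get("ElementType"), "MET_UCHAR"))
    data_error("only MET_UCHAR volumes are supported")
  raw <- readBin(con, "raw", n = prod(d))
  labels <- array(as.integer(raw), dim = d)
  voxel_volume(labels, sp, org, gp)
}
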