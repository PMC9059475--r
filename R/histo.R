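#' Calcein double-label measurement set
#'
#' @param distances interlabel distances between the two calcein fronts on
#'   double-labeled surfaces, micrometres (pooled across fields).
#' @param fields \code{data.frame} with per-field \code{dl_surface},
#'   \code{sl_surface}, \code{total_bone_surface} (mm).
#' @param interval days between the two calcein doses (default 7).
#' @return A \code{histo_label_set}.
#' @export
histo_label_set <- function(distances, fields, interval = 7) {
  if (interval <= 0) param_error("interval must be > 0")
  if (any(distances < 0)) param_error("distances must be >= 0")
  need <- c("dl_surface", "sl_surface", "total_bone_surface")
  if (!all(need %in% names(fields)))
    param_error("fields must have dl_surface, sl_surface, total_bone_surface")
  if (any(fields$dl_surface + fields$sl_surface >
            fields$total_bone_surface + 1e-9))
    data_error("labeled surface exceeds total bone surface")
  structure(list(distances = as.numeric(distances), fields = fields,
                 interval = interval),
            class = "histo_label_set")
}

#' Mineral apposition rate
#'
#' Mean distance between the two calcein fronts divided by the interlabel
#' interval.
#'
#' @param distances interlabel distances, micrometres.
#' @param interval days between doses.
#' @return MAR in um/day.
#' @export
mar <- function(distances, interval = 7) {
  if (length(distances) == 0L)
    undefined_metric("MAR undefined without interlabel distances")
  if (interval <= 0) param_error("interval must be > 0")
  mean(distances) / interval
}

#' Mineralizing surface fraction
#'
#' \code{MS/BS = (dL + sL/2) / BS}: double-labeled plus half the
#' single-labeled surface over the total bone surface.
#'
#' @param dl double-labeled surface, mm.
#' @param sl single-labeled surface, mm.
#' @param bs total bone surface, mm.
#' @return Fraction in \code{[0, 1]}.
#' @export
ms_bs <- function(dl, sl, bs) {
  if (bs <= 0) undefined_metric("MS/BS undefined for zero bone surface")
  if (dl + sl > bs + 1e-9) data_error("dL + sL exceeds BS")
  (dl + 0.5 * sl) / bs
}

#' Surface-referent bone formation rate
#'
#' \code{BFR/BS = MAR * MS/BS}, in um^3/um^2/day.
#'
#' @param mar_value um/day.
#' @param ms_bs_value fraction.
#' @return BFR/BS.
#' @export
bfr_bs <- function(mar_value, ms_bs_value) {
  if (mar_value < 0 || ms_bs_value < 0) param_error("inputs must be >= 0")
  mar_value * ms_bs_value
}

#' Cell density per bone perimeter
#'
#' Osteoclast candidates with fewer than \code{min_nuclei} nuclei are
#' excluded before counting (the TRAP-positive counting rule requires three
#' or more nuclei); other cell types are counted as-is. Density is
#' count / perimeter.
#'
#' @param cells \code{data.frame} with columns \code{cell_type} and
#'   \code{n_nuclei}.
#' @param perimeter bone perimeter, mm.
#' @param min_nuclei osteoclast inclusion threshold.
#' @return Named vector of densities (1/mm), one per cell type.
#' @export
cell_density <- function(cells, perimeter, min_nuclei = 3) {
  if (perimeter <= 0) data_error("perimeter must be > 0")
  keep <- cells$cell_type != "osteoclast" | cells$n_nuclei >= min_nuclei
  counts <- table(cells$cell_type[keep])
  types <- unique(cells$cell_type)
  out <- setNames(numeric(length(types)), types)
  out[names(counts)] <- as.numeric(counts) / perimeter
  out
}

#' Histomorphometry report from a label set
#'
#' Pools fields: MAR from all interlabel distances, MS/BS from summed
#' surfaces, and their product BFR/BS.
#'
#' @param label_set a \code{\link{histo_label_set}}.
#' @return One-row \code{data.frame}: \code{mar} (um/day), \code{ms_bs},
#'   \code{bfr_bs} (um^3/um^2/day).
#' @export
histo_report <- function(label_set) {
  stopifnot(inherits(label_set, "histo_label_set"))
  m <- mar(label_set$distances, label_set$interval)
  fr <- ms_bs(sum(label_set$fields$dl_surface),
              sum(label_set$fields$sl_surface),
              sum(label_set$fields$total_bone_surface))
  data.frame(mar = m, ms_bs = fr, bfr_bs = bfr_bs(m, fr))
}
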