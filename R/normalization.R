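#' Correct plate-to-plate variability against reference wells
#'
#' Divides every library well's raw signal by the median signal of its own
#' plate's reference wells (non-transfected cells by default), removing
#' multiplicative plate effects before any cross-plate statistics.
#'
#' @param wells Plate table ([read_plate_table()] format).
#' @param reference_role Role used as the per-plate reference
#'   (default `"non_transfected"`).
#' @return A `data.table` of the library wells with columns `plate`,
#'   `sirna_id`, `raw_signal`, `plate_normalized`.
#' @details Every plate must carry at least two reference wells; a plate
#'   without them is a hard error naming the plate.
#' @export
plate_normalize <- function(wells, reference_role = "non_transfected") {
  wells <- as.data.table(wells)
  stopifnot(reference_role %in% ROLE_LEVELS)
  ref <- wells[role == reference_role,
               .(ref_median = median(signal), n_ref = .N), by = plate]
  missing_ref <- setdiff(unique(wells$plate), ref$plate)
  if (length(missing_ref)) {
    stop("plate '", missing_ref[1], "' has no wells with role '",
         reference_role, "'")
  }
  if (any(ref$n_ref < 2L)) {
    stop("plate '", ref$plate[ref$n_ref < 2L][1], "' has fewer than 2 '",
         reference_role, "' wells")
  }
  if (any(ref$ref_median <= 0)) {
    stop("plate '", ref$plate[ref$ref_median <= 0][1],
         "' has non-positive reference median")
  }
  lib <- wells[role == "library"]
  lib <- merge(lib, ref[, .(plate, ref_median)], by = "plate", sort = FALSE)
  lib[, .(plate, sirna_id = id, raw_signal = signal,
          plate_normalized = signal / ref_median)]
}

#' Robust Z-scores
#'
#' `z_i = (x_i - median(x)) / (1.4826 * MAD(x))`, the usual
#' normal-consistent robust standardization of screen activities. Computed
#' over the full vector supplied, i.e. per screen/cell line when called on
#' one cell line's plate-normalized library values.
#'
#' @param x Numeric vector (length >= 3).
#' @return Numeric vector of robust Z-scores.
#' @details A zero MAD means a degenerate screen and is a hard error.
#' @export
robust_z <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("robust_z needs at least 3 values")
  if (anyNA(x)) stop("robust_z input contains NA")
  s <- mad(x)  # stats::mad already applies the 1.4826 consistency constant
  if (s == 0) stop("MAD is zero: degenerate screen, robust Z undefined")
  (x - median(x)) / s
}

#' Normalize a verification screen against plate controls
#'
#' Converts raw RLUs of a verification screen to relative viabilities using
#' the per-plate medians of the lethal positive and non-silencing negative
#' control wells.
#'
#' @param wells Plate table with `positive_control` and `negative_control`
#'   wells on every plate.
#' @param formula `"literal"` (default): `v = (x - med(pos)) / med(neg)`.
#'   `"span"`: `v = (x - med(pos)) / (med(neg) - med(pos))`, the usual
#'   percent-of-control span normalization.
#' @return A `data.table` with `plate`, `sirna_id`, `raw_signal`,
#'   `viability`.
#' @details Inverted controls (`med(neg) <= med(pos)`) on any plate are a
#'   hard error. The two formulas agree when the positive-control median is
#'   zero.
#' @export
normalize_verification <- function(wells, formula = c("literal", "span")) {
  formula <- match.arg(formula)
  wells <- as.data.table(wells)
  ctrl <- wells[role %in% c("positive_control", "negative_control"),
                .(med = median(signal)), by = .(plate, role)]
  ctrl <- dcast(ctrl, plate ~ role, value.var = "med")
  have <- unique(wells$plate)
  if (!all(c("positive_control", "negative_control") %in% names(ctrl)) ||
      !all(have %in% ctrl$plate) ||
      anyNA(ctrl$positive_control) || anyNA(ctrl$negative_control)) {
    stop("every plate needs both positive_control and negative_control wells")
  }
  if (any(ctrl$negative_control <= ctrl$positive_control)) {
    bad <- ctrl$plate[ctrl$negative_control <= ctrl$positive_control][1]
    stop("plate '", bad, "' has inverted controls ",
         "(negative median <= positive median)")
  }
  lib <- merge(wells[role == "library"], ctrl, by = "plate", sort = FALSE)
  denom <- if (formula == "literal") {
    lib$negative_control
  } else {
    lib$negative_control - lib$positive_control
  }
  lib[, .(plate, sirna_id = id, raw_signal = signal,
          viability = (signal - positive_control) / denom)]
}
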