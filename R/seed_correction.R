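#' Extract the seed region of a guide strand
#'
#' The seed is the miRNA-like recognition region of the siRNA guide strand,
#' by default positions 2-7 (a hexamer); a 7-nt variant is available via
#' `length = 7`.
#'
#' @param guide Character vector of RNA guide sequences.
#' @param start 1-based start position (default 2).
#' @param length Seed length in nt (default 6).
#' @return Character vector of seed substrings.
#' @export
extract_seed <- function(guide, start = 2L, length = 6L) {
  stopifnot(start >= 1L, length >= 1L)
  too_short <- nchar(guide) < start + length - 1L
  if (any(too_short)) {
    stop("guide of length ", nchar(guide)[too_short][1],
         " too short for seed positions ", start, "..", start + length - 1L)
  }
  substr(guide, start, start + length - 1L)
}

#' Group an siRNA library by seed sequence
#'
#' Fills the `seed` column of a library table and partitions the library
#' into exact-string seed groups.
#'
#' @param library Library table ([read_library()] format).
#' @param start,length Seed coordinates, see [extract_seed()].
#' @return The library `data.table` with `seed` filled and an integer
#'   `group_size` column (number of library siRNAs sharing the seed).
#' @export
group_by_seed <- function(library, start = 2L, length = 6L) {
  lib <- as.data.table(library)
  lib <- copy(lib)
  lib[, seed := extract_seed(guide_sequence, start, length)]
  lib[, group_size := .N, by = seed]
  lib[]
}

#' Common-seed (CSA) median correction of siRNA activities
#'
#' Removes seed-driven off-target signal by subtracting, from each siRNA's
#' activity, the median activity of all siRNAs sharing its seed. Groups
#' smaller than `min_group_size` carry too little information to estimate a
#' seed effect (a singleton would simply zero itself out), so they are
#' corrected by the library-wide median instead.
#'
#' @param scores Table with columns `sirna_id` and an activity column
#'   (default `robust_z`).
#' @param library Seed-grouped library ([group_by_seed()] output).
#' @param min_group_size Minimum seed-group size for group-median
#'   correction (default 3).
#' @param leave_one_out If `TRUE`, each siRNA is corrected by the median of
#'   the *other* group members (its own value excluded). Default `FALSE`:
#'   self-inclusive median as in classical common-seed analysis.
#' @param activity_col Name of the activity column in `scores`.
#' @return A `data.table` with `sirna_id`, `seed`, `group_size`,
#'   `corrected`.
#' @export
median_seed_correct <- function(scores, library, min_group_size = 3L,
                                leave_one_out = FALSE,
                                activity_col = "robust_z") {
  scores <- as.data.table(scores)
  if (!activity_col %in% names(scores)) {
    stop("scores has no column '", activity_col, "'")
  }
  lib <- as.data.table(library)
  if (!"seed" %in% names(lib) || anyNA(lib$seed)) {
    stop("library seeds not extracted; run group_by_seed() first")
  }
  dt <- merge(scores[, .(sirna_id, activity = get(activity_col))],
              lib[, .(sirna_id, seed)], by = "sirna_id")
  if (nrow(dt) < nrow(scores)) {
    stop("some scored siRNAs are absent from the library annotation")
  }
  global_med <- median(dt$activity)
  dt[, group_size := .N, by = seed]
  if (leave_one_out) {
    loo_med <- function(v) {
      if (length(v) == 1L) return(NA_real_)
      vapply(seq_along(v), function(i) median(v[-i]), numeric(1))
    }
    dt[, grp_med := loo_med(activity), by = seed]
  } else {
    dt[, grp_med := median(activity), by = seed]
  }
  dt[, corrected := ifelse(group_size >= min_group_size & !is.na(grp_med),
                           activity - grp_med,
                           activity - global_med)]
  dt[, .(sirna_id, seed, group_size, corrected)]
}
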