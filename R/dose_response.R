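#' Serial dilution concentration series
#'
#' `c_k = top_conc / ratio^(k-1)`, k = 1..n_points — the 1:3, 11-point
#' series of the quantitative HTS design by default.
#'
#' @param top_conc Highest (in-plate) concentration, molar.
#' @param ratio Dilution factor (> 1), default 3.
#' @param n_points Number of points, default 11.
#' @return Numeric vector of concentrations, descending.
#' @export
dilution_series <- function(top_conc, ratio = 3, n_points = 11L) {
  stopifnot(top_conc > 0, ratio > 1, n_points >= 1L)
  top_conc / ratio^(seq_len(n_points) - 1)
}

#' Normalize drug-plate viability against DMSO and bortezomib controls
#'
#' Maps each library well's RLU onto the percent-viability scale anchored
#' by the plate's control medians:
#' `v = 100 * (x - med(bortezomib)) / (med(DMSO) - med(bortezomib))`,
#' so DMSO = 100% viability and the cytotoxic bortezomib control = 0%.
#'
#' @param wells Plate table with `dmso` and `bortezomib` control wells
#'   (>= 2 of each per plate).
#' @return A `data.table` with `plate`, `compound_id`, `well_row`,
#'   `well_col`, `raw_signal`, `viability_pct`.
#' @details `med(DMSO) <= med(bortezomib)` is a hard error (dead controls).
#' @export
normalize_dose_viability <- function(wells) {
  wells <- as.data.table(wells)
  ctrl <- wells[role %in% c("dmso", "bortezomib"),
                .(med = median(signal), n = .N), by = .(plate, role)]
  if (any(ctrl$n < 2L)) {
    stop("plate '", ctrl$plate[ctrl$n < 2L][1],
         "' has fewer than 2 control wells of role '",
         ctrl$role[ctrl$n < 2L][1], "'")
  }
  wide <- dcast(ctrl, plate ~ role, value.var = "med")
  if (!all(c("dmso", "bortezomib") %in% names(wide)) ||
      !all(unique(wells$plate) %in% wide$plate) ||
      anyNA(wide$dmso) || anyNA(wide$bortezomib)) {
    stop("every plate needs both dmso and bortezomib control wells")
  }
  if (any(wide$dmso <= wide$bortezomib)) {
    stop("plate '", wide$plate[wide$dmso <= wide$bortezomib][1],
         "' has DMSO median <= bortezomib median")
  }
  lib <- merge(wells[role == "library"], wide, by = "plate", sort = FALSE)
  lib[, .(plate, compound_id = id, well_row, well_col, raw_signal = signal,
          viability_pct = 100 * (signal - bortezomib) / (dmso - bortezomib))]
}

# 4PL response: bottom + (top - bottom) / (1 + (c / ac50)^hill)
# hill > 0 -> decreasing in c (viability), hill < 0 -> increasing
# (activation readouts such as caspase 3/7)
.fourpl <- function(conc, top, bottom, ac50, hill) {
  bottom + (top - bottom) / (1 + (conc / ac50)^hill)
}

#' Grid-based robust four-parameter logistic fit
#'
#' Fits `v(c) = bottom + (top - bottom) / (1 + (c/ac50)^hill)` to a
#' dose-response series with a coarse-to-fine strategy built for screen
#' data with occasional outlier wells:
#' 1. A grid over log10(ac50) spanning the tested concentration range plus
#'    one decade each side, and over Hill slopes in `hill_bounds` (both
#'    orientations). At each node top/bottom are solved by linear least
#'    squares (the model is linear in them) and clamped to
#'    `[-20, 120]`%; the node is scored by the sum of absolute residuals.
#' 2. The best node is refined by Nelder-Mead on all four parameters under
#'    the same robust loss.
#' 3. Points with |residual| > 3 x MAD(residuals) are masked once and the
#'    fit repeated on the remaining points.
#' The fit is flagged `converged = FALSE` when it fails to beat the best
#' flat-line (constant) model, e.g. for compounds with no activity.
#'
#' @param concentrations Molar concentrations (>= 5 points, >= 4 distinct).
#' @param viability_pct Percent viability per point.
#' @param hill_bounds Allowed |Hill| range, default `c(0.3, 5)`.
#' @param loss `"lad"` (default, robust sum of absolute residuals) or
#'   `"ls"` (ordinary least squares; reference mode, no outlier masking
#'   gain intended).
#' @param mask_outliers Apply the single 3xMAD masking pass (default
#'   `TRUE`).
#' @param ac50_pad Decades added either side of the tested range for the
#'   ac50 grid.
#' @return Object of class `fourpl_fit`: `top`, `bottom`, `ac50`, `hill`
#'   (signed; > 0 means viability decreases with dose), `loss`,
#'   `converged`, `outlier_mask` (TRUE = masked), `n_used`.
#' @export
fit_4pl_grid <- function(concentrations, viability_pct,
                         hill_bounds = c(0.3, 5),
                         loss = c("lad", "ls"),
                         mask_outliers = TRUE, ac50_pad = 1) {
  loss <- match.arg(loss)
  conc <- as.numeric(concentrations)
  v <- as.numeric(viability_pct)
  if (length(conc) != length(v)) stop("length mismatch")
  keep0 <- is.finite(conc) & is.finite(v) & conc > 0
  conc <- conc[keep0]; v <- v[keep0]
  if (length(v) < 5L) stop("need at least 5 points")
  if (length(unique(conc)) < 4L) stop("need at least 4 distinct concentrations")

  fit_once <- function(conc, v) {
    lc <- log10(conc)
    ac_grid <- 10^seq(min(lc) - ac50_pad, max(lc) + ac50_pad, by = 0.125)
    h_grid <- exp(seq(log(hill_bounds[1]), log(hill_bounds[2]),
                      length.out = 12L))
    h_grid <- c(-rev(h_grid), h_grid)
    score <- function(top, bottom, ac50, hill) {
      r <- v - .fourpl(conc, top, bottom, ac50, hill)
      if (loss == "lad") sum(abs(r)) else sum(r^2)
    }
    node_fit <- function(ac50, hill) {
      x <- 1 / (1 + (conc / ac50)^hill)
      # v = bottom + (top - bottom) x: OLS in (top, bottom)
      sx <- sum(x); sxx <- sum(x^2); n <- length(x)
      det <- n * sxx - sx^2
      if (det < 1e-12) return(NULL)
      A <- (n * sum(x * v) - sx * sum(v)) / det         # top - bottom
      B <- (sum(v) - A * sx) / n                        # bottom
      top <- min(max(A + B, -20), 120)
      bottom <- min(max(B, -20), 120)
      c(top, bottom)
    }
    best <- NULL; best_loss <- Inf
    for (a in ac_grid) for (h in h_grid) {
      tb <- node_fit(a, h)
      if (is.null(tb)) next
      l <- score(tb[1], tb[2], a, h)
      if (l < best_loss) {
        best_loss <- l
        best <- c(top = tb[1], bottom = tb[2], ac50 = a, hill = h)
      }
    }
    if (is.null(best)) stop("degenerate dose-response design")
    # local refinement on (log10 ac50, log|hill|, top, bottom), hill sign
    # fixed from the grid; soft box constraints via penalty
    sgn <- sign(best["hill"])
    obj <- function(par) {
      top <- par[3]; bottom <- par[4]
      ac50 <- 10^par[1]; hill <- sgn * exp(par[2])
      pen <- 0
      pen <- pen + 1e4 * max(0, -20 - top)^2 + 1e4 * max(0, top - 120)^2
      pen <- pen + 1e4 * max(0, -20 - bottom)^2 + 1e4 * max(0, bottom - 120)^2
      pen <- pen + 1e4 * max(0, log(hill_bounds[1]) - par[2])^2 +
        1e4 * max(0, par[2] - log(hill_bounds[2]))^2
      pen <- pen + 1e4 * max(0, (min(lc) - ac50_pad) - par[1])^2 +
        1e4 * max(0, par[1] - (max(lc) + ac50_pad))^2
      score(top, bottom, ac50, hill) + pen
    }
    p0 <- c(log10(best["ac50"]), log(abs(best["hill"])),
            best["top"], best["bottom"])
    opt <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-12))
    # restart: Nelder-Mead can stall on the kinked LAD surface
    opt <- optim(opt$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-12))
    list(top = unname(opt$par[3]), bottom = unname(opt$par[4]),
         ac50 = unname(10^opt$par[1]), hill = unname(sgn * exp(opt$par[2])),
         loss = unname(opt$value))
  }

  fit <- fit_once(conc, v)
  mask <- rep(FALSE, length(v))
  if (mask_outliers) {
    r <- v - .fourpl(conc, fit$top, fit$bottom, fit$ac50, fit$hill)
    s <- mad(r)
    # floor guards exact-model data, where MAD is numerically zero and
    # every point would look like an outlier
    if (s > 1e-6) {
      mask <- abs(r) > 3 * s
      if (any(mask) && sum(!mask) >= 5L &&
          length(unique(conc[!mask])) >= 4L) {
        fit <- fit_once(conc[!mask], v[!mask])
      } else {
        mask <- rep(FALSE, length(v))
      }
    }
  }
  vu <- v[!mask]
  flat_loss <- if (loss == "lad") sum(abs(vu - median(vu))) else
    sum((vu - mean(vu))^2)
  converged <- fit$loss < flat_loss - 1e-9 &&
    abs(fit$top - fit$bottom) > 1e-6
  # canonicalize top >= bottom; orientation lives in the sign of hill
  top <- fit$top; bottom <- fit$bottom; hill <- fit$hill
  if (top < bottom) {
    tmp <- top; top <- bottom; bottom <- tmp
    hill <- -hill
  }
  full_mask <- rep(FALSE, length(keep0))
  full_mask[keep0] <- mask
  structure(list(top = top, bottom = bottom, ac50 = fit$ac50, hill = hill,
                 loss = fit$loss, converged = converged,
                 outlier_mask = full_mask, n_used = sum(!mask)),
            class = "fourpl_fit")
}

#' Predict viability from a 4PL fit
#'
#' @param object A `fourpl_fit`.
#' @param conc Concentrations (molar).
#' @param ... Unused.
#' @return Fitted percent viability at `conc`.
#' @export
predict.fourpl_fit <- function(object, conc, ...) {
  .fourpl(conc, object$top, object$bottom, object$ac50, object$hill)
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "4PL fit: top %.1f%%, bottom %.1f%%, ac50 %.4g, hill %.2f\n",
    "  loss %.3f, converged %s, %d point(s) masked\n"),
    x$top, x$bottom, x$ac50, x$hill, x$loss, x$converged,
    sum(x$outlier_mask)))
  invisible(x)
}

#' Normalized area under the dose-response curve
#'
#' Trapezoidal integral of viability over log10 concentration across the
#' tested range, as a percentage of the area of a flat 100%-viability
#' response: 100 = inactive compound, 0 = fully lethal at every dose.
#' Values above 100 indicate growth stimulation.
#'
#' @param fit A `fourpl_fit` (ignored in `mode = "raw"` unless available).
#' @param concentrations Tested concentrations (define the range).
#' @param mode `"fit"` (default): integrate the fitted curve on a fine
#'   grid. `"raw"`: trapezoid over the observed points; also the fallback,
#'   with a warning, when the fit did not converge.
#' @param viability_pct Observed viabilities (required for `"raw"`).
#' @return Normalized AUC in percent (floored at 0).
#' @export
normalized_auc <- function(fit, concentrations, mode = c("fit", "raw"),
                           viability_pct = NULL) {
  mode <- match.arg(mode)
  conc <- sort(as.numeric(concentrations))
  lc <- log10(conc)
  rng <- max(lc) - min(lc)
  if (rng <= 0) stop("need a nondegenerate concentration range")
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  if (mode == "fit" && (is.null(fit) || !isTRUE(fit$converged))) {
    warning("no converged fit; falling back to raw-point AUC")
    mode <- "raw"
  }
  if (mode == "fit") {
    g <- seq(min(lc), max(lc), length.out = 257L)
    y <- predict(fit, 10^g)
  } else {
    if (is.null(viability_pct)) stop("raw mode needs viability_pct")
    o <- order(log10(as.numeric(concentrations)))
    g <- log10(as.numeric(concentrations))[o]
    y <- as.numeric(viability_pct)[o]
  }
  max(0, 100 * trapz(g, y) / (100 * rng))
}

#' Absolute IC50 of a fitted viability curve
#'
#' The concentration at which the fitted curve crosses 50% of control
#' viability, solved in closed form:
#' `ic50 = ac50 * ((top - 50) / (50 - bottom))^(1/hill)`.
#' Undefined (`NA`) when the curve never crosses 50% (e.g. bottom above
#' 50%) or the fit did not converge — a real, reportable outcome for
#' inactive compounds.
#'
#' @param fit A `fourpl_fit`.
#' @return Molar concentration or `NA_real_`.
#' @export
ic50_absolute <- function(fit) {
  if (!inherits(fit, "fourpl_fit")) stop("fit must be a fourpl_fit")
  if (!isTRUE(fit$converged)) return(NA_real_)
  if (!(fit$bottom < 50 && fit$top > 50)) return(NA_real_)
  fit$ac50 * ((fit$top - 50) / (50 - fit$bottom))^(1 / fit$hill)
}

#' Relative EC50 of a fitted curve
#'
#' The curve's half-maximal (inflection) concentration — the fitted ac50 —
#' regardless of orientation; the conventional summary for activation
#' readouts such as caspase 3/7 induction.
#'
#' @param fit A `fourpl_fit`.
#' @return Molar concentration or `NA_real_` for unconverged fits.
#' @export
ec50_relative <- function(fit) {
  if (!inherits(fit, "fourpl_fit")) stop("fit must be a fourpl_fit")
  if (!isTRUE(fit$converged)) return(NA_real_)
  fit$ac50
}

#' Genotype-class summaries of drug sensitivity
#'
#' Per class (e.g. MYCN-amplified vs non-amplified): arithmetic mean of the
#' normalized AUC and median of the defined absolute IC50s, with the count
#' of curves whose IC50 is undefined (never crosses 50%).
#'
#' @param curves Table with `cell_line`, `n_auc` and `ic50` columns (one
#'   row per compound x cell line curve).
#' @param class_map Named character vector, cell line -> class label.
#' @return A `data.table` with `class`, `n_curves`, `mean_n_auc`,
#'   `median_ic50`, `n_ic50_undefined`.
#' @export
class_summary <- function(curves, class_map) {
  curves <- as.data.table(curves)
  if (!all(curves$cell_line %in% names(class_map))) {
    stop("every cell line needs a class assignment")
  }
  curves <- copy(curves)
  curves[, class := class_map[cell_line]]
  if (!all(unique(class_map) %in% curves$class)) {
    stop("class '", setdiff(unique(class_map), curves$class)[1],
         "' has no curves")
  }
  curves[, .(n_curves = .N,
             mean_n_auc = mean(n_auc),
             median_ic50 = median(ic50[!is.na(ic50)]),
             n_ic50_undefined = sum(is.na(ic50))), by = class]
}

#' Xenograft tumor volume from caliper axes
#'
#' `volume = long_axis * short_axis^2 / 2` (mm^3). Axes given in the wrong
#' order are swapped with a warning; negative axes are a hard error.
#'
#' @param long_axis,short_axis Caliper measurements in mm.
#' @return Tumor volume in mm^3.
#' @export
tumor_volume <- function(long_axis, short_axis) {
  if (any(long_axis < 0) || any(short_axis < 0)) {
    stop("tumor axes must be nonnegative")
  }
  swap <- short_axis > long_axis
  if (any(swap)) {
    warning("short axis exceeds long axis; swapping")
    tmp <- long_axis[swap]
    long_axis[swap] <- short_axis[swap]
    short_axis[swap] <- tmp
  }
  long_axis * short_axis^2 / 2
}
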