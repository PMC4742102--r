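test_that("dilution_series follows c_k = top / ratio^(k-1)", {
  s <- dilution_series(38.3e-6)
  expect_length(s, 11L)
  expect_equal(s[11], 38.3e-6 / 3^10)        # ~6.486e-10 M = 6.486e-4 uM
  expect_equal(s[11] * 1e6, 6.486e-4, tolerance = 1e-3)
  expect_equal(unique(round(s[-11] / s[-1], 12)), 3)
  expect_equal(dilution_series(1e-6, n_points = 1L), 1e-6)
})

test_that("normalize_dose_viability anchors DMSO at 100 and bortezomib at 0", {
  wells <- data.table::data.table(
    plate = "DP1", well_row = 1L, well_col = 1:9,
    role = c(rep("library", 3), rep("dmso", 3), rep("bortezomib", 3)),
    id = c("cpd", "cpd", "cpd", rep(NA, 6)),
    signal = c(20000, 1000, 10500, 19000, 20000, 21000, 900, 1000, 1100))
  out <- normalize_dose_viability(wells)
  expect_equal(out$viability_pct, c(100, 0, 50))
  inv <- data.table::copy(wells)
  inv[role == "dmso", signal := 500]
  expect_error(normalize_dose_viability(inv), "DMSO median <= bortezomib")
  few <- wells[-4]
  few[role == "dmso", role := "library"]
  expect_error(normalize_dose_viability(few), "control wells")
})

test_that("fit_4pl_grid recovers exact curves and degrades gracefully", {
  conc <- dilution_series(38.3e-6)
  v <- 0 + (100 - 0) / (1 + (conc / 1e-8)^1)
  fit <- fit_4pl_grid(conc, v)
  expect_true(fit$converged)
  expect_equal(fit$ac50, 1e-8, tolerance = 1e-3)
  expect_equal(fit$top, 100, tolerance = 1e-3)
  expect_equal(fit$bottom, 0, tolerance = 0.11)
  expect_equal(fit$hill, 1, tolerance = 1e-2)

  flat <- fit_4pl_grid(conc, rep(100, 11))
  expect_false(flat$converged)
  expect_true(is.na(ic50_absolute(flat)))

  expect_error(fit_4pl_grid(conc[1:4], v[1:4]), "at least 5")
  expect_error(fit_4pl_grid(rep(1e-8, 5), v[1:5]), "4 distinct")
})

test_that("the robust fit shrugs off an injected outlier", {
  conc <- dilution_series(38.3e-6)
  v <- 100 / (1 + (conc / 1e-8)^1)
  v_out <- v
  v_out[11] <- 0  # lowest concentration forced to 0% viability
  fit <- fit_4pl_grid(conc, v_out)
  expect_true(fit$converged)
  expect_lt(abs(log(fit$ac50 / 1e-8)), log(1.5))  # within 1.5-fold
  expect_true(fit$outlier_mask[11])
  # the plain least-squares reference misses by more
  ref <- fit_4pl_grid(conc, v_out, loss = "ls", mask_outliers = FALSE)
  expect_gt(abs(log(ref$ac50 / 1e-8)), abs(log(fit$ac50 / 1e-8)))
})

test_that("increasing (activation) curves fit with the orientation in hill", {
  conc <- dilution_series(1e-5)
  act <- 5 + (95 - 5) * (conc / 3e-8)^1.2 / (1 + (conc / 3e-8)^1.2)
  fit <- fit_4pl_grid(conc, act)
  expect_true(fit$converged)
  expect_lt(fit$hill, 0)  # increasing orientation
  expect_equal(fit$ac50, 3e-8, tolerance = 1e-2)
  expect_equal(ec50_relative(fit), fit$ac50)
  expect_gte(fit$top, fit$bottom)  # canonical form
})

test_that("normalized_auc integrates the fitted curve on the log scale", {
  conc <- dilution_series(38.3e-6)
  lc <- log10(conc)
  mid <- 10^mean(range(lc))
  steep <- fit_4pl_grid(conc, 100 / (1 + (conc / mid)^5))
  # steep sigmoid centered mid-range: half the area of a flat 100% curve
  expect_equal(normalized_auc(steep, conc), 50, tolerance = 2)

  # flat anchors via raw mode
  expect_equal(normalized_auc(NULL, conc, mode = "raw",
                              viability_pct = rep(100, 11)), 100)
  expect_equal(normalized_auc(NULL, conc, mode = "raw",
                              viability_pct = rep(0, 11)), 0)

  # monotone in potency: smaller ac50 never increases the AUC
  aucs <- vapply(c(1e-6, 1e-7, 1e-8), function(a) {
    f <- fit_4pl_grid(conc, 100 / (1 + (conc / a)^1))
    normalized_auc(f, conc)
  }, numeric(1))
  expect_true(all(diff(aucs) <= 1e-6))
})

test_that("ac50 recovery under 5% Gaussian noise stays under 25% median error", {
  set.seed(33)
  conc <- dilution_series(38.3e-6)
  lc <- log10(conc)
  err <- vapply(seq_len(200L), function(i) {
    top <- runif(1, 80, 110); bottom <- runif(1, 0, 30)
    la <- runif(1, min(lc), max(lc)); hill <- runif(1, 0.5, 3)
    v <- bottom + (top - bottom) / (1 + (conc / 10^la)^hill) +
      rnorm(11, 0, 5)
    abs(log10(fit_4pl_grid(conc, v)$ac50) - la)
  }, numeric(1))
  expect_lt(median(10^err - 1), 0.25)
})

test_that("ic50_absolute solves the 50% crossing in closed form", {
  mk <- function(top, bottom, ac50, hill) {
    structure(list(top = top, bottom = bottom, ac50 = ac50, hill = hill,
                   converged = TRUE, loss = 0,
                   outlier_mask = logical(0), n_used = 11L),
              class = "fourpl_fit")
  }
  expect_equal(ic50_absolute(mk(100, 0, 1e-8, 1.7)), 1e-8)  # symmetry
  expect_equal(ic50_absolute(mk(100, 40, 10, 1)), 50)       # hand-solved
  expect_true(is.na(ic50_absolute(mk(100, 60, 10, 1))))     # never crosses
  expect_equal(ec50_relative(mk(100, 40, 10, 1)), 10)
})

test_that("class_summary aggregates per genotype class", {
  curves <- data.table::data.table(
    cell_line = c("IMR5", "IMR32", "SKNAS", "NBEB", "SKNAS"),
    n_auc = c(40, 60, 88, 90, 95),
    ic50 = c(5e-9, 1e-8, 1e-6, NA, 3.83e-5))
  cls <- c(IMR5 = "MNA", IMR32 = "MNA", SKNAS = "nonMNA", NBEB = "nonMNA")
  out <- class_summary(curves, cls)
  expect_equal(out[class == "MNA", mean_n_auc], 50)
  expect_equal(out[class == "MNA", median_ic50], 7.5e-9)
  expect_equal(out[class == "nonMNA", n_ic50_undefined], 1L)
  expect_equal(out[class == "nonMNA", median_ic50],
               median(c(1e-6, 3.83e-5)))
  expect_error(class_summary(curves[cell_line == "IMR5"], cls), "no curves")
})

test_that("tumor_volume applies (long x short^2) / 2 with canonicalization", {
  expect_equal(tumor_volume(10, 4), 80)
  expect_equal(tumor_volume(10, 0), 0)
  expect_warning(v <- tumor_volume(4, 10), "swapping")
  expect_equal(v, 80)
  expect_error(tumor_volume(-1, 2), "nonnegative")
})
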