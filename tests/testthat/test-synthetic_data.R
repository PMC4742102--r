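test_that("gen_library has the right shape and is deterministic", {
  lib <- gen_library(100L, 2L, rng_seed = 42L)
  expect_equal(nrow(lib), 200L)
  expect_equal(data.table::uniqueN(lib$gene), 100L)
  expect_true(all(nchar(lib$guide_sequence) == 21L))
  expect_true(all(grepl("^[ACGU]+$", lib$guide_sequence)))
  expect_identical(lib, gen_library(100L, 2L, rng_seed = 42L))
  expect_false(identical(lib, gen_library(100L, 2L, rng_seed = 43L)))
})

test_that("seed collisions match the birthday bound over the hexamer space", {
  n <- 4000L
  lib <- group_by_seed(gen_library(n / 2L, 2L, rng_seed = 77L))
  n_distinct <- data.table::uniqueN(lib$seed)
  # E[#distinct] = S * (1 - (1 - 1/S)^n), S = 4^6
  S <- 4^6
  expected <- S * (1 - (1 - 1 / S)^n)
  expect_equal(n_distinct, expected, tolerance = 0.02)
})

test_that("simulate_discovery is exact in the null case and deterministic", {
  lib <- gen_library(50L, 2L, rng_seed = 5L)
  truth <- default_truth(lib, n_hits = 0L, n_toxic_seeds = 0L, rng_seed = 5L)
  wells <- simulate_discovery(lib, truth, noise_sd = 0, rng_seed = 5L)
  norm <- plate_normalize(wells)
  expect_equal(norm$plate_normalized, rep(1, nrow(norm)))  # exact null
  expect_identical(wells, simulate_discovery(lib, truth, noise_sd = 0,
                                             rng_seed = 5L))
})

test_that("planted hits land in the lower robust-Z tail at the analytic rate", {
  lib <- gen_library(1000L, 2L, rng_seed = 6L)
  truth <- default_truth(lib, n_hits = 40L, hit_effect = -3,
                         n_toxic_seeds = 0L, rng_seed = 6L)
  wells <- simulate_discovery(lib, truth, noise_sd = 1, rng_seed = 6L)
  norm <- plate_normalize(wells)
  norm[, z := robust_z(log(plate_normalized))]  # effects are log-additive
  norm <- merge(norm, lib[, .(sirna_id, gene)], by = "sirna_id")
  hit_z <- norm[gene %in% names(truth$hit_genes), z]
  # each hit siRNA sits at -3 +- 1, so P(z < -2) ~ pnorm(1) ~ 0.84
  expect_equal(mean(hit_z < -2), pnorm(1), tolerance = 0.12)
  expect_lt(median(hit_z), -2.5)
})

test_that("simulate_utrs plants recoverable sites", {
  utrs <- simulate_utrs(paste0("G", 1:30), length = 200L,
                        planted = c(G1 = "AGCGUA", G7 = "UUUACG"),
                        rng_seed = 9L)
  expect_gte(count_seed_matches("AGCGUA", utrs[["G1"]]), 1L)
  expect_gte(count_seed_matches("UUUACG", utrs[["G7"]]), 1L)
  at <- attr(utrs, "planted_at")
  expect_equal(substr(utrs[["G1"]], at["G1"], at["G1"] + 5L),
               seed_site("AGCGUA"))
  expect_identical(
    utrs, simulate_utrs(paste0("G", 1:30), length = 200L,
                        planted = c(G1 = "AGCGUA", G7 = "UUUACG"),
                        rng_seed = 9L))
  # unplanted background matches stay near the analytic expectation
  bg <- vapply(paste0("G", 2:6), function(g) {
    count_seed_matches("AGCGUA", utrs[[g]])
  }, integer(1))
  expect_lt(mean(bg), 5 * (200 - 5) / 4^6 + 1)
})

test_that("simulate_dose_plate round-trips through normalize and fit", {
  conc <- dilution_series(38.3e-6)
  cp <- data.frame(compound = "barasertib-like", top = 100, bottom = 0,
                   ac50 = 2e-8, hill = 1.3)
  plate <- simulate_dose_plate(cp, conc, noise_sd_pct = 0, outlier_rate = 0,
                               gain = 2.5, rng_seed = 3L)
  norm <- normalize_dose_viability(plate)
  lw <- plate[role == "library"]  # same order as norm
  expect_equal(norm$viability_pct, 100 / (1 + (lw$conc / 2e-8)^1.3),
               tolerance = 1e-9)
  fit <- fit_4pl_grid(lw$conc, norm$viability_pct)
  expect_equal(fit$ac50, 2e-8, tolerance = 1e-3)
  expect_equal(fit$hill, 1.3, tolerance = 1e-2)
})

test_that("dose-plate controls normalize to their defining levels", {
  conc <- dilution_series(1e-5)
  cp <- data.frame(compound = "c1", top = 100, bottom = 20,
                   ac50 = 1e-7, hill = 2)
  plate <- simulate_dose_plate(cp, conc, noise_sd_pct = 5,
                               outlier_rate = 0.1, rng_seed = 13L)
  ctrl <- plate[role != "library"]
  norm_all <- 100 * (ctrl$signal - median(ctrl$signal[ctrl$role == "bortezomib"])) /
    (median(ctrl$signal[ctrl$role == "dmso"]) -
       median(ctrl$signal[ctrl$role == "bortezomib"]))
  expect_equal(norm_all[ctrl$role == "dmso"], rep(100, 8))
  expect_equal(norm_all[ctrl$role == "bortezomib"], rep(0, 8))
})
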