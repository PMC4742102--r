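# run code with a local, restored RNG state so simulators are pure in
# (config, rng_seed) and never disturb the caller's stream
with_seed <- function(rng_seed, code) {
  if (!is.null(rng_seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(rng_seed)
  }
  force(code)
}

#' Generate a synthetic siRNA library
#'
#' Random 21-nt guide strands, `sirnas_per_gene` per gene, mirroring the
#' structure of a druggable-genome library (thousands of genes, two or more
#' siRNAs each) at configurable scale. Deterministic in `rng_seed`.
#'
#' @param n_genes Number of genes.
#' @param sirnas_per_gene siRNAs per gene (default 2).
#' @param rng_seed Integer seed.
#' @return Library `data.table` in [read_library()] format (`seed` unset).
#' @export
gen_library <- function(n_genes, sirnas_per_gene = 2L, rng_seed = 1L) {
  stopifnot(n_genes >= 1L, sirnas_per_gene >= 1L)
  with_seed(rng_seed, {
    n <- n_genes * sirnas_per_gene
    guides <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), 21L, replace = TRUE),
            collapse = "")
    }, character(1))
    data.table(sirna_id = sprintf("si%05d", seq_len(n)),
               gene = rep(sprintf("G%04d", seq_len(n_genes)),
                          each = sirnas_per_gene),
               guide_sequence = guides,
               seed = NA_character_)
  })
}

#' Default simulation ground truth for a discovery screen
#'
#' Plants on-target vulnerability genes and seed-mediated off-target
#' ("toxic seed") effects into a library, and draws log-normal plate
#' effects. Toxic seeds are chosen among seed groups with at least
#' `min_toxic_group` members none of which targets a planted hit gene, so
#' the off-target signal is separable from the on-target signal.
#'
#' Effect sizes are in units of the log-scale well noise SD (with the
#' default `noise_sd = 1` in [simulate_discovery()] they are robust-Z
#' units): the default -3 for hits and -2 for toxic seeds emulate strong
#' lethality phenotypes against unit assay noise.
#'
#' @param library Library table (seeds may be unset; extracted here).
#' @param n_hits Number of planted vulnerability genes (default 50).
#' @param hit_effect Log-scale effect per hit-gene siRNA (default -3).
#' @param n_toxic_seeds Number of planted toxic seeds (default 10).
#' @param seed_effect Log-scale effect per toxic-seed siRNA (default -2).
#' @param n_plates Number of plates; default sized for 384-well plates
#'   with 16 reference wells each.
#' @param plate_effect_sd SD of log plate effects (default 0.25).
#' @param min_toxic_group Minimum members for a toxic seed group
#'   (default 4).
#' @param rng_seed Integer seed.
#' @return Object of class `sim_truth`: list with `hit_genes` (named
#'   numeric), `toxic_seeds` (named numeric), `plate_effects` (named
#'   numeric), `rng_seed`.
#' @export
default_truth <- function(library, n_hits = 50L, hit_effect = -3,
                          n_toxic_seeds = 10L, seed_effect = -2,
                          n_plates = NULL, plate_effect_sd = 0.25,
                          min_toxic_group = 4L, rng_seed = 1L) {
  lib <- group_by_seed(library)
  stopifnot(hit_effect < 0, seed_effect < 0)
  with_seed(rng_seed, {
    genes <- unique(lib$gene)
    if (n_hits > length(genes)) stop("more hits than genes")
    hit_genes <- sort(sample(genes, n_hits))
    hits <- setNames(rep(hit_effect, n_hits), hit_genes)
    toxic <- setNames(numeric(0), character(0))
    if (n_toxic_seeds > 0L) {
      grp <- lib[, .(size = .N, touches_hit = any(gene %in% hit_genes)),
                 by = seed]
      eligible <- grp[size >= min_toxic_group & touches_hit == FALSE]
      if (nrow(eligible) < n_toxic_seeds) {
        # fall back to the largest clean groups available
        eligible <- grp[touches_hit == FALSE][order(-size)]
      }
      if (nrow(eligible) < n_toxic_seeds) stop("not enough seed groups")
      pick <- eligible[sample(nrow(eligible))][order(-size)][
        seq_len(n_toxic_seeds)]
      toxic <- setNames(rep(seed_effect, n_toxic_seeds), pick$seed)
    }
    if (is.null(n_plates)) {
      n_plates <- ceiling(nrow(lib) / (384L - 16L))
    }
    pe <- setNames(exp(rnorm(n_plates, 0, plate_effect_sd)),
                   sprintf("P%02d", seq_len(n_plates)))
    structure(list(hit_genes = hits, toxic_seeds = toxic,
                   plate_effects = pe, rng_seed = rng_seed),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation truth (rng_seed %d): %d hit genes, %d toxic seeds, ",
    "%d plates\n"),
    x$rng_seed, length(x$hit_genes), length(x$toxic_seeds),
    length(x$plate_effects)))
  invisible(x)
}

#' Simulate a discovery-screen plate set
#'
#' Emulates a reverse-transfection viability screen read out in RLU:
#' per-well log-signal = log(baseline) + log(plate effect) + gene effect
#' (for planted hit genes) + seed effect (for toxic-seed members) +
#' Gaussian(0, `noise_sd`), exponentiated to RLU. Non-transfected
#' reference wells carry the plate effect and noise but no phenotype, so
#' ratio-based plate normalization is exact in expectation.
#'
#' @param library Library table.
#' @param truth A `sim_truth` ([default_truth()]).
#' @param noise_sd Log-scale well noise SD (default 1; effect sizes in
#'   `truth` are expressed against this unit).
#' @param controls_per_plate Non-transfected reference wells per plate
#'   (default 16).
#' @param wells_per_plate Plate capacity (default 384).
#' @param baseline_rlu Reference RLU level (default 1e4).
#' @param cell_line Label stamped on the output (metadata only).
#' @param rng_seed Integer seed.
#' @return Plate table ([read_plate_table()] format) with an extra
#'   `cell_line` column.
#' @export
simulate_discovery <- function(library, truth, noise_sd = 1,
                               controls_per_plate = 16L,
                               wells_per_plate = 384L,
                               baseline_rlu = 1e4,
                               cell_line = "CL1", rng_seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  lib <- group_by_seed(library)
  lib_per_plate <- wells_per_plate - controls_per_plate
  n_plates <- length(truth$plate_effects)
  if (n_plates * lib_per_plate < nrow(lib)) {
    stop("truth has too few plates for this library")
  }
  with_seed(rng_seed, {
    plate_idx <- rep(seq_len(n_plates), each = lib_per_plate)[seq_len(nrow(lib))]
    gene_eff <- ifelse(lib$gene %in% names(truth$hit_genes),
                       truth$hit_genes[lib$gene], 0)
    seed_eff <- ifelse(lib$seed %in% names(truth$toxic_seeds),
                       truth$toxic_seeds[lib$seed], 0)
    log_pe <- log(truth$plate_effects)[plate_idx]
    log_sig <- log(baseline_rlu) + log_pe + gene_eff + seed_eff +
      rnorm(nrow(lib), 0, noise_sd)
    n_rows <- 16L  # 384-well geometry: 16 rows x 24 columns
    pos <- ((seq_len(nrow(lib)) - 1L) %% lib_per_plate)
    lib_wells <- data.table(
      plate = names(truth$plate_effects)[plate_idx],
      well_row = as.integer(pos %% n_rows + 1L),
      well_col = as.integer(pos %/% n_rows + 1L),
      role = "library", id = lib$sirna_id, signal = exp(log_sig),
      cell_line = cell_line)
    ctrl <- CJ(plate = names(truth$plate_effects),
               k = seq_len(controls_per_plate))
    ctrl_pos <- lib_per_plate + ctrl$k - 1L
    ctrl_log <- log(baseline_rlu) + log(truth$plate_effects)[
      match(ctrl$plate, names(truth$plate_effects))] +
      rnorm(nrow(ctrl), 0, noise_sd)
    ctrl_wells <- data.table(
      plate = ctrl$plate,
      well_row = as.integer(ctrl_pos %% n_rows + 1L),
      well_col = as.integer(ctrl_pos %/% n_rows + 1L),
      role = "non_transfected", id = NA_character_,
      signal = exp(ctrl_log), cell_line = cell_line)
    rbind(lib_wells, ctrl_wells)
  })
}

#' Simulate 3'-UTR sequences with planted seed sites
#'
#' Random DNA of fixed length per gene; for each (gene, seed) entry of
#' `planted`, the seed's reverse-complement site is written at a random
#' position. Insertion positions are recorded in the `"planted_at"`
#' attribute.
#'
#' @param genes Character vector of gene symbols.
#' @param length UTR length in nt (default 800).
#' @param planted Named character vector, gene -> RNA seed to plant.
#' @param rng_seed Integer seed.
#' @return Named character vector gene -> DNA sequence, with attribute
#'   `planted_at` (named integer positions).
#' @export
simulate_utrs <- function(genes, length = 800L, planted = character(),
                          rng_seed = 1L) {
  stopifnot(length >= 10L)
  if (!all(names(planted) %in% genes)) {
    stop("planted genes must be in `genes`")
  }
  with_seed(rng_seed, {
    seqs <- vapply(genes, function(g) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
    at <- setNames(integer(0), character(0))
    for (g in names(planted)) {
      site <- seed_site(planted[[g]])
      pos <- sample.int(length - nchar(site) + 1L, 1L)
      substr(seqs[[g]], pos, pos + nchar(site) - 1L) <- site
      at[g] <- pos
    }
    attr(seqs, "planted_at") <- at
    seqs
  })
}

#' Simulate a quantitative HTS dose-response plate
#'
#' Percent viability from 4PL curves plus Gaussian noise; a fraction of
#' wells is replaced by uniform(0, 120)% outliers. DMSO and bortezomib
#' control wells are generated at their defining 100% / 0% levels so the
#' control medians anchor normalization exactly. Viabilities are converted
#' to RLU with a per-plate gain.
#'
#' @param curve_params `data.frame` with columns `compound`, `top`,
#'   `bottom`, `ac50`, `hill` (one curve per row).
#' @param concentrations Shared concentration series
#'   ([dilution_series()]).
#' @param noise_sd_pct Gaussian noise SD on the percent scale (default 5).
#' @param outlier_rate Per-well probability of an outlier (default 0).
#' @param n_control Control wells per role (default 8).
#' @param gain Per-plate RLU gain (default 1).
#' @param plate Plate label.
#' @param rng_seed Integer seed.
#' @return Plate table with an extra `conc` column on library wells
#'   (`NA` for controls).
#' @export
simulate_dose_plate <- function(curve_params, concentrations,
                                noise_sd_pct = 5, outlier_rate = 0,
                                n_control = 8L, gain = 1,
                                plate = "DP01", rng_seed = 1L) {
  cp <- as.data.table(curve_params)
  need <- c("compound", "top", "bottom", "ac50", "hill")
  if (!all(need %in% names(cp))) {
    stop("curve_params needs columns: ", paste(need, collapse = ", "))
  }
  conc <- as.numeric(concentrations)
  bz_rlu <- 1000; dmso_rlu <- 20000  # control anchor levels at gain 1
  with_seed(rng_seed, {
    grid <- cp[rep(seq_len(nrow(cp)), each = length(conc))]
    grid[, conc := rep(conc, nrow(cp))]
    v <- .fourpl(grid$conc, grid$top, grid$bottom, grid$ac50, grid$hill)
    v <- v + rnorm(length(v), 0, noise_sd_pct)
    out <- runif(length(v)) < outlier_rate
    v[out] <- runif(sum(out), 0, 120)
    rlu <- gain * (bz_rlu + v / 100 * (dmso_rlu - bz_rlu))
    n_rows <- 16L
    pos <- seq_len(nrow(grid)) - 1L
    lib_wells <- data.table(
      plate = plate,
      well_row = as.integer(pos %% n_rows + 1L),
      well_col = as.integer(pos %/% n_rows + 1L),
      role = "library", id = grid$compound,
      signal = pmax(rlu, 0), conc = grid$conc, is_outlier = out)
    cpos <- nrow(grid) + seq_len(2L * n_control) - 1L
    ctrl_wells <- data.table(
      plate = plate,
      well_row = as.integer(cpos %% n_rows + 1L),
      well_col = as.integer(cpos %/% n_rows + 1L),
      role = rep(c("dmso", "bortezomib"), each = n_control),
      id = NA_character_,
      signal = gain * rep(c(dmso_rlu, bz_rlu), each = n_control),
      conc = NA_real_, is_outlier = FALSE)
    rbind(lib_wells, ctrl_wells)
  })
}
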