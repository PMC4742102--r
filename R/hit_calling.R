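#' Fit a heavy-tailed activity model to corrected siRNA activities
#'
#' Screen activity distributions are approximately symmetric around zero but
#' heavier-tailed than normal ("super-Gaussian"). This fits the symmetric
#' exponential-power family (see [exppow]) by profile maximum likelihood:
#' the location is the sample median; for each candidate shape `beta` the
#' scale has the closed-form MLE
#' `alpha = (beta * mean(|x - mu|^beta))^(1/beta)`, and `beta` is chosen on
#' a coarse grid then refined by one-dimensional optimization. Sample
#' skewness and excess kurtosis are attached as descriptive diagnostics
#' (the model itself is symmetric and cannot express skewness).
#'
#' @param x Numeric vector of activities; n >= 100 recommended for a stable
#'   shape estimate.
#' @param beta_range Search range for the shape exponent.
#' @return An object of class `tail_model`: list with `location`, `scale`,
#'   `shape`, `sample_skewness`, `sample_excess_kurtosis`, `n`, `loglik`.
#' @details Zero sample variance is a hard error.
#' @export
fit_tail_model <- function(x, beta_range = c(0.3, 4)) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite activities")
  if (length(x) < 3L) stop("need at least 3 values")
  if (sd(x) == 0) stop("zero variance: cannot fit a tail model")
  mu <- median(x)
  d <- abs(x - mu)
  d_pos <- d[d > 0]
  n <- length(x)
  # profile negative log-likelihood in beta (alpha concentrated out)
  nll <- function(beta) {
    alpha <- (beta * mean(d^beta))^(1 / beta)
    -(n * (log(beta) - log(2 * alpha) - lgamma(1 / beta)) -
        sum((d / alpha)^beta))
  }
  grid <- exp(seq(log(beta_range[1]), log(beta_range[2]), length.out = 25L))
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(nll, interval = c(lo, hi))
  beta <- opt$minimum
  alpha <- (beta * mean(d^beta))^(1 / beta)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  structure(list(location = mu, scale = alpha, shape = beta,
                 sample_skewness = m3 / m2^1.5,
                 sample_excess_kurtosis = m4 / m2^2 - 3,
                 n = n, loglik = -opt$objective),
            class = "tail_model")
}

#' @export
print.tail_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Exponential-power tail model (n = %d)\n",
    "  location %.4f, scale %.4f, shape %.3f\n",
    "  sample skewness %.3f, sample excess kurtosis %.3f\n"),
    x$n, x$location, x$scale, x$shape,
    x$sample_skewness, x$sample_excess_kurtosis))
  invisible(x)
}

#' Lower-tail significance cutoff for siRNA activities
#'
#' Returns the activity value below which a fraction `p` of the fitted
#' activity distribution lies; siRNAs below the cutoff are called "active".
#'
#' @param model A `tail_model` from [fit_tail_model()].
#' @param p Lower-tail significance level, 0 < p < 0.5 (default 0.05).
#' @param mode `"quantile"` (default): the p-quantile of the fitted
#'   symmetric exponential-power model. `"exponential_tail"`: a one-sided
#'   exponential is fit to the negative deviations from the location
#'   (rate = 1 / mean deviation) and the cutoff solves
#'   `0.5 * exp(-rate * (location - c)) = p`, i.e. the value below which a
#'   fraction p of a symmetric density with exponential lower tail falls.
#' @param values Raw activities; required for `mode = "exponential_tail"`.
#' @return The cutoff (a negative activity value for small p in a centered
#'   screen).
#' @export
estimate_cutoff <- function(model, p = 0.05,
                            mode = c("quantile", "exponential_tail"),
                            values = NULL) {
  mode <- match.arg(mode)
  if (!inherits(model, "tail_model")) stop("model must be a tail_model fit")
  if (!(p > 0 && p < 0.5)) stop("p must be in (0, 0.5)")
  if (mode == "quantile") {
    qexppow(p, mu = model$location, alpha = model$scale, beta = model$shape)
  } else {
    if (is.null(values)) {
      stop("mode 'exponential_tail' needs the raw activity values")
    }
    dev <- model$location - values[values < model$location]
    if (length(dev) < 10L) stop("too few lower-tail values to fit")
    rate <- 1 / mean(dev)
    model$location - (-log(2 * p) / rate)
  }
}

#' Redundant siRNA activity (RSA) gene ranking
#'
#' Ranks all scored siRNAs by activity (rank 1 = most negative = most
#' active, ties broken deterministically by `sirna_id`) and assigns each
#' gene the best iterated hypergeometric tail probability over its siRNAs:
#' for a gene whose n siRNAs sit at sorted ranks r_1 < ... < r_n among N
#' scored siRNAs,
#' \deqn{p_g = \min_i P(X \ge i), \quad
#'   X \sim \mathrm{Hypergeometric}(N, n, r_i),}
#' i.e. the probability that at least i of the gene's n siRNAs would land
#' in the top r_i by chance. Tails are computed in log space so screens up
#' to N = 1e5 are safe.
#'
#' @param corrected Table with `sirna_id` and an activity column.
#' @param gene_map Table with `sirna_id`, `gene`.
#' @param activity_col Activity column name (default `"corrected"`).
#' @return A `data.table` with one row per gene: `gene`, `rsa_log10p`,
#'   `best_activity` (most negative activity among its siRNAs),
#'   `n_sirnas`.
#' @details Genes with no scored siRNA are excluded with a warning.
#'   `rsa_log10p` is always <= 0.
#' @export
rsa_rank <- function(corrected, gene_map, activity_col = "corrected") {
  corrected <- as.data.table(corrected)
  gene_map <- as.data.table(gene_map)
  if (!activity_col %in% names(corrected)) {
    stop("no column '", activity_col, "' in activity table")
  }
  dt <- merge(corrected[, .(sirna_id, activity = get(activity_col))],
              gene_map[, .(sirna_id, gene)], by = "sirna_id")
  lost <- setdiff(gene_map$gene, dt$gene)
  if (length(lost)) {
    warning(length(lost), " gene(s) with no scored siRNA excluded")
  }
  setorder(dt, activity, sirna_id)
  dt[, rank := .I]
  N <- nrow(dt)
  dt[, n_sirnas := .N, by = gene]
  setorder(dt, gene, rank)
  dt[, i := seq_len(.N), by = gene]
  # log10 P(X >= i), X ~ Hypergeom(N, n, draws = rank)
  dt[, log10p_i := phyper(i - 1L, m = n_sirnas, n = N - n_sirnas, k = rank,
                          lower.tail = FALSE, log.p = TRUE) / log(10)]
  res <- dt[, .(rsa_log10p = min(log10p_i),
                best_activity = activity[1L],
                n_sirnas = .N), by = gene]
  res[, rsa_log10p := pmin(rsa_log10p, 0)]
  res[]
}

#' Flag discovery-screen hits
#'
#' A gene is a hit when its RSA ranking is significant *and* at least one
#' of its siRNAs is active below the screen's significance cutoff:
#' `is_hit = (rsa_log10p < log10p_threshold) & (best_activity < cutoff)`.
#'
#' @param results [rsa_rank()] output.
#' @param cutoff Activity significance cutoff ([estimate_cutoff()]).
#' @param log10p_threshold RSA threshold; default `-1.301` = log10(0.05).
#' @return `results` with a logical `is_hit` column added.
#' @export
select_hits <- function(results, cutoff, log10p_threshold = -1.301) {
  results <- as.data.table(results)
  results <- copy(results)
  results[, is_hit := rsa_log10p < log10p_threshold & best_activity < cutoff]
  results[]
}

#' Combine per-line hits into screen-level candidates
#'
#' A gene is a candidate when it is a hit in both cell lines of at least
#' one genetic subgroup, or a hit in three or more cell lines overall.
#'
#' @param per_line_hits Named list, cell line -> character vector of hit
#'   genes.
#' @param subgroups Named character vector, cell line -> subgroup label
#'   (e.g. `c(IMR32 = "MNA", IMR5 = "MNA", `SK-N-AS` = "nonMNA", ...)`).
#' @return Sorted character vector of candidate genes.
#' @export
combine_across_lines <- function(per_line_hits, subgroups) {
  lines <- names(per_line_hits)
  if (length(lines) < 2L) stop("need at least 2 cell lines")
  if (!all(lines %in% names(subgroups))) {
    stop("every cell line needs a subgroup assignment")
  }
  genes <- unique(unlist(per_line_hits, use.names = FALSE))
  if (!length(genes)) return(character())
  hitmat <- vapply(per_line_hits, function(h) genes %in% h,
                   logical(length(genes)))
  if (length(genes) == 1L) hitmat <- matrix(hitmat, nrow = 1L)
  n_lines <- rowSums(hitmat)
  sub_full <- vapply(unique(subgroups[lines]), function(sg) {
    cols <- lines[subgroups[lines] == sg]
    rowSums(hitmat[, cols, drop = FALSE]) == length(cols) & length(cols) >= 2L
  }, logical(length(genes)))
  if (length(genes) == 1L) sub_full <- matrix(sub_full, nrow = 1L)
  sort(genes[n_lines >= 3L | rowSums(sub_full) > 0L])
}

#' Verification-screen RSA scoring
#'
#' Applies RSA to normalized verification-screen viabilities (rank 1 =
#' lowest relative viability). A gene is verified in a cell line when its
#' RSA log10 p-value falls below the threshold.
#'
#' @param viability Table with `sirna_id` and `viability`
#'   ([normalize_verification()] output).
#' @param gene_map Table with `sirna_id`, `gene`.
#' @param log10p_threshold Default `-1.301` (p < 0.05).
#' @return A `data.table` with `gene`, `rsa_log10p`, `best_activity`
#'   (lowest viability), `n_sirnas`, `is_verified`.
#' @export
verify_genes <- function(viability, gene_map, log10p_threshold = -1.301) {
  res <- rsa_rank(viability, gene_map, activity_col = "viability")
  res[, is_verified := rsa_log10p < log10p_threshold]
  res[]
}

#' Expression filter for candidate genes
#'
#' Drops candidates that are not expressed in any screened cell line.
#' FPKM values are smoothed by +0.01 before log2 transformation; a gene
#' passes when its maximum `log2(fpkm + 0.01)` across cell lines reaches
#' the threshold. Candidates absent from the expression table are treated
#' as FPKM 0 with a warning.
#'
#' @param genes Table with a `gene` column (e.g. verified candidates).
#' @param expr Expression table with `gene`, `fpkm` and optionally
#'   `cell_line` (multiple rows per gene are reduced by max).
#' @param threshold Minimum `log2(fpkm + 0.01)` (default 0, i.e. FPKM
#'   around 1).
#' @return `genes` with `log2_fpkm` (max across cell lines) and logical
#'   `passes_expression` added.
#' @export
expression_filter <- function(genes, expr, threshold = 0) {
  genes <- as.data.table(genes)
  genes <- copy(genes)
  expr <- as.data.table(expr)
  if (any(expr$fpkm < 0, na.rm = TRUE)) stop("negative FPKM")
  mx <- expr[, .(log2_fpkm = log2(max(fpkm) + 0.01)), by = gene]
  absent <- setdiff(genes$gene, mx$gene)
  if (length(absent)) {
    warning(length(absent),
            " candidate gene(s) missing from expression table; treated as ",
            "FPKM 0")
  }
  genes[, log2_fpkm := mx$log2_fpkm[match(gene, mx$gene)]]
  genes[is.na(log2_fpkm), log2_fpkm := log2(0.01)]
  genes[, passes_expression := log2_fpkm >= threshold]
  genes[]
}

#' Run the discovery-screen pipeline on one cell line
#'
#' Convenience wrapper chaining plate normalization, per-screen robust
#' Z-scores, common-seed correction, tail-model fitting, cutoff estimation,
#' RSA ranking and hit selection.
#'
#' @param wells Plate table for one cell line.
#' @param library siRNA library table ([read_library()] format).
#' @param reference_role Plate-normalization reference role.
#' @param p_cutoff Lower-tail significance level for the activity cutoff.
#' @param log10p_threshold RSA hit threshold.
#' @param cutoff_mode See [estimate_cutoff()].
#' @param correct_seeds Apply common-seed correction (default `TRUE`;
#'   `FALSE` ranks the raw robust Z-scores, for comparison runs).
#' @param log_transform Robust Z-score the natural log of the
#'   plate-normalized viability ratio (default `TRUE`). On the log scale
#'   plate effects and knockdown phenotypes are additive and a lethal
#'   effect of k noise-SDs scores close to a robust Z of -k; the raw ratio
#'   scale compresses the lethal tail.
#' @param seed_start,seed_length,min_group_size Seed-correction parameters.
#' @return List of class `discovery_result`: `scores` (per-siRNA table),
#'   `model` (`tail_model`), `cutoff`, `genes` (per-gene table with
#'   `is_hit`).
#' @export
run_discovery <- function(wells, library,
                          reference_role = "non_transfected",
                          p_cutoff = 0.05, log10p_threshold = -1.301,
                          cutoff_mode = c("quantile", "exponential_tail"),
                          correct_seeds = TRUE, log_transform = TRUE,
                          seed_start = 2L, seed_length = 6L,
                          min_group_size = 3L) {
  cutoff_mode <- match.arg(cutoff_mode)
  lib <- group_by_seed(library, seed_start, seed_length)
  scores <- plate_normalize(wells, reference_role)
  if (log_transform) {
    if (any(scores$plate_normalized <= 0)) {
      stop("non-positive normalized viability; cannot log-transform")
    }
    scores[, robust_z := robust_z(log(plate_normalized))]
  } else {
    scores[, robust_z := robust_z(plate_normalized)]
  }
  if (correct_seeds) {
    corr <- median_seed_correct(scores, lib, min_group_size = min_group_size)
  } else {
    corr <- scores[, .(sirna_id, seed = NA_character_, group_size = NA_integer_,
                       corrected = robust_z)]
  }
  model <- fit_tail_model(corr$corrected)
  cutoff <- estimate_cutoff(model, p = p_cutoff, mode = cutoff_mode,
                            values = corr$corrected)
  genes <- rsa_rank(corr, lib[, .(sirna_id, gene)])
  genes <- select_hits(genes, cutoff, log10p_threshold)
  structure(list(scores = merge(scores, corr, by = "sirna_id"),
                 model = model, cutoff = cutoff, genes = genes),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Discovery screen: %d siRNAs, %d genes\n",
    "  tail shape %.3f, activity cutoff %.3f\n",
    "  hits: %d genes (log10p < threshold and best activity < cutoff)\n"),
    nrow(x$scores), nrow(x$genes), x$model$shape, x$cutoff,
    sum(x$genes$is_hit)))
  invisible(x)
}
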