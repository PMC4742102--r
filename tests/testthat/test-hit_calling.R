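test_that("fit_tail_model recovers known shapes", {
  set.seed(101)
  xn <- rnorm(5e4)
  mn <- fit_tail_model(xn)
  expect_equal(mn$shape, 2, tolerance = 0.1)
  expect_equal(mn$sample_excess_kurtosis, 0, tolerance = 0.15)
  expect_equal(mn$scale, sqrt(2), tolerance = 0.05)

  xl <- rexppow(5e4, mu = 0.5, alpha = 1, beta = 1)  # Laplace
  ml <- fit_tail_model(xl)
  expect_equal(ml$shape, 1, tolerance = 0.1)
  expect_equal(ml$location, 0.5, tolerance = 0.05)

  expect_error(fit_tail_model(rep(1, 100)), "zero variance")
})

test_that("estimate_cutoff returns exact model quantiles", {
  normal <- structure(list(location = 0, scale = sqrt(2), shape = 2),
                      class = "tail_model")
  expect_equal(estimate_cutoff(normal, 0.05), qnorm(0.05),
               tolerance = 1e-10)
  laplace <- structure(list(location = 0, scale = 1, shape = 1),
                       class = "tail_model")
  expect_equal(estimate_cutoff(laplace, 0.05), log(0.1), tolerance = 1e-10)

  # exponential-tail mode: Laplace lower tail is exactly exponential
  set.seed(7)
  x <- rexppow(2e5, 0, 1, 1)
  ml <- fit_tail_model(x)
  expect_equal(estimate_cutoff(ml, 0.05, "exponential_tail", values = x),
               log(0.1), tolerance = 0.05)

  expect_error(estimate_cutoff(normal, 0.7), "in \\(0, 0.5\\)")
})

test_that("rsa_rank matches hand-computed hypergeometric tails", {
  # N = 10, one siRNA at rank 1: p = 1/10
  gm <- data.table::data.table(sirna_id = sprintf("s%02d", 1:10),
                               gene = paste0("g", 1:10))
  act <- data.table::data.table(sirna_id = gm$sirna_id,
                                corrected = c(-5, seq(0.1, 0.9, 0.1)))
  r <- rsa_rank(act, gm)
  expect_equal(r[gene == "g1", rsa_log10p], -1)

  # N = 4, gene's siRNAs at the two worst ranks: p = 1, log10p = 0
  gm2 <- data.table::data.table(sirna_id = c("a", "b", "c", "d"),
                                gene = c("gO", "gO", "gX", "gX"))
  act2 <- data.table::data.table(sirna_id = c("a", "b", "c", "d"),
                                 corrected = c(-2, -1, 1, 2))
  r2 <- rsa_rank(act2, gm2)  # gX occupies the two worst ranks {3, 4}
  expect_equal(r2[gene == "gX", rsa_log10p], 0)
  expect_equal(r2[gene == "gX", best_activity], 1)
})

test_that("rsa_rank equals brute-force enumeration on small screens", {
  for (s in 1:60) {
    N <- sample(8:20, 1)
    scr <- random_screen(N, n_genes = sample(3:6, 1), seed = s)
    got <- rsa_rank(scr[, .(sirna_id, corrected)],
                    scr[, .(sirna_id, gene)])
    want <- rsa_brute(scr$corrected, scr$sirna_id, scr$gene)
    expect_equal(got$rsa_log10p, unname(want[got$gene]), tolerance = 1e-10)
  }
})

test_that("rsa_rank p-values are monotone in rank improvements", {
  set.seed(9)
  base <- random_screen(60, n_genes = 10, seed = 99)
  g <- base$gene[1]
  before <- rsa_rank(base[, .(sirna_id, corrected)],
                     base[, .(sirna_id, gene)])
  # move one of g's siRNAs to the very best rank
  improved <- data.table::copy(base)
  improved[gene == g][1]
  improved[which(improved$gene == g)[1], corrected := min(base$corrected) - 1]
  after <- rsa_rank(improved[, .(sirna_id, corrected)],
                    improved[, .(sirna_id, gene)])
  expect_lte(after[gene == g, rsa_log10p], before[gene == g, rsa_log10p])
  expect_true(all(after$rsa_log10p <= 0))
})

test_that("select_hits needs both the RSA and the activity condition", {
  res <- data.table::data.table(
    gene = c("a", "b", "c"),
    rsa_log10p = c(-2.0, -1.2, -1.5),
    best_activity = c(-1.0, -3.0, -3.0),
    n_sirnas = 2L)
  out <- select_hits(res, cutoff = -2)
  expect_equal(out$is_hit, c(FALSE, FALSE, TRUE))
})

test_that("combine_across_lines applies the subgroup/3-line rule", {
  sub <- c(L1 = "MNA", L2 = "MNA", L3 = "nonMNA", L4 = "nonMNA")
  hits <- list(L1 = c("gBoth", "gThree", "gOne"),
               L2 = c("gBoth", "gThree"),
               L3 = c("gThree", "gCross"),
               L4 = c("gCrossB"))
  out <- combine_across_lines(hits, sub)
  expect_true("gBoth" %in% out)    # both lines of the MNA subgroup
  expect_true("gThree" %in% out)   # three lines across subgroups
  expect_false("gOne" %in% out)    # single line
  expect_false("gCross" %in% out)  # one line per subgroup only
})

test_that("verify_genes calls verified genes from a 639-siRNA screen", {
  # 213 genes x 3 siRNAs = 639, mirroring the verification screen scale
  set.seed(12)
  genes <- sprintf("vg%03d", 1:213)
  gm <- data.table::data.table(sirna_id = sprintf("v%03d", 1:639),
                               gene = rep(genes, each = 3))
  viab <- data.table::data.table(sirna_id = gm$sirna_id,
                                 viability = runif(639, 0.5, 1.2))
  # one gene with all three siRNAs at the very bottom of the viability range
  viab[gm$gene == "vg007", viability := c(0.01, 0.02, 0.03)]
  out <- verify_genes(viab, gm)
  expect_true(out[gene == "vg007", is_verified])
  # scattered-rank genes are not verified
  worst <- out[gene != "vg007"][order(rsa_log10p)]
  expect_equal(out[gene == "vg007", rsa_log10p],
               min(out$rsa_log10p))
  # oracle check on the full screen
  want <- rsa_brute(viab$viability, viab$sirna_id, gm$gene)
  expect_equal(out$rsa_log10p, unname(want[out$gene]), tolerance = 1e-9)
})

test_that("expression_filter smooths, flags and warns on missing genes", {
  genes <- data.table::data.table(gene = c("AURKB", "GABRD", "TINAGL1",
                                           "KIF2B", "KIF11"))
  expr <- data.table::data.table(
    gene = rep(c("AURKB", "GABRD", "TINAGL1", "KIF11"), each = 2),
    cell_line = rep(c("CL1", "CL2"), 4),
    fpkm = c(12, 30, 0, 0.1, 0.2, 0.05, 5, 2))
  expect_warning(out <- expression_filter(genes, expr, threshold = 0),
                 "missing from expression")
  expect_equal(out[gene == "GABRD", log2_fpkm], log2(0.11))
  expect_equal(out[gene == "KIF2B", log2_fpkm], log2(0.01))  # absent -> 0
  expect_equal(out$passes_expression,
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(sum(out$passes_expression), nrow(out) - 3L)

  # all-above-threshold leaves the collection unchanged
  ok <- expression_filter(genes[gene %in% c("AURKB", "KIF11")], expr)
  expect_true(all(ok$passes_expression))

  expect_error(expression_filter(genes, data.table::data.table(
    gene = "AURKB", fpkm = -1)), "negative FPKM")
})
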