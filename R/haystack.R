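#' Reverse-complement DNA site of an RNA seed
#'
#' The 3'-UTR site recognized by a seed is the reverse complement of the
#' seed transcribed back to DNA: seed "AGCGUA" pairs with the genomic site
#' "TACGCT".
#'
#' @param seed RNA seed string(s) over A/C/G/U.
#' @return DNA site string(s).
#' @export
seed_site <- function(seed) {
  dna <- chartr("U", "T", toupper(seed))
  comp <- chartr("ACGT", "TGCA", dna)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""),
         character(1))
}

#' Count seed-complementary sites in a 3'-UTR
#'
#' Number of occurrences of the seed's reverse-complement DNA site in the
#' UTR, counting overlapping occurrences; `N` bases never match.
#'
#' @param seed RNA seed (6-7 nt).
#' @param utr DNA string over A/C/G/T/N.
#' @return Integer count.
#' @export
count_seed_matches <- function(seed, utr) {
  if (nchar(seed) < 6L || nchar(seed) > 7L) stop("seed must be 6-7 nt")
  site <- seed_site(seed)
  hits <- gregexpr(paste0("(?=", site, ")"), toupper(utr), perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Build the siRNA-by-gene seed-match matrix
#'
#' For every (siRNA, gene) pair, the number of sites in the gene's 3'-UTR
#' complementary to the siRNA's seed. Rows are a pure function of the seed,
#' so siRNAs sharing a seed get identical rows. Genes without a UTR get a
#' zero column with a warning.
#'
#' @param library Seed-grouped library ([group_by_seed()] output).
#' @param utrs Named character vector, gene -> UTR DNA
#'   ([read_fasta_utrs()] output).
#' @param binary If `TRUE`, entries are 0/1 presence indicators.
#' @param genes Gene universe for the columns; defaults to `names(utrs)`.
#'   A gene without a UTR gets a zero column with a warning.
#' @return Integer matrix, rownames = `sirna_id`, colnames = gene.
#' @export
build_match_matrix <- function(library, utrs, binary = FALSE,
                               genes = names(utrs)) {
  lib <- as.data.table(library)
  if (!"seed" %in% names(lib) || anyNA(lib$seed)) {
    stop("library seeds not extracted; run group_by_seed() first")
  }
  no_utr <- setdiff(genes, names(utrs))
  if (length(no_utr)) {
    warning(length(no_utr), " gene(s) without a UTR get zero columns")
  }
  sites <- seed_site(lib$seed)
  usite <- unique(sites)
  k <- nchar(usite[1])
  # per-gene counts for every distinct site, via the UTR's k-mer spectrum
  site_counts <- matrix(0L, nrow = length(usite), ncol = length(genes),
                        dimnames = list(usite, genes))
  for (j in seq_along(genes)) {
    if (!genes[j] %in% names(utrs)) next
    utr <- toupper(utrs[[genes[j]]])
    L <- nchar(utr)
    if (L < k) next
    kmers <- substring(utr, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    tab <- table(kmers)
    found <- intersect(names(tab), usite)
    if (length(found)) site_counts[found, j] <- as.integer(tab[found])
  }
  M <- site_counts[match(sites, usite), , drop = FALSE]
  rownames(M) <- lib$sirna_id
  if (binary) M <- (M >= 1L) * 1L
  storage.mode(M) <- "integer"
  M
}

#' Haystack seed off-target regression
#'
#' For each gene, regresses siRNA activity on a seed-match predictor
#' (default: the 0/1 indicator of having at least one complementary site in
#' that gene's 3'-UTR) by ordinary least squares and tests the slope with a
#' two-sided t-test. P-values are Benjamini-Hochberg adjusted across tested
#' genes; a gene is a candidate off-target victim when its slope is
#' negative (siRNAs matching it are more lethal) and its q-value is below
#' `alpha`.
#'
#' With a binary predictor the OLS slope is exactly
#' `mean(activity | match) - mean(activity | no match)`.
#'
#' @param activities Table with `sirna_id` and an activity column, or a
#'   plain numeric vector aligned with the matrix rows.
#' @param matrix Seed-match matrix ([build_match_matrix()]).
#' @param alpha Candidate significance level on the q-value (default 0.05).
#' @param predictor `"binary"` (default) or `"count"`.
#' @param min_per_group Minimum matching and non-matching siRNAs per tested
#'   gene (default 5); genes failing it are skipped with a warning.
#' @param min_sirnas Minimum number of scored siRNAs overall (default 30).
#' @param activity_col Activity column name when `activities` is a table.
#' @return A `data.table` with `gene`, `n_match`, `estimate`, `p_value`,
#'   `q_value`, `is_candidate`.
#' @export
haystack_regress <- function(activities, matrix, alpha = 0.05,
                             predictor = c("binary", "count"),
                             min_per_group = 5L, min_sirnas = 30L,
                             activity_col = "corrected") {
  predictor <- match.arg(predictor)
  if (is.numeric(activities)) {
    if (length(activities) != nrow(matrix)) {
      stop("activity vector length does not match matrix rows")
    }
    a <- as.numeric(activities)
  } else {
    activities <- as.data.table(activities)
    idx <- match(rownames(matrix), activities$sirna_id)
    if (anyNA(idx)) stop("matrix rows missing from activity table")
    a <- as.numeric(activities[[activity_col]][idx])
  }
  S <- length(a)
  if (S < min_sirnas) {
    stop("need at least ", min_sirnas, " siRNAs for the regression")
  }
  X <- if (predictor == "binary") (matrix >= 1L) * 1 else matrix * 1
  ind <- (matrix >= 1L) * 1  # grouping always by presence for the n checks
  n1 <- colSums(ind)
  testable <- n1 >= min_per_group & (S - n1) >= min_per_group
  if (!all(testable)) {
    warning(sum(!testable), " gene(s) skipped: fewer than ", min_per_group,
            " matching or non-matching siRNAs")
  }
  X <- X[, testable, drop = FALSE]
  if (ncol(X) == 0L) stop("no testable genes")
  # per-gene simple OLS of a on x, vectorized over genes
  sx <- colSums(X)
  sxx <- colSums(X^2)
  sxa <- as.numeric(crossprod(X, a))
  sa <- sum(a)
  saa <- sum(a^2)
  vx <- sxx - sx^2 / S
  beta1 <- (sxa - sx * sa / S) / vx
  beta0 <- (sa - beta1 * sx) / S
  rss <- saa - beta0 * sa - beta1 * sxa
  rss <- pmax(rss, 0)
  se <- sqrt(rss / (S - 2L) / vx)
  tstat <- beta1 / se
  pval <- 2 * pt(-abs(tstat), df = S - 2L)
  qval <- p.adjust(pval, method = "BH")
  data.table(gene = colnames(X), n_match = n1[testable],
             estimate = beta1, p_value = pval, q_value = qval,
             is_candidate = beta1 < 0 & qval < alpha)
}
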