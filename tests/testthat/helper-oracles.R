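# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (brute-force enumeration, sliding windows) so
# agreement is evidence, not tautology.

# Brute-force RSA: for each gene, min over i of P(X >= i) with the tail sum
# computed directly from binomial coefficients.
rsa_brute <- function(activity, sirna_id, gene) {
  ord <- order(activity, sirna_id)
  rank <- integer(length(activity))
  rank[ord] <- seq_along(activity)
  N <- length(activity)
  vapply(unique(gene), function(g) {
    rs <- sort(rank[gene == g])
    n <- length(rs)
    p <- 1
    for (i in seq_len(n)) {
      r <- rs[i]
      js <- i:min(n, r)
      tail_p <- sum(choose(n, js) * choose(N - n, r - js)) / choose(N, r)
      p <- min(p, tail_p)
    }
    log10(min(max(p, .Machine$double.xmin), 1))
  }, numeric(1))
}

# Sliding-window substring match counter (overlap-counting).
window_count <- function(site, utr) {
  k <- nchar(site)
  L <- nchar(utr)
  if (L < k) return(0L)
  sum(substring(utr, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L) ==
        site)
}

# Overwrite the seed region (guide positions 2-7) of chosen siRNAs so they
# share a seed group; used to engineer off-target fixtures in libraries too
# small for natural hexamer collisions.
plant_shared_seed <- function(lib, sirna_ids, seed) {
  lib <- data.table::copy(lib)
  rows <- match(sirna_ids, lib$sirna_id)
  for (r in rows) {
    g <- lib$guide_sequence[r]
    substr(g, 2L, 1L + nchar(seed)) <- seed
    lib$guide_sequence[r] <- g
  }
  lib$seed <- NA_character_
  group_by_seed(lib)
}

# Tiny random screen for RSA oracle comparisons.
random_screen <- function(N, n_genes, seed) {
  set.seed(seed)
  gene <- sample(paste0("g", seq_len(n_genes)), N, replace = TRUE)
  data.table::data.table(
    sirna_id = sprintf("s%03d", seq_len(N)),
    gene = gene,
    corrected = rnorm(N))
}

# Four-cell-line synthetic discovery screen with shared biological truth
# (hit genes, toxic seeds) and line-specific plates/noise; the stated
# default world: 2000 genes x 2 siRNAs, 50 hits at -3 SD, 10 toxic seeds
# at -2 SD, noise SD 1.
default_screen <- function(rng_seed = 1L, n_lines = 4L, n_genes = 2000L) {
  lib <- gen_library(n_genes, 2L, rng_seed = rng_seed)
  truth <- default_truth(lib, rng_seed = rng_seed)
  lines <- paste0("CL", seq_len(n_lines))
  wells <- lapply(seq_along(lines), function(i) {
    ti <- truth
    # line-specific plate effects, same biology
    set.seed(rng_seed * 1000L + i)
    ti$plate_effects[] <- exp(rnorm(length(ti$plate_effects), 0, 0.25))
    simulate_discovery(lib, ti, cell_line = lines[i],
                       rng_seed = rng_seed * 100L + i)
  })
  names(wells) <- lines
  list(library = lib, truth = truth, wells = wells, lines = lines)
}
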