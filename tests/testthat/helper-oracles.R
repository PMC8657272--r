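# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms/code paths than R/.

# step-by-step TMM: explicit sort-based trimming, then weighted mean
oracle_tmm <- function(counts, lib = colSums(counts), trim_m = 0.30,
                       trim_a = 0.05) {
  cpm0 <- sweep(counts, 2, lib, "/") * 1e6
  uq <- apply(cpm0, 2, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    M <- log2((o[keep] / lib[j]) / (r[keep] / lib[ref]))
    A <- 0.5 * log2((o[keep] / lib[j]) * (r[keep] / lib[ref]))
    w <- (lib[j] - o[keep]) / (lib[j] * o[keep]) +
      (lib[ref] - r[keep]) / (lib[ref] * r[keep])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    kM <- floor(n * trim_m)
    kA <- floor(n * trim_a)
    okM <- M >= sort(M)[kM + 1] & M <= sort(M)[n - kM]
    okA <- A >= sort(A)[kA + 1] & A <= sort(A)[n - kA]
    use <- okM & okA
    2^(sum(M[use] / w[use]) / sum(1 / w[use]))
  })
  f / exp(mean(log(f)))
}

# conditional binomial two-sided p by full enumeration
oracle_binom_p <- function(s_a, total, n_a, n_b) {
  p <- dbinom(0:total, total, n_a / (n_a + n_b))
  obs <- p[s_a + 1]
  sum(p[p <= obs * (1 + 1e-9)])
}

# BH by the direct step-up definition: q_i = min over p_(j) >= p_i of m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  sapply(p, function(pi) {
    j <- which(sp >= pi - 1e-15)
    min(1, min(m * sp[j] / j))
  })
}

# running-sum ES by explicit walk (signed maximum deviation; on a
# magnitude tie the positive deviation wins, as in the implementation)
oracle_es <- function(ranking, gene_set) {
  hit <- ranking %in% gene_set
  nh <- sum(hit)
  nm <- length(ranking) - nh
  run <- cumsum(ifelse(hit, 1 / nh, -1 / nm))
  mx <- max(run)
  mn <- min(run, 0)
  # cumsum rounding can tip an exact magnitude tie either way
  if (abs(mx) >= abs(mn) - 1e-9) mx else mn
}

# log-rank by a naive per-time loop (independent of the vectorized path)
oracle_logrank <- function(time, event, g1) {
  tt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  d2tot <- 0
  for (t in tt) {
    n1 <- sum(time >= t & g1); n2 <- sum(time >= t & !g1)
    d1 <- sum(time == t & event == 1 & g1)
    d2 <- sum(time == t & event == 1 & !g1)
    n <- n1 + n2; d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    d2tot <- d2tot + d2
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  O <- c(O1, d2tot)
  E <- c(E1, sum(event) - E1)
  list(observed = O, expected = E, chisq = (O[1] - E[1])^2 / V,
       hr = (O[1] / E[1]) / (O[2] / E[2]))
}

# per-nucleotide site mapping: enumerate the UTR's genomic coordinates one
# by one in transcript order, directly from the block table
oracle_map_site <- function(blocks_start0, blocks_end_excl, strand,
                            site_start, site_end) {
  per_block <- lapply(seq_along(blocks_start0), function(i) {
    g <- blocks_start0[i]:(blocks_end_excl[i] - 1)
    if (strand == "-") rev(g) else g
  })
  if (strand == "-") {
    o <- order(blocks_start0, decreasing = TRUE)
    per_block <- per_block[o]
  }
  nt <- unlist(per_block)
  sort(nt[site_start:site_end])
}

# expand mapped half-open blocks back to genomic positions
expand_blocks <- function(df) {
  sort(unlist(lapply(seq_len(nrow(df)), function(i) df$start[i]:(df$end[i] - 1))))
}
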