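# small cohort config for module tests (fast; acceptance uses defaults)
small_config <- function(seed = 1, ...) {
  sim_config(n_mirna = 60, n_planted_up = 4, n_planted_dn = 8,
             n_genes = 80, decoy_interactions = 200,
             n_surv_samples = 120, seed = seed, ...)
}

# toy count matrix with two classes
toy_counts <- function(seed = 1, n_feat = 50, n_a = 4, n_b = 6,
                       mu = 100, phi = 0.1) {
  set.seed(seed)
  n <- n_a + n_b
  m <- matrix(rnbinom(n_feat * n, mu = mu, size = 1 / phi), n_feat, n,
              dimnames = list(sprintf("f%03d", 1:n_feat),
                              sprintf("s%02d", 1:n)))
  count_matrix(m, rep(c("ATC", "other"), c(n_a, n_b)))
}

# in-code annotation: GRanges of three_prime_utr blocks
make_ann <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "test"
  S4Vectors::mcols(gr)$type <- "three_prime_utr"
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  annotation_from_granges(gr)
}

# random single-gene annotation with 1-3 UTR blocks on a random strand
random_ann <- function(n_blocks = sample(1:3, 1),
                       strand = sample(c("+", "-"), 1)) {
  starts <- cumsum(sample(200:500, n_blocks))
  widths <- sample(20:120, n_blocks, replace = TRUE)
  make_ann(data.frame(chrom = "chrT", start = starts,
                      end = starts + widths - 1, strand = strand,
                      gene_id = "G1", transcript_id = "G1.t1"))
}
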