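#' Configuration for the synthetic cohort generator
#'
#' Captures the study design being emulated: a 28-sample thyroid carcinoma
#' cohort (10 ATC / 6 PTC / 6 FTC / 6 NT) with negative-binomially
#' distributed miRNA counts, 23 planted UP- and 62 planted DN-miRNAs in ATC,
#' target mRNAs with inverse fold changes, decoy interactions, signed
#' essentiality scores across ATC-derived cell lines and a survival cohort
#' with expression-dependent hazards.
#'
#' @param n_per_group named integer vector of samples per class.
#' @param n_mirna number of miRNAs.
#' @param n_planted_up,n_planted_dn planted UP-/DN-miRNA counts (23 / 62).
#' @param planted_log2fc ATC shift of planted miRNAs, log2 units.
#' @param baseline_cpm_range log-uniform baseline CPM range for miRNAs.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param n_genes mRNA gene universe size.
#' @param targets_per_planted_mirna true target genes per planted miRNA.
#' @param decoy_interactions number of decoy interaction records.
#' @param target_inverse_log2fc ATC shift of true target mRNAs (sign is
#'   opposite to the targeting miRNA's direction).
#' @param ess_onco_mean,ess_ts_mean gene-effect centers for planted
#'   oncogene / suppressor targets (negative = fitness cost on knockout).
#' @param surv_beta log-hazard per SD of the oncogenic expression program.
#' @param censor_rate approximate fraction of censored survival samples.
#' @param n_surv_samples survival cohort size.
#' @param n_cell_lines essentiality screen cell-line count.
#' @param lib_size_range log-uniform library-size range (2x span by default,
#'   to force non-trivial TMM factors).
#' @param seed RNG seed; identical config + seed gives identical datasets.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(ATC = 10, PTC = 6, FTC = 6, NT = 6),
                       n_mirna = 800,
                       n_planted_up = 23,
                       n_planted_dn = 62,
                       planted_log2fc = 2.0,
                       baseline_cpm_range = c(50, 5000),
                       nb_dispersion = 0.1,
                       n_genes = 400,
                       targets_per_planted_mirna = 3,
                       decoy_interactions = 2000,
                       target_inverse_log2fc = 1.5,
                       ess_onco_mean = -1.0,
                       ess_ts_mean = 0.5,
                       surv_beta = 1.0,
                       censor_rate = 0.4,
                       n_surv_samples = 200,
                       n_cell_lines = 9,
                       lib_size_range = c(5e4, 1e5),
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_per_group, cfg$n_mirna, cfg$n_genes,
              cfg$targets_per_planted_mirna, cfg$n_surv_samples,
              cfg$n_cell_lines)
  if (any(counts <= 0)) stop("invalid config: all counts must be positive")
  if (cfg$n_planted_up < 0 || cfg$n_planted_dn < 0)
    stop("invalid config: planted counts must be >= 0")
  if (cfg$nb_dispersion < 0) stop("invalid config: dispersion must be >= 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop("invalid config: censor_rate must be in [0, 1]")
  if (cfg$n_planted_up + cfg$n_planted_dn > cfg$n_mirna)
    stop("invalid config: more planted miRNAs than miRNAs")
  if ((cfg$n_planted_up + cfg$n_planted_dn) *
        cfg$targets_per_planted_mirna > cfg$n_genes)
    stop("invalid config: planted targets exceed the gene universe")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a complete synthetic pipeline dataset with planted truth
#'
#' Draws every input the pipeline consumes - miRNA counts, mRNA FPKM,
#' interaction records, transcript annotation, essentiality scores and a
#' survival cohort - together with a ledger of the planted ground truth.
#' Planted miRNAs have their ATC group mean shifted by `planted_log2fc`
#' (up or down); their true target genes shift inversely in ATC and carry
#' maximal binding evidence (probability 1, both predictor flags set).
#' Targets of DN-miRNAs are labeled oncogenes (negative essentiality,
#' hazard-increasing expression); targets of UP-miRNAs are suppressors with
#' the mirror pattern. One designated prime oncogene (targeted by up to four
#' DN-miRNAs) and one prime suppressor (two UP-miRNAs) carry the strongest
#' effects on every evidence axis.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_dataset`: list with `mirna_counts`
#'   (a [count_matrix()]), `mrna_fpkm`, `interactions`, `annotation`
#'   (+ `annotation_gr`), `essentiality`, `survival`
#'   (`clinical` + `expr`), `truth` and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  samples <- sprintf("S%02d_%s", seq_along(groups), groups)
  names(groups) <- samples
  n_samp <- length(samples)
  is_atc <- groups == "ATC"

  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  planted_up <- mirnas[seq_len(cfg$n_planted_up)]
  planted_dn <- mirnas[cfg$n_planted_up + seq_len(cfg$n_planted_dn)]
  planted <- c(planted_up, planted_dn)

  ## --- miRNA counts -------------------------------------------------------
  lib <- exp(stats::runif(n_samp, log(cfg$lib_size_range[1]),
                          log(cfg$lib_size_range[2])))
  lib <- round(lib)
  lo <- cfg$baseline_cpm_range[1]
  hi <- cfg$baseline_cpm_range[2]
  base_cpm <- exp(stats::runif(cfg$n_mirna, log(lo), log(hi)))
  # planted DE miRNAs emulate the abundant deregulated set (the selection
  # rule requires mean CPM > 100 even after a 4-fold drop in 10/28 samples)
  base_cpm[mirnas %in% planted] <-
    exp(stats::runif(length(planted), log(max(400, lo)), log(hi)))
  names(base_cpm) <- mirnas
  shift <- stats::setNames(rep(0, cfg$n_mirna), mirnas)
  shift[planted_up] <- cfg$planted_log2fc
  shift[planted_dn] <- -cfg$planted_log2fc
  mu <- outer(base_cpm, lib / 1e6) * 2^outer(shift, as.numeric(is_atc))
  counts <- matrix(0, cfg$n_mirna, n_samp,
                   dimnames = list(mirnas, samples))
  if (cfg$nb_dispersion > 0) {
    counts[] <- stats::rnbinom(length(mu), mu = mu,
                               size = 1 / cfg$nb_dispersion)
  } else {
    counts[] <- stats::rpois(length(mu), mu)
  }
  mirna_counts <- count_matrix(counts, groups)

  ## --- target assignment and gene labels ---------------------------------
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  tpm <- cfg$targets_per_planted_mirna
  n_need <- (cfg$n_planted_up + cfg$n_planted_dn) * tpm
  pool <- sample(genes, n_need)
  tgt <- split(pool, rep(seq_along(planted), each = tpm))
  names(tgt) <- planted
  prime_onco <- if (length(planted_dn)) tgt[[planted_dn[1]]][1] else NA
  prime_supp <- if (length(planted_up)) tgt[[planted_up[1]]][1] else NA
  # shared prime targets: up to 4 DN-miRNAs hit the prime oncogene,
  # up to 2 UP-miRNAs the prime suppressor (replacing one own target)
  onco_mirnas <- utils::head(planted_dn, 4)
  supp_mirnas <- utils::head(planted_up, 2)
  for (m in onco_mirnas[-1]) tgt[[m]][1] <- prime_onco
  for (m in supp_mirnas[-1]) tgt[[m]][1] <- prime_supp
  edges <- do.call(rbind, lapply(planted, function(m) {
    data.frame(mirna = m, gene = unique(tgt[[m]]),
               stringsAsFactors = FALSE)
  }))
  onco_genes <- unique(unlist(tgt[planted_dn], use.names = FALSE))
  supp_genes <- unique(unlist(tgt[planted_up], use.names = FALSE))
  gene_labels <- rbind(
    data.frame(gene = onco_genes, label = "oncogene",
               stringsAsFactors = FALSE),
    data.frame(gene = supp_genes, label = "suppressor",
               stringsAsFactors = FALSE))

  ## --- mRNA FPKM (cohort) -------------------------------------------------
  base_fpkm <- stats::setNames(
    exp(stats::runif(cfg$n_genes, log(1), log(100))), genes)
  # designated prime genes are well expressed (their planted shift must not
  # be flattened by the log2(FPKM + 1) transform of the mRNA DE step)
  prime_ids <- c(prime_onco, prime_supp)
  prime_ids <- prime_ids[!is.na(prime_ids)]
  base_fpkm[prime_ids] <- exp(stats::runif(length(prime_ids),
                                           log(30), log(100)))
  gshift <- stats::setNames(rep(0, cfg$n_genes), genes)
  gshift[onco_genes] <- cfg$target_inverse_log2fc
  gshift[supp_genes] <- -cfg$target_inverse_log2fc
  if (!is.na(prime_onco)) gshift[prime_onco] <- 1.5 * cfg$target_inverse_log2fc
  if (!is.na(prime_supp)) gshift[prime_supp] <- -1.5 * cfg$target_inverse_log2fc
  noise <- matrix(stats::rnorm(cfg$n_genes * n_samp, 0, 0.5),
                  cfg$n_genes, n_samp)
  mrna_fpkm <- base_fpkm * 2^(outer(gshift, as.numeric(is_atc)) + noise)
  dimnames(mrna_fpkm) <- list(genes, samples)

  ## --- transcript annotation and interactions -----------------------------
  ann <- .synth_annotation(genes)
  interactions <- .synth_interactions(cfg, mirnas, planted, tgt, ann)

  ## --- essentiality -------------------------------------------------------
  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  center <- stats::setNames(rep(0, cfg$n_genes), genes)
  center[onco_genes] <- cfg$ess_onco_mean
  center[supp_genes] <- cfg$ess_ts_mean
  if (!is.na(prime_onco)) center[prime_onco] <- cfg$ess_onco_mean - 0.5
  if (!is.na(prime_supp)) center[prime_supp] <- cfg$ess_ts_mean + 0.3
  ess <- matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_lines,
                             mean = center, sd = 0.2),
                cfg$n_genes, cfg$n_cell_lines,
                dimnames = list(genes, lines))
  # sprinkle missing screen values on non-planted genes (missing policy)
  bg <- setdiff(genes, c(onco_genes, supp_genes))
  na_idx <- cbind(match(sample(bg, ceiling(0.05 * length(bg))), genes),
                  sample(cfg$n_cell_lines, ceiling(0.05 * length(bg)),
                         replace = TRUE))
  ess[na_idx] <- NA

  ## --- survival cohort ----------------------------------------------------
  surv <- .synth_survival(cfg, genes, base_fpkm, onco_genes, supp_genes,
                          prime_onco, prime_supp)

  truth <- list(
    planted_mirnas = data.frame(
      mirna = planted,
      direction = rep(c("UP", "DN"), c(cfg$n_planted_up, cfg$n_planted_dn)),
      stringsAsFactors = FALSE),
    edges = edges,
    gene_labels = gene_labels,
    prime_oncogene = prime_onco,
    prime_suppressor = prime_supp)

  structure(list(mirna_counts = mirna_counts, mrna_fpkm = mrna_fpkm,
                 interactions = interactions,
                 annotation = annotation_from_granges(ann),
                 annotation_gr = ann,
                 essentiality = ess, survival = surv, truth = truth,
                 config = cfg),
            class = "synthetic_dataset")
}

# one locus per gene on a cycle of 4 chromosomes; ~half the genes get a
# second transcript whose 3'-UTR extends past the first (meta-UTR merging),
# and ~a quarter get a spliced UTR (two blocks -> junction-spanning sites)
.synth_annotation <- function(genes) {
  n <- length(genes)
  chrom <- paste0("chr", (seq_len(n) - 1) %% 4 + 1)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- 10000 * seq_len(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w1 <- sample(100:400, 1)
    spliced <- stats::runif(1) < 0.25
    second_tx <- stats::runif(1) < 0.5
    tx1 <- sprintf("%s.t1", genes[i])
    blocks <- if (spliced) {
      gap <- sample(50:200, 1)
      w2 <- sample(50:200, 1)
      data.frame(start = c(start[i], start[i] + w1 + gap),
                 end = c(start[i] + w1 - 1, start[i] + w1 + gap + w2 - 1))
    } else {
      data.frame(start = start[i], end = start[i] + w1 - 1)
    }
    df <- data.frame(chrom = chrom[i], start = blocks$start,
                     end = blocks$end, strand = strand[i],
                     type = "three_prime_utr", gene_id = genes[i],
                     transcript_id = tx1, stringsAsFactors = FALSE)
    if (second_tx) {
      ext <- sample(50:150, 1)
      df2 <- df[nrow(df), , drop = FALSE]
      df2$end <- df2$end + ext
      df2$transcript_id <- sprintf("%s.t2", genes[i])
      if (nrow(df) > 1) {
        df2 <- rbind(df[1, , drop = FALSE], df2)
        df2$transcript_id <- sprintf("%s.t2", genes[i])
      }
      df <- rbind(df, df2)
    }
    rows[[i]] <- df
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$source <- "miris_sim"
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tab$transcript_id
  gr
}

# true edges: binding probability 1, both predictor flags set, a 7-nt site
# inside transcript t1's UTR; decoys: uniform over non-planted pairs
# (any miRNA x non-planted-target gene, so a decoy is a spurious prediction
# for a gene without a planted deregulation and the planted edges dominate
# every evidence component) with probability in [0.95, 1], Bernoulli(0.5)
# flags
.synth_interactions <- function(cfg, mirnas, planted, tgt, ann) {
  md <- S4Vectors::mcols(ann)
  utr_len <- tapply(GenomicRanges::width(ann), md$transcript_id, sum)
  t1_of <- function(g) sprintf("%s.t1", g)
  site_in <- function(tx) {
    len <- utr_len[[tx]]
    s <- sample(seq_len(max(1, len - 6)), 1)
    c(s, min(s + 6, len))
  }
  true_rows <- do.call(rbind, lapply(planted, function(m) {
    do.call(rbind, lapply(unique(tgt[[m]]), function(g) {
      tx <- t1_of(g)
      se <- site_in(tx)
      data.frame(mirna = m, gene = g, transcript = tx,
                 site_start = se[1], site_end = se[2],
                 binding_probability = 1, flag_ts = 1, flag_mirdb = 1,
                 region = "3UTR", stringsAsFactors = FALSE)
    }))
  }))
  true_key <- paste(true_rows$mirna, true_rows$gene)
  genes <- unique(md$gene_id)
  decoy_genes <- setdiff(genes, unique(true_rows$gene))
  if (!length(decoy_genes)) decoy_genes <- genes
  n_dec <- cfg$decoy_interactions
  dm <- sample(mirnas, 2 * n_dec, replace = TRUE)
  dg <- sample(decoy_genes, 2 * n_dec, replace = TRUE)
  keep <- !(paste(dm, dg) %in% true_key) &
    !duplicated(paste(dm, dg))
  dm <- dm[keep][seq_len(min(n_dec, sum(keep)))]
  dg <- dg[keep][seq_len(min(n_dec, sum(keep)))]
  dec_site <- t(vapply(t1_of(dg), site_in, numeric(2)))
  decoys <- data.frame(
    mirna = dm, gene = dg, transcript = t1_of(dg),
    site_start = dec_site[, 1], site_end = dec_site[, 2],
    binding_probability = stats::runif(length(dm), 0.95, 1),
    flag_ts = stats::rbinom(length(dm), 1, 0.5),
    flag_mirdb = stats::rbinom(length(dm), 1, 0.5),
    region = "3UTR", stringsAsFactors = FALSE)
  out <- rbind(true_rows, decoys)
  rownames(out) <- NULL
  out
}

# survival: exponential times with baseline hazard 0.1; an oncogenic
# expression program (latent factor, loading sqrt(0.5)) raises the hazard,
# the suppressor program lowers it; independent exponential censoring
.synth_survival <- function(cfg, genes, base_fpkm, onco_genes, supp_genes,
                            prime_onco, prime_supp) {
  n <- cfg$n_surv_samples
  ids <- sprintf("T%03d", seq_len(n))
  u_onco <- stats::rnorm(n)
  u_supp <- stats::rnorm(n)
  load <- sqrt(0.5)
  z <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
              dimnames = list(genes, ids))
  z[onco_genes, ] <- load * rep(u_onco, each = length(onco_genes)) +
    sqrt(1 - load^2) * z[onco_genes, ]
  z[supp_genes, ] <- load * rep(u_supp, each = length(supp_genes)) +
    sqrt(1 - load^2) * z[supp_genes, ]
  if (!is.na(prime_onco))
    z[prime_onco, ] <- 0.9 * u_onco + sqrt(1 - 0.81) * stats::rnorm(n)
  if (!is.na(prime_supp))
    z[prime_supp, ] <- 0.9 * u_supp + sqrt(1 - 0.81) * stats::rnorm(n)
  expr <- base_fpkm * 2^(0.75 * z)
  # a sliver of near-silent genes exercises the >= 1 total-FPKM filter
  silent <- utils::tail(setdiff(genes, c(onco_genes, supp_genes)),
                        ceiling(0.03 * cfg$n_genes))
  expr[silent, ] <- expr[silent, ] * 1e-4
  h0 <- 0.1
  hazard <- h0 * exp(cfg$surv_beta * u_onco - cfg$surv_beta * u_supp)
  t_event <- stats::rexp(n, rate = hazard)
  if (cfg$censor_rate > 0 && cfg$censor_rate < 1) {
    c_rate <- h0 * cfg$censor_rate / (1 - cfg$censor_rate)
    t_cens <- stats::rexp(n, rate = c_rate)
  } else if (cfg$censor_rate == 0) {
    t_cens <- rep(Inf, n)
  } else {
    t_cens <- rep(0, n)
  }
  event <- as.integer(t_event <= t_cens)
  time <- pmin(t_event, t_cens)
  time <- pmax(time, 1e-6)
  list(clinical = data.frame(sample = ids, time = time, event = event,
                             stringsAsFactors = FALSE),
       expr = expr)
}
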