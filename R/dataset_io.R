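#' Write a synthetic dataset to a directory of plain-text files
#'
#' Serializes every pipeline input: count/FPKM/clinical tables as TSV, the
#' interaction catalog as CSV, the transcript annotation as GTF, and the
#' truth ledger as TSV. Reading the directory back with [read_dataset()]
#' reproduces the dataset (numeric values round-trip at full precision).
#'
#' @param ds a `synthetic_dataset` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return manifest `data.frame` with `file` and `rows` per written file.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create directory: ", dir)
  fw <- function(df, file, sep) {
    data.table::fwrite(df, file.path(dir, file), sep = sep)
    data.frame(file = file, rows = nrow(df), stringsAsFactors = FALSE)
  }
  mat_df <- function(m, id) {
    cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                          id),
          as.data.frame(m))
  }
  manifest <- rbind(
    fw(mat_df(ds$mirna_counts$counts, "mirna"), "mirna_counts.tsv", "\t"),
    fw(data.frame(sample = names(ds$mirna_counts$groups),
                  group = unname(ds$mirna_counts$groups)),
       "sample_groups.tsv", "\t"),
    fw(mat_df(ds$mrna_fpkm, "gene"), "mrna_fpkm.tsv", "\t"),
    fw(ds$interactions, "interactions.csv", ","),
    fw(mat_df(ds$essentiality, "gene"), "essentiality.csv", ","),
    fw(ds$survival$clinical, "survival_clinical.tsv", "\t"),
    fw(mat_df(ds$survival$expr, "gene"), "survival_fpkm.tsv", "\t"),
    fw(ds$truth$planted_mirnas, "truth_mirnas.tsv", "\t"),
    fw(ds$truth$edges, "truth_edges.tsv", "\t"),
    fw(ds$truth$gene_labels, "truth_gene_labels.tsv", "\t"))
  rtracklayer::export(ds$annotation_gr, file.path(dir, "annotation.gtf"),
                      format = "gtf")
  manifest <- rbind(manifest,
                    data.frame(file = "annotation.gtf",
                               rows = length(ds$annotation_gr)))
  rownames(manifest) <- NULL
  manifest
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing the files written by [write_dataset()].
#' @return a `synthetic_dataset` (without the generator config).
#' @export
read_dataset <- function(dir) {
  fr <- function(file, sep) {
    data.table::fread(file.path(dir, file), sep = sep, header = TRUE,
                      data.table = FALSE)
  }
  df_mat <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
  grp <- fr("sample_groups.tsv", "\t")
  group_map <- stats::setNames(grp$group, grp$sample)
  mirna_counts <- read_count_matrix(file.path(dir, "mirna_counts.tsv"),
                                    group_map)
  ess_df <- fr("essentiality.csv", ",")
  gr <- rtracklayer::import(file.path(dir, "annotation.gtf"), format = "gtf")
  structure(list(
    mirna_counts = mirna_counts,
    mrna_fpkm = df_mat(fr("mrna_fpkm.tsv", "\t")),
    interactions = read_interaction_table(file.path(dir, "interactions.csv")),
    annotation = annotation_from_granges(gr),
    annotation_gr = gr,
    essentiality = df_mat(ess_df),
    survival = list(clinical = fr("survival_clinical.tsv", "\t"),
                    expr = df_mat(fr("survival_fpkm.tsv", "\t"))),
    truth = list(planted_mirnas = fr("truth_mirnas.tsv", "\t"),
                 edges = fr("truth_edges.tsv", "\t"),
                 gene_labels = fr("truth_gene_labels.tsv", "\t"),
                 prime_oncogene = NA, prime_suppressor = NA),
    config = NULL), class = "synthetic_dataset")
}

#' Run the integrated scoring pipeline on a dataset
#'
#' Executes the full analysis: TMM/CPM and differential miRNA expression,
#' DE-miRNA selection (FDR < 0.01, mean CPM > 100), mRNA differential
#' expression, essentiality averaging, survival screening, interaction
#' scoring (IS), prime-target selection, OncoScore and signature
#' extraction, IS-positive target enrichment, and unsupervised summaries.
#'
#' @param ds a `synthetic_dataset` (generated or read from disk).
#' @param gene_sets optional named list of gene sets for enrichment.
#' @param out_dir optional directory; when given, result tables are written
#'   as TSV (deterministically formatted).
#' @param gsea_seed seed for the enrichment permutations.
#' @param n_perm permutations for enrichment (default 1000).
#' @return list with `de`, `de_selected`, `mrna_de`, `es_mean`, `survival`,
#'   `scored`, `prime`, `onco`, `signature`, `gsea_dn`, `gsea_up`, `pca`,
#'   `clusters`.
#' @export
run_pipeline <- function(ds, gene_sets = NULL, out_dir = NULL,
                         gsea_seed = 1, n_perm = 1000) {
  cm <- ds$mirna_counts
  f <- tmm_factors(cm)
  cpm_lin <- cpm(cm, f, log = FALSE)
  de <- run_de_contrast(cm)
  sel <- select_de_features(de, cpm_lin)
  mrna_de <- mrna_de_table(ds$mrna_fpkm, cm$groups)
  es_mean <- average_essentiality(ds$essentiality)
  surv <- gene_survival_screen(ds$survival$expr, ds$survival$clinical)
  scored <- score_interactions(ds$interactions, sel, mrna_de,
                               es_mean = es_mean, hr = surv)
  prime <- select_prime_targets(scored)
  onco <- onco_score(prime)
  signature <- extract_signature(prime)
  rankings <- target_subset_rankings(scored, mrna_de)
  gsea_run <- function(rk, seed) {
    if (is.null(gene_sets) || !nrow(rk)) return(NULL)
    tryCatch(preranked_gsea(rk$gene, gene_sets, n_perm = n_perm,
                            seed = seed),
             error = function(e) NULL)
  }
  gsea_dn <- gsea_run(rankings$dn, gsea_seed)
  gsea_up <- gsea_run(rankings$up, gsea_seed + 1)
  lcpm <- cpm(cm, f, log = TRUE)
  de_lcpm <- lcpm[rownames(lcpm) %in% sel$feature, , drop = FALSE]
  pca <- if (nrow(de_lcpm) >= 2) pca_project(de_lcpm) else NULL
  clusters <- if (nrow(de_lcpm) >= 1 && ncol(de_lcpm) >= 2)
    hierarchical_cluster(row_scale_minmax(de_lcpm), k = 2) else NULL
  res <- list(de = de, de_selected = sel, mrna_de = mrna_de,
              es_mean = es_mean, survival = surv, scored = scored,
              prime = prime, onco = onco, signature = signature,
              gsea_dn = gsea_dn, gsea_up = gsea_up, pca = pca,
              clusters = clusters)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, file) {
    if (is.null(df)) return(invisible(NULL))
    data.table::fwrite(df, file.path(out_dir, file), sep = "\t")
  }
  wr(res$de, "mirna_de.tsv")
  wr(res$de_selected, "mirna_de_selected.tsv")
  wr(res$mrna_de, "mrna_de.tsv")
  wr(data.frame(gene = names(res$es_mean), es_mean = unname(res$es_mean)),
     "essentiality_mean.tsv")
  wr(res$survival, "survival_screen.tsv")
  wr(as.data.frame(res$scored), "scored_interactions.tsv")
  wr(as.data.frame(res$prime), "prime_targets.tsv")
  wr(res$onco, "onco_score.tsv")
  wr(res$signature, "signature.tsv")
  wr(res$gsea_dn, "gsea_dn_targets.tsv")
  wr(res$gsea_up, "gsea_up_targets.tsv")
  if (!is.null(res$pca))
    wr(data.frame(sample = rownames(res$pca$coords),
                  round(as.data.frame(res$pca$coords[, 1:2]), 10)),
       "pca_coords.tsv")
  if (!is.null(res$clusters))
    wr(data.frame(sample = names(res$clusters$clusters),
                  cluster = unname(res$clusters$clusters)),
       "cluster_labels.tsv")
  invisible(NULL)
}
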