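test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(censor_rate = 1.5), "censor_rate")
  expect_error(sim_config(n_mirna = 10, n_planted_up = 8, n_planted_dn = 8),
               "more planted")
  expect_error(sim_config(n_genes = 5), "exceed the gene universe")
  expect_error(sim_config(n_mirna = 0), "positive")
})

test_that("identical config and seed give identical datasets", {
  a <- generate_cohort(small_config(seed = 77))
  b <- generate_cohort(small_config(seed = 77))
  expect_identical(a$mirna_counts$counts, b$mirna_counts$counts)
  expect_identical(a$mrna_fpkm, b$mrna_fpkm)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$essentiality, b$essentiality)
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_config(seed = 78))
  expect_false(identical(a$mirna_counts$counts, c$mirna_counts$counts))
})

test_that("every planted edge appears in the interactions exactly once", {
  ds <- generate_cohort(small_config(seed = 81))
  key <- paste(ds$interactions$mirna, ds$interactions$gene)
  tkey <- paste(ds$truth$edges$mirna, ds$truth$edges$gene)
  expect_true(all(tkey %in% key))
  expect_true(all(table(key[key %in% tkey]) == 1))
  # planted edges carry maximal binding evidence
  planted <- ds$interactions[key %in% tkey, ]
  expect_true(all(planted$binding_probability == 1))
  expect_true(all(planted$flag_ts == 1 & planted$flag_mirdb == 1))
  # truth labels reference generated identifiers
  expect_true(all(ds$truth$gene_labels$gene %in% rownames(ds$mrna_fpkm)))
  expect_true(all(ds$truth$planted_mirnas$mirna %in%
                    rownames(ds$mirna_counts$counts)))
})

test_that("null construction: zero planted effect leaves groups exchangeable", {
  ds <- generate_cohort(small_config(seed = 82, planted_log2fc = 0,
                                     target_inverse_log2fc = 0))
  expect_equal(nrow(ds$truth$planted_mirnas), 12)  # ledger still filled
  de <- run_de_contrast(ds$mirna_counts)
  expect_lte(mean(de$fdr < 0.01), 0.02)
})

test_that("planted fold change is recovered empirically at the default scale", {
  ds <- generate_cohort(sim_config(seed = 1))
  cm <- ds$mirna_counts
  lin <- cpm(cm, tmm_factors(cm))
  atc <- cm$groups == "ATC"
  up <- ds$truth$planted_mirnas$mirna[ds$truth$planted_mirnas$direction ==
                                        "UP"]
  emp <- log2(rowMeans(lin[up, atc]) / rowMeans(lin[up, !atc]))
  expect_lt(abs(mean(emp) - 2.0), 0.3)
  dn <- ds$truth$planted_mirnas$mirna[ds$truth$planted_mirnas$direction ==
                                        "DN"]
  emp_dn <- log2(rowMeans(lin[dn, atc]) / rowMeans(lin[dn, !atc]))
  expect_lt(abs(mean(emp_dn) + 2.0), 0.3)
})

test_that("write_dataset/read_dataset round-trip and manifest row counts", {
  ds <- generate_cohort(small_config(seed = 83))
  dir <- file.path(tempdir(), "miris_rt")
  manifest <- write_dataset(ds, dir)
  # manifest covers every file; row counts match in-memory sizes
  expect_setequal(manifest$file,
                  c("mirna_counts.tsv", "sample_groups.tsv", "mrna_fpkm.tsv",
                    "interactions.csv", "essentiality.csv",
                    "survival_clinical.tsv", "survival_fpkm.tsv",
                    "truth_mirnas.tsv", "truth_edges.tsv",
                    "truth_gene_labels.tsv", "annotation.gtf"))
  expect_equal(manifest$rows[manifest$file == "mirna_counts.tsv"],
               nrow(ds$mirna_counts$counts))
  expect_equal(manifest$rows[manifest$file == "interactions.csv"],
               nrow(ds$interactions))
  expect_equal(manifest$rows[manifest$file == "annotation.gtf"],
               length(ds$annotation_gr))

  rt <- read_dataset(dir)
  expect_equal(rt$mirna_counts$counts, ds$mirna_counts$counts)
  expect_equal(rt$mirna_counts$groups, ds$mirna_counts$groups)
  expect_equal(rt$mrna_fpkm, ds$mrna_fpkm, tolerance = 1e-12)
  ints <- rt$interactions
  attr(ints, "dropped_non_utr3") <- NULL
  expect_equal(ints, ds$interactions, tolerance = 1e-12)
  expect_equal(rt$essentiality, ds$essentiality, tolerance = 1e-12)
  expect_equal(rt$survival$clinical, ds$survival$clinical,
               tolerance = 1e-12)
  expect_equal(rt$survival$expr, ds$survival$expr, tolerance = 1e-12)
  # annotation round-trips through GTF: same meta-UTRs
  g <- ds$truth$edges$gene[1]
  expect_equal(build_meta_utr(g, rt$annotation),
               build_meta_utr(g, ds$annotation))
})

test_that("an empty interaction list writes a header-only CSV", {
  ds <- generate_cohort(small_config(seed = 84))
  ds$interactions <- ds$interactions[0, ]
  dir <- file.path(tempdir(), "miris_empty")
  manifest <- write_dataset(ds, dir)
  expect_equal(manifest$rows[manifest$file == "interactions.csv"], 0)
  lines <- readLines(file.path(dir, "interactions.csv"))
  expect_equal(length(lines), 1)  # header only
  expect_equal(nrow(read_interaction_table(file.path(dir,
                                                     "interactions.csv"))), 0)
})
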