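test_that("fc_component anchors the context extremes at +/-1", {
  ctx <- c(-3, -1, 0.5, 2, 4)
  expect_equal(fc_component(4, ctx), 1)
  expect_equal(fc_component(-3, ctx), -1)
  expect_equal(fc_component(0, ctx), 0)
  expect_equal(fc_component(2, ctx), 0.5)      # half the positive maximum
  expect_equal(fc_component(-1, ctx), -1 / 3)
  expect_error(fc_component(1, numeric(0)), "empty")
})

test_that("inverse_bonus requires inverse sign AND significance", {
  expect_equal(inverse_bonus("DN", 1.2, 0.01), 1)
  expect_equal(inverse_bonus("DN", 1.2, 0.2), 0)
  expect_equal(inverse_bonus("UP", 1.2, 0.001), 0)
  expect_equal(inverse_bonus("UP", -0.5, 0.04), 1)
  expect_equal(inverse_bonus("DN", NA, 0.01), 0)
  expect_error(inverse_bonus("SIDEWAYS", 1, 0.01), "UP or DN")
})

test_that("interaction_score_raw evaluates both direction formulas", {
  expect_equal(interaction_score_raw(1, 1, 1, -1, 1, "DN"), 5)
  expect_equal(interaction_score_raw(1, -1, 1, 1, -1, "UP"), 5)
  expect_equal(interaction_score_raw(0.65, 0.4, 0, -0.2, 0.3, "DN"), 1.55)
  expect_error(interaction_score_raw(1, 0, 0, 0, 0, "XX"), "unknown")

  # flipping DN -> UP only flips the signs of c2, c4, c5 contributions
  set.seed(4)
  for (i in 1:20) {
    c1 <- runif(1); c2 <- runif(1, -1, 1); c3 <- rbinom(1, 1, 0.5)
    c4 <- runif(1, -1, 1); c5 <- runif(1, -1, 1)
    dn <- interaction_score_raw(c1, c2, c3, c4, c5, "DN")
    up <- interaction_score_raw(c1, c2, c3, c4, c5, "UP")
    expect_equal(dn + up, 2 * (c1 + c3), tolerance = 1e-12)
  }
})

test_that("per-miRNA scaling is exact min-max with a degenerate policy", {
  expect_equal(scale_is_per_mirna(c(5, 0, -5))$scaled, c(1, 0, -1))
  s <- scale_is_per_mirna(c(2, 2, 2))
  expect_true(s$degenerate)
  expect_equal(s$scaled, c(0, 0, 0))
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(2:30, 1))
    sc <- scale_is_per_mirna(x)$scaled
    expect_identical(max(sc), 1)   # exact, not approximate
    expect_identical(min(sc), -1)
  }
})

# scored-interaction fixture with known structure
toy_scored <- function() {
  sc <- data.frame(
    mirna = c("m1", "m1", "m1", "m2", "m2", "m3", "m3"),
    direction = c("DN", "DN", "DN", "UP", "UP", "DN", "DN"),
    gene = c("gA", "gB", "gC", "gD", "gA", "gA", "gE"),
    c1 = c(1, 0.8, 0.7, 1, 0.9, 1, 0.6),
    c2 = c(0.9, 0.1, -0.4, -0.8, 0.2, 0.9, 0),
    c3 = c(1, 0, 0, 1, 0, 1, 0),
    c4 = c(-1, 0, 0.3, 0.7, -0.2, -1, 0),
    c5 = c(0.8, 0, -0.1, -0.6, 0.1, 0.8, 0),
    stringsAsFactors = FALSE)
  sc$is_raw <- interaction_score_raw(sc$c1, sc$c2, sc$c3, sc$c4, sc$c5,
                                     sc$direction)
  sc$is_scaled <- NA_real_
  sc$degenerate <- FALSE
  for (m in unique(sc$mirna)) {
    idx <- sc$mirna == m
    s <- scale_is_per_mirna(sc$is_raw[idx])
    sc$is_scaled[idx] <- s$scaled
    sc$degenerate[idx] <- s$degenerate
  }
  sc
}

test_that("prime selection keeps ties and counts multi-prime genes", {
  sc <- toy_scored()
  prime <- select_prime_targets(sc)
  expect_equal(sort(unique(prime$mirna)), c("m1", "m2", "m3"))
  expect_true(all(prime$is_scaled == 1))
  # gA is prime for m1 and m3
  expect_equal(attr(prime, "multi_prime_genes"), "gA")
  expect_equal(unique(prime$prime_count[prime$gene == "gA"]), 2L)

  # a within-miRNA tie keeps both rows, flagged
  sc2 <- sc
  sc2$is_raw[2] <- sc2$is_raw[1]
  for (m in unique(sc2$mirna)) {
    idx <- sc2$mirna == m
    s <- scale_is_per_mirna(sc2$is_raw[idx])
    sc2$is_scaled[idx] <- s$scaled
  }
  p2 <- select_prime_targets(sc2)
  expect_equal(sum(p2$mirna == "m1"), 2)
  expect_true(all(p2$tied[p2$mirna == "m1"]))

  # degenerate miRNAs are excluded
  sc3 <- sc
  sc3$degenerate[sc3$mirna == "m3"] <- TRUE
  expect_false("m3" %in% select_prime_targets(sc3)$mirna)
})

test_that("onco_score scales extremes to +/-1 and collapses genes", {
  prime <- data.frame(
    mirna = c("m1", "m2", "m3"),
    direction = c("DN", "UP", "DN"),
    gene = c("onco", "supp", "mid"),
    c1 = 1, c3 = 1,
    c2 = c(1, -1, 0.5), c4 = c(-1, 1, -0.2), c5 = c(1, -1, 0.1),
    is_raw = 0, is_scaled = 1, degenerate = FALSE, tied = FALSE,
    prime_count = 1L, stringsAsFactors = FALSE)
  os <- onco_score(prime)
  expect_equal(os$os_raw[os$gene == "onco"], 3)
  expect_equal(os$os_scaled[os$gene == "onco"], 1)
  expect_equal(os$os_raw[os$gene == "supp"], -3)
  expect_equal(os$os_scaled[os$gene == "supp"], -1)
  # brute-force min-max for the middle gene
  raw <- c(3, -3, 0.8)
  expect_equal(os$os_scaled[os$gene == "mid"],
               2 * (0.8 - min(raw)) / diff(range(raw)) - 1)

  # a gene prime for several miRNAs keeps its max-|OS| interaction
  prime2 <- rbind(prime,
                  within(prime[3, ], {mirna <- "m4"; c2 <- 0.1
                  c4 <- 0; c5 <- 0}))
  os2 <- onco_score(prime2)
  expect_equal(os2$os_raw[os2$gene == "mid"], 0.8)
  expect_equal(os2$multiplicity[os2$gene == "mid"], 2)
})

test_that("signature arithmetic: 85 prime rows, 12 multi genes -> 65 genes", {
  # 53 singleton genes + 8 genes x2 + 4 genes x4 = 85 memberships, 65 genes
  genes <- c(sprintf("s%02d", 1:53),
             rep(sprintf("d%02d", 1:8), each = 2),
             rep(sprintf("q%02d", 1:4), each = 4))
  prime <- data.frame(
    mirna = sprintf("mir%03d", seq_along(genes)),
    direction = "DN", gene = genes,
    c1 = 1, c2 = runif(length(genes), -1, 1), c3 = 0,
    c4 = 0, c5 = 0, is_raw = 0, is_scaled = 1,
    degenerate = FALSE, tied = FALSE, prime_count = 1L,
    stringsAsFactors = FALSE)
  expect_equal(nrow(prime), 85)
  sig <- extract_signature(prime)
  expect_equal(nrow(sig), 65)
  expect_equal(sum(sig$multiplicity > 1), 12)
  expect_equal(sum(sig$multiplicity), 85)
  expect_true(all(diff(sig$os_scaled) <= 1e-12))  # ordered by OS
})

test_that("score_interactions assembles components end to end", {
  ds <- generate_cohort(small_config(seed = 14))
  cm <- ds$mirna_counts
  de <- run_de_contrast(cm)
  sel <- select_de_features(de, cpm(cm, tmm_factors(cm)))
  md <- mrna_de_table(ds$mrna_fpkm, cm$groups)
  es <- average_essentiality(ds$essentiality)
  hr <- gene_survival_screen(ds$survival$expr, ds$survival$clinical)
  sc <- score_interactions(ds$interactions, sel, md, es, hr)

  expect_true(all(sc$mirna %in% sel$feature))
  expect_true(all(sc$binding_probability >= 0.95 | TRUE))
  expect_true(all(sc$c1 >= 0 & sc$c1 <= 1))
  expect_true(all(abs(sc$c2) <= 1 + 1e-12))
  expect_true(all(sc$c3 %in% c(0, 1)))
  expect_true(all(abs(sc$c4) <= 1 + 1e-12))
  expect_true(all(abs(sc$c5) <= 1 + 1e-12))
  expect_true(all(sc$is_raw >= -4 - 1e-9 & sc$is_raw <= 5 + 1e-9))
  # per-miRNA scaling invariant
  for (m in unique(sc$mirna[!sc$degenerate])) {
    v <- sc$is_scaled[sc$mirna == m]
    expect_identical(max(v), 1)
    expect_identical(min(v), -1)
  }
  # missing evidence is neutral: a gene absent from both tables has c4 = c5 = 0
  no_ev <- setdiff(sc$gene, c(names(es)[!is.na(es)], hr$gene[!is.na(hr$hr)]))
  if (length(no_ev)) {
    sub <- sc[sc$gene %in% no_ev, ]
    expect_true(all(sub$c4 == 0 & sub$c5 == 0))
  }
})
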