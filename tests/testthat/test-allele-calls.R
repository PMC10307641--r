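# Fixture for the differential-engagement tests: a compact two-stage
# experiment with one gene planted to differ between modalities (RNA 50%
# paternal, ribosome occupancy 5%), planted on a gene that carries CDS
# SNPs. Error-free: the planted contrast is the quantity under test, and
# the MII paternal-read filter would otherwise act on error reads.
engagement_sim <- function(seed = 61, rna_pct = 50, ribo_pct = 5,
                           n_genes = 25, reads = 25000) {
  mk_stages <- function(ov = NULL) list(
    stage_spec("MII", n_ribo = 2, n_rna = 2, reads_per_replicate = reads),
    stage_spec("8c", paternal_fraction = 47.7, n_ribo = 3, n_rna = 3,
               reads_per_replicate = reads, gene_overrides = ov))
  cfg0 <- sim_config(n_genes = n_genes, snp_rate = 3, seed = seed,
                     stages = mk_stages())
  tx <- simulate_transcriptome(cfg0)
  planted <- tx$snps |>
    dplyr::filter(region == "CDS") |>
    dplyr::count(gene_id) |>
    dplyr::filter(n >= 2) |>
    dplyr::pull(gene_id) |>
    head(1)
  ov <- tibble(gene_id = planted, paternal_fraction_rna = rna_pct,
               paternal_fraction_ribo = ribo_pct)
  cfg <- sim_config(n_genes = n_genes, snp_rate = 3, seed = seed,
                    stages = mk_stages(ov))
  sim <- simulate_experiment(cfg, transcriptome = tx, errors = FALSE)
  list(allele_counts = build_allele_counts(dedup_reads(sim$reads), tx$snps),
       planted = planted)
}

test_that("a planted ribo/RNA allelic difference is called; nulls are not", {
  es <- engagement_sim()
  res <- differential_allelic_engagement(es$allele_counts, "8c", B = 40,
                                         seed = 7)
  calls <- tidy(res)
  expect_true(calls$called[calls$gene_id == es$planted])
  expect_equal(sum(calls$called), 1)
  expect_lt(calls$p_value[calls$gene_id == es$planted], 1e-6)
  # direction: ribo paternal proportion below RNA
  expect_lt(calls$diff[calls$gene_id == es$planted], -0.3)
  expect_equal(glance(res)$n_called, 1)

  # determinism under a fixed seed
  res2 <- differential_allelic_engagement(es$allele_counts, "8c", B = 40,
                                          seed = 7)
  expect_identical(tidy(res), tidy(res2))
})

test_that("genes with paternal MII reads are never called", {
  es <- engagement_sim(seed = 62)
  ac <- es$allele_counts
  # contaminate the planted gene's MII data with paternal reads
  mii_extra <- make_allele_counts(es$planted,
                                  ac$snp_id[ac$gene_id == es$planted][1],
                                  "MII", "ribo", 1, maternal = 50, paternal = 5)
  res <- differential_allelic_engagement(dplyr::bind_rows(ac, mii_extra),
                                         "8c", B = 20, seed = 3)
  calls <- tidy(res)
  expect_false(any(calls$called[calls$gene_id == es$planted]))
  # without MII data the filter is skipped with a warning
  expect_warning(
    differential_allelic_engagement(dplyr::filter(ac, stage != "MII"),
                                    "8c", B = 5, seed = 1),
    "MII")
})

test_that("differential engagement controls false positives on all-null data", {
  # no planted effects: both modalities share the stage's paternal fraction
  cfg <- sim_config(
    n_genes = 500, snp_rate = 3, seed = 71,
    stages = list(
      stage_spec("MII", n_ribo = 2, n_rna = 2, reads_per_replicate = 60000),
      stage_spec("4c", paternal_fraction = 30, n_ribo = 3, n_rna = 3,
                 reads_per_replicate = 60000)))
  sim <- simulate_experiment(cfg)
  ac <- build_allele_counts(dedup_reads(sim$reads), sim$transcriptome$snps)
  res <- differential_allelic_engagement(ac, "4c", B = 25, seed = 13)
  calls <- tidy(res)
  n_tested <- sum(calls$eligible)
  expect_gt(n_tested, 50) # the filters leave a real test set
  # empirical false-positive fraction stays below the nominal FDR
  expect_lte(sum(calls$called) / max(n_tested, 1), 0.2)
  # and in practice the bootstrap-support requirement keeps it near zero
  expect_lte(sum(calls$called), 2)
})

test_that("allelic bias classification recovers planted categories", {
  px <- plant_bias_experiment(fractions = c(95, 95, 95, 5, 5, 5, 100, 0),
                              seed = 81, n_genes = 30, reads = 60000)
  planted <- px$overrides$gene_id
  cl <- classify_allelic_bias(px$allele_counts, B = 1000, seed = 5)
  calls <- tidy(cl)
  got <- setNames(calls$category, calls$gene_id)
  expect_true(all(got[planted[1:3]] == "paternal_biased"))
  expect_true(all(got[planted[4:6]] == "maternal_biased"))
  # remaining well-covered genes at 50% are biallelic (<1% misclassification)
  null_genes <- dplyr::filter(calls,
                              !gene_id %in% planted,
                              paternal + maternal >= 100)
  expect_true(all(null_genes$category == "biallelic"))
  # monoallelic genes are flagged and inherit the biased direction
  expect_equal(got[[planted[7]]], "paternal_biased")
  expect_true(calls$monoallelic[calls$gene_id == planted[7]])
  expect_equal(got[[planted[8]]], "maternal_biased")
  expect_true(calls$monoallelic[calls$gene_id == planted[8]])
  # multi-SNP support flags strongly biased genes with >= 2 SNPs
  hc <- dplyr::filter(calls, gene_id %in% planted[1:6], n_snps >= 2)
  expect_true(all(hc$high_confidence))
  expect_equal(glance(cl)$n_monoallelic, sum(calls$monoallelic))
})

test_that("maternal-only counts give a monoallelic maternal call", {
  ac <- dplyr::bind_rows(
    make_allele_counts("g1", "s1", "4c", "rna", 1, maternal = 30, paternal = 0),
    make_allele_counts("g1", "s1", "4c", "rna", 2, maternal = 25, paternal = 0))
  cl <- classify_allelic_bias(ac, B = 200, seed = 2)
  expect_equal(tidy(cl)$category, "maternal_biased")
  expect_true(tidy(cl)$monoallelic)
  expect_error(classify_allelic_bias(ac, min_reads = 100), "No genes pass")
})

test_that("TE group comparison reports Wilcoxon p and median fold change", {
  set.seed(11)
  te <- tibble(gene_id = sprintf("g%03d", 1:40), te = rlnorm(40))
  same <- compare_te_groups(te, te$gene_id[1:20], te$gene_id[1:20])
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)

  # scaling group A by 0.5 halves the fold change
  te2 <- dplyr::bind_rows(
    tibble(gene_id = sprintf("a%03d", 1:200), te = 0.5 * rlnorm(200)),
    tibble(gene_id = sprintf("b%03d", 1:200), te = rlnorm(200)))
  half <- compare_te_groups(te2, sprintf("a%03d", 1:200), sprintf("b%03d", 1:200))
  expect_equal(half$fold_change, 0.5, tolerance = 0.35)
  expect_lt(half$p_value, 0.01)
  expect_error(compare_te_groups(te, character(0), te$gene_id), "nonempty|defined")
})

test_that("planted 0.55x efficiency on biased genes is detected", {
  biased <- sprintf("g%03d", 1:200)
  biallelic <- sprintf("g%03d", 201:2200)
  set.seed(21)
  base <- rlnorm(2200, 0, 0.5)
  te <- tibble(gene_id = c(biased, biallelic),
               te = base * c(rep(0.55, 200), rep(1, 2000)))
  res <- compare_te_groups(te, biased, biallelic)
  expect_equal(res$fold_change, 0.55, tolerance = 0.1)
  expect_lt(res$p_value, 1e-10)
})

test_that("biallelic control matching balances the covariates", {
  set.seed(31)
  covars <- tibble(gene_id = sprintf("g%04d", 1:600),
                   rna_abundance = rlnorm(600, 3, 1),
                   cds_len = round(rlnorm(600, 6.5, 0.5)))
  biased <- covars$gene_id[1:60]
  pool <- covars$gene_id[61:600]
  m <- match_biallelic_controls(biased, pool, covars, seed = 4)
  expect_equal(nrow(m$matches), 60)
  expect_equal(anyDuplicated(m$matches$control_gene), 0)
  expect_true(all(m$balance$ks_distance < 0.25))
  # deterministic given the seed
  m2 <- match_biallelic_controls(biased, pool, covars, seed = 4)
  expect_identical(m$matches, m2$matches)
  # a twin pool: every gene finds its duplicated covariate partner
  twins <- dplyr::mutate(covars[1:60, ], gene_id = paste0(gene_id, "_twin"))
  mt <- match_biallelic_controls(biased, twins$gene_id,
                                 dplyr::bind_rows(covars[1:60, ], twins),
                                 seed = 1)
  expect_equal(sort(paste0(mt$matches$biased_gene, "_twin")),
               sort(mt$matches$control_gene))
  expect_true(all(mt$matches$distance < 1e-12))
  expect_error(match_biallelic_controls(biased, pool[1:10], covars),
               "at least as many")
})
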