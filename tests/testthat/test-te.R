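test_that("clr normalization matches its closed form and handles zeros", {
  expect_equal(clr_normalize(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(clr_normalize(c(1, exp(1), exp(2))), c(-1, 0, 1))
  # zeros are excluded from the geometric mean and stay undefined
  z <- clr_normalize(c(5, 0, 5))
  expect_equal(z, c(0, NA, 0))
  expect_error(clr_normalize(c(0, 0)), "All values are zero")
  expect_error(clr_normalize(c(-1, 2)), "negative")

  # sum-zero over included genes; invariance to global scaling
  set.seed(1)
  x <- rlnorm(200)
  x[sample(200, 20)] <- 0
  cx <- clr_normalize(x)
  expect_equal(sum(cx, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(clr_normalize(7.3 * x), cx, tolerance = 1e-12)
})

test_that("CDS density scales counts by CDS length", {
  expect_equal(cds_density(100, 1000), 0.1)
  expect_equal(cds_density(c(10, 10), c(300, 600)),
               c(10 / 300, 10 / 600))
  expect_error(cds_density(5, 0), "positive")
})

test_that("translation efficiency is exp(clr difference) with per-modality means", {
  ann <- tibble(gene_id = c("a", "b", "c"), cds_len = c(300L, 600L, 900L))
  mk_counts <- function(modality, rep, counts) {
    tibble(gene_id = c("a", "b", "c"),
           sample_id = paste0("S_", modality, rep), stage = "GV",
           replicate = rep, modality = modality, count = counts)
  }
  # identical ribo and RNA profiles: te = 1 everywhere
  counts <- dplyr::bind_rows(
    mk_counts("ribo", 1L, c(10L, 40L, 90L)), mk_counts("ribo", 2L, c(12L, 44L, 80L)),
    mk_counts("rna", 1L, c(10L, 40L, 90L)), mk_counts("rna", 2L, c(12L, 44L, 80L)))
  te <- compute_te(counts, counts, ann)
  expect_equal(te$te, rep(1, 3))
  expect_equal(te$te, exp(te$te_log))

  # single replicate: the mean is that replicate
  one <- dplyr::bind_rows(mk_counts("ribo", 1L, c(30L, 60L, 90L)),
                          mk_counts("rna", 1L, c(10L, 40L, 90L)))
  te1 <- compute_te(one, one, ann)
  dens_r <- c(30, 60, 90) / c(300, 600, 900)
  dens_n <- c(10, 40, 90) / c(300, 600, 900)
  expect_equal(te1$te_log,
               clr_normalize(dens_r) - clr_normalize(dens_n))

  # a gene with zero counts in every replicate of one modality is NA
  zero <- dplyr::bind_rows(mk_counts("ribo", 1L, c(0L, 60L, 90L)),
                           mk_counts("ribo", 2L, c(0L, 50L, 80L)),
                           mk_counts("rna", 1L, c(10L, 40L, 90L)),
                           mk_counts("rna", 2L, c(10L, 40L, 90L)))
  tez <- compute_te(zero, zero, ann)
  expect_true(is.na(tez$te[tez$gene_id == "a"]))
  expect_false(any(is.na(tez$te[tez$gene_id != "a"])))
})

test_that("planted TE multipliers are recovered within 10%", {
  planted2 <- tibble(gene_id = sprintf("gene%03d", 1:6), multiplier = 2)
  planted055 <- tibble(gene_id = sprintf("gene%03d", 7:12), multiplier = 0.55)
  cfg <- flat_geometry_config(
    n_genes = 40, snp_rate = 0, seed = 19,
    stages = list(stage_spec("GV", n_ribo = 5, n_rna = 5,
                             reads_per_replicate = 50000,
                             te_multipliers = dplyr::bind_rows(planted2, planted055))))
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_experiment(cfg)
  counts <- count_cds(dedup_reads(sim$reads), tx$genes,
                      offsets = cfg$asite_offsets)
  te <- compute_te(counts, counts, tx$genes)
  bg <- dplyr::filter(te, !gene_id %in% c(planted2$gene_id, planted055$gene_id))
  r2 <- median(dplyr::filter(te, gene_id %in% planted2$gene_id)$te) /
    median(bg$te)
  r055 <- median(dplyr::filter(te, gene_id %in% planted055$gene_id)$te) /
    median(bg$te)
  expect_equal(r2, 2, tolerance = 0.1)
  expect_equal(r055, 0.55, tolerance = 0.1)
})

test_that("bootstrap TE intervals are deterministic, degenerate-aware and calibrated", {
  ann <- tibble(gene_id = c("a", "b"), cds_len = c(300L, 300L))
  mk <- function(modality, rep, counts) {
    tibble(gene_id = c("a", "b"), sample_id = paste0(modality, rep),
           stage = "GV", replicate = rep, modality = modality, count = counts)
  }
  # identical replicates: zero-width interval
  same <- dplyr::bind_rows(mk("ribo", 1L, c(20L, 40L)), mk("ribo", 2L, c(20L, 40L)),
                           mk("rna", 1L, c(30L, 30L)), mk("rna", 2L, c(30L, 30L)))
  ci <- bootstrap_te_ci(same, same, ann, B = 50, seed = 9)
  expect_equal(ci$te_log_lo, ci$te_log_hi)
  expect_error(bootstrap_te_ci(same, same, ann, B = 0), "at least 1")
  # seeded determinism
  expect_identical(ci, bootstrap_te_ci(same, same, ann, B = 50, seed = 9))

  # coverage under a null simulation: with identical geometry and no
  # planted effect the true te_log is 0; nominal 95% intervals should
  # cover it in at least ~90% of gene-level draws. Eight replicates per
  # modality: percentile intervals are asymptotic in the number of
  # replicates and undercover noticeably below that
  cfg <- flat_geometry_config(
    n_genes = 15, snp_rate = 0, seed = 23,
    stages = list(stage_spec("GV", n_ribo = 8, n_rna = 8,
                             reads_per_replicate = 20000)))
  covered <- unlist(lapply(1:8, function(i) {
    cfg$seed <- 23L + i
    sim <- simulate_experiment(cfg)
    counts <- count_cds(dedup_reads(sim$reads), sim$transcriptome$genes,
                        offsets = cfg$asite_offsets)
    ci <- bootstrap_te_ci(counts, counts, sim$transcriptome$genes,
                          B = 300, seed = i)
    ci$te_log_lo <= 0 & ci$te_log_hi >= 0
  }))
  expect_gte(mean(covered), 0.90)
})

test_that("poly(A) association bins equally and detects monotone structure", {
  d <- tibble(gene_id = sprintf("g%02d", 1:12),
              tail_length = 1:12, te = (1:12)^2)
  pa <- polya_te_association(d)
  expect_equal(pa$rho, 1)
  expect_equal(pa$bins$n, rep(2L, 6)) # n = 12 gives bins of 2
  expect_equal(nrow(pa$bins), 6)
  expect_error(polya_te_association(d[1:5, ]), "at least 6")

  # independent te and tail length: correlation near zero
  set.seed(77)
  null <- tibble(gene_id = sprintf("g%04d", 1:5000),
                 tail_length = runif(5000), te = rlnorm(5000))
  expect_lt(abs(polya_te_association(null)$rho), 0.05)
  expect_gt(polya_te_association(null)$p_value, 0.01)

  # glance/tidy accessors
  expect_equal(glance(pa)$rho, 1)
  expect_equal(nrow(tidy(pa)), 6)
})
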