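# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small enough for the whole suite to run in minutes.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# A compact single-stage configuration used by many tests.
tiny_config <- function(stage = "MII", paternal_fraction = 0, n_genes = 5,
                        reads = 5000, seed = 1, snp_rate = 3, ...) {
  sim_config(
    n_genes = n_genes, snp_rate = snp_rate, seed = seed,
    stages = list(stage_spec(stage, paternal_fraction = paternal_fraction,
                             n_ribo = 2, n_rna = 2,
                             reads_per_replicate = reads)),
    ...)
}

# Configuration with degenerate (identical) transcript geometry, so that
# planted effects are not confounded by per-gene length ratios.
flat_geometry_config <- function(...) {
  sim_config(utr5_range = c(90, 90), cds_range = c(600, 600),
             utr3_range = c(90, 90), ...)
}

# A dense-SNP transcriptome where essentially every read covers >= 1 SNP;
# used for allele-level simulations at scale.
dense_snp_config <- function(stages, seed = 1, snp_rate = 30, ...) {
  sim_config(n_genes = 4, snp_rate = snp_rate,
             utr5_range = c(60, 60), cds_range = c(300, 300),
             utr3_range = c(60, 60),
             stages = stages, seed = seed, ...)
}

# Hand-built read table rows (bypassing the generator) for boundary tests.
make_read <- function(gene_id, five_prime_pos, length, modality = "ribo",
                      sample_id = "S1", stage = "MII", replicate = 1L,
                      umi = "AAAAAAAAAAAA", snp_obs = "",
                      true_allele = "maternal", read_id = NULL) {
  tibble(read_id = read_id %||% paste0("r", five_prime_pos, "_", length, "_",
                                       sample(1e6, 1)),
         sample_id = sample_id, stage = stage, replicate = replicate,
         modality = modality, gene_id = gene_id,
         five_prime_pos = as.integer(five_prime_pos),
         length = as.integer(length), umi = umi,
         true_allele = true_allele, snp_obs = snp_obs)
}

`%||%` <- rlang::`%||%`

# One-gene annotation with a homopolymer body (uniform 3'-end context),
# explicit start/stop codons.
uniform_annotation <- function(utr5 = 30L, cds = 300L, utr3 = 60L) {
  seq <- strrep("A", utr5 + cds + utr3)
  substr(seq, utr5 + 1L, utr5 + 3L) <- "ATG"
  substr(seq, utr5 + cds - 2L, utr5 + cds) <- "TAA"
  tibble(gene_id = "g1", utr5_len = utr5, cds_len = cds, utr3_len = utr3,
         tx_len = utr5 + cds + utr3, expression_level = 1, sequence = seq)
}

# Allele count rows built directly.
make_allele_counts <- function(gene_id, snp_id, stage, modality, replicate,
                               maternal, paternal, other = 0L,
                               sample_id = NULL) {
  tibble(gene_id = gene_id, snp_id = snp_id,
         sample_id = sample_id %||%
           paste(stage, modality, paste0("rep", replicate), sep = "_"),
         stage = stage, replicate = as.integer(replicate),
         modality = modality,
         maternal_count = as.integer(maternal),
         paternal_count = as.integer(paternal),
         other_count = as.integer(other))
}

make_test_pwm <- function(name = "RBP1", seed = 1, width = 7) {
  set.seed(seed)
  m <- matrix(runif(width * 4), nrow = width,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm(name, m)
}

# PWM with one high-information position (4: T strongly preferred, G
# forbidden) over a moderate background; the T->G swap at position 4 is
# the largest allelic score change any SNP can produce against the
# whole library below.
planted_motif_pwm <- function() {
  set.seed(2)
  m <- matrix(runif(28), nrow = 7, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[4, ] <- c(1.5, 0.02, 0, 3)
  pwm("RBP1", m)
}

# A small motif library (as a PWM collection always is in practice):
# several diffuse random motifs plus the informative one. Across many
# motifs the null score differences form a quasi-continuous distribution
# centred near zero, which is what the robust standardization assumes.
planted_motif_library <- function(n_random = 9) {
  c(lapply(seq_len(n_random), function(i)
    make_test_pwm(paste0("BG", i), seed = 100 + i,
                  width = sample(6:8, 1))),
    list(planted_motif_pwm()))
}

# 1 planted consensus-destroying SNP among n_null well-separated null
# SNPs with random allele pairs that never form the extreme T/G swap of
# the informative position.
planted_motif_fixture <- function(n_null = 1000, seed = 3) {
  p <- planted_motif_pwm()
  set.seed(seed)
  mk_seq <- function() paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                             collapse = "")
  genes <- tibble(gene_id = sprintf("null%04d", seq_len(n_null)),
                  sequence = vapply(seq_len(n_null), function(i) mk_seq(),
                                    character(1)))
  seq_p <- mk_seq()
  substr(seq_p, 26, 32) <- p$consensus # 0-based positions 25..31
  genes <- dplyr::bind_rows(genes,
                            tibble(gene_id = "planted", sequence = seq_p))
  null_mat <- substr(genes$sequence[seq_len(n_null)], 31, 31)
  # random partner allele, excluding the maternal base and the T/G pair
  partner <- vapply(null_mat, function(b) {
    pool <- setdiff(c("A", "C", "G", "T"), b)
    if (b == "T") pool <- setdiff(pool, "G")
    if (b == "G") pool <- setdiff(pool, "T")
    sample(pool, 1)
  }, character(1), USE.NAMES = FALSE)
  snps <- dplyr::bind_rows(
    tibble(snp_id = paste0("s_", genes$gene_id[seq_len(n_null)]),
           gene_id = genes$gene_id[seq_len(n_null)], pos = 30L,
           maternal_allele = null_mat, paternal_allele = partner),
    tibble(snp_id = "s_planted", gene_id = "planted", pos = 28L,
           maternal_allele = "T", paternal_allele = "G"))
  list(genes = genes, snps = snps, pwms = planted_motif_library(),
       pwm = p)
}

# Reads covering exactly one CDS SNP each (the observation and the read
# coincide, so plain binomial error applies), with substitution errors
# injected; at least n_target such reads are produced.
mii_single_snp_reads <- function(modality, n_target, error_pct, seed,
                                 stage = "MII", paternal_fraction = 0) {
  stg <- list(stage_spec(stage, paternal_fraction = paternal_fraction,
                         n_ribo = 1, n_rna = 1, reads_per_replicate = 1000))
  cfg <- dense_snp_config(stg, seed = seed, snp_rate = 25)
  tx <- simulate_transcriptome(cfg)
  cds_snps <- tx$snps$snp_id[tx$snps$region == "CDS"]
  kept <- list()
  n_kept <- 0L
  chunk <- 1L
  while (n_kept < n_target && chunk <= 12L) {
    cfg_c <- cfg
    cfg_c$seed <- as.integer((seed + 7919 * chunk) %% 2147483647)
    r <- simulate_reads(tx, cfg_c, stage, modality, 1,
                        n_reads = ceiling(n_target * 2))
    k <- rep(0L, nrow(r))
    obs <- tibble(row = seq_len(nrow(r)), snp_obs = r$snp_obs) |>
      filter(snp_obs != "") |>
      tidyr::separate_rows(snp_obs, sep = ";") |>
      mutate(snp = sub(":[ACGT]$", "", snp_obs)) |>
      filter(snp %in% cds_snps) |>
      count(row)
    k[obs$row] <- obs$n
    r <- r[k == 1L, ]
    r$read_id <- paste0("c", chunk, "_", r$read_id)
    kept[[chunk]] <- r
    n_kept <- n_kept + nrow(r)
    chunk <- chunk + 1L
  }
  r <- head(bind_rows(kept), n_target)
  stopifnot(nrow(r) == n_target)
  r <- inject_errors(r, error_pct, seed = seed + 1)
  list(counts = build_allele_counts(r, tx$snps), n_reads = nrow(r))
}

# Transcriptome plus one embryonic RNA stage with allele-bias overrides
# planted on genes guaranteed to carry >= 2 CDS SNPs.
plant_bias_experiment <- function(fractions, seed, n_genes = 25,
                                  reads = 50000, n_rna = 4) {
  base_stage <- function(ov = NULL) {
    list(stage_spec("4c", paternal_fraction = 50, n_ribo = 2, n_rna = n_rna,
                    reads_per_replicate = reads, gene_overrides = ov))
  }
  cfg0 <- sim_config(n_genes = n_genes, snp_rate = 3, seed = seed,
                     stages = base_stage())
  tx <- simulate_transcriptome(cfg0)
  rich <- tx$snps |>
    filter(region == "CDS") |>
    count(gene_id) |>
    filter(n >= 2) |>
    pull(gene_id)
  stopifnot(length(rich) >= length(fractions))
  ov <- tibble(gene_id = head(rich, length(fractions)),
               paternal_fraction = fractions)
  cfg <- sim_config(n_genes = n_genes, snp_rate = 3, seed = seed,
                    stages = base_stage(ov))
  sim <- simulate_experiment(cfg, transcriptome = tx, errors = FALSE)
  ac <- build_allele_counts(dedup_reads(sim$reads), tx$snps) |>
    filter(modality == "rna")
  list(allele_counts = ac, overrides = ov)
}
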