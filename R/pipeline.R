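#' Assemble a pipeline run configuration
#'
#' Bundles either a simulation configuration or paths to existing input
#' tables, the analysis thresholds (all at their standard defaults), a
#' master seed and an output directory. The configuration hash stamped
#' into every output changes iff the configuration content changes.
#'
#' @param outdir Output directory.
#' @param simulation A [sim_config()] (simulation mode), or `NULL` when
#'   `reads_tsv`/`annotation_tsv`/`vcf` point at existing inputs.
#' @param reads_tsv,annotation_tsv,fasta,vcf Input paths (real-data mode).
#' @param protein_tsv Optional protein abundance TSV
#'   (`gene_id`, `stage`, `abundance`) for the integration stage.
#' @param polya_tsv Optional poly(A) tail length TSV
#'   (`gene_id`, `tail_length`).
#' @param pwm_tsv Optional PWM TSV for the variant stage.
#' @param engagement_stages Stages tested for differential allelic
#'   engagement.
#' @param classification_stages Stages classified for allelic bias (RNA).
#' @param thresholds Named list overriding analysis defaults
#'   (`min_total`, `min_allele`, `ci_guard`, `fdr`, `engagement_support`,
#'   `engagement_B`, `bias_threshold`, `bias_support`, `bias_B`,
#'   `min_reads`, `multi_snp_frac`, `te_B`, `percentile`, `min_snp_gap`).
#' @param seed Master seed.
#' @return A `run_config` object.
#' @export
run_config <- function(outdir, simulation = NULL, reads_tsv = NULL,
                       annotation_tsv = NULL, fasta = NULL, vcf = NULL,
                       protein_tsv = NULL, polya_tsv = NULL, pwm_tsv = NULL,
                       engagement_stages = c("8c"),
                       classification_stages = c("4c", "8c"),
                       thresholds = list(), seed = 1L) {
  defaults <- list(min_total = 10L, min_allele = 3L, ci_guard = 0.05,
                   fdr = 0.2, engagement_support = 0.66, engagement_B = 100L,
                   bias_threshold = 0.7, bias_support = 0.8, bias_B = 1000L,
                   min_reads = 10L, multi_snp_frac = 0.6, te_B = 1000L,
                   percentile = 95, min_snp_gap = 5L)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown threshold(s): %s", paste(unknown, collapse = ", ")))
  }
  th <- utils::modifyList(defaults, thresholds)
  if (th$bias_threshold <= 0.5 || th$bias_threshold >= 1) {
    abort("`bias_threshold` must lie in (0.5, 1).")
  }
  if (is.null(simulation)) {
    req <- list(reads_tsv = reads_tsv, annotation_tsv = annotation_tsv,
                vcf = vcf)
    bad <- names(req)[vapply(req, function(p) is.null(p) || !file.exists(p),
                             logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("Missing input file(s): %s (supply `simulation` or existing paths).",
                    paste(bad, collapse = ", ")))
    }
  }
  cfg <- structure(
    list(outdir = outdir, simulation = simulation, reads_tsv = reads_tsv,
         annotation_tsv = annotation_tsv, fasta = fasta, vcf = vcf,
         protein_tsv = protein_tsv, polya_tsv = polya_tsv, pwm_tsv = pwm_tsv,
         engagement_stages = engagement_stages,
         classification_stages = classification_stages,
         thresholds = th, seed = as.integer(seed)),
    class = "run_config")
  cfg
}

#' Stable content hash of a run configuration
#' @param config A [run_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  rlang::hash(x)
}

#' Load a run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; a `simulation`
#' block, when present, is passed to [sim_config()] (its `stages` entries
#' to [stage_spec()]).
#'
#' @param path YAML file.
#' @param outdir,seed Optional overrides of the file's values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    if (!is.null(s$stages)) {
      s$stages <- purrr::map(s$stages, ~ do.call(stage_spec, .x))
    }
    if (!is.null(s$footprint_len_probs)) {
      s$footprint_len_probs <- unlist(s$footprint_len_probs)
    }
    if (!is.null(s$asite_offsets)) s$asite_offsets <- unlist(s$asite_offsets)
    sim <- do.call(sim_config, s)
  }
  run_config(
    outdir = outdir %||% y$outdir %||% ".",
    simulation = sim,
    reads_tsv = y$reads_tsv, annotation_tsv = y$annotation_tsv,
    fasta = y$fasta, vcf = y$vcf, protein_tsv = y$protein_tsv,
    polya_tsv = y$polya_tsv, pwm_tsv = y$pwm_tsv,
    engagement_stages = y$engagement_stages %||% c("8c"),
    classification_stages = y$classification_stages %||% c("4c", "8c"),
    thresholds = y$thresholds %||% list(),
    seed = seed %||% y$seed %||% 1L)
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[riboallele] ", fmt), ...))

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (when a simulation configuration is
#' present) -> preprocess (length filter, deduplication, CDS and allele
#' counting) -> footprint QC (offset calibration, frame statistic, region
#' occupancy) -> translation efficiency (with bootstrap intervals) ->
#' allele-specific analysis (error rates, stage summary, differential
#' engagement, bias classification) -> integration (when a protein table
#' is supplied) -> variant effects (uORF scan; motif scoring when PWMs
#' are supplied). Read and gene tallies are logged after every filter.
#' Every TSV carries the package version, master seed and configuration
#' hash; a rerun with the same configuration reproduces the outputs
#' byte-identically.
#'
#' @param config A [run_config()].
#' @param stages Subset of pipeline stages to run (dependencies are
#'   computed in-memory regardless; this controls what is written).
#' @return Invisible list of all result objects.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "qc", "te",
                                    "allele", "integrate", "variants")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  stamp <- function(x, name) write_tsv_stamped(
    x, file.path(config$outdir, name), seed = seed, hash = hash)
  res <- list(config_hash = hash)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- simulate_experiment(config$simulation)
    if ("simulate" %in% stages) {
      write_simulation(sim, file.path(config$outdir, "simulated"), seed, hash)
    }
    reads <- sim$reads
    annotation <- sim$transcriptome$genes
    snps <- sim$transcriptome$snps
    log_stage("simulated %d reads over %d samples (%d genes, %d SNPs)",
              nrow(reads), nrow(sim$samples), nrow(annotation), nrow(snps))
  } else {
    reads <- read_reads_tsv(config$reads_tsv)
    annotation <- read_tsv_stamped(config$annotation_tsv)
    if (!is.null(config$fasta)) {
      fa <- read_fasta(config$fasta)
      annotation$sequence <- unname(fa[annotation$gene_id])
    }
    if (!"tx_len" %in% names(annotation)) {
      annotation$tx_len <- annotation$utr5_len + annotation$cds_len +
        annotation$utr3_len
    }
    snps <- read_snp_vcf(config$vcf, annotation = annotation)
    log_stage("loaded %d reads (%d genes, %d SNPs)",
              nrow(reads), nrow(annotation), nrow(snps))
  }
  res$annotation <- annotation
  res$snps <- snps

  # ---- preprocess ---------------------------------------------------------
  is_ribo <- reads$modality == "ribo"
  ribo <- filter_footprint_lengths(reads[is_ribo, ])
  log_stage("footprint length filter: %d -> %d reads", sum(is_ribo), nrow(ribo))
  reads <- bind_rows(ribo, reads[!is_ribo, ])
  n0 <- nrow(reads)
  reads <- dedup_reads(reads)
  log_stage("deduplication: %d -> %d reads", n0, nrow(reads))
  allele_counts <- build_allele_counts(reads, snps)
  res$allele_counts <- allele_counts
  if ("preprocess" %in% stages) stamp(allele_counts, "allele_counts.tsv")

  # ---- qc -----------------------------------------------------------------
  ribo_reads <- filter(reads, .data$modality == "ribo")
  profile <- stop_metagene(ribo_reads, annotation)
  offsets <- calibrate_asite_offsets(profile)
  res$offsets <- offsets
  counts <- count_cds(reads, annotation, offsets = offsets)
  res$counts <- counts
  if ("preprocess" %in% stages) stamp(counts, "cds_counts.tsv")
  if ("qc" %in% stages) {
    stamp(profile, "stop_metagene.tsv")
    stamp(tibble(length = as.integer(names(offsets)), offset = unname(offsets)),
          "asite_offsets.tsv")
    fs <- frame_statistic(ribo_reads, annotation)
    res$frame <- fs
    stamp(tibble(frame = 0:2, count = unname(fs$triplet),
                 statistic = fs$statistic, p_value = fs$p_value,
                 n_excluded = fs$n_excluded), "frame_statistic.tsv")
    rd <- region_distribution(ribo_reads, annotation, offsets = offsets)
    res$region_distribution <- rd
    stamp(rd, "region_distribution.tsv")
    occ <- ribo_reads |> count(.data$gene_id, name = "count")
    wrl <- weighted_region_lengths(occ, annotation)
    res$weighted_region_lengths <- wrl
    stamp(wrl, "weighted_region_lengths.tsv")
    log_stage("qc: frame p = %.3g, offsets for %d lengths",
              fs$p_value, length(offsets))
  }

  # ---- translation efficiency --------------------------------------------
  te <- compute_te(counts, counts, annotation)
  res$te <- te
  if ("te" %in% stages) {
    stamp(te, "translation_efficiency.tsv")
    ci <- bootstrap_te_ci(counts, counts, annotation,
                          B = config$thresholds$te_B,
                          seed = derive_seed(seed, "te_ci"))
    res$te_ci <- ci
    stamp(ci, "translation_efficiency_ci.tsv")
    if (!is.null(config$polya_tsv)) {
      polya <- read_tsv_stamped(config$polya_tsv)
      stage1 <- unique(te$stage)[1]
      pa <- polya |>
        inner_join(filter(te, .data$stage == stage1), by = "gene_id") |>
        polya_te_association()
      res$polya <- pa
      stamp(pa$bins, "polya_te_bins.tsv")
    }
    log_stage("te: %d gene-stage rows", nrow(te))
  }

  # ---- allele-specific ----------------------------------------------------
  if ("allele" %in% stages) {
    th <- config$thresholds
    errors <- c(
      ribo = estimate_error_rate(allele_counts, "ribo")$error_pct,
      rna = estimate_error_rate(allele_counts, "rna")$error_pct)
    res$error_estimates <- errors
    summary <- stage_paternal_summary(allele_counts, errors)
    res$stage_summary <- summary
    stamp(summary, "stage_paternal_summary.tsv")
    log_stage("allele: error ribo %.3f%%, rna %.3f%%", errors[["ribo"]],
              errors[["rna"]])
    res$engagement <- purrr::map(
      setNames(config$engagement_stages, config$engagement_stages),
      function(stg) {
        e <- differential_allelic_engagement(
          allele_counts, stg, error_estimates = errors,
          min_total = th$min_total, min_allele = th$min_allele,
          ci_guard = th$ci_guard, fdr = th$fdr,
          support_frac = th$engagement_support, B = th$engagement_B,
          seed = derive_seed(seed, "engagement", stg))
        stamp(e$calls, sprintf("allelic_engagement_%s.tsv", stg))
        log_stage("engagement %s: %d called", stg, sum(e$calls$called))
        e
      })
    res$bias <- purrr::map(
      setNames(config$classification_stages, config$classification_stages),
      function(stg) {
        d <- filter(allele_counts, .data$modality == "rna", .data$stage == stg)
        if (nrow(d) == 0) return(NULL)
        cl <- classify_allelic_bias(
          d, min_reads = th$min_reads, bias_threshold = th$bias_threshold,
          support_frac = th$bias_support, multi_snp_frac = th$multi_snp_frac,
          B = th$bias_B, seed = derive_seed(seed, "bias", stg))
        stamp(cl$calls, sprintf("allelic_bias_%s.tsv", stg))
        log_stage("bias %s: %d genes classified", stg, nrow(cl$calls))
        cl
      })
  }

  # ---- integration --------------------------------------------------------
  if ("integrate" %in% stages && !is.null(config$protein_tsv)) {
    protein <- read_tsv_stamped(config$protein_tsv)
    grid <- cross_stage_grid(te, protein)
    res$grid <- grid
    stamp(grid, "correlation_grid.tsv")
    log_stage("integration: %d grid cells", nrow(grid))
  }

  # ---- variant effects ----------------------------------------------------
  if ("variants" %in% stages) {
    if (!"sequence" %in% names(annotation)) {
      log_stage("variants: no sequences available, skipped")
    } else {
      uorf <- find_uorf_candidates(snps, annotation)
      res$uorf <- uorf
      stamp(uorf, "uorf_candidates.tsv")
      log_stage("variants: %d uORF candidate(s)", nrow(uorf))
      if (!is.null(config$pwm_tsv)) {
        pwms <- read_pwm_tsv(config$pwm_tsv)
        eff <- tryCatch(
          score_snp_motif_effects(
            snps, annotation, pwms,
            percentile = config$thresholds$percentile,
            min_snp_gap = config$thresholds$min_snp_gap),
          error = function(e) {
            log_stage("variants: motif scoring skipped (%s)", conditionMessage(e))
            NULL
          })
        if (!is.null(eff)) {
          res$motif_effects <- eff
          stamp(eff, "snp_motif_effects.tsv")
          log_stage("variants: %d motif effect row(s), %d selected",
                    nrow(eff), sum(eff$selected))
        }
      }
    }
  }
  invisible(res)
}
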