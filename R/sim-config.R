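#' Describe one developmental stage for the simulator
#'
#' A stage specification fixes, for one developmental stage (oocyte or
#' cleavage-stage embryo), the number of replicate libraries per modality,
#' the fraction of transcripts that are paternally derived before any
#' sequencing error, and optional per-gene overrides used to plant
#' allele-biased genes or translation-efficiency effects.
#'
#' Oocyte stages (GV, MII) must be purely maternal: the embryo inherits its
#' transcript pool from the mother and paternal transcripts only appear
#' after zygotic genome activation.
#'
#' @param stage Stage label, e.g. `"GV"`, `"MII"`, `"1c"`, `"2c"`, `"4c"`, `"8c"`.
#' @param n_ribo,n_rna Number of replicate libraries per modality.
#' @param paternal_fraction Percentage (0-100) of molecules that are
#'   paternally derived, before sequencing error.
#' @param reads_per_replicate Molecules drawn per replicate library.
#' @param gene_overrides Optional tibble `gene_id`, `paternal_fraction`
#'   planting allele-biased or monoallelic genes at this stage. Columns
#'   `paternal_fraction_ribo` / `paternal_fraction_rna` may be used
#'   instead of (or alongside) `paternal_fraction` to plant
#'   modality-specific allelic differences, i.e. differential allelic
#'   ribosome engagement.
#' @param te_multipliers Optional tibble `gene_id`, `multiplier` scaling
#'   ribosome-footprint (not RNA) sampling weight, i.e. planted
#'   translation-efficiency fold changes.
#' @return A `stage_spec` list.
#' @export
stage_spec <- function(stage, n_ribo = 4, n_rna = 4, paternal_fraction = 0,
                       reads_per_replicate = 20000,
                       gene_overrides = NULL, te_multipliers = NULL) {
  if (paternal_fraction < 0 || paternal_fraction > 100) {
    abort("`paternal_fraction` must be between 0 and 100.")
  }
  if (stage %in% c("GV", "MII") && paternal_fraction != 0) {
    abort("Oocyte stages (GV, MII) are purely maternal: paternal_fraction must be 0.")
  }
  if (!is.null(gene_overrides)) {
    assert_columns(gene_overrides, "gene_id")
    if (!any(c("paternal_fraction", "paternal_fraction_ribo",
               "paternal_fraction_rna") %in% names(gene_overrides))) {
      abort("`gene_overrides` needs a paternal_fraction column (optionally per modality).")
    }
  }
  if (!is.null(te_multipliers)) assert_columns(te_multipliers, c("gene_id", "multiplier"))
  structure(
    list(stage = stage, n_ribo = as.integer(n_ribo), n_rna = as.integer(n_rna),
         paternal_fraction = paternal_fraction,
         reads_per_replicate = as.integer(reads_per_replicate),
         gene_overrides = gene_overrides, te_multipliers = te_multipliers),
    class = "stage_spec"
  )
}

#' Default developmental-stage design
#'
#' Six stages spanning oocyte maturation through the eight-cell embryo.
#' Oocytes carry no paternal transcripts; the paternal share of the
#' transcript pool rises from 7.1% at the two-cell stage to 47.7% at the
#' eight-cell stage, reflecting zygotic genome activation. The one-cell and
#' four-cell values (1% and 30%) are interpolating choices consistent with
#' a steady increase across cleavage stages.
#'
#' @param reads_per_replicate Molecules per replicate library.
#' @return List of [stage_spec()] objects.
#' @export
default_stages <- function(reads_per_replicate = 20000) {
  list(
    stage_spec("GV",  paternal_fraction = 0,    reads_per_replicate = reads_per_replicate),
    stage_spec("MII", paternal_fraction = 0,    reads_per_replicate = reads_per_replicate),
    stage_spec("1c",  paternal_fraction = 1,    reads_per_replicate = reads_per_replicate),
    stage_spec("2c",  paternal_fraction = 7.1,  reads_per_replicate = reads_per_replicate),
    stage_spec("4c",  paternal_fraction = 30,   reads_per_replicate = reads_per_replicate),
    stage_spec("8c",  paternal_fraction = 47.7, reads_per_replicate = reads_per_replicate)
  )
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator: transcriptome
#' geometry, SNP density, footprint-length distribution and per-length
#' A-site offsets, reading-frame fidelity, per-read substitution error
#' rates, and PCR duplication.
#'
#' Defaults encode the study conditions of low-input embryo ribosome
#' profiling: footprints of 29-35 nt with a peaked length distribution,
#' per-read substitution error rates of 2.67% (ribosome profiling) and
#' 0.40% (RNA-seq) as estimated from purely maternal MII oocytes, and
#' strong but imperfect 3-nt periodicity.
#'
#' @param n_genes Number of transcripts (one isoform per gene).
#' @param utr5_range,cds_range,utr3_range Length ranges in nt; CDS lengths
#'   are rounded to multiples of 3 and include start and stop codons.
#' @param snp_rate Expected strain-distinguishing SNPs per kilobase.
#' @param stages List of [stage_spec()]; defaults to [default_stages()].
#' @param footprint_len_probs Named numeric, probabilities over footprint
#'   lengths 29-35 nt (must sum to 1).
#' @param asite_offsets Named integer, 5' end to A-site offset per length;
#'   must cover every length with positive probability.
#' @param frame_fidelity Probability that a footprint's A-site falls in the
#'   dominant (codon) frame; the remainder spreads evenly over the other two.
#' @param start_bias,stop_bias Multiplicative sampling weight of the
#'   initiation and termination codon relative to an interior codon,
#'   emulating ribosome pausing at start and stop. 1 disables the
#'   enrichment; a dominant `stop_bias` is what makes stop-metagene
#'   A-site calibration identifiable.
#' @param rna_read_length RNA-seq read length in nt.
#' @param ribo_error_pct,rna_error_pct Per-read substitution error
#'   percentage applied to SNP-covering reads.
#' @param duplication_rate Expected extra PCR copies per molecule (Poisson).
#' @param umi_length UMI length in nt (12-mers by default; collision
#'   probability at the simulated scales is negligible and documented).
#' @param seed Master seed; every stream is sub-seeded deterministically.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50,
                       utr5_range = c(60, 150),
                       cds_range = c(300, 1500),
                       utr3_range = c(60, 300),
                       snp_rate = 2,
                       stages = default_stages(),
                       footprint_len_probs = c(
                         "29" = 0.05, "30" = 0.10, "31" = 0.25, "32" = 0.30,
                         "33" = 0.17, "34" = 0.08, "35" = 0.05),
                       asite_offsets = c(
                         "29" = 14, "30" = 14, "31" = 15, "32" = 15,
                         "33" = 16, "34" = 16, "35" = 17),
                       frame_fidelity = 0.85,
                       start_bias = 1,
                       stop_bias = 1,
                       rna_read_length = 40,
                       ribo_error_pct = 2.67,
                       rna_error_pct = 0.40,
                       duplication_rate = 0,
                       umi_length = 12,
                       seed = 1L) {
  if (inherits(stages, "stage_spec")) stages <- list(stages)
  check_range <- function(r, nm) {
    if (length(r) != 2 || any(r < 1) || r[1] > r[2]) {
      abort(sprintf("`%s` must be c(min, max) with 1 <= min <= max.", nm))
    }
  }
  check_range(utr5_range, "utr5_range")
  check_range(cds_range, "cds_range")
  check_range(utr3_range, "utr3_range")
  if (cds_range[1] < 6) abort("CDS lengths must be at least 6 nt (start + stop codon).")
  if (abs(sum(footprint_len_probs) - 1) > 1e-8) {
    abort("`footprint_len_probs` must sum to 1.")
  }
  lens <- names(footprint_len_probs)[footprint_len_probs > 0]
  missing_off <- setdiff(lens, names(asite_offsets))
  if (length(missing_off) > 0) {
    abort(sprintf("`asite_offsets` missing length(s): %s",
                  paste(missing_off, collapse = ", ")))
  }
  for (p in c(ribo_error_pct, rna_error_pct)) {
    if (p < 0 || p > 100) abort("error percentages must lie in [0, 100].")
  }
  if (duplication_rate < 0) abort("`duplication_rate` must be non-negative.")
  if (frame_fidelity < 0 || frame_fidelity > 1) abort("`frame_fidelity` must lie in [0, 1].")
  if (start_bias < 0 || stop_bias < 0) abort("start/stop biases must be non-negative.")
  structure(
    list(n_genes = as.integer(n_genes),
         utr5_range = utr5_range, cds_range = cds_range, utr3_range = utr3_range,
         snp_rate = snp_rate, stages = stages,
         footprint_len_probs = footprint_len_probs,
         asite_offsets = asite_offsets,
         frame_fidelity = frame_fidelity,
         start_bias = start_bias, stop_bias = stop_bias,
         rna_read_length = as.integer(rna_read_length),
         ribo_error_pct = ribo_error_pct, rna_error_pct = rna_error_pct,
         duplication_rate = duplication_rate,
         umi_length = as.integer(umi_length),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d | SNP rate: %g/kb | seed: %d\n",
              x$n_genes, x$snp_rate, x$seed))
  cat(sprintf("  stages: %s\n",
              paste(vapply(x$stages, function(s)
                sprintf("%s (pat %g%%)", s$stage, s$paternal_fraction),
                character(1)), collapse = ", ")))
  cat(sprintf("  errors: ribo %g%%, rna %g%% | duplication rate %g\n",
              x$ribo_error_pct, x$rna_error_pct, x$duplication_rate))
  invisible(x)
}
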