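#' Filter ribosome footprints by length
#'
#' Retains footprints within the standard ribosome-protected-fragment size
#' window (29-35 nt by default); all downstream footprint analyses assume
#' this window. Row order is preserved.
#'
#' @param reads Read table.
#' @param min,max Inclusive length bounds (nt).
#' @return Filtered read table.
#' @export
filter_footprint_lengths <- function(reads, min = 29L, max = 35L) {
  if (min > max) abort("`min` must not exceed `max`.")
  assert_columns(reads, "length", "reads")
  filter(reads, .data$length >= min, .data$length <= max)
}

#' Collapse PCR duplicates
#'
#' Deduplication key per sample:
#' * ribosome profiling with UMIs: one read kept per
#'   (gene, 5' position, length, UMI);
#' * ribosome profiling without UMIs: per (gene, 5' position, length);
#' * RNA-seq with UMIs: per (gene, UMI) irrespective of position, i.e.
#'   per-gene UMI collapsing;
#' * RNA-seq without UMIs: falls back to the positional key.
#'
#' The first occurrence is kept, so the operation is idempotent and order
#' preserving.
#'
#' @param reads Read table; the `modality` column selects the key per row.
#' @param has_umi Whether UMIs are available (`TRUE` for this protocol).
#' @return Deduplicated read table.
#' @export
dedup_reads <- function(reads, has_umi = TRUE) {
  assert_columns(reads, c("sample_id", "modality", "gene_id",
                          "five_prime_pos", "length", "umi"), "reads")
  is_rna <- reads$modality == "rna"
  key <- if (has_umi) {
    if_else(is_rna,
            paste(reads$sample_id, reads$gene_id, reads$umi, sep = "\r"),
            paste(reads$sample_id, reads$gene_id, reads$five_prime_pos,
                  reads$length, reads$umi, sep = "\r"))
  } else {
    paste(reads$sample_id, reads$gene_id, reads$five_prime_pos,
          reads$length, sep = "\r")
  }
  reads[!duplicated(key), ]
}

ribo_asite <- function(reads, offsets) {
  off <- offsets[as.character(reads$length)]
  missing_len <- unique(reads$length[is.na(off)])
  if (length(missing_len) > 0) {
    abort(sprintf("No A-site offset for footprint length(s): %s",
                  paste(sort(missing_len), collapse = ", ")))
  }
  reads$five_prime_pos + as.integer(off)
}

# Position used for region assignment: A-site for ribo, 5' end for RNA.
assigned_position <- function(reads, offsets = NULL) {
  pos <- reads$five_prime_pos
  is_ribo <- reads$modality == "ribo"
  if (any(is_ribo)) {
    if (is.null(offsets)) abort("Ribosome footprints need `offsets` for A-site assignment.")
    pos[is_ribo] <- ribo_asite(reads[is_ribo, ], offsets)
  }
  pos
}

#' Count reads over coding sequences
#'
#' A ribosome footprint is counted for a gene when its A-site
#' (5' position + per-length offset) lies within the CDS interval
#' `[cds_start, cds_end)`; an RNA-seq read when its 5' end does. Counts
#' are completed with zeros over all genes in the annotation and all
#' samples present in the read table.
#'
#' @param reads Deduplicated read table.
#' @param annotation Gene annotation tibble with `gene_id`, `utr5_len`,
#'   `cds_len` (e.g. `transcriptome$genes`).
#' @param offsets Named A-site offset map (required when ribosome
#'   footprints are present).
#' @return Long count tibble: `gene_id`, `sample_id`, `stage`, `replicate`,
#'   `modality`, `count`.
#' @export
count_cds <- function(reads, annotation, offsets = NULL) {
  assert_columns(annotation, c("gene_id", "utr5_len", "cds_len"), "annotation")
  ann <- select(annotation, "gene_id", "utr5_len", "cds_len")
  reads <- inner_join(reads, ann, by = "gene_id")
  pos <- assigned_position(reads, offsets)
  in_cds <- pos >= reads$utr5_len & pos < reads$utr5_len + reads$cds_len
  counted <- reads[in_cds, ] |>
    count(.data$gene_id, .data$sample_id, .data$stage, .data$replicate,
          .data$modality, name = "count")
  samples <- distinct(reads, .data$sample_id, .data$stage, .data$replicate,
                      .data$modality)
  tidyr::crossing(gene_id = annotation$gene_id, samples) |>
    left_join(counted,
              by = c("gene_id", "sample_id", "stage", "replicate", "modality")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    arrange(.data$gene_id, .data$sample_id)
}

#' Pivot a long count table to a gene-by-sample matrix
#'
#' @param counts Long count tibble from [count_cds()].
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
as_count_matrix <- function(counts) {
  wide <- counts |>
    select("gene_id", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

#' Tally allele observations at strain SNPs
#'
#' Expands the per-read SNP observations and classifies each against the
#' SNP's maternal and paternal alleles: an observed base equal to the
#' maternal allele increments `maternal_count`, equal to the paternal
#' allele `paternal_count`, and any other base `other_count`
#' (a sequencing-error signature). A read covering k SNPs contributes k
#' observations. By default only CDS SNPs are used, matching the
#' allele-specific analysis contract.
#'
#' @param reads Deduplicated read table.
#' @param snps SNP tibble (`snp_id`, `gene_id`, `pos`, `maternal_allele`,
#'   `paternal_allele`, `region`).
#' @param cds_only Restrict to SNPs annotated in the CDS.
#' @return Long tibble: `gene_id`, `snp_id`, `sample_id`, `stage`,
#'   `replicate`, `modality`, `maternal_count`, `paternal_count`,
#'   `other_count`.
#' @export
build_allele_counts <- function(reads, snps, cds_only = TRUE) {
  assert_columns(snps, c("snp_id", "gene_id", "maternal_allele",
                         "paternal_allele", "region"), "snps")
  use <- if (cds_only) filter(snps, .data$region == "CDS") else snps
  obs <- reads |>
    filter(!is.na(.data$snp_obs), .data$snp_obs != "") |>
    select("sample_id", "stage", "replicate", "modality", "gene_id", "snp_obs") |>
    tidyr::separate_rows("snp_obs", sep = ";") |>
    tidyr::separate_wider_delim("snp_obs", ":", names = c("snp_id", "obs_base"))
  unknown <- setdiff(unique(obs$snp_id), snps$snp_id)
  if (length(unknown) > 0) {
    abort(sprintf("Read table references unknown snp_id(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  obs |>
    inner_join(select(use, "snp_id", "maternal_allele", "paternal_allele"),
               by = "snp_id") |>
    mutate(class = dplyr::case_when(
      .data$obs_base == .data$maternal_allele ~ "maternal_count",
      .data$obs_base == .data$paternal_allele ~ "paternal_count",
      TRUE ~ "other_count")) |>
    count(.data$gene_id, .data$snp_id, .data$sample_id, .data$stage,
          .data$replicate, .data$modality, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L) |>
    (\(d) {
      for (col in c("maternal_count", "paternal_count", "other_count")) {
        if (!col %in% names(d)) d[[col]] <- 0L
      }
      d
    })() |>
    select("gene_id", "snp_id", "sample_id", "stage", "replicate", "modality",
           "maternal_count", "paternal_count", "other_count") |>
    arrange(.data$gene_id, .data$snp_id, .data$sample_id)
}
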