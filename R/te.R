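#' Centred log-ratio normalization
#'
#' `clr(g) = ln(g / M)` where `M` is the geometric mean over genes with
#' non-zero values in the sample. Zero-count genes are excluded from `M`
#' and returned as `NA` (undefined), never as a numeric zero: the clr of a
#' composition is only defined on its support, and the per-sample clr
#' values sum to zero over the included genes.
#'
#' @param values Non-negative per-gene values (counts or densities) for
#'   one sample.
#' @return Numeric vector of clr values, `NA` where the input was zero.
#' @export
clr_normalize <- function(values) {
  if (any(values < 0, na.rm = TRUE)) abort("clr is undefined for negative values.")
  nz <- !is.na(values) & values > 0
  if (!any(nz)) abort("All values are zero: clr undefined.")
  out <- rep(NA_real_, length(values))
  out[nz] <- log(values[nz] / geometric_mean(values[nz]))
  names(out) <- names(values)
  out
}

#' Read density over the coding sequence
#'
#' Density is the CDS read count divided by the CDS length. Any constant
#' scaling (e.g. per-kilobase) cancels in the subsequent clr
#' normalization, so plain per-nucleotide density is used.
#'
#' @param count Non-negative read counts.
#' @param cds_len Matching CDS lengths (nt, positive).
#' @return Numeric densities.
#' @export
cds_density <- function(count, cds_len) {
  if (any(cds_len <= 0)) abort("CDS lengths must be positive.")
  count / cds_len
}

# clr matrix (genes x samples) of CDS densities from a long count table
clr_matrix <- function(counts, annotation) {
  m <- as_count_matrix(counts)
  cds <- annotation$cds_len[match(rownames(m), annotation$gene_id)]
  if (anyNA(cds)) abort("Count table contains genes absent from the annotation.")
  apply(m / cds, 2, clr_normalize)
}

#' Translation efficiency per gene and stage
#'
#' For each sample the CDS read density is clr-normalized; clr values are
#' averaged across replicates within each (stage, modality), over the
#' replicates where the gene is defined (non-zero). Translation efficiency
#' on the log scale is the difference of the replicate-mean clr values,
#' `te_log = clr_ribo - clr_rna`, and `te = exp(te_log)` is the
#' ratio-scale equivalent (the ratio of normalized ribosome occupancy to
#' normalized RNA expression). A gene with zero counts in every replicate
#' of a modality is undefined (`NA`) for that stage, never silently zero.
#'
#' @param ribo_counts,rna_counts Long count tibbles from [count_cds()]
#'   (may be a single combined tibble passed to both arguments; the
#'   `modality` column disambiguates).
#' @param annotation Gene annotation with `gene_id` and `cds_len`.
#' @return A `te_tbl` tibble: `gene_id`, `stage`, `clr_ribo`, `clr_rna`,
#'   `n_ribo_reps`, `n_rna_reps`, `te_log`, `te`.
#' @export
compute_te <- function(ribo_counts, rna_counts, annotation) {
  assert_columns(annotation, c("gene_id", "cds_len"), "annotation")
  modality_means <- function(counts, modality) {
    counts <- filter(counts, .data$modality == !!modality)
    if (nrow(counts) == 0) abort(sprintf("No %s counts supplied.", modality))
    purrr::map_dfr(split(counts, counts$stage), function(d) {
      cm <- clr_matrix(d, annotation)
      tibble(gene_id = rownames(cm), stage = d$stage[1],
             clr = unname(rowMeans(cm, na.rm = TRUE)),
             n_reps = unname(rowSums(!is.na(cm))))
    }) |>
      mutate(clr = if_else(.data$n_reps == 0, NA_real_, .data$clr))
  }
  ribo <- modality_means(ribo_counts, "ribo") |>
    rename(clr_ribo = "clr", n_ribo_reps = "n_reps")
  rna <- modality_means(rna_counts, "rna") |>
    rename(clr_rna = "clr", n_rna_reps = "n_reps")
  out <- inner_join(ribo, rna, by = c("gene_id", "stage")) |>
    mutate(te_log = .data$clr_ribo - .data$clr_rna,
           te = exp(.data$te_log)) |>
    arrange(.data$stage, .data$gene_id)
  class(out) <- c("te_tbl", class(out))
  out
}

#' Bootstrap confidence intervals for translation efficiency
#'
#' Resamples replicate libraries with replacement, independently for
#' ribosome profiling and RNA-seq within each stage, recomputes the
#' replicate-mean clr difference, and reports percentile intervals of
#' `te_log` (and their exponentials for `te`). Deterministic given `seed`.
#'
#' @inheritParams compute_te
#' @param B Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Seed for the resampling stream.
#' @return Tibble `gene_id`, `stage`, `te_log_lo`, `te_log_hi`, `te_lo`,
#'   `te_hi`.
#' @export
bootstrap_te_ci <- function(ribo_counts, rna_counts, annotation,
                            B = 1000L, level = 0.95, seed = 1L) {
  if (B < 1) abort("`B` must be at least 1.")
  set.seed(seed)
  ribo_counts <- filter(ribo_counts, .data$modality == "ribo")
  rna_counts <- filter(rna_counts, .data$modality == "rna")
  stages <- intersect(unique(ribo_counts$stage), unique(rna_counts$stage))
  alpha <- (1 - level) / 2
  purrr::map_dfr(stages, function(stg) {
    cm_ribo <- clr_matrix(filter(ribo_counts, .data$stage == stg), annotation)
    cm_rna <- clr_matrix(filter(rna_counts, .data$stage == stg), annotation)
    boot <- replicate(B, {
      i <- sample.int(ncol(cm_ribo), replace = TRUE)
      j <- sample.int(ncol(cm_rna), replace = TRUE)
      rowMeans(cm_ribo[, i, drop = FALSE], na.rm = TRUE) -
        rowMeans(cm_rna[, j, drop = FALSE], na.rm = TRUE)
    })
    qs <- apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
    tibble(gene_id = rownames(cm_ribo), stage = stg,
           te_log_lo = qs[1, ], te_log_hi = qs[2, ],
           te_lo = exp(qs[1, ]), te_hi = exp(qs[2, ]))
  })
}

#' Association between translation efficiency and poly(A) tail length
#'
#' Genes are grouped into `n_bins` equal-count bins by poly(A) tail
#' length (rank order, ties broken stably by gene identifier); each bin is
#' summarised by boxplot statistics of translation efficiency (median,
#' quartiles, whiskers at 1.5 times the interquartile range limited to the
#' data range). The unbinned association is summarised by a Spearman rank
#' correlation.
#'
#' @param data Tibble with columns `gene_id`, `tail_length` (mean poly(A)
#'   tail length, nt) and `te` (translation efficiency; either scale,
#'   Spearman is rank-based).
#' @param n_bins Number of equal-count bins (six in the standard
#'   analysis).
#' @return A `polya_assoc` object: list with `bins` (per-bin boxplot
#'   stats), `rho`, `p_value`, `n`.
#' @export
polya_te_association <- function(data, n_bins = 6L) {
  assert_columns(data, c("gene_id", "tail_length", "te"), "data")
  d <- filter(data, !is.na(.data$tail_length), !is.na(.data$te))
  if (nrow(d) < n_bins) {
    abort(sprintf("Need at least %d genes with both values.", n_bins))
  }
  d <- d |>
    arrange(.data$tail_length, .data$gene_id) |>
    mutate(bin = dplyr::ntile(row_number(), n_bins))
  bins <- d |>
    group_by(.data$bin) |>
    summarise(
      n = n(),
      tail_min = min(.data$tail_length), tail_max = max(.data$tail_length),
      q1 = quantile(.data$te, 0.25), median = median(.data$te),
      q3 = quantile(.data$te, 0.75)) |>
    mutate(iqr = .data$q3 - .data$q1,
           whisker_lo = .data$q1 - 1.5 * .data$iqr,
           whisker_hi = .data$q3 + 1.5 * .data$iqr)
  ct <- suppressWarnings(cor.test(d$tail_length, d$te, method = "spearman",
                                  exact = FALSE))
  structure(list(bins = bins, rho = unname(ct$estimate),
                 p_value = ct$p.value, n = nrow(d), data = d),
            class = "polya_assoc")
}

#' @export
print.polya_assoc <- function(x, ...) {
  cat(sprintf("<polya_assoc> %d genes in %d bins | Spearman rho = %.3f (p = %.3g)\n",
              x$n, nrow(x$bins), x$rho, x$p_value))
  invisible(x)
}
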