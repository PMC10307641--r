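#' Replicate-to-replicate reliability of a measurement
#'
#' Reliability of a modality is estimated as the mean pairwise Spearman
#' correlation between replicate measurements, computed over the genes
#' defined in both members of each pair. Being rank-based, it is
#' invariant to monotone transformations of the values.
#'
#' @param replicate_matrix Numeric matrix, genes in rows and replicates in
#'   columns (`NA` for undefined entries).
#' @return Reliability coefficient (scalar).
#' @export
replicate_reliability <- function(replicate_matrix) {
  m <- as.matrix(replicate_matrix)
  if (ncol(m) < 2) abort("Need at least two replicates.")
  pairs <- utils::combn(ncol(m), 2)
  rhos <- apply(pairs, 2, function(ij) {
    ok <- complete.cases(m[, ij])
    cor(m[ok, ij[1]], m[ok, ij[2]], method = "spearman")
  })
  mean(rhos)
}

#' Spearman correlation corrected for measurement unreliability
#'
#' Classical disattenuation: the observed rank correlation is divided by
#' the geometric mean of the two reliabilities,
#' `corrected = observed / sqrt(rel_x * rel_y)`. Corrected values are
#' capped at +/-1 (with a flag), since an attenuation-corrected
#' correlation can exceed the admissible range when reliabilities are
#' underestimated.
#'
#' @param x,y Paired numeric vectors; pairs with `NA` are dropped.
#' @param rel_x,rel_y Reliability coefficients in (0, 1\].
#' @return One-row tibble: `observed`, `corrected`, `capped`, `n`.
#' @export
disattenuated_spearman <- function(x, y, rel_x, rel_y) {
  if (rel_x <= 0 || rel_y <= 0) abort("Reliabilities must be positive.")
  ok <- !is.na(x) & !is.na(y)
  obs <- cor(x[ok], y[ok], method = "spearman")
  raw <- obs / sqrt(rel_x * rel_y)
  tibble(observed = obs,
         corrected = pmin(pmax(raw, -1), 1),
         capped = abs(raw) > 1,
         n = sum(ok))
}

#' Standard measurement reliabilities
#'
#' Replicate-to-replicate reliability coefficients used for
#' disattenuation: translation efficiency 0.53, ribosome profiling 0.71,
#' RNA-seq 0.79, mass spectrometry 0.80.
#'
#' @return Named numeric vector with entries `te`, `ribo`, `rna`, `protein`.
#' @export
default_reliabilities <- function() {
  c(te = 0.53, ribo = 0.71, rna = 0.79, protein = 0.8)
}

#' Cross-stage correlation grid against protein abundance
#'
#' Correlates each (modality, stage) profile - clr RNA expression, clr
#' ribosome occupancy, and log translation efficiency - with protein
#' abundance at every protein stage, reporting observed and
#' reliability-corrected Spearman coefficients per cell. Gene pairs with
#' undefined entries are dropped per cell; cells with fewer than `min_n`
#' shared genes are flagged unreliable.
#'
#' @param te_table A [compute_te()] table (carries `clr_rna`, `clr_ribo`
#'   and `te_log` per gene and stage).
#' @param protein_table Long tibble `gene_id`, `stage`, `abundance`.
#' @param reliabilities Named vector as [default_reliabilities()].
#' @param min_n Minimum shared genes per cell.
#' @return A `correlation_grid` tibble: `modality`, `source_stage`,
#'   `protein_stage`, `observed`, `corrected`, `capped`, `n`, `reliable`.
#' @export
cross_stage_grid <- function(te_table, protein_table,
                             reliabilities = default_reliabilities(),
                             min_n = 30L) {
  assert_columns(protein_table, c("gene_id", "stage", "abundance"),
                 "protein_table")
  value_cols <- c(rna = "clr_rna", ribo = "clr_ribo", te = "te_log")
  cells <- tidyr::crossing(
    modality = names(value_cols),
    source_stage = unique(te_table$stage),
    protein_stage = unique(protein_table$stage))
  out <- purrr::pmap_dfr(cells, function(modality, source_stage, protein_stage) {
    src <- filter(te_table, .data$stage == source_stage)
    prot <- filter(protein_table, .data$stage == protein_stage)
    d <- inner_join(select(src, "gene_id", value = dplyr::all_of(value_cols[[modality]])),
                    select(prot, "gene_id", "abundance"), by = "gene_id")
    d <- filter(d, !is.na(.data$value), !is.na(.data$abundance))
    if (nrow(d) < 3) {
      return(tibble(modality = modality, source_stage = source_stage,
                    protein_stage = protein_stage, observed = NA_real_,
                    corrected = NA_real_, capped = NA, n = nrow(d),
                    reliable = FALSE))
    }
    ds <- disattenuated_spearman(d$value, d$abundance,
                                 reliabilities[[modality]],
                                 reliabilities[["protein"]])
    tibble(modality = modality, source_stage = source_stage,
           protein_stage = protein_stage, observed = ds$observed,
           corrected = ds$corrected, capped = ds$capped, n = ds$n,
           reliable = ds$n >= min_n)
  })
  class(out) <- c("correlation_grid", class(out))
  out
}
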