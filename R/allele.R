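#' Estimate the sequencing error rate from MII oocytes
#'
#' MII oocyte transcripts are purely maternal, so any SNP observation that
#' is not the maternal allele must be a sequencing (or alignment) error.
#' The error percentage is the share of non-maternal observations
#' (paternal allele plus any other base) among all SNP observations of the
#' given modality in MII-stage samples.
#'
#' @param allele_counts Allele count table from [build_allele_counts()].
#' @param modality `"ribo"` or `"rna"`.
#' @param stage Stage treated as purely maternal (`"MII"`).
#' @return One-row tibble: `modality`, `error_pct`, `n_obs`.
#' @export
estimate_error_rate <- function(allele_counts, modality = c("ribo", "rna"),
                                stage = "MII") {
  modality <- match.arg(modality)
  d <- filter(allele_counts, .data$modality == !!modality, .data$stage == !!stage)
  total <- sum(d$maternal_count) + sum(d$paternal_count) + sum(d$other_count)
  if (total == 0) {
    abort(sprintf("No %s-stage SNP observations for modality '%s'.", stage, modality))
  }
  non_maternal <- sum(d$paternal_count) + sum(d$other_count)
  tibble(modality = modality, error_pct = 100 * non_maternal / total,
         n_obs = total)
}

#' Pseudocounted paternal ratio
#'
#' `100 * (paternal + 1) / (paternal + 1 + maternal + 1)`. The unit
#' pseudocounts keep the ratio strictly inside (0, 100) and give 50 for a
#' gene with no parent-of-origin reads.
#'
#' @param paternal,maternal Non-negative read counts (vectorized).
#' @return Percentage in (0, 100).
#' @export
paternal_ratio <- function(paternal, maternal) {
  if (any(paternal < 0) || any(maternal < 0)) abort("Counts must be non-negative.")
  100 * (paternal + 1) / (paternal + 1 + maternal + 1)
}

#' Error-corrected paternal ratio
#'
#' Inverts the random-substitution error model. If `c` is the true
#' paternal percentage and `e` the sequencing error percentage, the
#' observed paternal percentage (paternal observations out of all SNP
#' observations) is
#' `obs = c * (100 - e) / 100 + (100 - c) * e / 300`:
#' a true paternal read survives with probability `1 - e/100`, and an
#' errored read of either origin shows the paternal allele in one of the
#' three possible substitutions. Solving for `c` gives
#' `corrected = (300 * obs - 100 * e) / (300 - 4 * e)`.
#'
#' `obs = 25` is a fixed point for every error rate: a fully random base
#' shows any given allele a quarter of the time. The correction is
#' strictly increasing in `obs` for fixed `e`, and requires `e < 75`
#' (at which the denominator vanishes).
#'
#' @param observed_pct Observed paternal percentage (0-100, vectorized).
#' @param error_pct Sequencing error percentage, below 75.
#' @return Corrected percentages, clamped to \[0, 100\]; a logical
#'   `clamped` attribute records where clamping occurred.
#' @export
correct_paternal_ratio <- function(observed_pct, error_pct) {
  if (any(error_pct < 0)) abort("`error_pct` must be non-negative.")
  if (any(error_pct >= 75)) {
    abort("`error_pct` must be below 75: the correction denominator vanishes.")
  }
  raw <- (300 * observed_pct - 100 * error_pct) / (300 - 4 * error_pct)
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "clamped") <- raw < 0 | raw > 100
  out
}

#' Per-stage corrected paternal percentage, mean and SEM over replicates
#'
#' For each replicate library the SNP observations are pooled over genes
#' and SNPs; the observed paternal percentage is the pseudocounted share
#' of paternal observations among all SNP observations (maternal +
#' paternal + other in the denominator, matching the error model under
#' which the correction formula is exact). The per-replicate corrected
#' percentages are then summarised per stage and modality by their mean
#' and standard error.
#'
#' @param allele_counts Allele count table.
#' @param error_by_modality Named numeric, e.g.
#'   `c(ribo = 2.67, rna = 0.40)`; typically from [estimate_error_rate()].
#' @return Tibble `stage`, `modality`, `mean_corrected_pct`, `sem`,
#'   `n_replicates`.
#' @export
stage_paternal_summary <- function(allele_counts, error_by_modality) {
  per_rep <- allele_counts |>
    group_by(.data$stage, .data$modality, .data$replicate) |>
    summarise(paternal = sum(.data$paternal_count),
              maternal = sum(.data$maternal_count),
              other = sum(.data$other_count), .groups = "drop") |>
    mutate(
      observed_pct = 100 * (.data$paternal + 1) /
        (.data$paternal + .data$maternal + .data$other + 2),
      corrected_pct = as.numeric(correct_paternal_ratio(
        .data$observed_pct, error_by_modality[.data$modality])))
  per_rep |>
    group_by(.data$stage, .data$modality) |>
    summarise(mean_corrected_pct = mean(.data$corrected_pct),
              sem = sd(.data$corrected_pct) / sqrt(n()),
              n_replicates = n(), .groups = "drop")
}

#' Two-sample proportion test with continuity correction
#'
#' Yates-corrected chi-squared test (1 df) for the equality of two
#' proportions, with the continuity-corrected Wald confidence interval for
#' the difference `p1 - p2` (widened by the correction term and truncated
#' to \[-1, 1\]). The correction term is capped so it can never reverse
#' the sign of an observed difference, hence the statistic is 0 and the
#' p-value 1 for identical proportions. Fully vectorized.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two samples.
#' @param conf_level Confidence level for the interval.
#' @return Tibble `estimate1`, `estimate2`, `diff`, `statistic`,
#'   `p_value`, `conf_lo`, `conf_hi`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, conf_level = 0.95) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("Sample sizes must be positive.")
  if (any(x1 > n1) || any(x2 > n2) || any(x1 < 0) || any(x2 < 0)) {
    abort("Successes must lie within [0, n].")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  delta <- p1 - p2
  inv_n <- 1 / n1 + 1 / n2
  yates <- pmin(0.5, abs(delta) / inv_n)
  phat <- (x1 + x2) / (n1 + n2)
  e11 <- n1 * phat; e12 <- n1 * (1 - phat)
  e21 <- n2 * phat; e22 <- n2 * (1 - phat)
  statistic <- (abs(x1 - e11) - yates)^2 / e11 +
    (abs(n1 - x1 - e12) - yates)^2 / e12 +
    (abs(x2 - e21) - yates)^2 / e21 +
    (abs(n2 - x2 - e22) - yates)^2 / e22
  degenerate <- phat == 0 | phat == 1
  statistic[degenerate] <- 0
  width <- qnorm((1 + conf_level) / 2) *
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) + yates * inv_n
  tibble(estimate1 = p1, estimate2 = p2, diff = delta,
         statistic = statistic,
         p_value = pchisq(statistic, df = 1, lower.tail = FALSE),
         conf_lo = pmax(delta - width, -1),
         conf_hi = pmin(delta + width, 1))
}

# genes x replicates paternal/maternal count matrices for one modality
allele_rep_matrices <- function(allele_counts, modality, genes) {
  d <- filter(allele_counts, .data$modality == !!modality) |>
    group_by(.data$gene_id, .data$replicate) |>
    summarise(p = sum(.data$paternal_count), m = sum(.data$maternal_count),
              .groups = "drop")
  reps <- sort(unique(filter(allele_counts, .data$modality == !!modality)$replicate))
  P <- matrix(0, nrow = length(genes), ncol = length(reps),
              dimnames = list(genes, reps))
  M <- P
  i <- cbind(match(d$gene_id, genes), match(d$replicate, reps))
  P[i] <- d$p
  M[i] <- d$m
  list(P = P, M = M, n_reps = length(reps))
}

#' Differential allelic engagement of ribosomes versus RNA
#'
#' Identifies, for one embryonic stage, the genes whose paternal
#' proportion differs between ribosome occupancy and RNA expression.
#' The full-data pass, and each bootstrap pass, proceed as:
#'
#' 1. pool parent-of-origin reads per gene across replicates and SNPs,
#'    separately per modality;
#' 2. keep genes with more than `min_total` parent-of-origin reads in both
#'    modalities and at least `min_allele` maternal and paternal reads
#'    (pooled across modalities);
#' 3. test the paternal proportion, ribo versus RNA, with
#'    [two_proportion_test()];
#' 4. drop genes whose 95% confidence interval for the difference
#'    overlaps `(-ci_guard, ci_guard)` (effect too small to matter);
#' 5. Benjamini-Hochberg adjust the remaining p-values and keep
#'    `padj < fdr`;
#' 6. drop genes with any paternal reads in MII oocytes (alignment-error
#'    prone positions).
#'
#' Robustness is then established by repeating the procedure on `B`
#' resamples of replicate labels (with replacement, independently per
#' modality): a gene is called when it is significant in at least
#' `support_frac * B` resamples.
#'
#' @param allele_counts Allele count table containing the target stage
#'   (both modalities) and, for the MII filter, MII-stage rows.
#' @param stage Target embryonic stage.
#' @param error_estimates Optional named vector `c(ribo = , rna = )` of
#'   error percentages; when given, corrected per-gene paternal ratios are
#'   annotated in the output (the test itself runs on raw counts).
#' @param min_total,min_allele,ci_guard,fdr,support_frac,B Procedure
#'   thresholds; defaults are the standard analysis settings.
#' @param seed Seed for the bootstrap stream.
#' @return An `allelic_engagement` object wrapping a per-gene tibble with
#'   full-data statistics, bootstrap `support`, and the final `called`
#'   flag.
#' @export
differential_allelic_engagement <- function(allele_counts, stage,
                                            error_estimates = NULL,
                                            min_total = 10L, min_allele = 3L,
                                            ci_guard = 0.05, fdr = 0.2,
                                            support_frac = 0.66, B = 100L,
                                            seed = 1L) {
  if (B < 1) abort("`B` must be at least 1.")
  target <- filter(allele_counts, .data$stage == !!stage)
  if (nrow(target) == 0) abort(sprintf("No allele counts for stage '%s'.", stage))
  genes <- sort(unique(target$gene_id))
  ribo <- allele_rep_matrices(target, "ribo", genes)
  rna <- allele_rep_matrices(target, "rna", genes)
  if (ribo$n_reps < 2 || rna$n_reps < 2) {
    abort("Need at least two replicates per modality.")
  }

  mii <- filter(allele_counts, .data$stage == "MII")
  if (nrow(mii) == 0) {
    warn("No MII-stage counts available: the paternal-MII filter is skipped.")
    mii_paternal <- rep(0L, length(genes))
  } else {
    mp <- mii |> group_by(.data$gene_id) |>
      summarise(p = sum(.data$paternal_count))
    mii_paternal <- mp$p[match(genes, mp$gene_id)]
    mii_paternal[is.na(mii_paternal)] <- 0L
  }

  run_once <- function(w_ribo, w_rna, full = FALSE) {
    pr <- drop(ribo$P %*% w_ribo); mr <- drop(ribo$M %*% w_ribo)
    pn <- drop(rna$P %*% w_rna); mn <- drop(rna$M %*% w_rna)
    eligible <- (pr + mr > min_total) & (pn + mn > min_total) &
      (pr + pn >= min_allele) & (mr + mn >= min_allele)
    res <- tibble(gene_id = genes, ribo_paternal = pr, ribo_maternal = mr,
                  rna_paternal = pn, rna_maternal = mn,
                  eligible = eligible, statistic = NA_real_,
                  p_value = NA_real_, diff = NA_real_,
                  conf_lo = NA_real_, conf_hi = NA_real_, padj = NA_real_)
    if (any(eligible)) {
      tt <- two_proportion_test(pr[eligible], pr[eligible] + mr[eligible],
                                pn[eligible], pn[eligible] + mn[eligible])
      res$statistic[eligible] <- tt$statistic
      res$p_value[eligible] <- tt$p_value
      res$diff[eligible] <- tt$diff
      res$conf_lo[eligible] <- tt$conf_lo
      res$conf_hi[eligible] <- tt$conf_hi
      effect_ok <- eligible
      effect_ok[eligible] <- tt$conf_lo >= ci_guard | tt$conf_hi <= -ci_guard
      res$padj[effect_ok] <- p.adjust(res$p_value[effect_ok], method = "BH")
      significant <- !is.na(res$padj) & res$padj < fdr & mii_paternal == 0
    } else {
      significant <- rep(FALSE, length(genes))
    }
    if (full) list(table = res, significant = significant) else significant
  }

  full <- run_once(rep(1, ribo$n_reps), rep(1, rna$n_reps), full = TRUE)

  set.seed(seed)
  support <- rep(0L, length(genes))
  for (b in seq_len(B)) {
    w_ribo <- tabulate(sample.int(ribo$n_reps, replace = TRUE), ribo$n_reps)
    w_rna <- tabulate(sample.int(rna$n_reps, replace = TRUE), rna$n_reps)
    support <- support + run_once(w_ribo, w_rna)
  }

  out <- full$table |>
    mutate(mii_paternal = mii_paternal,
           significant_full = full$significant,
           support = support, B = B,
           called = support >= support_frac * B)
  if (!is.null(error_estimates)) {
    out <- out |>
      mutate(
        ribo_corrected_pct = as.numeric(correct_paternal_ratio(
          paternal_ratio(.data$ribo_paternal, .data$ribo_maternal),
          error_estimates[["ribo"]])),
        rna_corrected_pct = as.numeric(correct_paternal_ratio(
          paternal_ratio(.data$rna_paternal, .data$rna_maternal),
          error_estimates[["rna"]])))
  }
  structure(list(calls = out, stage = stage, B = B,
                 support_frac = support_frac, fdr = fdr),
            class = "allelic_engagement")
}

#' @export
print.allelic_engagement <- function(x, ...) {
  cat(sprintf("<allelic_engagement> stage %s: %d gene(s) called (of %d tested; %d bootstraps, support >= %.0f%%)\n",
              x$stage, sum(x$calls$called), sum(x$calls$eligible),
              x$B, 100 * x$support_frac))
  invisible(x)
}

#' Classify genes by allelic bias in RNA expression
#'
#' Genes with at least `min_reads` parent-of-origin differentiating reads
#' are classified by a replicate bootstrap: in each of `B` resamples,
#' replicate labels are drawn with replacement (as many as observed),
#' reads are pooled over replicates and SNPs, and the raw paternal
#' fraction `paternal / (paternal + maternal)` is computed. A gene is
#' paternally biased when the fraction exceeds `bias_threshold` in at
#' least `support_frac * B` resamples, maternally biased when it falls
#' below `1 - bias_threshold` likewise, and biallelic otherwise. Genes
#' whose pooled full-data counts contain only one allele are additionally
#' flagged monoallelic. Biased genes supported by multiple SNPs - at
#' least `multi_snp_frac` of a gene's SNPs having a pseudocounted paternal
#' ratio on the biased side of 50% - receive a high-confidence flag.
#'
#' @param allele_counts Allele count table for one stage and modality
#'   (typically four-cell or eight-cell RNA expression).
#' @param min_reads Minimum pooled parent-of-origin reads.
#' @param bias_threshold Paternal-fraction threshold defining bias.
#' @param support_frac Required fraction of supporting bootstrap samples.
#' @param multi_snp_frac Required fraction of concordant SNPs for the
#'   high-confidence tier.
#' @param B Number of bootstrap samples.
#' @param seed Seed for the bootstrap stream.
#' @return An `allelic_calls` object wrapping a per-gene tibble:
#'   pooled counts, `ratio`, bootstrap supports, `category`
#'   (`paternal_biased` / `maternal_biased` / `biallelic`), `monoallelic`,
#'   `n_snps`, `high_confidence`.
#' @export
classify_allelic_bias <- function(allele_counts, min_reads = 10L,
                                  bias_threshold = 0.7, support_frac = 0.8,
                                  multi_snp_frac = 0.6, B = 1000L, seed = 1L) {
  if (B < 1) abort("`B` must be at least 1.")
  pooled <- allele_counts |>
    group_by(.data$gene_id) |>
    summarise(paternal = sum(.data$paternal_count),
              maternal = sum(.data$maternal_count), .groups = "drop") |>
    filter(.data$paternal + .data$maternal >= min_reads)
  if (nrow(pooled) == 0) abort("No genes pass the minimum-read filter.")
  genes <- pooled$gene_id
  mats <- allele_rep_matrices(
    semi_join(allele_counts, pooled, by = "gene_id"),
    allele_counts$modality[1], genes)

  set.seed(seed)
  pat_support <- mat_support <- rep(0L, length(genes))
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(mats$n_reps, replace = TRUE), mats$n_reps)
    p <- drop(mats$P %*% w)
    m <- drop(mats$M %*% w)
    tot <- p + m
    ratio <- ifelse(tot > 0, p / tot, NA_real_)
    pat_support <- pat_support + (!is.na(ratio) & ratio > bias_threshold)
    mat_support <- mat_support + (!is.na(ratio) & ratio < 1 - bias_threshold)
  }
  need <- support_frac * B
  category <- dplyr::case_when(
    pat_support >= need ~ "paternal_biased",
    mat_support >= need ~ "maternal_biased",
    TRUE ~ "biallelic")

  snp_side <- allele_counts |>
    semi_join(pooled, by = "gene_id") |>
    group_by(.data$gene_id, .data$snp_id) |>
    summarise(p = sum(.data$paternal_count), m = sum(.data$maternal_count),
              .groups = "drop") |>
    mutate(pseudo_ratio = paternal_ratio(.data$p, .data$m) / 100) |>
    group_by(.data$gene_id) |>
    summarise(n_snps = n(),
              frac_paternal_side = mean(.data$pseudo_ratio > 0.5),
              frac_maternal_side = mean(.data$pseudo_ratio < 0.5))

  out <- pooled |>
    mutate(ratio = .data$paternal / (.data$paternal + .data$maternal),
           support_paternal = pat_support, support_maternal = mat_support,
           B = B, category = category,
           monoallelic = (.data$paternal == 0 | .data$maternal == 0) &
             category != "biallelic") |>
    left_join(snp_side, by = "gene_id") |>
    mutate(high_confidence = dplyr::case_when(
      category == "paternal_biased" ~ .data$frac_paternal_side >= multi_snp_frac,
      category == "maternal_biased" ~ .data$frac_maternal_side >= multi_snp_frac,
      TRUE ~ FALSE))
  structure(list(calls = out, B = B, bias_threshold = bias_threshold,
                 support_frac = support_frac),
            class = "allelic_calls")
}

#' @export
print.allelic_calls <- function(x, ...) {
  tab <- table(x$calls$category)
  cat(sprintf("<allelic_calls> %d genes: %s | %d monoallelic, %d high-confidence\n",
              nrow(x$calls),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              sum(x$calls$monoallelic), sum(x$calls$high_confidence)))
  invisible(x)
}

#' Compare translation efficiency between gene groups
#'
#' Two-sided Wilcoxon rank sum test between the translation efficiencies
#' of two gene sets, with the fold change reported as the ratio of group
#' medians on the ratio-scale efficiency.
#'
#' @param te A [compute_te()] table (or any tibble with `gene_id`, `te`).
#' @param group_a,group_b Character vectors of gene identifiers (e.g.
#'   allele-biased and biallelic genes).
#' @return One-row tibble: `n_a`, `n_b`, `median_a`, `median_b`,
#'   `fold_change`, `p_value`.
#' @export
compare_te_groups <- function(te, group_a, group_b) {
  assert_columns(te, c("gene_id", "te"), "te")
  a <- filter(te, .data$gene_id %in% group_a, !is.na(.data$te))$te
  b <- filter(te, .data$gene_id %in% group_b, !is.na(.data$te))$te
  if (length(a) == 0 || length(b) == 0) {
    abort("Both groups must contain genes with defined translation efficiency.")
  }
  w <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(n_a = length(a), n_b = length(b),
         median_a = median(a), median_b = median(b),
         fold_change = median(a) / median(b), p_value = w$p.value)
}

#' Match biallelic control genes on abundance and CDS length
#'
#' Selects, for each allele-biased gene, the nearest unused biallelic gene
#' in standardized (log RNA abundance, log CDS length) space - 1:1 greedy
#' nearest-neighbour matching without replacement, in seeded random order.
#' Kolmogorov-Smirnov distances between the matched covariate
#' distributions quantify balance.
#'
#' @param biased_genes,biallelic_genes Character vectors of gene ids.
#' @param covariates Tibble `gene_id`, `rna_abundance`, `cds_len`.
#' @param seed Seed fixing the matching order.
#' @return A list with `matches` (tibble `biased_gene`, `control_gene`,
#'   `distance`) and `balance` (KS distances per covariate).
#' @export
match_biallelic_controls <- function(biased_genes, biallelic_genes,
                                     covariates, seed = 1L) {
  assert_columns(covariates, c("gene_id", "rna_abundance", "cds_len"),
                 "covariates")
  if (length(biallelic_genes) < length(biased_genes)) {
    abort("Need at least as many biallelic genes as biased genes.")
  }
  pool <- filter(covariates, .data$gene_id %in% c(biased_genes, biallelic_genes)) |>
    mutate(z_abund = as.numeric(scale(log(.data$rna_abundance))),
           z_len = as.numeric(scale(log(.data$cds_len))))
  z <- as.matrix(pool[, c("z_abund", "z_len")])
  rownames(z) <- pool$gene_id
  if (!all(biased_genes %in% pool$gene_id) ||
      !all(biallelic_genes %in% pool$gene_id)) {
    abort("All genes must be present in `covariates`.")
  }
  set.seed(seed)
  order_b <- sample(biased_genes)
  available <- biallelic_genes
  matches <- purrr::map_dfr(order_b, function(g) {
    dd <- sqrt(colSums((t(z[available, , drop = FALSE]) - z[g, ])^2))
    k <- which.min(dd)
    hit <- tibble(biased_gene = g, control_gene = available[k],
                  distance = dd[k])
    available <<- available[-k]
    hit
  })
  ks <- function(col) {
    suppressWarnings(ks.test(z[matches$biased_gene, col],
                             z[matches$control_gene, col]))$statistic
  }
  list(matches = arrange(matches, .data$biased_gene),
       balance = tibble(covariate = c("log_rna_abundance", "log_cds_len"),
                        ks_distance = c(unname(ks("z_abund")),
                                        unname(ks("z_len")))))
}
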