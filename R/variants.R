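#' Construct a position weight matrix object
#'
#' @param name RNA-binding protein name.
#' @param matrix Numeric matrix, motif positions in rows and columns
#'   `A`, `C`, `G`, `T` (RNA alphabets with `U` are accepted and mapped
#'   to `T`). At least 3 positions.
#' @param consensus Optional consensus string; derived from the
#'   per-position argmax when missing.
#' @return A `pwm` object.
#' @export
pwm <- function(name, matrix, consensus = NULL) {
  m <- as.matrix(matrix)
  colnames(m) <- sub("U", "T", toupper(colnames(m)))
  if (!all(BASES %in% colnames(m))) {
    abort("PWM must have columns A, C, G, T (or U).")
  }
  m <- m[, BASES, drop = FALSE]
  if (nrow(m) < 3) abort("PWM must have at least 3 positions.")
  if (any(!is.finite(m))) abort("PWM weights must be finite.")
  if (is.null(consensus)) {
    consensus <- paste(BASES[max.col(m, ties.method = "first")], collapse = "")
  }
  structure(list(name = name, matrix = m, consensus = consensus,
                 width = nrow(m)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%d nt, consensus %s)\n", x$name, x$width, x$consensus))
  invisible(x)
}

#' Read position weight matrices from a TSV file
#'
#' Expected columns: `rbp`, `pwm_id`, `pos` (1-based), and base weights
#' `A`, `C`, `G`, `T`/`U`; one row per motif position.
#'
#' @param path TSV file path.
#' @return Named list of [pwm()] objects (one per `pwm_id`).
#' @export
read_pwm_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  names(d) <- sub("^U$", "T", names(d))
  assert_columns(d, c("rbp", "pwm_id", "pos", "A", "C", "G", "T"), "pwm table")
  split(d, d$pwm_id) |>
    purrr::map(function(x) {
      x <- arrange(x, .data$pos)
      pwm(x$rbp[1], as.matrix(x[, BASES]))
    })
}

#' Matrix similarity score of a sequence window
#'
#' Min-max normalized additive PWM score: the per-position weights of the
#' observed bases are summed and rescaled by the minimal and maximal
#' attainable sums, giving a score in \[0, 1\] - 1 for the per-position
#' argmax (consensus) sequence and 0 for the per-position argmin. For a
#' fully degenerate PWM (equal weights everywhere) the score is defined
#' as 0.5; any allele swap then yields a difference of zero. The score is
#' invariant to affine rescaling of the PWM.
#'
#' @param window Character sequence of the motif's width (A/C/G/T, or U).
#' @param pwm A [pwm()] object.
#' @return Score in \[0, 1\].
#' @export
matrix_similarity_score <- function(window, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  w <- strsplit(chartr("U", "T", toupper(window)), "")[[1]]
  if (length(w) != pwm$width) {
    abort(sprintf("Window length %d does not match motif width %d.",
                  length(w), pwm$width))
  }
  idx <- match(w, BASES)
  if (anyNA(idx)) abort("Window contains an ambiguous or non-ACGT base.")
  s <- sum(pwm$matrix[cbind(seq_len(pwm$width), idx)])
  s_min <- sum(apply(pwm$matrix, 1, min))
  s_max <- sum(apply(pwm$matrix, 1, max))
  if (s_max == s_min) return(0.5)
  (s - s_min) / (s_max - s_min)
}

#' Score SNP effects on RNA-binding-protein motifs
#'
#' For each SNP, every motif window overlapping the SNP position is
#' scored on the maternal and the paternal sequence with
#' [matrix_similarity_score()], and the allelic score difference
#' (paternal minus maternal) with the largest absolute value across
#' windows represents that (SNP, PWM) pair. The procedure then follows
#' the standard collapse-and-standardize scheme:
#'
#' 1. SNPs lying within `min_snp_gap` nt of another SNP on the same
#'    transcript are removed (their windows confound two substitutions);
#' 2. for RBPs with several PWMs, the signed difference with maximal
#'    absolute value is kept;
#' 3. RBPs sharing a consensus motif at the same SNP are collapsed into
#'    one comma-joined annotation with the median difference;
#' 4. differences are robust-standardized globally
#'    (`(x - median) / IQR`);
#' 5. SNPs at or above the `percentile`-th percentile of the absolute
#'    standardized difference are flagged `selected`.
#'
#' @param snps SNP tibble (`snp_id`, `gene_id`, `pos`, `maternal_allele`,
#'   `paternal_allele`).
#' @param annotation Gene annotation including the (maternal) transcript
#'   `sequence`.
#' @param pwms List of [pwm()] objects.
#' @param percentile Selection percentile on \|standardized difference\|.
#' @param min_snp_gap Minimum spacing (nt) between SNPs on a transcript.
#' @param exclude_rbps Optional character vector of RBP names to drop
#'   (e.g. RBPs without a homologue or without detectable expression).
#' @return A `snp_motif_effects` tibble: `snp_id`, `gene_id`, `rbp`,
#'   `consensus`, `raw_diff`, `standardized`, `selected`.
#' @export
score_snp_motif_effects <- function(snps, annotation, pwms, percentile = 95,
                                    min_snp_gap = 5L, exclude_rbps = NULL) {
  assert_columns(snps, c("snp_id", "gene_id", "pos", "maternal_allele",
                         "paternal_allele"), "snps")
  assert_columns(annotation, c("gene_id", "sequence"), "annotation")
  if (!is.null(exclude_rbps)) {
    pwms <- purrr::keep(pwms, ~ !.x$name %in% exclude_rbps)
  }
  if (length(pwms) == 0) abort("No PWMs to score.")

  # proximity filter: drop every SNP with a neighbour closer than min_snp_gap
  keep <- snps |>
    group_by(.data$gene_id) |>
    arrange(.data$pos, .by_group = TRUE) |>
    mutate(d_prev = .data$pos - dplyr::lag(.data$pos, default = -1e9),
           d_next = dplyr::lead(.data$pos, default = 1e9) - .data$pos) |>
    ungroup() |>
    filter(.data$d_prev >= min_snp_gap, .data$d_next >= min_snp_gap)

  seqs <- setNames(annotation$sequence, annotation$gene_id)
  # per-PWM normalization constants; the additive score difference between
  # alleles reduces to the weight gap at the SNP's in-motif position over
  # the min-max range, so windows are scored without rebuilding strings
  pwm_denom <- vapply(pwms, function(p) {
    sum(apply(p$matrix, 1, max)) - sum(apply(p$matrix, 1, min))
  }, numeric(1))
  pwm_names <- vapply(pwms, `[[`, character(1), "name")
  pwm_cons <- vapply(pwms, `[[`, character(1), "consensus")
  effects <- purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    s <- keep[i, ]
    seq_full <- seqs[[s$gene_id]]
    if (is.null(seq_full)) abort(sprintf("No sequence for gene '%s'.", s$gene_id))
    mat_i <- match(s$maternal_allele, BASES)
    pat_i <- match(s$paternal_allele, BASES)
    purrr::map_dfr(seq_along(pwms), function(k) {
      p <- pwms[[k]]
      lo <- max(0L, s$pos - p$width + 1L)
      hi <- min(s$pos, nchar(seq_full) - p$width)
      if (hi < lo || pwm_denom[k] == 0) return(NULL)
      at <- s$pos - (lo:hi) + 1L # SNP's position within each window
      diffs <- (p$matrix[cbind(at, pat_i)] - p$matrix[cbind(at, mat_i)]) /
        pwm_denom[k]
      tibble(snp_id = s$snp_id, gene_id = s$gene_id, rbp = pwm_names[k],
             consensus = pwm_cons[k],
             diff = diffs[which.max(abs(diffs))])
    })
  })
  if (nrow(effects) == 0) {
    out <- tibble(snp_id = character(), gene_id = character(),
                  rbp = character(), consensus = character(),
                  raw_diff = numeric(), standardized = numeric(),
                  selected = logical())
    class(out) <- c("snp_motif_effects", class(out))
    return(out)
  }
  collapsed <- effects |>
    # per RBP keep the PWM whose |difference| is maximal
    group_by(.data$snp_id, .data$gene_id, .data$rbp, .data$consensus) |>
    summarise(diff = .data$diff[which.max(abs(.data$diff))], .groups = "drop") |>
    # RBPs sharing a consensus at the same SNP: median difference
    group_by(.data$snp_id, .data$gene_id, .data$consensus) |>
    summarise(rbp = paste(sort(unique(.data$rbp)), collapse = ","),
              raw_diff = median(.data$diff), .groups = "drop")
  iqr <- stats::IQR(collapsed$raw_diff)
  if (iqr == 0) abort("Degenerate score-difference distribution (IQR = 0).")
  collapsed <- collapsed |>
    mutate(standardized = (.data$raw_diff - median(.data$raw_diff)) / iqr,
           selected = abs(.data$standardized) >=
             quantile(abs(.data$standardized), percentile / 100)) |>
    select("snp_id", "gene_id", "rbp", "consensus", "raw_diff",
           "standardized", "selected")
  class(collapsed) <- c("snp_motif_effects", class(collapsed))
  collapsed
}

#' Default RBP exclusion list
#'
#' RNA-binding proteins excluded from SNP motif-effect scoring because
#' they have no mouse homologue or no detectable expression across the
#' profiled developmental stages.
#'
#' @return Character vector of RBP names.
#' @export
default_rbp_exclusions <- function() {
  readLines(system.file("extdata", "rbp_exclude.txt", package = "riboallele"))
}

# 9-nt initiation-context pattern: ..R..VTGR.. layout centred on the SNP
UORF_PATTERN <- "[ATCG]+[AG]{1}[ATCG]{2}[ACG]{1}TG[AG]{1}[ATCG]+"

#' Find 5'UTR SNPs that create or destroy translation-initiation contexts
#'
#' Tests, for each 5'UTR SNP, whether the 9-nt window centred on the SNP
#' matches the non-canonical initiation-context pattern
#' `[ATCG]+[AG][ATCG]{2}[ACG]TG[AG][ATCG]+` under the maternal and/or the
#' paternal allele - candidate upstream open reading frame (uORF) starts,
#' which typically repress main-ORF translation. SNPs whose window runs
#' outside the transcript are skipped and tallied.
#'
#' @param snps SNP tibble; only rows with `region == "5UTR"` are tested
#'   when a `region` column is present.
#' @param annotation Gene annotation including transcript `sequence`.
#' @param efficiency_table Optional lookup tibble `context`, `efficiency`
#'   mapping -4..+4 initiation contexts (9 nt) to measured initiation
#'   efficiencies; matching windows are annotated per allele.
#' @return Tibble of candidate SNPs with `window_maternal`,
#'   `window_paternal`, `match_maternal`, `match_paternal` (and optional
#'   efficiencies); SNPs with no matching allele are absent. The number
#'   of skipped out-of-bounds SNPs is in attribute `n_skipped`.
#' @export
find_uorf_candidates <- function(snps, annotation, efficiency_table = NULL) {
  assert_columns(snps, c("snp_id", "gene_id", "pos", "maternal_allele",
                         "paternal_allele"), "snps")
  assert_columns(annotation, c("gene_id", "sequence"), "annotation")
  d <- if ("region" %in% names(snps)) filter(snps, .data$region == "5UTR") else snps
  d <- inner_join(d, select(annotation, "gene_id", "sequence"), by = "gene_id")
  in_bounds <- d$pos >= 4L & d$pos + 4L < nchar(d$sequence)
  n_skipped <- sum(!in_bounds)
  d <- d[in_bounds, ]
  win <- substr(d$sequence, d$pos - 3L, d$pos + 5L) # 9 nt centred (0-based pos)
  d <- d |>
    mutate(window_maternal = `substr<-`(win, 5L, 5L, value = .data$maternal_allele),
           window_paternal = `substr<-`(win, 5L, 5L, value = .data$paternal_allele),
           match_maternal = grepl(UORF_PATTERN, .data$window_maternal),
           match_paternal = grepl(UORF_PATTERN, .data$window_paternal)) |>
    filter(.data$match_maternal | .data$match_paternal) |>
    select("snp_id", "gene_id", "pos", "maternal_allele", "paternal_allele",
           "window_maternal", "window_paternal",
           "match_maternal", "match_paternal")
  if (!is.null(efficiency_table)) {
    assert_columns(efficiency_table, c("context", "efficiency"),
                   "efficiency_table")
    d <- d |>
      left_join(rename(efficiency_table, window_maternal = "context",
                       efficiency_maternal = "efficiency"),
                by = "window_maternal") |>
      left_join(rename(efficiency_table, window_paternal = "context",
                       efficiency_paternal = "efficiency"),
                by = "window_paternal")
  }
  attr(d, "n_skipped") <- n_skipped
  d
}
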