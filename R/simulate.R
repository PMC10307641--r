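#' Simulate a transcriptome with strain-distinguishing SNPs
#'
#' Draws one transcript per gene with 5'UTR / CDS / 3'UTR lengths sampled
#' from the configured ranges (CDS a multiple of 3, starting with ATG and
#' ending in a stop codon), a random maternal sequence, a log-normal
#' relative abundance, and Poisson-distributed strain SNPs at
#' `snp_rate` per kilobase. The maternal allele is the reference base of
#' the transcript sequence; the paternal allele is a different base.
#'
#' Coordinates are 0-based, half-open throughout.
#'
#' @param config A [sim_config()].
#' @return A `transcriptome`: list with tibbles `genes`
#'   (`gene_id`, `utr5_len`, `cds_len`, `utr3_len`, `tx_len`,
#'   `expression_level`, `sequence`) and `snps`
#'   (`snp_id`, `gene_id`, `pos`, `maternal_allele`, `paternal_allele`,
#'   `region`).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "transcriptome"))
  n <- config$n_genes
  utr5 <- sample_range(config$utr5_range[1], config$utr5_range[2], n)
  cds <- 3L * sample_range(ceiling(config$cds_range[1] / 3),
                           floor(config$cds_range[2] / 3), n)
  utr3 <- sample_range(config$utr3_range[1], config$utr3_range[2], n)
  tx_len <- utr5 + cds + utr3
  stops <- c("TAA", "TAG", "TGA")
  sequence <- vapply(seq_len(n), function(i) {
    s <- sample(BASES, tx_len[i], replace = TRUE)
    s[utr5[i] + 1:3] <- c("A", "T", "G")
    s[utr5[i] + cds[i] - (2:0)] <- strsplit(sample(stops, 1), "")[[1]]
    paste(s, collapse = "")
  }, character(1))
  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(n)),
    utr5_len = as.integer(utr5), cds_len = as.integer(cds),
    utr3_len = as.integer(utr3), tx_len = as.integer(tx_len),
    expression_level = rlnorm(n, 0, 1),
    sequence = sequence
  )
  n_snp <- rpois(n, config$snp_rate * tx_len / 1000)
  n_snp <- pmin(n_snp, tx_len)
  snps <- purrr::map_dfr(seq_len(n), function(i) {
    if (n_snp[i] == 0) return(NULL)
    pos <- sort(sample.int(tx_len[i], n_snp[i]) - 1L)
    mat <- strsplit(genes$sequence[i], "")[[1]][pos + 1L]
    tibble(
      gene_id = genes$gene_id[i], pos = pos,
      maternal_allele = mat, paternal_allele = other_base(mat),
      region = position_region(pos, utr5[i], cds[i])
    )
  })
  if (nrow(snps) == 0) {
    snps <- tibble(snp_id = character(), gene_id = character(),
                   pos = integer(), maternal_allele = character(),
                   paternal_allele = character(), region = character())
  } else {
    snps <- snps |>
      mutate(snp_id = paste0(.data$gene_id, "_", .data$pos)) |>
      select("snp_id", "gene_id", "pos", "maternal_allele",
             "paternal_allele", "region")
  }
  structure(list(genes = genes, snps = snps), class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> %d genes, %d SNPs\n",
              nrow(x$genes), nrow(x$snps)))
  invisible(x)
}

random_umis <- function(n, len) {
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

resolve_stage <- function(config, stage) {
  if (inherits(stage, "stage_spec")) return(stage)
  for (s in config$stages) if (s$stage == stage) return(s)
  abort(sprintf("Stage '%s' not found in config.", stage))
}

#' Simulate one replicate library of aligned reads
#'
#' Draws `n_reads` molecules for one (stage, modality, replicate) library.
#' Each molecule picks a gene proportionally to its expression level
#' (times any planted translation-efficiency multiplier for ribosome
#' footprints), a parental origin by a Bernoulli draw at the stage's
#' paternal fraction (with per-gene overrides), and a position:
#'
#' * Ribosome footprints sample a length from the configured length
#'   distribution; with probability `frame_fidelity` the A-site
#'   (5' end + per-length offset) lands on a codon boundary of the CDS,
#'   otherwise in frame 1 or 2. A-sites are uniform over CDS codons.
#' * RNA-seq reads have fixed length and a uniform 5' position over the
#'   transcript.
#'
#' Observed bases at covered SNPs are initialised to the true parental
#' allele; apply [inject_errors()] afterwards to add substitution error.
#'
#' @param transcriptome A [simulate_transcriptome()] result.
#' @param config A [sim_config()].
#' @param stage Stage name or [stage_spec()].
#' @param modality `"ribo"` or `"rna"`.
#' @param replicate Replicate index (1-based, RNG stream is sub-seeded per
#'   stage/modality/replicate).
#' @param n_reads Molecules to draw; defaults to the stage's
#'   `reads_per_replicate`.
#' @return Read table tibble: `read_id`, `sample_id`, `stage`, `replicate`,
#'   `modality`, `gene_id`, `five_prime_pos`, `length`, `umi`,
#'   `true_allele`, `snp_obs` (encoded `"snp:base;snp:base"`, `""` if the
#'   read covers no SNP).
#' @export
simulate_reads <- function(transcriptome, config, stage, modality = c("ribo", "rna"),
                           replicate = 1L, n_reads = NULL) {
  modality <- match.arg(modality)
  st <- resolve_stage(config, stage)
  n_rep <- if (modality == "ribo") st$n_ribo else st$n_rna
  if (n_rep < 1) abort(sprintf("Stage '%s' has 0 %s replicates.", st$stage, modality))
  if (replicate > n_rep) {
    abort(sprintf("Replicate %d requested but stage '%s' has %d %s replicates.",
                  replicate, st$stage, n_rep, modality))
  }
  set.seed(derive_seed(config$seed, st$stage, modality, replicate))
  genes <- transcriptome$genes
  n <- as.integer(n_reads %||% st$reads_per_replicate)

  w <- genes$expression_level
  if (modality == "ribo" && !is.null(st$te_multipliers)) {
    mult <- st$te_multipliers$multiplier[match(genes$gene_id, st$te_multipliers$gene_id)]
    w <- w * dplyr::coalesce(mult, 1)
  }
  gi <- sample.int(nrow(genes), n, replace = TRUE, prob = w)

  pf <- rep(st$paternal_fraction, nrow(genes))
  if (!is.null(st$gene_overrides)) {
    go <- st$gene_overrides
    pick <- function(col) {
      if (col %in% names(go)) go[[col]][match(genes$gene_id, go$gene_id)]
      else rep(NA_real_, nrow(genes))
    }
    ov <- dplyr::coalesce(pick(paste0("paternal_fraction_", modality)),
                          pick("paternal_fraction"))
    pf <- dplyr::coalesce(ov, pf)
  }
  true_allele <- if_else(runif(n) * 100 < pf[gi], "paternal", "maternal")

  cds_start <- genes$utr5_len[gi]
  tx_len <- genes$tx_len[gi]
  if (modality == "ribo") {
    probs <- config$footprint_len_probs
    len <- as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
    off <- as.integer(config$asite_offsets[as.character(len)])
    cds_end <- cds_start + genes$cds_len[gi]
    a_min <- pmax(off, cds_start)
    a_max <- pmin(cds_end - 1L, tx_len - len + off)
    if (any(a_max < a_min + 2L)) {
      abort("Transcript geometry too tight for the footprint length/offset configuration; widen the UTR ranges.")
    }
    fshift <- if_else(runif(n) < config$frame_fidelity, 0L,
                      sample(1:2, n, replace = TRUE))
    k_min <- as.integer(ceiling((a_min - cds_start) / 3))
    k_max <- pmax(k_min, as.integer(floor((a_max - fshift - cds_start) / 3)))
    n_cod <- k_max - k_min + 1L
    if (config$start_bias == 1 && config$stop_bias == 1) {
      k <- k_min + as.integer(floor(runif(n) * n_cod))
    } else {
      # weighted codon draw: first codon carries start_bias, last stop_bias,
      # interior codons weight 1 (falls back to uniform when too few codons)
      sb <- config$start_bias
      eb <- config$stop_bias
      u <- runif(n) * (pmax(n_cod - 2L, 0L) + sb + eb)
      k <- if_else(
        n_cod < 3L,
        k_min + as.integer(floor(runif(n) * n_cod)),
        if_else(u < sb, k_min,
                if_else(u < sb + eb, k_max,
                        pmin(k_min + 1L + as.integer(floor(u - sb - eb)),
                             k_max - 1L))))
    }
    five <- cds_start + 3L * k + fshift - off
  } else {
    len <- rep(config$rna_read_length, n)
    if (any(tx_len < len)) abort("RNA read length exceeds a transcript length.")
    five <- as.integer(floor(runif(n) * (tx_len - len + 1L)))
  }

  reads <- tibble(
    read_id = sprintf("%s_%s_rep%d_%07d", st$stage, modality, replicate, seq_len(n)),
    sample_id = sample_id_of(st$stage, modality, replicate),
    stage = st$stage, replicate = as.integer(replicate), modality = modality,
    gene_id = genes$gene_id[gi],
    five_prime_pos = as.integer(five), length = as.integer(len),
    umi = random_umis(n, config$umi_length),
    true_allele = true_allele
  )
  reads$snp_obs <- observe_snps(reads, transcriptome$snps)
  reads
}

# True-allele SNP observations for each read, encoded "snp:base;snp:base".
observe_snps <- function(reads, snps) {
  if (nrow(snps) == 0 || nrow(reads) == 0) return(rep("", nrow(reads)))
  hits <- reads |>
    mutate(.row = row_number()) |>
    select(".row", "gene_id", "five_prime_pos", "length", "true_allele") |>
    inner_join(snps, by = "gene_id", relationship = "many-to-many") |>
    filter(.data$pos >= .data$five_prime_pos,
           .data$pos < .data$five_prime_pos + .data$length) |>
    mutate(obs = if_else(.data$true_allele == "paternal",
                         .data$paternal_allele, .data$maternal_allele)) |>
    arrange(.data$.row, .data$pos) |>
    group_by(.data$.row) |>
    summarise(snp_obs = paste0(.data$snp_id, ":", .data$obs, collapse = ";"))
  out <- rep("", nrow(reads))
  out[hits$.row] <- hits$snp_obs
  out
}

#' Inject random substitution sequencing errors at SNP positions
#'
#' Models per-read substitution error: independently for each read that
#' covers at least one SNP, with probability `error_pct`/100 the read is
#' an error read and the observed base at every covered SNP is replaced by
#' one of the three other nucleotides, uniformly. Under this model a
#' maternal-origin observation is seen as the paternal allele with
#' probability `error_pct`/300, matching the assumption that sequencing
#' errors are random across bases.
#'
#' @param reads Read table (see [simulate_reads()]).
#' @param error_pct Error percentage in \[0, 100\].
#' @param seed Optional seed for reproducibility of the error draw.
#' @return The read table with `snp_obs` rewritten on error reads.
#' @export
inject_errors <- function(reads, error_pct, seed = NULL) {
  if (error_pct < 0 || error_pct > 100) abort("`error_pct` must lie in [0, 100].")
  if (!is.null(seed)) set.seed(seed)
  if (error_pct == 0 || nrow(reads) == 0) return(reads)
  covered <- which(!is.na(reads$snp_obs) & reads$snp_obs != "")
  if (length(covered) == 0) return(reads)
  err <- covered[runif(length(covered)) < error_pct / 100]
  if (length(err) == 0) return(reads)
  obs <- strsplit(reads$snp_obs[err], ";", fixed = TRUE)
  lens <- lengths(obs)
  flat <- unlist(obs, use.names = FALSE)
  snp <- sub(":[ACGT]$", "", flat)
  base <- substr(flat, nchar(flat), nchar(flat))
  renew <- paste0(snp, ":", other_base(base))
  grp <- factor(rep(seq_along(err), lens), levels = seq_along(err))
  reads$snp_obs[err] <- vapply(split(renew, grp), paste, character(1), collapse = ";")
  reads
}

#' Add PCR duplicates
#'
#' Emits, for each molecule, a Poisson(`rate`) number of extra copies that
#' share the UMI, position, length and SNP observations of the original,
#' so that UMI-aware deduplication recovers the original molecule count
#' exactly (up to UMI collisions, negligible with 12-mers at these scales).
#'
#' @param reads Read table.
#' @param rate Expected extra copies per molecule; must be non-negative.
#' @param seed Optional seed.
#' @return Read table with duplicate rows appended in place (copies carry a
#'   `_dupN` suffix on `read_id`).
#' @export
apply_duplication <- function(reads, rate, seed = NULL) {
  if (rate < 0) abort("`rate` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || nrow(reads) == 0) return(reads)
  copies <- rpois(nrow(reads), rate)
  idx <- rep(seq_len(nrow(reads)), copies + 1L)
  out <- reads[idx, ]
  dup_n <- sequence(copies + 1L) - 1L
  out$read_id <- if_else(dup_n == 0L, out$read_id,
                         paste0(out$read_id, "_dup", dup_n))
  out
}

#' Simulate a full multi-stage experiment
#'
#' Runs [simulate_reads()] for every stage, modality and replicate in the
#' configuration, then applies [inject_errors()] (at the per-modality
#' configured rate) and [apply_duplication()]. All RNG streams are
#' sub-seeded from `config$seed`, so output is reproducible and
#' independent of execution order.
#'
#' @param config A [sim_config()].
#' @param transcriptome Optional pre-built transcriptome; simulated from
#'   `config` when `NULL`.
#' @param errors,duplication Toggle error injection / PCR duplication.
#' @return List with `transcriptome`, `reads` (all libraries bound into one
#'   tibble) and a `samples` sheet.
#' @export
simulate_experiment <- function(config, transcriptome = NULL,
                                errors = TRUE, duplication = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  tx <- transcriptome %||% simulate_transcriptome(config)
  pieces <- list()
  samples <- list()
  for (st in config$stages) {
    for (modality in c("ribo", "rna")) {
      n_rep <- if (modality == "ribo") st$n_ribo else st$n_rna
      err_pct <- if (modality == "ribo") config$ribo_error_pct else config$rna_error_pct
      for (r in seq_len(n_rep)) {
        reads <- simulate_reads(tx, config, st, modality, r)
        if (errors && err_pct > 0) {
          reads <- inject_errors(reads, err_pct,
                                 seed = derive_seed(config$seed, "err", st$stage, modality, r))
        }
        if (duplication && config$duplication_rate > 0) {
          reads <- apply_duplication(reads, config$duplication_rate,
                                     seed = derive_seed(config$seed, "dup", st$stage, modality, r))
        }
        pieces[[length(pieces) + 1L]] <- reads
        samples[[length(samples) + 1L]] <- tibble(
          sample_id = sample_id_of(st$stage, modality, r),
          stage = st$stage, modality = modality, replicate = r)
      }
    }
  }
  list(transcriptome = tx, reads = bind_rows(pieces), samples = bind_rows(samples))
}
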