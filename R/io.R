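#' @name riboallele-io
#' @title Plain-text interchange formats
#' @description All intermediate artifacts are plain TSV (plus FASTA for
#'   sequences and a minimal VCF for SNPs) so every pipeline step can be
#'   inspected with standard tools. Transcript coordinates are 0-based
#'   half-open internally; VCF POS is 1-based, converted at the reader and
#'   writer boundary only.
NULL

tsv_header <- function(seed = NULL, hash = NULL) {
  h <- sprintf("# riboallele %s", as.character(packageVersion("riboallele")))
  if (!is.null(seed)) h <- paste0(h, sprintf(" | seed=%s", seed))
  if (!is.null(hash)) h <- paste0(h, sprintf(" | config=%s", hash))
  h
}

#' Write a tibble as TSV with a provenance header comment
#'
#' @param x Tibble.
#' @param path Output path.
#' @param seed,hash Optional provenance fields embedded in the `#` header.
#' @export
write_tsv_stamped <- function(x, path, seed = NULL, hash = NULL) {
  writeLines(tsv_header(seed, hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_stamped()]
#' @param path File path.
#' @return Tibble (header comments skipped).
#' @export
read_tsv_stamped <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write transcript sequences as FASTA
#' @param sequences Named character vector (names are gene ids).
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  lines <- character(2L * length(sequences))
  lines[c(TRUE, FALSE)] <- paste0(">", names(sequences))
  lines[c(FALSE, TRUE)] <- unname(sequences)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr)) abort("Not a FASTA file: no '>' header found.")
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", sub("\\s.*$", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste, character(1),
                 collapse = "")
  setNames(toupper(unname(seqs)), headers)
}

#' Write strain SNPs as a minimal VCF
#'
#' CHROM is the transcript/gene id, POS is 1-based, REF the maternal and
#' ALT the paternal allele.
#'
#' @param snps SNP tibble (0-based `pos`).
#' @param path Output path.
#' @export
write_snp_vcf <- function(snps, path) {
  assert_columns(snps, c("snp_id", "gene_id", "pos", "maternal_allele",
                         "paternal_allele"), "snps")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  snps$gene_id, snps$pos + 1L, snps$snp_id,
                  snps$maternal_allele, snps$paternal_allele)
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=riboallele %s",
                       as.character(packageVersion("riboallele"))),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body), path)
  invisible(path)
}

#' Read strain SNPs from VCF
#'
#' REF is interpreted as the maternal and ALT as the paternal allele;
#' CHROM must be a transcript/gene identifier. POS is converted from
#' 1-based VCF convention to the package's 0-based coordinates.
#' Multi-allelic and non-SNP records are skipped with a warning;
#' structurally malformed records raise an error citing the record number.
#'
#' @param path VCF path (plain or gzipped).
#' @param annotation Optional gene annotation used to annotate each SNP's
#'   transcript region (5'UTR / CDS / 3'UTR).
#' @return SNP tibble.
#' @export
read_snp_vcf <- function(path, annotation = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) { # single record drops to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0) abort("VCF contains no records.")
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | pos < 1 | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]))
  if (length(bad) > 0) {
    abort(sprintf("Malformed VCF record %d (POS/REF/ALT invalid).", bad[1]))
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  multi <- grepl(",", alt, fixed = TRUE)
  not_snp <- nchar(ref) != 1 | (nchar(alt) != 1 & !multi) |
    !(ref %in% BASES)
  drop <- multi | not_snp
  if (any(drop)) {
    warn(sprintf("Skipping %d multi-allelic or non-SNP record(s).", sum(drop)))
  }
  keep <- !drop
  ids <- fix[keep, "ID"]
  out <- tibble(
    snp_id = if_else(is.na(ids) | ids == ".",
                     paste0(fix[keep, "CHROM"], "_", pos[keep] - 1L), ids),
    gene_id = fix[keep, "CHROM"],
    pos = pos[keep] - 1L,
    maternal_allele = ref[keep],
    paternal_allele = alt[keep])
  if (!is.null(annotation)) {
    assert_columns(annotation, c("gene_id", "utr5_len", "cds_len"), "annotation")
    out <- out |>
      left_join(select(annotation, "gene_id", "utr5_len", "cds_len"),
                by = "gene_id") |>
      mutate(region = position_region(.data$pos, .data$utr5_len, .data$cds_len)) |>
      select(-"utr5_len", -"cds_len")
  }
  out
}

#' Write the generator's artifacts to a directory
#'
#' Emits the transcript annotation TSV, transcript FASTA, SNP VCF, read
#' table TSV and sample sheet TSV for a simulated experiment.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @param seed,hash Provenance fields for the TSV headers.
#' @return Named character vector of written paths.
#' @export
write_simulation <- function(sim, dir, seed = NULL, hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sim$transcriptome$genes
  paths <- c(
    annotation = file.path(dir, "annotation.tsv"),
    fasta = file.path(dir, "transcripts.fa"),
    vcf = file.path(dir, "snps.vcf"),
    reads = file.path(dir, "reads.tsv"),
    samples = file.path(dir, "samples.tsv"))
  write_tsv_stamped(select(genes, "gene_id", "utr5_len", "cds_len",
                           "utr3_len", "expression_level"),
                    paths["annotation"], seed, hash)
  write_fasta(setNames(genes$sequence, genes$gene_id), paths["fasta"])
  write_snp_vcf(sim$transcriptome$snps, paths["vcf"])
  write_tsv_stamped(sim$reads, paths["reads"], seed, hash)
  write_tsv_stamped(sim$samples, paths["samples"], seed, hash)
  paths
}

#' Read a read table TSV
#' @param path File path.
#' @return Read table tibble with the column types the pipeline expects.
#' @export
read_reads_tsv <- function(path) {
  d <- read_tsv_stamped(path)
  assert_columns(d, c("read_id", "sample_id", "stage", "replicate", "modality",
                      "gene_id", "five_prime_pos", "length", "umi"), "reads")
  d$snp_obs <- dplyr::coalesce(as.character(d$snp_obs), "")
  d
}
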