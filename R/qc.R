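#' Stop-codon metagene profile of footprint 5' ends
#'
#' Aggregates, per footprint length, the number of 5' ends at each position
#' relative to the translation stop site, over all genes. The anchor
#' (position 0) is the first nucleotide of the stop codon. The per-length
#' peak upstream of the anchor is what calibrates the A-site offset.
#'
#' @param reads Deduplicated ribosome footprint table.
#' @param annotation Gene annotation with `gene_id`, `utr5_len`, `cds_len`.
#' @param window Integer window `c(from, to)` relative to the anchor.
#' @return Tibble `length`, `position`, `count`, complete over the window
#'   (zeros included), with class `metagene_profile`.
#' @export
stop_metagene <- function(reads, annotation, window = c(-40L, 10L)) {
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be c(from, to) with from <= to.")
  }
  assert_columns(annotation, c("gene_id", "utr5_len", "cds_len"), "annotation")
  lengths_present <- sort(unique(reads$length))
  if (length(lengths_present) == 0) lengths_present <- integer(0)
  counts <- reads |>
    inner_join(select(annotation, "gene_id", "utr5_len", "cds_len"),
               by = "gene_id") |>
    mutate(position = .data$five_prime_pos -
             (.data$utr5_len + .data$cds_len - 3L)) |>
    filter(.data$position >= window[1], .data$position <= window[2]) |>
    count(.data$length, .data$position, name = "count")
  out <- tidyr::crossing(length = lengths_present,
                         position = window[1]:window[2]) |>
    left_join(counts, by = c("length", "position")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Calibrate per-length A-site offsets from stop metagene profiles
#'
#' For each footprint length, the offset is the distance from the highest
#' 5'-end peak strictly upstream of the stop site to the stop site itself:
#' `offset = |argmax position < 0|`. Ties are broken toward the smaller
#' absolute position (the peak closest to the stop).
#'
#' @param profile A [stop_metagene()] profile.
#' @return Named integer vector, footprint length -> offset (nt).
#' @export
calibrate_asite_offsets <- function(profile) {
  assert_columns(profile, c("length", "position", "count"), "profile")
  up <- filter(profile, .data$position < 0)
  offsets <- up |>
    group_by(.data$length) |>
    summarise(all_zero = all(.data$count == 0),
              offset = {
                m <- max(.data$count)
                cand <- .data$position[.data$count == m]
                -max(cand) # position closest to 0, i.e. smallest |position|
              })
  bad <- offsets$length[offsets$all_zero]
  if (length(bad) > 0) {
    abort(sprintf("No upstream signal to calibrate offset for length(s): %s",
                  paste(bad, collapse = ", ")))
  }
  setNames(as.integer(offsets$offset), offsets$length)
}

seq_context <- function(sequence, at, n) {
  substr(sequence, at + 1L, at + n)
}

#' Reading-frame periodicity statistic
#'
#' The frame of a footprint is `(5' position - cds_start) mod 3`.
#' Footprints are partitioned into groups by length and by their 3'-end
#' sequence context (the 2 nt upstream of the 3' end and 1 nt downstream),
#' which absorbs ligation/digestion sequence preferences. Within each
#' group the frame counts (S0, S1, S2) are cyclically shifted so the
#' maximum lands in the first component; shifted triplets are then summed
#' component-wise into (T0, T1, T2) and compared against the uniform
#' expectation (sum/3 per frame) with a chi-squared test on 2 degrees of
#' freedom (upper tail).
#'
#' Footprints whose 3' end lies within 1 nt of the transcript end have an
#' undefined downstream context; they are excluded from grouping and
#' reported in the exclusion tally.
#'
#' @param reads Deduplicated ribosome footprint table.
#' @param annotation Gene annotation including transcript `sequence`,
#'   `utr5_len` and `tx_len`.
#' @return A `frame_stat` object: list with `triplet` (T0, T1, T2),
#'   `statistic`, `p_value`, `groups` (per-group S triplets) and
#'   `n_excluded`.
#' @export
frame_statistic <- function(reads, annotation) {
  assert_columns(annotation, c("gene_id", "utr5_len", "tx_len", "sequence"),
                 "annotation")
  d <- reads |>
    inner_join(select(annotation, "gene_id", "utr5_len", "tx_len", "sequence"),
               by = "gene_id") |>
    mutate(frame = (.data$five_prime_pos - .data$utr5_len) %% 3L,
           end3 = .data$five_prime_pos + .data$length - 1L)
  defined <- d$end3 + 1L < d$tx_len & d$end3 >= 2L
  n_excluded <- sum(!defined)
  d <- d[defined, ]
  if (nrow(d) == 0) abort("No footprints with defined 3'-end context.")
  d <- d |>
    mutate(up2 = seq_context(.data$sequence, .data$end3 - 2L, 2L),
           down1 = seq_context(.data$sequence, .data$end3 + 1L, 1L))
  groups <- d |>
    count(.data$length, .data$up2, .data$down1, .data$frame) |>
    tidyr::pivot_wider(names_from = "frame", values_from = "n",
                       values_fill = 0L, names_prefix = "S")
  for (col in c("S0", "S1", "S2")) if (!col %in% names(groups)) groups[[col]] <- 0L
  s <- as.matrix(groups[, c("S0", "S1", "S2")])
  shift <- max.col(s, ties.method = "first") - 1L
  idx <- cbind(rep(seq_len(nrow(s)), each = 3L),
               (rep(0:2, nrow(s)) + rep(shift, each = 3L)) %% 3L + 1L)
  shifted <- matrix(s[idx], ncol = 3L, byrow = TRUE)
  triplet <- colSums(shifted)
  names(triplet) <- c("T0", "T1", "T2")
  expected <- rep(sum(triplet) / 3, 3)
  statistic <- sum((triplet - expected)^2 / expected)
  structure(
    list(triplet = triplet, statistic = statistic,
         p_value = pchisq(statistic, df = 2, lower.tail = FALSE),
         groups = groups, n_excluded = n_excluded),
    class = "frame_stat"
  )
}

#' @export
print.frame_stat <- function(x, ...) {
  cat("<frame_stat>\n")
  cat(sprintf("  T = (%s) | chi-squared = %.4g (df = 2), p = %.3g\n",
              paste(x$triplet, collapse = ", "), x$statistic, x$p_value))
  cat(sprintf("  %d group(s), %d footprint(s) excluded (3'-end context undefined)\n",
              nrow(x$groups), x$n_excluded))
  invisible(x)
}

#' Distribution of reads across transcript regions
#'
#' Fraction of reads assigned to the 5'UTR, CDS and 3'UTR. Ribosome
#' footprints are assigned by their A-site position; RNA-seq reads by
#' their 5' end.
#'
#' @param reads Deduplicated read table (one modality at a time is
#'   typical; mixed tables are assigned per row).
#' @param annotation Gene annotation with region lengths.
#' @param offsets A-site offset map (required for footprints).
#' @return Tibble `region`, `count`, `fraction` with regions ordered
#'   5'UTR, CDS, 3'UTR; fractions sum to 1.
#' @export
region_distribution <- function(reads, annotation, offsets = NULL) {
  if (nrow(reads) == 0) abort("Empty read table: region distribution undefined.")
  assert_columns(annotation, c("gene_id", "utr5_len", "cds_len"), "annotation")
  d <- inner_join(reads, select(annotation, "gene_id", "utr5_len", "cds_len"),
                  by = "gene_id")
  pos <- assigned_position(d, offsets)
  region <- position_region(pos, d$utr5_len, d$cds_len)
  tibble(region = factor(c("5UTR", "CDS", "3UTR"),
                         levels = c("5UTR", "CDS", "3UTR"))) |>
    left_join(tibble(region = region) |> count(.data$region, name = "count"),
              by = "region") |>
    mutate(count = dplyr::coalesce(.data$count, 0L),
           fraction = .data$count / sum(.data$count))
}

#' Occupancy-weighted transcript region length percentages
#'
#' For each transcript the region length ratios (region length divided by
#' transcript length) are weighted by the transcript's ribosome occupancy;
#' weighted ratios are summed over transcripts, and each region's weighted
#' sum is expressed as a percentage of the total. The three percentages
#' sum to 100.
#'
#' @param occupancy Tibble `gene_id`, `count` of per-transcript ribosome
#'   occupancy (reads).
#' @param annotation Gene annotation with region lengths.
#' @return Tibble `region`, `weighted_sum`, `percentage`.
#' @export
weighted_region_lengths <- function(occupancy, annotation) {
  assert_columns(occupancy, c("gene_id", "count"), "occupancy")
  assert_columns(annotation, c("gene_id", "utr5_len", "cds_len", "utr3_len"),
                 "annotation")
  d <- inner_join(occupancy, annotation, by = "gene_id")
  if (nrow(d) == 0 || sum(d$count) == 0) {
    abort("Total occupancy is zero: weighted region lengths undefined.")
  }
  tx_len <- d$utr5_len + d$cds_len + d$utr3_len
  w <- c(`5UTR` = sum(d$count * d$utr5_len / tx_len),
         CDS = sum(d$count * d$cds_len / tx_len),
         `3UTR` = sum(d$count * d$utr3_len / tx_len))
  tibble(region = factor(names(w), levels = names(w)),
         weighted_sum = unname(w),
         percentage = unname(w) / sum(w) * 100)
}
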