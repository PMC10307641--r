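test_that("stop metagene counts 5' ends relative to the stop codon", {
  ann <- uniform_annotation(utr5 = 30L, cds = 300L, utr3 = 60L)
  anchor <- 30L + 300L - 3L # first nt of the stop codon
  prof <- stop_metagene(make_read("g1", anchor - 14L, 32), ann)
  expect_s3_class(prof, "metagene_profile")
  expect_equal(dplyr::filter(prof, position == -14)$count, 1L)
  expect_equal(sum(prof$count), 1L)

  # empty input: all-zero profile over the window
  empty <- stop_metagene(make_read("g1", 0, 32)[0, ], ann)
  expect_equal(sum(empty$count), 0)
  expect_error(stop_metagene(make_read("g1", 5, 32), ann, window = c(10, -40)),
               "window")

  # planted spike at -17 for length 32 dominates a uniform background
  bg <- dplyr::bind_rows(lapply(seq(-40, -1), function(p)
    make_read("g1", anchor + p, 32)))
  spike <- dplyr::bind_rows(replicate(10, make_read("g1", anchor - 17L, 32),
                                      simplify = FALSE))
  prof2 <- stop_metagene(dplyr::bind_rows(bg, spike), ann)
  expect_equal(prof2$position[which.max(prof2$count)], -17)
})

test_that("A-site calibration reads the upstream peak with the documented tie-break", {
  prof <- tibble(length = 32L, position = -40:10, count = 0L) |>
    dplyr::mutate(count = replace(count, position == -14, 10L))
  expect_equal(calibrate_asite_offsets(prof), c("32" = 14L))
  # tie at -14 and -17 resolves to the smaller distance
  tie <- dplyr::mutate(prof, count = replace(count, position == -17, 10L))
  expect_equal(calibrate_asite_offsets(tie), c("32" = 14L))
  # all-zero upstream signal is an error naming the length
  expect_error(calibrate_asite_offsets(dplyr::mutate(prof, count = 0L)), "32")

  # round trip: a noise-free simulation returns the configured map exactly
  cfg <- tiny_config(reads = 20000, seed = 3, frame_fidelity = 1,
                     stop_bias = 12, start_bias = 4)
  tx <- simulate_transcriptome(cfg)
  r <- simulate_reads(tx, cfg, "MII", "ribo", 1)
  off <- calibrate_asite_offsets(stop_metagene(r, tx$genes))
  expect_equal(off[names(cfg$asite_offsets)],
               vapply(cfg$asite_offsets, as.integer, integer(1)))
})

test_that("frame statistic applies the cyclic shift and conserves totals", {
  # uniform sequence -> single (length, context) group; plant S = (2, 10, 1)
  ann <- uniform_annotation(utr5 = 30L, cds = 300L, utr3 = 60L)
  reads <- dplyr::bind_rows(
    lapply(c(rep(0, 2), rep(1, 10), rep(2, 1)), function(f)
      make_read("g1", 60L + f, 30)))
  fs <- frame_statistic(reads, ann)
  expect_equal(unname(fs$triplet), c(10, 1, 2))
  expect_equal(sum(fs$triplet), nrow(reads)) # Sigma S = Sigma T
  exp_t <- rep(13 / 3, 3)
  expect_equal(fs$statistic, sum((c(10, 1, 2) - exp_t)^2 / exp_t))
  expect_equal(fs$p_value, pchisq(fs$statistic, 2, lower.tail = FALSE))

  # perfect periodicity: everything lands in the first component
  cfg <- tiny_config(reads = 6000, seed = 7, frame_fidelity = 1)
  tx <- simulate_transcriptome(cfg)
  r <- simulate_reads(tx, cfg, "MII", "ribo", 1)
  fs2 <- frame_statistic(r, tx$genes)
  expect_equal(unname(fs2$triplet), c(nrow(r), 0, 0))
  expect_lt(fs2$p_value, 1e-100)
  expect_equal(sum(fs2$triplet) + fs2$n_excluded, nrow(r))

  # footprints without downstream context are excluded but tallied
  edge <- make_read("g1", 390L - 30L, 30) # 3' end = last transcript nt
  fs3 <- frame_statistic(dplyr::bind_rows(reads, edge), ann)
  expect_equal(fs3$n_excluded, 1L)
  expect_equal(sum(fs3$triplet), nrow(reads))

  # broom accessors
  expect_equal(glance(fs)$n_footprints, 13)
  expect_equal(tidy(fs)$count, c(10, 1, 2))
})

test_that("frame statistic is calibrated under uniform frames", {
  # single-group design (homopolymer transcript, one footprint length):
  # the cyclic shift only permutes components, so the statistic keeps its
  # chi-squared null distribution and rejections stay near the nominal rate
  ann <- uniform_annotation(utr5 = 30L, cds = 3000L, utr3 = 60L)
  set.seed(42)
  n <- 3000
  pvals <- vapply(1:20, function(i) {
    pos <- 60L + sample.int(2800L, n, replace = TRUE)
    reads <- make_read("g1", 0, 30)[rep(1, n), ]
    reads$five_prime_pos <- pos
    reads$read_id <- as.character(seq_len(n))
    fs <- frame_statistic(reads, ann)
    # component deviations stay near the multinomial SD; the bound takes
    # 4 SDs because the cyclic shift reports the max component first,
    # which inflates the extreme deviation relative to a single component
    expect_true(all(abs(fs$triplet - n / 3) < 4 * sqrt(n * 2 / 9)))
    fs$p_value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4)
})

test_that("region distribution recovers a planted 10/80/10 split", {
  ann <- uniform_annotation(utr5 = 100L, cds = 300L, utr3 = 100L)
  mk <- function(n, lo, hi) {
    if (n == 0) return(NULL)
    r <- make_read("g1", 0, 40, modality = "rna")[rep(1, n), ]
    r$five_prime_pos <- as.integer(seq(lo, hi, length.out = n))
    r$read_id <- paste0(lo, "_", seq_len(n))
    r
  }
  reads <- dplyr::bind_rows(mk(10, 0, 99), mk(80, 100, 399), mk(10, 400, 459))
  rd <- region_distribution(reads, ann)
  expect_equal(rd$fraction, c(0.1, 0.8, 0.1))
  expect_error(region_distribution(reads[0, ], ann), "Empty")
})

test_that("weighted region length percentages follow the printed arithmetic", {
  ann <- tibble(gene_id = c("t1", "t2"),
                utr5_len = c(100L, 50L), cds_len = c(200L, 300L),
                utr3_len = c(100L, 250L))
  w <- weighted_region_lengths(tibble(gene_id = "t1", count = 10), ann)
  expect_equal(w$percentage, c(25, 50, 25))
  expect_equal(sum(w$percentage), 100, tolerance = 1e-9)

  # scale invariance: duplicating the transcript's occupancy changes nothing
  two <- weighted_region_lengths(
    tibble(gene_id = c("t1", "t1"), count = c(10, 10)), ann)
  expect_equal(two$percentage, w$percentage)

  # shifting occupancy onto a long-3'UTR transcript raises its share
  mix1 <- weighted_region_lengths(tibble(gene_id = c("t1", "t2"),
                                         count = c(90, 10)), ann)
  mix2 <- weighted_region_lengths(tibble(gene_id = c("t1", "t2"),
                                         count = c(10, 90)), ann)
  expect_gt(mix2$percentage[3], mix1$percentage[3])
  expect_error(weighted_region_lengths(tibble(gene_id = "t1", count = 0), ann),
               "zero")
})
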