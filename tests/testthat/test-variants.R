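test_that("matrix similarity score spans [0, 1] with min-max normalization", {
  p <- make_test_pwm()
  best <- paste(c("A", "C", "G", "T")[max.col(p$matrix)], collapse = "")
  worst <- paste(c("A", "C", "G", "T")[apply(p$matrix, 1, which.min)],
                 collapse = "")
  expect_equal(matrix_similarity_score(best, p), 1)
  expect_equal(matrix_similarity_score(worst, p), 0)
  mid <- matrix_similarity_score(substr("ACGTACG", 1, p$width), p)
  expect_true(mid >= 0 && mid <= 1)

  # affine rescaling of the PWM leaves the score unchanged
  p2 <- pwm("scaled", 3 * p$matrix + 11)
  win <- "ACGTACG"
  expect_equal(matrix_similarity_score(win, p2),
               matrix_similarity_score(win, p))

  # degenerate (uniform) PWM: any allele swap gives a zero difference
  u <- pwm("flat", matrix(1, 5, 4, dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_equal(matrix_similarity_score("AAAAA", u) -
                 matrix_similarity_score("CCCCC", u), 0)

  expect_error(matrix_similarity_score("ACG", p), "match")
  expect_error(matrix_similarity_score("ACGTANG", p), "ambiguous")
  # RNA alphabet is accepted
  expect_equal(matrix_similarity_score(gsub("T", "U", best), p), 1)
})



test_that("a planted consensus-destroying SNP is selected among 1000 nulls", {
  fx <- planted_motif_fixture(n_null = 1000)
  eff <- score_snp_motif_effects(fx$snps, fx$genes, fx$pwms)
  expect_gt(dplyr::n_distinct(eff$snp_id), 900)
  planted <- dplyr::filter(eff, snp_id == "s_planted", grepl("RBP1", rbp))
  expect_true(planted$selected)
  expect_lt(planted$raw_diff, 0) # paternal destroys the motif
  # the percentile rule selects on the order of 5% of rows
  expect_lt(mean(eff$selected), 0.07)
  expect_gte(mean(eff$selected), 0.04)

  # swapping maternal/paternal labels negates raw differences and
  # preserves the selected set
  swapped <- dplyr::rename(fx$snps, maternal_allele = paternal_allele,
                           paternal_allele = maternal_allele)
  eff_sw <- score_snp_motif_effects(swapped, fx$genes, fx$pwms)
  j <- dplyr::inner_join(eff, eff_sw, by = c("snp_id", "rbp"))
  expect_equal(j$raw_diff.x, -j$raw_diff.y)
  expect_equal(j$selected.x, j$selected.y)
})

test_that("motif-effect bookkeeping: proximity filter, multi-PWM, consensus collapse", {
  # proximity: SNPs 3 nt apart are both removed; isolated SNPs survive.
  # A small null background keeps the score distribution non-degenerate.
  fx <- planted_motif_fixture(n_null = 80, seed = 9)
  close_gene <- tibble(gene_id = "close_g", sequence = strrep("ACGTT", 12))
  close_snps <- tibble(snp_id = c("close1", "close2"),
                       gene_id = "close_g", pos = c(20L, 23L),
                       maternal_allele = c("A", "T"),
                       paternal_allele = c("G", "G"))
  eff <- score_snp_motif_effects(dplyr::bind_rows(fx$snps, close_snps),
                                 dplyr::bind_rows(fx$genes, close_gene),
                                 fx$pwms)
  expect_false(any(c("close1", "close2") %in% eff$snp_id))
  expect_true("s_null0001" %in% eff$snp_id)

  # a SNP with no full-length window around it yields no rows
  tiny <- tibble(gene_id = "g3", sequence = "ACG")
  s3 <- tibble(snp_id = "nowin", gene_id = "g3", pos = 1L,
               maternal_allele = "C", paternal_allele = "T")
  expect_equal(nrow(score_snp_motif_effects(
    dplyr::bind_rows(fx$snps, s3),
    dplyr::bind_rows(fx$genes, tiny), fx$pwms) |>
      dplyr::filter(snp_id == "nowin")), 0)

  # RBPs sharing a consensus at one SNP collapse to a comma-joined row
  pa <- pwm("AAA_bindA", matrix(c(9, 1, 1, 1), 3, 4, byrow = TRUE,
                                dimnames = list(NULL, c("A", "C", "G", "T"))))
  pb <- pwm("AAA_bindB", matrix(c(5, 1, 1, 1), 3, 4, byrow = TRUE,
                                dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_equal(pa$consensus, pb$consensus)
  set.seed(8)
  bg <- tibble(gene_id = sprintf("bg%03d", 1:60),
               sequence = vapply(1:60, function(i)
                 paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
                 character(1)))
  bg_snps <- tibble(snp_id = paste0("s", 1:60), gene_id = bg$gene_id, pos = 15L,
                    maternal_allele = substr(bg$sequence, 16, 16),
                    paternal_allele = ifelse(substr(bg$sequence, 16, 16) == "A",
                                             "C", "A")) # always swaps A in or out
  eff2 <- score_snp_motif_effects(bg_snps, bg, list(pa, pb))
  expect_true(all(eff2$rbp == "AAA_bindA,AAA_bindB"))
  expect_equal(nrow(eff2), dplyr::n_distinct(eff2$snp_id))

  # exclusion list removes RBPs before scoring
  expect_error(score_snp_motif_effects(bg_snps, bg, list(pa, pb),
                                       exclude_rbps = c("AAA_bindA", "AAA_bindB")),
               "No PWMs")
  expect_true("A1CF" %in% default_rbp_exclusions())
})

test_that("uORF candidate scan matches the initiation-context pattern per allele", {
  # documented traces of the 9-nt window
  expect_true(grepl(riboallele:::UORF_PATTERN, "AAGCCTGAA"))
  expect_false(grepl(riboallele:::UORF_PATTERN, "AATTTTTTA"))

  ann <- tibble(gene_id = "g1", utr5_len = 20L, cds_len = 30L, utr3_len = 10L,
                sequence = paste0("CCCCAAGCCTGAACCCCCCC", strrep("A", 27),
                                  "TAA", strrep("C", 10)))
  snps <- tibble(
    snp_id = c("hit_mat", "hit_pat", "miss", "edge"),
    gene_id = "g1",
    pos = c(8L, 8L, 16L, 1L),
    maternal_allele = c("C", "G", "C", "C"),
    paternal_allele = c("T", "C", "G", "T"),
    region = "5UTR")
  u <- find_uorf_candidates(snps, ann)
  expect_setequal(u$snp_id, c("hit_mat", "hit_pat"))
  # window centred on the SNP carries the allele at its centre
  expect_equal(substr(u$window_maternal[u$snp_id == "hit_mat"], 5, 5), "C")
  expect_true(u$match_maternal[u$snp_id == "hit_mat"])
  # T at the centre breaks the [ACG] position: the paternal allele kills it
  expect_false(u$match_paternal[u$snp_id == "hit_mat"])
  # out-of-bounds windows are skipped and tallied
  expect_equal(attr(u, "n_skipped"), 1L)

  # efficiency annotation joins on the window context
  effic <- tibble(context = "AAGCCTGAA", efficiency = 0.42)
  u2 <- find_uorf_candidates(snps, ann, efficiency_table = effic)
  expect_equal(u2$efficiency_maternal[u2$snp_id == "hit_mat"], 0.42)
})
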