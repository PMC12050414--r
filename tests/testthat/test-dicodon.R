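test_that("in-frame codon counting frames, flags and separates stops", {
  cc <- count_codons("ATGGCGTAA")
  expect_equal(unname(cc$counts["ATG"]), 1)
  expect_equal(unname(cc$counts["GCG"]), 1)
  expect_equal(unname(cc$stop_counts["TAA"]), 1)
  expect_equal(cc$total, 2)
  expect_equal(count_codons(character(0))$total, 0)
  cc <- count_codons(c(ok = "ATGGCGTAA", bad = "ATGGC"))
  expect_equal(cc$skipped, "bad")
  expect_equal(cc$total, 2)
  # ambiguous codons skipped without error
  expect_equal(count_codons("ATGNNNTAA")$total, 1)
})

test_that("dicodon counting slides by one codon and excludes stop pairs", {
  dc <- count_dicodons("ATGGCGGCGTAA")
  expect_equal(unname(dc$counts["ATGGCG"]), 1)
  expect_equal(unname(dc$counts["GCGGCG"]), 1)
  expect_false("GCGTAA" %in% names(dc$counts))
  expect_equal(dc$total, 2)
  expect_equal(count_dicodons("ATGTAA")$total, 0)
  fl <- dicodon_cpg_flags("GCGGCG")
  expect_true(fl["within1"] && fl["within2"])
  expect_false(fl["junction"])
  fl <- dicodon_cpg_flags("GTCGAA")
  expect_false(fl["within1"] || fl["within2"])
  expect_true(fl["junction"])

  set.seed(13)
  tab <- codon_table()
  for (i in 1:100) {
    n <- sample(1:10, 1)
    seqs <- vapply(seq_len(n), function(j)
      paste(sample(names(tab$mapping), sample(2:12, 1), replace = TRUE),
            collapse = ""), character(1))
    got <- count_dicodons(seqs)$counts
    exp <- brute_dicodons(seqs)
    expect_equal(sort(names(got)), sort(names(exp)))
    if (length(exp)) expect_equal(got[names(exp)],
                                  setNames(as.integer(exp), names(exp)))
  }
})

test_that("pair conservation: retained pairs = per-gene pairs minus exclusions", {
  set.seed(19)
  cds <- generate_cds_set(n_genes = 40, length_codons = function(n)
    sample(10:40, n, replace = TRUE), seed = 19)
  dc <- count_dicodons(cds$sequences)
  # every gene is <sense codons><stop>; the stop voids exactly one pair
  m <- cds$truth$length_codons
  expect_equal(dc$total, sum(m - 1))
})

test_that("enrichment follows the observed/expected formula", {
  cc <- structure(list(counts = c(AAA = 50L, GGG = 50L), total = 100L),
                  class = "codon_counts")
  dc <- list(counts = c(AAAGGG = 50L), total = 100L)
  enr <- dicodon_enrichment(cc, dc)
  row <- enr[enr$dicodon == "AAAGGG", ]
  expect_equal(row$expected, 25)
  expect_equal(row$enrichment, 2)
  # observed == expected everywhere -> enrichment 1
  cc2 <- structure(list(counts = c(AAA = 100L), total = 100L),
                   class = "codon_counts")
  dc2 <- list(counts = c(AAAAAA = 99L), total = 99L)
  enr2 <- dicodon_enrichment(cc2, dc2)
  expect_equal(enr2$enrichment[enr2$dicodon == "AAAAAA"], 1)
})

test_that("enrichment is invariant to duplicating the CDS set", {
  set.seed(23)
  cds <- generate_cds_set(n_genes = 30, length_codons = 50, seed = 23)
  one <- dicodon_enrichment(count_codons(cds$sequences),
                            count_dicodons(cds$sequences))
  dup <- c(as.character(cds$sequences), as.character(cds$sequences))
  names(dup) <- paste0("s", seq_along(dup))
  two <- dicodon_enrichment(count_codons(dup), count_dicodons(dup))
  expect_equal(two$enrichment, one$enrichment, tolerance = 1e-12)
})

test_that("an injected dicodon depletion is recovered at its predicted level", {
  cds <- generate_cds_set(n_genes = 500, length_codons = 400,
                          cpg_depletion = 1,
                          dicodon_factors = c(GCGGCG = 0.1), seed = 31)
  enr <- dicodon_enrichment(count_codons(cds$sequences),
                            count_dicodons(cds$sequences))
  got <- enr$enrichment[enr$dicodon == "GCGGCG"]
  want <- unname(cds$truth$expected_enrichment["GCGGCG"])
  expect_lt(got, 1)
  row <- enr[enr$dicodon == "GCGGCG", ]
  se <- sqrt(want * row$expected) / row$expected   # binomial SE at the depleted rate
  expect_lt(abs(got - want), 3 * se)
})

test_that("top dicodon extraction orders both extremes", {
  set.seed(37)
  cds <- generate_cds_set(n_genes = 300, length_codons = 200,
                          dicodon_factors = c(GCGGCG = 0.05, AAAAAA = 4),
                          seed = 37)
  enr <- dicodon_enrichment(count_codons(cds$sequences),
                            count_dicodons(cds$sequences))
  tops <- top_dicodons(enr, k = 3)
  expect_equal(nrow(tops$under), 3)
  expect_equal(tops$under$dicodon[1], "GCGGCG")
  expect_equal(tops$over$dicodon[1], "AAAAAA")
  expect_true(all(diff(tops$under$enrichment) >= 0))
  expect_true(all(diff(tops$over$enrichment) <= 0))
})
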