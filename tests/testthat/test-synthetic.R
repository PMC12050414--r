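test_that("genome generator is deterministic and honours its depletion knob", {
  g1 <- generate_genome(lengths = c(chr1 = 5000, chr2 = 2000), seed = 8)
  g2 <- generate_genome(lengths = c(chr1 = 5000, chr2 = 2000), seed = 8)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_equal(Biostrings::width(g1$sequences), c(5000, 2000),
               ignore_attr = TRUE)
  # lambda = 0 forbids CpG entirely
  g0 <- generate_genome(lengths = c(chr1 = 3e4), cpg_depletion = 0, seed = 9)
  expect_equal(count_dinucleotides(g0$sequences[[1]])$n_cpg, 0)
  expect_error(generate_genome(gc_fraction = 1.4), "probabilities")
})

test_that("generated chains have the prescribed first-order transition structure", {
  gc <- 0.5; bias <- 0.6; lam <- 0.4
  g <- generate_genome(lengths = c(chr1 = 2e5), gc_fraction = gc,
                       strand_bias = bias, cpg_depletion = lam, seed = 14)
  ch <- strsplit(as.character(g$sequences[[1]]), "")[[1]]
  prev <- ch[-length(ch)]; nxt <- ch[-1]
  pi_g <- gc * bias
  # P(G | prev C) should be lambda pi_G / (1 - pi_G (1 - lambda))
  p_gc_theory <- lam * pi_g / (1 - pi_g * (1 - lam))
  n_c <- sum(prev == "C")
  p_gc_hat <- sum(prev == "C" & nxt == "G") / n_c
  expect_lt(abs(p_gc_hat - p_gc_theory),
            3 * sqrt(p_gc_theory * (1 - p_gc_theory) / n_c))
  # P(G | prev not C) should be pi_G
  n_nc <- sum(prev != "C")
  p_g_hat <- sum(prev != "C" & nxt == "G") / n_nc
  expect_lt(abs(p_g_hat - pi_g), 3 * sqrt(pi_g * (1 - pi_g) / n_nc))
})

test_that("measured CpG content tracks the closed-form expectation", {
  for (lam in c(0.25, 1)) {
    g <- generate_genome(lengths = c(chr1 = 2e5), gc_fraction = 0.45,
                         cpg_depletion = lam, seed = 21)
    tiles <- tile_sequence(as.character(g$sequences[[1]]), width = 1e4)
    want <- g$truth$expected_cpg_content
    se <- sd(tiles$cpg_content) / sqrt(nrow(tiles))
    expect_lt(abs(mean(tiles$cpg_content) - want), 3 * se)
  }
})

test_that("CDS generator yields valid in-frame genes with the requested structure", {
  cds <- generate_cds_set(n_genes = 60, length_codons = function(n)
    sample(seq(67, 120), n, replace = TRUE), frac_symbolless = 0.25,
    seed = 5)
  s <- as.character(cds$sequences)
  tab <- codon_table()
  expect_true(all(nchar(s) %% 3 == 0))
  expect_true(all(substr(s, 1, 3) == "ATG"))
  for (x in s) {
    cods <- substring(x, seq(1, nchar(x) - 2, 3), seq(3, nchar(x), 3))
    expect_true(cods[length(cods)] %in% tab$stops)
    expect_false(any(cods[-length(cods)] %in% tab$stops))
  }
  expect_true(all(nchar(s) >= 201))
  # symbol-less genes carry LOC placeholders at roughly the requested rate
  syms <- sub("^\\S+\\s+", "", names(s))
  frac <- mean(grepl("^LOC", syms))
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 60))
  expect_identical(grepl("^LOC", syms), cds$truth$symbolless)
  # determinism
  again <- generate_cds_set(n_genes = 60, length_codons = function(n)
    sample(seq(67, 120), n, replace = TRUE), frac_symbolless = 0.25,
    seed = 5)
  expect_identical(s, as.character(again$sequences))
})

test_that("generated CDS pass the pipeline filters at the implied rates", {
  cds <- generate_cds_set(n_genes = 80, length_codons = 100,
                          frac_symbolless = 0.2, seed = 6)
  fg <- filter_genes(cds$sequences)
  expect_equal(nrow(fg$genes) + sum(fg$ledger$reason == "no_symbol"), 80)
  expect_equal(nrow(fg$genes), sum(!cds$truth$symbolless))
})

test_that("terminal-window depletion shifts the 5' and 3' windows as injected", {
  cds <- generate_cds_set(n_genes = 400, length_codons = 120,
                          cpg_depletion = 1, lambda5 = 1, lambda3 = 0.15,
                          seed = 41)
  tab <- gene_table(cds$sequences)
  expect_gt(median(tab$first_content, na.rm = TRUE),
            median(tab$last_content, na.rm = TRUE))
})

test_that("region fixtures realise the requested enrichment structure", {
  genome <- c(chr1 = 1e5, chr2 = 8e4)
  fx <- generate_region_fixture(genome, subject_coverage = 0.1,
                                query_n = 40, query_length = 200,
                                enrichment_level = 1, seed = 3)
  # every query region lies fully inside the subject
  ov <- observed_overlap(fx$query, fx$subject)
  expect_equal(ov, sum(fx$query$regions$end - fx$query$regions$start))
  # subject coverage close to requested
  cov <- sum(fx$subject$regions$end - fx$subject$regions$start) / sum(genome)
  expect_lt(abs(cov - 0.1), 0.03)
  empty <- generate_region_fixture(genome, query_n = 0, seed = 4)
  expect_equal(nrow(empty$query$regions), 0)
  expect_equal(observed_overlap(empty$query, empty$subject), 0)
  expect_error(generate_region_fixture(genome, subject_coverage = 0), "0, 1")
})
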