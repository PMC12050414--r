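test_that("the standard code partitions as expected (brute-force enumeration)", {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  tab <- codon_table()
  expect_setequal(names(tab$mapping), all64)
  expect_length(tab$sense, 61)
  expect_setequal(tab$stops, c("TAA", "TAG", "TGA"))
  expect_true("ATG" %in% tab$starts)
  # every amino acid has at least one codon
  expect_length(tab$amino_acids, 20)
  # brute-force class sizes over all sense codons
  expect_equal(sum(grepl("CG", tab$sense)), 8)
  expect_equal(sum(substr(tab$sense, 3, 3) == "C"), 16)
  expect_equal(sum(substr(tab$sense, 1, 1) == "G"), 16)
})

test_that("CpG codon enumeration matches hand enumeration", {
  rep <- enumerate_cpg_codons()
  expect_setequal(rep$within_pos12, c("CGT", "CGC", "CGA", "CGG"))
  expect_equal(rep$aa_pos12, "R")
  expect_setequal(rep$aa_pos23, c("S", "P", "T", "A"))
  expect_length(rep$within_all, 8)
  expect_length(rep$aa_within_all, 5)
  expect_length(rep$aa_c_ending, 15)
  expect_setequal(rep$aa_g_starting, c("V", "A", "D", "E", "G"))
  # the two within-codon positions are disjoint in the standard code
  expect_length(intersect(rep$within_pos12, rep$within_pos23), 0)
  # union is exactly the CG-containing codons
  expect_setequal(rep$within_all, codon_table()$sense[grepl("CG", codon_table()$sense)])
})

test_that("CpG-context-free amino acids match rule-based enumeration", {
  tab <- codon_table()
  # independent enumeration straight from the defining rule
  oracle <- Filter(function(a) {
    cods <- tab$sense[tab$mapping[tab$sense] == a]
    !any(grepl("CG", cods) | substr(cods, 3, 3) == "C" |
           substr(cods, 1, 1) == "G")
  }, tab$amino_acids)
  res <- never_cpg_amino_acids()
  expect_setequal(res, oracle)
  expect_true(all(c("M", "Q", "W") %in% res))
  # disjoint from the within-codon CpG amino acids
  expect_length(intersect(res, c("R", "S", "P", "T", "A")), 0)
})

test_that("CpG-free codon repertoire covers all amino acids and is junction-safe", {
  fs <- cpg_free_codons()
  expect_length(fs$codons, 38)
  expect_true(fs$complete)
  expect_false(any(grepl("CG", fs$codons)))
  expect_false(any(substr(fs$codons, 3, 3) == "C"))
  # exhaustive: no ordered concatenation of two retained codons forms a CpG
  hexamers <- outer(fs$codons, fs$codons, paste0)
  expect_false(any(grepl("CG", hexamers)))
})

test_that("dicodon space sizes are exact", {
  ds <- dicodon_space()
  expect_equal(ds$all_sense_pairs, 3721)
  expect_equal(ds$cpg_free_pairs, 1444)
  expect_gt(ds$reduction_percent, 60)
})

test_that("minimal synonymous escape steps agree with an independent path oracle", {
  expect_equal(min_synonymous_steps("CGC"), 2)
  expect_equal(min_synonymous_steps("CGT"), 2)
  expect_equal(min_synonymous_steps("CGA"), 1)
  expect_equal(min_synonymous_steps("CGG"), 1)
  expect_equal(min_synonymous_steps("GCG"), 1)
  expect_equal(min_synonymous_steps("TTT"), 0)
  tab <- codon_table()
  for (cod in tab$sense)
    expect_equal(min_synonymous_steps(cod), brute_min_steps(cod),
                 info = cod)
  expect_error(min_synonymous_steps("TAA"), "stop")
})

test_that("methylation-driven mutation effects classify correctly", {
  e <- methylation_mutation_effect("CGA", "1-2", "CG>TG")
  expect_equal(e$target_codon, "TGA")
  expect_equal(e$kind, "nonsense")
  e <- methylation_mutation_effect("ACG", "2-3", "CG>CA")
  expect_equal(e$target_codon, "ACA")
  expect_equal(e$kind, "synonymous")
  e <- methylation_mutation_effect("ACG", "2-3", "CG>TG")
  expect_equal(e$target_codon, "ATG")
  expect_equal(e$kind, "nonsynonymous")
  expect_error(methylation_mutation_effect("AAA", "1-2", "CG>TG"), "no CpG")

  tab <- codon_table()
  # third-position deamination (NCG, G>A) is always synonymous;
  # CGN codons never mutate synonymously at bases 1-2
  for (cod in tab$sense[substr(tab$sense, 2, 3) == "CG"])
    expect_equal(methylation_mutation_effect(cod, "2-3", "CG>CA")$kind,
                 "synonymous", info = cod)
  for (cod in tab$sense[substr(tab$sense, 1, 2) == "CG"]) {
    expect_false(methylation_mutation_effect(cod, "1-2", "CG>TG")$kind ==
                   "synonymous", info = cod)
    expect_false(methylation_mutation_effect(cod, "1-2", "CG>CA")$kind ==
                   "synonymous", info = cod)
  }
})

test_that("CpG SNP polymorphism classes are the six expected rows", {
  cls <- cpg_snp_classes()
  expect_equal(nrow(cls), 6)
  expect_setequal(cls$polymorphism[cls$high_mutation_rate],
                  c("CpG<->TpG", "CpG<->CpA"))
  r <- classify_cpg_snp("CpG<->TpG")
  expect_true(r$gc_conversion_acting)
  expect_true(r$high_mutation_rate)
  expect_equal(r$synonymous_at_3rd, "always")
  expect_equal(r$synonymous_at_1st, "never")
  r <- classify_cpg_snp("CpG<->GpG")
  expect_false(r$gc_conversion_acting)
  expect_false(r$high_mutation_rate)
  expect_equal(r$synonymous_at_3rd, "possible")
  r <- classify_cpg_snp("ApG")  # shorthand accepted
  expect_true(r$gc_conversion_acting)
  expect_equal(r$synonymous_at_1st, "possible")
  expect_error(classify_cpg_snp("CpG<->NpN"), "unknown")
})

test_that("CpG-free alternative encodings follow the code's structure", {
  r <- cpg_free_alternatives("R")
  expect_equal(r$site, "CGN")
  expect_setequal(r$alternatives, c("AGA", "AGG"))
  expect_equal(r$single_synonymous_change, "partial")
  expect_equal(r$gc_neutral, "no")
  s <- cpg_free_alternatives("S")
  expect_equal(s$site, "NCG")
  expect_true(all(c("TCT", "TCA", "TCC") %in% s$alternatives))
  expect_equal(s$single_synonymous_change, "always")
  expect_equal(s$gc_neutral, "yes")
  m <- cpg_free_alternatives("M")
  expect_equal(m$site, "none")
  f <- cpg_free_alternatives("F")   # C-ending only: junction case
  expect_equal(f$site, "junction")
  expect_equal(f$gc_neutral, "partially")
})
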