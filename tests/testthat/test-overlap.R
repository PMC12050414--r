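test_that("region sets validate, sort and merge input intervals", {
  g <- c(chr1 = 100, chr2 = 50)
  rs <- region_set(data.frame(chrom = c("chr1", "chr1"),
                              start = c(20, 0), end = c(30, 25)), g)
  expect_true(rs$merged)
  expect_equal(rs$regions$start, 0)
  expect_equal(rs$regions$end, 30)
  expect_error(region_set(data.frame(chrom = "chr3", start = 0, end = 1), g),
               "chromosome")
  expect_error(region_set(data.frame(chrom = "chr1", start = 5, end = 5), g),
               "start < end")
  expect_error(region_set(data.frame(chrom = "chr2", start = 0, end = 51), g),
               "exceeds")
})

test_that("observed overlap matches interval arithmetic and is symmetric", {
  g <- c(chr1 = 1000)
  a <- region_set(data.frame(chrom = "chr1", start = 0, end = 10), g)
  b <- region_set(data.frame(chrom = "chr1", start = 5, end = 15), g)
  expect_equal(observed_overlap(a, b), 5)
  expect_equal(observed_overlap(a, b, "count"), 1)
  expect_equal(observed_overlap(a, a), 10)
  d <- region_set(data.frame(chrom = "chr1", start = 500, end = 600), g)
  expect_equal(observed_overlap(a, d), 0)
  expect_equal(observed_overlap(a, d, "count"), 0)
  g2 <- c(chr1 = 999)
  expect_error(observed_overlap(a, region_set(data.frame(
    chrom = "chr1", start = 0, end = 10), g2)), "different genomes")

  set.seed(5)
  genome <- c(c1 = 500, c2 = 300)
  for (i in 1:100) {
    x <- region_set(random_region_df(genome, sample(1:8, 1)), genome)
    y <- region_set(random_region_df(genome, sample(1:8, 1)), genome)
    ov <- observed_overlap(x, y)
    expect_equal(ov, brute_overlap_bases(x, y))
    expect_equal(ov, observed_overlap(y, x))
  }
})

test_that("region permutation preserves lengths, respects bounds and is seeded", {
  g <- c(chr1 = 1e4, chr2 = 5e3)
  a <- region_set(data.frame(chrom = c("chr1", "chr2"),
                             start = c(0, 100), end = c(500, 400)), g)
  p1 <- permute_regions(a, seed = 3)
  p2 <- permute_regions(a, seed = 3)
  expect_identical(p1$regions, p2$regions)
  expect_equal(sort(p1$regions$end - p1$regions$start), c(300, 500))
  expect_true(all(p1$regions$end <= g[p1$regions$chrom]))
  # a region spanning its whole chromosome has a single forced placement
  full <- region_set(data.frame(chrom = "chr2", start = 0, end = 5e3), g)
  expect_equal(permute_regions(full, seed = 1)$regions$start, 0)
  expect_error(permute_regions(structure(list(
    regions = data.frame(chrom = "chr2", start = 0, end = 5e3),
    genome = c(chr2 = 4e3)), class = "region_set")), "longer")

  # placements of a length-100 region are uniform on [0, L-100]
  g1 <- c(chr = 1e6)
  r <- region_set(data.frame(chrom = "chr", start = 0, end = 100), g1)
  set.seed(11)
  starts <- vapply(1:2000, function(i) permute_regions(r)$regions$start,
                   numeric(1))
  ks <- suppressWarnings(ks.test(starts, "punif", 0, 1e6 - 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation test p-values follow the add-one formula", {
  g <- c(chr1 = 1e5)
  a <- region_set(data.frame(chrom = "chr1", start = c(0, 1000),
                             end = c(200, 1200)), g)
  # self-overlap on a sparse genome is never reached by chance
  pt <- permutation_test(a, a, n_perm = 999, seed = 2)
  expect_equal(pt$p_value, (1 + sum(pt$null >= pt$observed)) / 1000)
  expect_equal(pt$p_value, 1 / 1000)
  expect_gt(pt$z_score, 5)
  # b = whole genome: every permutation overlaps fully
  whole <- region_set(data.frame(chrom = "chr1", start = 0, end = 1e5), g)
  pt2 <- permutation_test(a, whole, n_perm = 99, seed = 2)
  expect_equal(pt2$p_value, 1)
  expect_true(is.na(pt2$z_score))   # degenerate null flagged
  pt3 <- permutation_test(a, a, n_perm = 99, seed = 4, alternative = "less")
  expect_equal(pt3$p_value, 1)
  expect_error(permutation_test(a, a, n_perm = 0), "at least 1")
})

test_that("BED and chromosome-sizes round-trip", {
  g <- c(chr1 = 1000, chr2 = 800)
  dir <- withr::local_tempdir()
  sizes <- file.path(dir, "sizes.tsv")
  write.table(data.frame(names(g), unname(g)), sizes, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_equal(read_chrom_sizes(sizes), g)
  bed <- file.path(dir, "q.bed")
  writeLines(c("chr1\t0\t10\tname\t0\t+", "chr2\t5\t25\tx\t1\t-"), bed)
  rs <- read_bed(bed, g)
  expect_equal(nrow(rs$regions), 2)
  expect_equal(rs$regions$end[rs$regions$chrom == "chr2"], 25)
})
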