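# Permutation test of overlap between two genomic region sets, in the
# style of regioneR: each query region is re-placed uniformly at random
# on its own chromosome (length preserved) and the overlap statistic is
# recomputed, giving an empirical null with add-one p-value. The interval
# arithmetic is kept in plain sorted integer vectors so the permutation
# inner loop stays fast; GenomicRanges serves as an independent
# cross-check in the test suite.

#' Construct a region set on a named genome
#'
#' Intervals are 0-based half-open on named chromosomes. Overlapping or
#' bookended input intervals are merged on load (flagged in the result);
#' intervals are validated against the chromosome lengths.
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` (extra
#'   columns ignored; BED-style).
#' @param genome Named numeric vector of chromosome lengths.
#' @return Object of class `region_set`: list with `regions` (sorted,
#'   merged data frame), `genome`, `n_input`, `merged` (`TRUE` if merging
#'   changed the input).
#' @examples
#' rs <- region_set(data.frame(chrom = "chr1", start = 0, end = 10),
#'                  c(chr1 = 100))
#' @export
region_set <- function(regions, genome) {
  if (is.null(names(genome)) || any(genome <= 0))
    stop("'genome' must be a named vector of positive chromosome lengths")
  regions <- as.data.frame(regions)[, c("chrom", "start", "end")]
  regions$chrom <- as.character(regions$chrom)
  if (nrow(regions)) {
    bad <- !(regions$chrom %in% names(genome))
    if (any(bad)) stop("chromosome not in genome: ",
                       paste(unique(regions$chrom[bad]), collapse = ", "))
    if (any(regions$start < 0) || any(regions$end <= regions$start))
      stop("intervals must satisfy 0 <= start < end")
    if (any(regions$end > genome[regions$chrom]))
      stop("interval exceeds chromosome length")
  }
  merged <- merge_intervals(regions)
  structure(list(regions = merged,
                 genome = genome,
                 n_input = nrow(regions),
                 merged = nrow(merged) != nrow(regions)),
            class = "region_set")
}

merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), ]
    s <- d$start; e <- d$end
    ks <- numeric(0); ke <- numeric(0)
    cs <- s[1L]; ce <- e[1L]
    for (i in seq_len(nrow(d))[-1L]) {
      if (s[i] <= ce) ce <- max(ce, e[i])
      else { ks <- c(ks, cs); ke <- c(ke, ce); cs <- s[i]; ce <- e[i] }
    }
    data.frame(chrom = d$chrom[1L], start = c(ks, cs), end = c(ke, ce),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", nrow(x$regions), "regions on", length(x$genome),
      "chromosomes")
  if (x$merged) cat(" (overlapping input intervals merged)")
  cat("\n")
  invisible(x)
}

#' Read a BED file into a region set
#'
#' First three columns (chrom, start, end; 0-based half-open) are used,
#' strand and score ignored.
#'
#' @param path BED file path.
#' @param genome Named chromosome lengths, e.g. from
#'   [read_chrom_sizes()].
#' @return A [region_set()].
#' @export
read_bed <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  region_set(df[, 1:3], genome)
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with columns chromosome name, length.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

check_same_genome <- function(a, b) {
  if (!identical(sort(names(a$genome)), sort(names(b$genome))) ||
      !identical(a$genome[sort(names(a$genome))],
                 b$genome[sort(names(b$genome))]))
    stop("region sets are defined on different genomes")
}

# per-region overlap of (possibly self-overlapping) rows against a
# merged, sorted subject: bases sums each row's intersected length,
# count tallies rows touching >= 1 subject interval. For disjoint rows
# the bases sum equals the merged intersection length.
overlap_rows <- function(df, subject, mode) {
  tot <- 0
  for (ch in unique(df$chrom)) {
    da <- df[df$chrom == ch, ]
    db <- subject[subject$chrom == ch, ]
    if (nrow(db) == 0L) next
    for (i in seq_len(nrow(da))) {
      ov <- pmin(da$end[i], db$end) - pmax(da$start[i], db$start)
      if (mode == "bases") tot <- tot + sum(ov[ov > 0])
      else if (any(ov > 0)) tot <- tot + 1
    }
  }
  tot
}

#' Overlap between two region sets
#'
#' @param a,b [region_set()] objects on the same genome.
#' @param mode `"bases"` (total intersected length, symmetric) or
#'   `"count"` (number of merged `a` regions intersecting at least one
#'   `b` region).
#' @return Numeric scalar.
#' @examples
#' g <- c(chr1 = 100)
#' a <- region_set(data.frame(chrom = "chr1", start = 0, end = 10), g)
#' b <- region_set(data.frame(chrom = "chr1", start = 5, end = 15), g)
#' observed_overlap(a, b)            # 5
#' observed_overlap(a, b, "count")   # 1
#' @export
observed_overlap <- function(a, b, mode = c("bases", "count")) {
  mode <- match.arg(mode)
  check_same_genome(a, b)
  overlap_rows(a$regions, b$regions, mode)
}

#' Randomly re-place the regions of a set on their chromosomes
#'
#' Each region is independently moved to a uniformly random start on its
#' own chromosome, preserving its length (regioneR-style randomisation
#' respecting chromosome structure). Permuted regions may overlap each
#' other; they are merged only for overlap computation.
#'
#' @param a A [region_set()].
#' @param seed Optional integer seed (set it for a deterministic draw;
#'   leave `NULL` inside a caller that manages the RNG state).
#' @return A [region_set()] with the re-placed regions.
#' @export
permute_regions <- function(a, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- a$regions
  if (nrow(r)) {
    len <- r$end - r$start
    maxs <- a$genome[r$chrom] - len
    if (any(maxs < 0)) stop("region longer than its chromosome")
    r$start <- floor(stats::runif(nrow(r)) * (maxs + 1))
    r$end <- r$start + len
  }
  region_set(r, a$genome)
}

#' Permutation test of region-set overlap
#'
#' Compares the observed overlap of `a` with `b` against a null built by
#' re-placing the `a` regions uniformly at random on their chromosomes
#' `n_perm` times. The empirical p-value uses the add-one correction
#' p = (1 + #\{null >= observed\}) / (1 + n_perm) for
#' `alternative = "greater"` (and with `<=` for `"less"`), so the
#' smallest attainable p is 1/(n_perm + 1).
#'
#' @param a,b [region_set()] objects on the same genome; `a` is permuted.
#' @param n_perm Number of permutations, default 1000.
#' @param mode Overlap statistic, `"bases"` or `"count"`.
#' @param alternative `"greater"` (default) or `"less"`.
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `cpg_permtest`: list with `observed`,
#'   `null` (length `n_perm`), `p_value`, `z_score` (`NA` when the null
#'   is degenerate), `n_perm`, `alternative`, `mode`.
#' @examples
#' g <- c(chr1 = 10000)
#' a <- region_set(data.frame(chrom = "chr1", start = c(0, 500),
#'                            end = c(100, 600)), g)
#' pt <- permutation_test(a, a, n_perm = 99, seed = 7)
#' pt$p_value
#' @export
permutation_test <- function(a, b, n_perm = 1000L,
                             mode = c("bases", "count"),
                             alternative = c("greater", "less"),
                             seed = 1L) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  check_same_genome(a, b)
  obs <- observed_overlap(a, b, mode)
  set.seed(seed)
  r <- a$regions
  len <- r$end - r$start
  maxs <- a$genome[r$chrom] - len
  if (any(maxs < 0)) stop("region longer than its chromosome")
  null <- vapply(seq_len(n_perm), function(i) {
    # re-place each region uniformly on its chromosome; the statistic is
    # the per-region sum, so self-overlaps among permuted regions need
    # no merging
    r$start <- floor(stats::runif(nrow(r)) * (maxs + 1))
    r$end <- r$start + len
    overlap_rows(r, b$regions, mode)
  }, numeric(1L))
  extreme <- if (alternative == "greater") sum(null >= obs) else sum(null <= obs)
  p <- (1 + extreme) / (1 + n_perm)
  sd0 <- stats::sd(null)
  z <- if (is.na(sd0) || sd0 == 0) NA_real_ else (obs - mean(null)) / sd0
  structure(list(observed = obs, null = null, p_value = p, z_score = z,
                 n_perm = n_perm, alternative = alternative, mode = mode),
            class = "cpg_permtest")
}

#' @export
print.cpg_permtest <- function(x, ...) {
  cat(sprintf("Permutation overlap test (%s, alternative = %s)\n",
              x$mode, x$alternative))
  cat(sprintf("  observed %.0f, null mean %.1f (sd %.1f), %d permutations\n",
              x$observed, mean(x$null), stats::sd(x$null), x$n_perm))
  cat(sprintf("  p = %.4g, z = %.2f\n", x$p_value, x$z_score))
  invisible(x)
}
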