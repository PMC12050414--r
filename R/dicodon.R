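# In-frame codon and dicodon counting and observed/expected enrichment.
#
# Dicodons are ordered pairs of adjacent in-frame codons (overlapping,
# sliding by one codon). Expected pair counts come from the pooled codon
# frequencies of the same CDS set with stop codons excluded; the
# enrichment ratio observed/expected flags pairs a genome avoids (CpG
# junction dicodons in most vertebrates) or favours (di-alanine,
# di-proline repeats).

as_named_character <- function(x) {
  nms <- names(x)            # as.character() drops names of character input
  s <- as.character(x)
  if (!is.null(nms)) names(s) <- nms
  if (is.null(names(s))) names(s) <- as.character(seq_along(s))
  s
}

split_codons <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n %% 3L != 0L) return(NULL)
  if (n == 0L) return(character(0))
  substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Count in-frame codons in a CDS set
#'
#' Tallies every codon of every in-frame CDS. Sequences whose length is
#' not a multiple of 3 are flagged and skipped; codons containing
#' non-ACGT bases are skipped; stop codons are tallied separately and
#' excluded from sense-codon totals.
#'
#' @param cds_set Character vector, list of sequences, or
#'   `Biostrings::DNAStringSet`.
#' @param table A [codon_table()].
#' @return An object of class `codon_counts`: list with `counts` (named
#'   integer vector over the 61 sense codons), `stop_counts`, `total`
#'   (total sense codons) and `skipped` (names/indices of frame-violating
#'   sequences).
#' @examples
#' count_codons("ATGGCGTAA")$counts[c("ATG", "GCG")]
#' @export
count_codons <- function(cds_set, table = codon_table()) {
  seqs <- as_named_character(cds_set)
  counts <- integer(length(table$sense)); names(counts) <- table$sense
  stop_counts <- integer(length(table$stops)); names(stop_counts) <- table$stops
  skipped <- character(0)
  for (nm in names(seqs)) {
    cods <- split_codons(seqs[[nm]])
    if (is.null(cods)) { skipped <- c(skipped, nm); next }
    tab <- table(cods)
    ok_sense <- intersect(names(tab), table$sense)
    counts[ok_sense] <- counts[ok_sense] + as.integer(tab[ok_sense])
    ok_stop <- intersect(names(tab), table$stops)
    stop_counts[ok_stop] <- stop_counts[ok_stop] + as.integer(tab[ok_stop])
  }
  structure(list(counts = counts, stop_counts = stop_counts,
                 total = sum(counts), skipped = skipped),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon counts:", x$total, "sense codons,", sum(x$stop_counts),
      "stops")
  if (length(x$skipped)) cat(",", length(x$skipped), "sequences skipped")
  cat("\n")
  invisible(x)
}

#' Count in-frame dicodons in a CDS set
#'
#' Counts every adjacent in-frame codon pair, sliding by one codon, within
#' each CDS; pairs never span CDS boundaries. Pairs involving a stop codon
#' or a codon with non-ACGT bases are excluded. Frame-violating sequences
#' are flagged and skipped.
#'
#' @inheritParams count_codons
#' @return List with `counts` (named integer vector, names are 6-mers,
#'   only observed pairs present), `total` (total retained pairs) and
#'   `skipped`.
#' @examples
#' count_dicodons("ATGGCGGCGTAA")$counts  # ATGGCG 1, GCGGCG 1
#' @export
count_dicodons <- function(cds_set, table = codon_table()) {
  seqs <- as_named_character(cds_set)
  acc <- list(); skipped <- character(0)
  for (nm in names(seqs)) {
    cods <- split_codons(seqs[[nm]])
    if (is.null(cods)) { skipped <- c(skipped, nm); next }
    if (length(cods) < 2L) next
    ok <- cods %in% table$sense
    pair_ok <- ok[-length(ok)] & ok[-1L]
    if (!any(pair_ok)) next
    pairs <- paste0(cods[-length(cods)], cods[-1L])[pair_ok]
    acc[[nm]] <- pairs
  }
  tab <- table(unlist(acc, use.names = FALSE))
  counts <- as.integer(tab); names(counts) <- names(tab)
  list(counts = counts, total = sum(counts), skipped = skipped)
}

#' Annotate CpG positions of a dicodon
#'
#' @param dicodon 6-mer string (two codons).
#' @return Logical vector with elements `within1` (CpG inside the first
#'   codon), `within2` (inside the second), `junction` (codon 1 ends in C
#'   and codon 2 starts with G).
#' @examples
#' dicodon_cpg_flags("GCGGCG")  # within1 & within2 TRUE, junction FALSE
#' @export
dicodon_cpg_flags <- function(dicodon) {
  d <- toupper(dicodon)
  if (nchar(d) != 6L) stop("dicodon must be a 6-mer")
  c(within1 = grepl("CG", substr(d, 1L, 3L)),
    within2 = grepl("CG", substr(d, 4L, 6L)),
    junction = substr(d, 3L, 3L) == "C" && substr(d, 4L, 4L) == "G")
}

#' Dicodon observed/expected enrichment
#'
#' Expected count of a pair (c1, c2) is N f(c1) f(c2), with N the total
#' retained pairs and f the pooled sense-codon frequencies; enrichment is
#' observed/expected. Pairs with expected count below `floor` are flagged
#' low-confidence (unstable ratios). Only pairs of sense codons are
#' scored; pairs never observed get observed = 0.
#'
#' @param codon_counts A [count_codons()] result.
#' @param dicodon_counts A [count_dicodons()] result.
#' @param floor Minimum expected count for a confident ratio, default 5.
#' @param all_pairs If `TRUE` (default) score all 61 x 61 ordered sense
#'   pairs; otherwise only observed pairs.
#' @param table A [codon_table()].
#' @return Data frame of class `dicodon_enrichment` with columns
#'   `dicodon`, `aa1`, `aa2`, `observed`, `expected`, `enrichment`,
#'   `cpg_within1`, `cpg_within2`, `cpg_junction`, `low_confidence`,
#'   sorted by ascending enrichment. Zero expected with nonzero observed
#'   yields `Inf` enrichment.
#' @examples
#' cds <- c("ATGGCGGCGGCGTAA")
#' enr <- dicodon_enrichment(count_codons(cds), count_dicodons(cds))
#' head(enr, 3)
#' @export
dicodon_enrichment <- function(codon_counts, dicodon_counts, floor = 5,
                               all_pairs = TRUE, table = codon_table()) {
  if (dicodon_counts$total <= 0) stop("no dicodon pairs to score")
  f <- codon_counts$counts / codon_counts$total
  N <- dicodon_counts$total
  if (all_pairs) {
    pairs <- as.vector(outer(table$sense, table$sense,
                             function(a, b) paste0(a, b)))
  } else {
    pairs <- names(dicodon_counts$counts)
  }
  c1 <- substr(pairs, 1L, 3L); c2 <- substr(pairs, 4L, 6L)
  observed <- dicodon_counts$counts[pairs]
  observed[is.na(observed)] <- 0L
  expected <- N * f[c1] * f[c2]
  enrichment <- ifelse(expected > 0, observed / expected,
                       ifelse(observed > 0, Inf, NA_real_))
  out <- data.frame(
    dicodon = pairs,
    aa1 = unname(table$mapping[c1]),
    aa2 = unname(table$mapping[c2]),
    observed = as.integer(observed),
    expected = unname(expected),
    enrichment = unname(enrichment),
    cpg_within1 = grepl("CG", c1),
    cpg_within2 = grepl("CG", c2),
    cpg_junction = substr(c1, 3L, 3L) == "C" & substr(c2, 1L, 1L) == "G",
    low_confidence = unname(expected) < floor,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$enrichment, out$dicodon), ]
  rownames(out) <- NULL
  class(out) <- c("dicodon_enrichment", "data.frame")
  out
}

#' Top under- and over-represented dicodons
#'
#' @param enrichment A [dicodon_enrichment()] result.
#' @param k Number of pairs to report at each extreme, default 3.
#' @param drop_low_confidence Exclude pairs flagged `low_confidence`,
#'   default `TRUE`.
#' @return List with data frames `under` (ascending enrichment) and
#'   `over` (descending).
#' @export
top_dicodons <- function(enrichment, k = 3L, drop_low_confidence = TRUE) {
  x <- enrichment
  if (drop_low_confidence) x <- x[!x$low_confidence, ]
  x <- x[is.finite(x$enrichment), ]
  list(under = utils::head(x[order(x$enrichment, x$dicodon), ], k),
       over = utils::head(x[order(-x$enrichment, x$dicodon), ], k))
}
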