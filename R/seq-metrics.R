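# Dinucleotide counting and the normalised CpG-content statistic.
#
# CpG content of a stretch of DNA is measured as #CpG / (#CpG + #GpC) over
# overlapping dinucleotide windows (step 1). GpC has the same base content
# as CpG but is not a methylation target, so the ratio is insensitive to GC
# fraction and window length; 0.5 is the neutral expectation under base
# independence and the statistic is bounded in [0, 1].

as_dna_string <- function(sequence) {
  if (methods::is(sequence, "DNAString")) return(sequence)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single character string or DNAString")
  Biostrings::DNAString(toupper(sequence))
}

#' Count CpG and GpC dinucleotides in a sequence
#'
#' Overlapping scan with step 1. Windows containing any non-ACGT base
#' (e.g. assembly N runs, IUPAC ambiguity codes) are skipped and do not
#' count towards the number of valid windows. Case-insensitive;
#' soft-masked lowercase bases are treated as ordinary bases.
#'
#' @param sequence Character string or `Biostrings::DNAString`.
#' @return An object of class `dinuc_counts`: list with `n_cpg`, `n_gpc`,
#'   `n_windows` (dinucleotide windows with both bases in ACGT) and
#'   `length` (bases). An empty sequence gives all-zero counts.
#' @examples
#' count_dinucleotides("CGCG")  # n_cpg 2, n_gpc 1
#' count_dinucleotides("AT")    # both 0
#' @export
count_dinucleotides <- function(sequence) {
  s <- as_dna_string(sequence)
  if (length(s) < 2L) {
    out <- list(n_cpg = 0L, n_gpc = 0L, n_windows = 0L, length = length(s))
  } else {
    f <- Biostrings::dinucleotideFrequency(s, step = 1L)
    out <- list(n_cpg = unname(f["CG"]), n_gpc = unname(f["GC"]),
                n_windows = sum(f), length = length(s))
  }
  class(out) <- "dinuc_counts"
  out
}

#' @export
print.dinuc_counts <- function(x, ...) {
  cat(sprintf("dinucleotide counts: CpG %d, GpC %d (%d valid windows, %d bases)\n",
              x$n_cpg, x$n_gpc, x$n_windows, x$length))
  invisible(x)
}

#' Normalised CpG content of a sequence or of dinucleotide counts
#'
#' CpG content = #CpG / (#CpG + #GpC), bounded in \[0, 1\]. Sequences (or
#' windows) lacking both CpG and GpC dinucleotides have an undefined
#' content and must be excluded by callers; this returns `NA` with
#' attribute `undefined = TRUE` in that case.
#'
#' @param x A `dinuc_counts` object, a sequence (character/`DNAString`),
#'   or a numeric vector `c(n_cpg, n_gpc)`.
#' @return Numeric scalar in \[0, 1\], or `NA` (attribute `undefined`)
#'   when `n_cpg + n_gpc == 0`.
#' @examples
#' cpg_content(c(2, 1))     # 2/3
#' cpg_content("ATATAT")    # NA (undefined)
#' @export
cpg_content <- function(x) {
  if (inherits(x, "dinuc_counts")) {
    n_cpg <- x$n_cpg; n_gpc <- x$n_gpc
  } else if (is.numeric(x) && length(x) == 2L) {
    n_cpg <- x[[1L]]; n_gpc <- x[[2L]]
  } else {
    cc <- count_dinucleotides(x)
    n_cpg <- cc$n_cpg; n_gpc <- cc$n_gpc
  }
  if (n_cpg < 0 || n_gpc < 0) stop("negative dinucleotide counts")
  if (n_cpg + n_gpc == 0)
    return(structure(NA_real_, undefined = TRUE))
  n_cpg / (n_cpg + n_gpc)
}

#' Expected CpG frequency under base independence
#'
#' If bases are independent, the per-window probability of a CpG is
#' P(C) P(G) where P(C) = gc (1 - bias) and P(G) = gc bias, with gc the
#' G+C fraction and bias the strand bias G/(G+C). Because P(CpG) = P(GpC)
#' under independence, the implied neutral value of the normalised content
#' statistic is 0.5 regardless of composition.
#'
#' @param gc_fraction G+C fraction of the sequence, in \[0, 1\].
#' @param strand_bias G/(G+C), in \[0, 1\].
#' @return List with `p_cpg` (expected per-window CpG probability,
#'   `gc_fraction^2 * strand_bias * (1 - strand_bias)`) and
#'   `neutral_content` (always 0.5).
#' @examples
#' expected_cpg_frequency(0.5, 0.5)$p_cpg  # 0.0625
#' @export
expected_cpg_frequency <- function(gc_fraction, strand_bias) {
  if (gc_fraction < 0 || gc_fraction > 1 || strand_bias < 0 || strand_bias > 1)
    stop("gc_fraction and strand_bias must lie in [0, 1]")
  list(p_cpg = gc_fraction^2 * strand_bias * (1 - strand_bias),
       neutral_content = 0.5)
}

#' Base composition with CpG/GpC-masked GC content
#'
#' Returns the G+C fraction, the strand bias G/(G+C), and the GC fraction
#' computed after masking every base that participates in an overlapping
#' CG or GC dinucleotide window. The masked variant decouples GC
#' composition from the CpG/GpC dinucleotides themselves when correlating
#' CpG content with base composition.
#'
#' @param sequence Character string or `DNAString`.
#' @return List with `gc_fraction`, `strand_bias` (`NA` with attribute
#'   `undefined` when the sequence has no G or C), and
#'   `gc_excluding_cpg_gpc` (`NA`/`undefined` when no unmasked ACGT base
#'   remains).
#' @examples
#' composition_stats("ATCGAT")$gc_excluding_cpg_gpc  # 0: only "ATAT" left
#' @export
composition_stats <- function(sequence) {
  s <- as_dna_string(sequence)
  ch <- strsplit(as.character(s), "")[[1L]]
  acgt <- ch %in% c("A", "C", "G", "T")
  nG <- sum(ch == "G"); nC <- sum(ch == "C")
  n_acgt <- sum(acgt)
  gc_fraction <- if (n_acgt > 0) (nG + nC) / n_acgt else
    structure(NA_real_, undefined = TRUE)
  strand_bias <- if (nG + nC > 0) nG / (nG + nC) else
    structure(NA_real_, undefined = TRUE)
  n <- length(ch)
  mask <- rep(FALSE, n)
  if (n >= 2L) {
    a <- ch[-n]; b <- ch[-1L]
    hit <- (a == "C" & b == "G") | (a == "G" & b == "C")
    idx <- which(hit)
    mask[idx] <- TRUE
    mask[idx + 1L] <- TRUE
  }
  keep <- acgt & !mask
  gc_ex <- if (sum(keep) > 0) sum(ch[keep] %in% c("G", "C")) / sum(keep) else
    structure(NA_real_, undefined = TRUE)
  list(gc_fraction = gc_fraction, strand_bias = strand_bias,
       gc_excluding_cpg_gpc = gc_ex)
}

#' GC content excluding CpG and GpC sites
#'
#' Convenience accessor for the masked GC fraction of
#' [composition_stats()].
#' @param sequence Character string or `DNAString`.
#' @return Numeric scalar, or `NA` (attribute `undefined`) when every
#'   remaining base is masked.
#' @export
gc_content_excluding_cpg_gpc <- function(sequence) {
  composition_stats(sequence)$gc_excluding_cpg_gpc
}

#' Tile a sequence into fixed-width genomic fragments
#'
#' Consecutive non-overlapping tiles of `width` bases anchored at
#' coordinate 0; the final tile keeps whatever remains (scaffolds shorter
#' than `width` yield a single short tile). Each tile carries its
#' dinucleotide counts and CpG content; tiles lacking both CpG and GpC are
#' flagged excluded rather than dropped.
#'
#' @param sequence Character string or `DNAString`.
#' @param width Tile width in bases, default 5000.
#' @param id Sequence name used in the output.
#' @return Data frame with columns `id`, `start`, `end` (0-based,
#'   half-open), `length`, `n_cpg`, `n_gpc`, `cpg_content`, `excluded`,
#'   `reason`.
#' @examples
#' nrow(tile_sequence(strrep("ACGT", 3000), width = 5000))  # 3 tiles
#' @export
tile_sequence <- function(sequence, width = 5000L, id = "seq") {
  if (width <= 0) stop("'width' must be positive")
  s <- as_dna_string(sequence)
  n <- length(s)
  if (n == 0L)
    return(data.frame(id = character(0), start = integer(0), end = integer(0),
                      length = integer(0), n_cpg = integer(0),
                      n_gpc = integer(0), cpg_content = numeric(0),
                      excluded = logical(0), reason = character(0),
                      stringsAsFactors = FALSE))
  starts <- seq.int(0L, n - 1L, by = width)
  ends <- pmin(starts + width, n)
  rows <- lapply(seq_along(starts), function(i) {
    cc <- count_dinucleotides(Biostrings::subseq(s, starts[i] + 1L, ends[i]))
    val <- cpg_content(cc)
    undef <- isTRUE(attr(val, "undefined"))
    data.frame(id = id, start = starts[i], end = ends[i],
               length = ends[i] - starts[i],
               n_cpg = cc$n_cpg, n_gpc = cc$n_gpc,
               cpg_content = as.numeric(val),
               excluded = undef,
               reason = if (undef) "zero_denominator" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Terminal 99-bp windows of a coding sequence
#'
#' The first and last 99 coding bases (33 codons each) of a CDS, used to
#' contrast CpG content at the 5'/N-terminal end with the 3'/C-terminal
#' end. Sequences shorter than 200 nt are excluded so the two windows are
#' always distinct.
#'
#' @param cds_sequence Character string or `DNAString`.
#' @param width Window width in bases, default 99.
#' @param min_length Minimum CDS length, default 200.
#' @return List with `first` and `last` (character), or `NULL` with a
#'   warning-free exclusion signal: the function returns
#'   `structure(NULL, excluded = "short")` when the CDS is too short.
#' @examples
#' w <- terminal_windows(strrep("ACG", 100))  # 300 nt
#' nchar(w$first)  # 99
#' @export
terminal_windows <- function(cds_sequence, width = 99L, min_length = 200L) {
  s <- as_dna_string(cds_sequence)
  n <- length(s)
  if (n < min_length) return(structure(list(), excluded = "short"))
  list(first = as.character(Biostrings::subseq(s, 1L, width)),
       last = as.character(Biostrings::subseq(s, n - width + 1L, n)))
}
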