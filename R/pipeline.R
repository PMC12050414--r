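# Orchestration of the empirical comparisons: gene filtering, per-gene
# and per-fragment CpG statistics, the coding vs genomic contrast
# (Mann-Whitney U), the CpG-content vs GC-content correlation (Kendall
# tau + OLS), the 5' vs 3' terminal-window contrast (paired Wilcoxon
# signed-rank), and a deterministic end-to-end run writing TSV tables and
# a JSON summary.

parse_gene_headers <- function(headers) {
  # "<gene_id> <symbol> ..." convention; symbol NA when absent
  ids <- sub("\\s.*$", "", headers)
  rest <- sub("^\\S+\\s*", "", headers)
  symbols <- sub("\\s.*$", "", rest)
  symbols[symbols == "" | rest == headers] <- NA_character_
  data.frame(gene_id = ids, gene_symbol = symbols, stringsAsFactors = FALSE)
}

#' Per-gene CpG statistics table
#'
#' Computes, for every CDS record, the dinucleotide counts, normalised
#' CpG content, base composition (including GC content with CpG/GpC
#' bases masked) and terminal-window CpG contents, together with the
#' exclusion flags used downstream.
#'
#' @param cds A named character vector or `Biostrings::DNAStringSet`
#'   (names `"<gene_id> <symbol>"`), or a FASTA path.
#' @param symbol_exclude Regular expression for placeholder symbols to
#'   treat as absent (default RefSeq-style `LOC` location indices).
#' @param min_length Minimum CDS length for terminal-window analysis,
#'   default 200 nt.
#' @param terminal Terminal-window width, default 99 nt.
#' @return Data frame with one row per input gene: `gene_id`,
#'   `gene_symbol`, `length`, `n_cpg`, `n_gpc`, `cpg_content`,
#'   `gc_fraction`, `strand_bias`, `gc_excluding`, `first_content`,
#'   `last_content`, and logical flags `no_symbol`, `short`,
#'   `zero_denominator`, `frame_violation`, `retained`.
#' @export
gene_table <- function(cds, symbol_exclude = "^LOC\\d+$",
                       min_length = 200L, terminal = 99L) {
  seqs <- load_sequences(cds)
  hdr <- parse_gene_headers(names(seqs))
  n <- length(seqs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    L <- nchar(s)
    cc <- count_dinucleotides(s)
    val <- cpg_content(cc)
    comp <- composition_stats(s)
    short <- L < min_length
    fc <- lc <- NA_real_
    if (!short) {
      w <- terminal_windows(s, width = terminal, min_length = min_length)
      fc <- as.numeric(cpg_content(w$first))
      lc <- as.numeric(cpg_content(w$last))
    }
    rows[[i]] <- data.frame(
      gene_id = hdr$gene_id[i], gene_symbol = hdr$gene_symbol[i],
      length = L, n_cpg = cc$n_cpg, n_gpc = cc$n_gpc,
      cpg_content = as.numeric(val),
      gc_fraction = as.numeric(comp$gc_fraction),
      strand_bias = as.numeric(comp$strand_bias),
      gc_excluding = as.numeric(comp$gc_excluding_cpg_gpc),
      first_content = fc, last_content = lc,
      no_symbol = is.na(hdr$gene_symbol[i]) ||
        grepl(symbol_exclude, hdr$gene_symbol[i]),
      short = short,
      zero_denominator = isTRUE(attr(val, "undefined")),
      frame_violation = L %% 3L != 0L,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$retained <- !out$no_symbol & !out$zero_denominator
  out
}

load_sequences <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    s <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- as.character(Biostrings::readDNAStringSet(x))
  } else if (is.character(x)) {
    s <- x
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  } else stop("cannot interpret sequence input")
  toupper(s)
}

#' Filter genes and build an exclusion ledger
#'
#' Retains genes with a real gene symbol (no RefSeq-style location
#' placeholder) and a defined CpG content; every excluded gene is listed
#' in the ledger with its reason so the retained set and the ledger
#' exactly partition the input. The length and frame flags are carried
#' through but only applied by the analyses that need them
#' (terminal-window contrast, dicodon counting).
#'
#' @inheritParams gene_table
#' @return List with `genes` (retained rows of [gene_table()]) and
#'   `ledger` (data frame `gene_id`, `reason`; one row per exclusion
#'   reason per gene).
#' @export
filter_genes <- function(cds, symbol_exclude = "^LOC\\d+$",
                         min_length = 200L, terminal = 99L) {
  tab <- gene_table(cds, symbol_exclude, min_length, terminal)
  reasons <- list(no_symbol = tab$no_symbol,
                  zero_denominator = tab$zero_denominator)
  ledger <- do.call(rbind, lapply(names(reasons), function(r) {
    hit <- reasons[[r]]
    if (!any(hit)) return(NULL)
    data.frame(gene_id = tab$gene_id[hit], reason = r,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ledger))
    ledger <- data.frame(gene_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  list(genes = tab[tab$retained, , drop = FALSE], ledger = ledger)
}

new_cpg_htest <- function(test_name, ht, n, direction, extra = list()) {
  structure(c(list(test_name = test_name,
                   statistic = unname(ht$statistic),
                   p_value = unname(ht$p.value),
                   n = n, direction = direction), extra),
            class = "cpg_htest")
}

#' @export
print.cpg_htest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test_name,
              x$statistic, x$p_value, paste(x$n, collapse = " vs ")))
  if (!is.null(x$direction) && !is.na(x$direction))
    cat("  direction:", x$direction, "\n")
  if (!is.null(x$tau))
    cat(sprintf("  tau = %.3f; OLS slope = %.4g (p = %.3g), intercept = %.4g\n",
                x$tau, x$slope, x$slope_p, x$intercept))
  invisible(x)
}

#' Coding vs genomic CpG content (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of per-gene CpG
#' content against per-fragment genomic CpG content.
#'
#' @param gene_contents Numeric vector of per-gene CpG contents.
#' @param fragment_contents Numeric vector of per-fragment contents.
#' @return `cpg_htest` with medians and effect direction
#'   (`"coding > genomic"`, `"genomic > coding"` or `"none"`).
#' @export
coding_vs_genomic <- function(gene_contents, fragment_contents) {
  x <- gene_contents[!is.na(gene_contents)]
  y <- fragment_contents[!is.na(fragment_contents)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ht <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  dmed <- stats::median(x) - stats::median(y)
  dir <- if (dmed > 0) "coding > genomic"
         else if (dmed < 0) "genomic > coding" else "none"
  new_cpg_htest("mann_whitney_u", ht, c(length(x), length(y)), dir,
                list(median_coding = stats::median(x),
                     median_genomic = stats::median(y)))
}

#' CpG content vs GC content correlation (Kendall tau + OLS)
#'
#' Kendall rank correlation between per-gene CpG content and GC content
#' computed with CpG/GpC bases masked, plus an ordinary least-squares
#' fit. Only genes inside the length window (default 150 to 2000 nt) are
#' used; this window applies to the correlation analysis only.
#'
#' @param genes A [gene_table()]-style data frame (needs `cpg_content`,
#'   `gc_excluding`, `length`).
#' @param min_len,max_len Length window in nt, defaults 150 and 2000.
#' @return `cpg_htest` with `tau`, `slope`, `intercept`, `slope_p`.
#' @export
content_gc_correlation <- function(genes, min_len = 150L, max_len = 2000L) {
  d <- genes[genes$length >= min_len & genes$length <= max_len &
               !is.na(genes$cpg_content) & !is.na(genes$gc_excluding), ]
  if (nrow(d) < 3L) stop("need at least 3 genes after the length filter")
  if (stats::sd(d$cpg_content) == 0 || stats::sd(d$gc_excluding) == 0)
    return(structure(list(test_name = "kendall_tau", statistic = NA_real_,
                          p_value = NA_real_, n = nrow(d),
                          direction = NA_character_, tau = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          slope_p = NA_real_, degenerate = TRUE),
                     class = "cpg_htest"))
  ht <- stats::cor.test(d$gc_excluding, d$cpg_content, method = "kendall",
                        exact = FALSE)
  fit <- stats::lm(cpg_content ~ gc_excluding, data = d)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  tau <- unname(ht$estimate)
  new_cpg_htest("kendall_tau", ht, nrow(d),
                if (tau > 0) "positive" else if (tau < 0) "negative" else "none",
                list(tau = tau,
                     slope = unname(stats::coef(fit)[2L]),
                     intercept = unname(stats::coef(fit)[1L]),
                     slope_p = sm$coefficients[2L, 4L],
                     degenerate = FALSE))
}

#' 5' vs 3' terminal-window CpG content (paired Wilcoxon)
#'
#' Paired Wilcoxon signed-rank test of the CpG content of the first
#' against the last terminal window of each gene. Genes failing the
#' 200-nt rule or with undefined content in either window are dropped
#' (their ids are reported).
#'
#' @param genes A [gene_table()]-style data frame (needs
#'   `first_content`, `last_content`, `short`).
#' @return `cpg_htest` with direction (`"start > end"` or
#'   `"end > start"`) and `dropped` (gene ids without a valid pair).
#' @export
start_vs_end <- function(genes) {
  ok <- !genes$short & !is.na(genes$first_content) &
    !is.na(genes$last_content)
  if (sum(ok) < 1L) stop("no valid gene pairs")
  first <- genes$first_content[ok]
  last <- genes$last_content[ok]
  if (all(first == last)) {
    # all differences zero: no evidence either way
    ht <- list(statistic = c(V = 0), p.value = 1)
  } else {
    ht <- stats::wilcox.test(first, last, paired = TRUE,
                             alternative = "two.sided", exact = FALSE)
  }
  dmed <- stats::median(first - last)
  dir <- if (dmed > 0) "start > end" else if (dmed < 0) "end > start" else "none"
  new_cpg_htest("wilcoxon_signed_rank", ht, sum(ok), dir,
                list(median_difference = dmed,
                     dropped = genes$gene_id[!ok]))
}

#' Genomic fragment CpG statistics
#'
#' Tiles every chromosome/scaffold of a genome into fixed-width
#' fragments and computes per-fragment dinucleotide counts and CpG
#' content.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param fragment_size Tile width in bases, default 5000.
#' @return Data frame as in [tile_sequence()], rows pooled over
#'   chromosomes.
#' @export
fragment_table <- function(genome, fragment_size = 5000L) {
  seqs <- load_sequences(genome)
  out <- do.call(rbind, lapply(names(seqs), function(nm)
    tile_sequence(seqs[[nm]], width = fragment_size, id = nm)))
  rownames(out) <- NULL
  out
}

fmt_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Run the full CpG-landscape analysis for one species
#'
#' End-to-end deterministic run: filters the CDS set, computes per-gene
#' and per-fragment statistics, the three named hypothesis tests, the
#' dicodon enrichment table, and writes everything (per-gene table,
#' per-fragment table, test results, dicodon table, exclusion ledger,
#' run manifest) to `out_dir`. Two runs on identical inputs produce
#' byte-identical outputs.
#'
#' @param cds CDS input (named sequences or FASTA path).
#' @param genome Genome input (named sequences or FASTA path).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param fragment_size Genomic tile width, default 5000.
#' @param terminal Terminal-window width, default 99.
#' @param symbol_exclude Placeholder-symbol regex, see [filter_genes()].
#' @param min_length Minimum CDS length for the terminal contrast,
#'   default 200.
#' @param cor_min_len,cor_max_len Length window for the correlation
#'   analysis, defaults 150 and 2000.
#' @param top_k Dicodons reported at each extreme, default 3.
#' @return Object of class `cpg_landscape`: list with `genes`,
#'   `fragments`, `ledger`, `tests` (list of `cpg_htest`), `dicodons`,
#'   `top_dicodons`, `config`.
#' @export
run_species <- function(cds, genome, out_dir = NULL,
                        fragment_size = 5000L, terminal = 99L,
                        symbol_exclude = "^LOC\\d+$", min_length = 200L,
                        cor_min_len = 150L, cor_max_len = 2000L,
                        top_k = 3L) {
  config <- list(fragment_size = fragment_size, terminal = terminal,
                 symbol_exclude = symbol_exclude, min_length = min_length,
                 cor_min_len = cor_min_len, cor_max_len = cor_max_len,
                 top_k = top_k)
  fg <- filter_genes(cds, symbol_exclude, min_length, terminal)
  if (nrow(fg$genes) == 0L)
    stop("no genes retained after filtering (",
         nrow(fg$ledger), " exclusions)")
  frags <- fragment_table(genome, fragment_size)
  tests <- list(
    coding_vs_genomic = coding_vs_genomic(
      fg$genes$cpg_content, frags$cpg_content[!frags$excluded]),
    content_gc_correlation = content_gc_correlation(
      fg$genes, cor_min_len, cor_max_len),
    start_vs_end = start_vs_end(fg$genes)
  )
  seqs <- load_sequences(cds)
  hdr <- parse_gene_headers(names(seqs))
  retained_seqs <- seqs[hdr$gene_id %in% fg$genes$gene_id]
  cc <- count_codons(retained_seqs)
  dc <- count_dicodons(retained_seqs)
  enr <- dicodon_enrichment(cc, dc)
  res <- structure(list(genes = fg$genes, fragments = frags,
                        ledger = fg$ledger, tests = tests, dicodons = enr,
                        top_dicodons = top_dicodons(enr, top_k),
                        config = config),
                   class = "cpg_landscape")
  if (!is.null(out_dir)) write_run(res, out_dir, cds, genome)
  res
}

write_run <- function(res, out_dir, cds, genome) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt_tsv(res$genes, file.path(out_dir, "per_gene.tsv"))
  fmt_tsv(res$fragments, file.path(out_dir, "per_fragment.tsv"))
  fmt_tsv(res$dicodons, file.path(out_dir, "dicodon.tsv"))
  fmt_tsv(res$ledger, file.path(out_dir, "exclusions.tsv"))
  tests <- lapply(res$tests, function(t) t[setdiff(names(t), "dropped")])
  jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "cpglandscape",
    version = as.character(utils::packageVersion("cpglandscape")),
    config = res$config,
    input_md5 = list(
      cds = if (is.character(cds) && length(cds) == 1L && file.exists(cds))
        unname(tools::md5sum(cds)) else NA,
      genome = if (is.character(genome) && length(genome) == 1L &&
                   file.exists(genome))
        unname(tools::md5sum(genome)) else NA),
    n_genes_retained = nrow(res$genes),
    n_fragments = nrow(res$fragments))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cpg_landscape <- function(x, ...) {
  cat("CpG landscape run\n")
  cat(" ", nrow(x$genes), "genes retained,", nrow(x$ledger),
      "exclusions;", nrow(x$fragments), "genomic fragments\n")
  for (t in x$tests) print(t)
  invisible(x)
}

#' @method summary cpg_landscape
#' @export
summary.cpg_landscape <- function(object, ...) {
  cat("CpG landscape run summary\n")
  cat("  genes retained:   ", nrow(object$genes), "\n")
  cat("  median gene CpG content:    ",
      signif(stats::median(object$genes$cpg_content), 4), "\n")
  ok <- !object$fragments$excluded
  cat("  median fragment CpG content:",
      signif(stats::median(object$fragments$cpg_content[ok]), 4), "\n")
  for (t in object$tests) print(t)
  cat("  top underrepresented dicodons:",
      paste(object$top_dicodons$under$dicodon, collapse = " "), "\n")
  cat("  top overrepresented dicodons: ",
      paste(object$top_dicodons$over$dicodon, collapse = " "), "\n")
  invisible(object)
}
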