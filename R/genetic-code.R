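#' The standard genetic code as a codon table
#'
#' Builds the codon table used by all genetic-code combinatorics in this
#' package: the 64 DNA codons (uppercase, T not U) of the standard code,
#' partitioned into 61 sense codons and the 3 stop codons, with initiator
#' codons flagged.
#'
#' @param code_id Identifier of the code; only `"standard"` is built in, but
#'   a custom table can be supplied wherever a `codon_table` is accepted.
#' @return An object of class `codon_table`: a list with elements
#'   `code_id`, `mapping` (named character vector, codon to single-letter
#'   amino acid, `"*"` for stop), `sense` (61 codons), `stops` (3 codons),
#'   `starts` (initiator codons, at minimum `ATG`), and `amino_acids`
#'   (the 20 encoded letters).
#' @examples
#' tab <- codon_table()
#' length(tab$sense)   # 61
#' tab$mapping["ATG"]  # "M"
#' @export
codon_table <- function(code_id = "standard") {
  if (!identical(code_id, "standard"))
    stop("only the standard genetic code is built in")
  mapping <- Biostrings::GENETIC_CODE
  stops <- names(mapping)[mapping == "*"]
  sense <- names(mapping)[mapping != "*"]
  starts <- c("ATG", attr(Biostrings::GENETIC_CODE, "alt_init_codons"))
  out <- list(
    code_id = code_id,
    mapping = mapping,
    sense = sense,
    stops = stops,
    starts = starts,
    amino_acids = sort(unique(unname(mapping[sense])))
  )
  stopifnot(length(out$sense) == 61L, length(out$stops) == 3L,
            all(c("TAA", "TAG", "TGA") %in% out$stops))
  class(out) <- "codon_table"
  out
}

#' @export
print.codon_table <- function(x, ...) {
  cat("Codon table:", x$code_id, "\n")
  cat(" ", length(x$sense), "sense codons,", length(x$stops),
      "stop codons (", paste(x$stops, collapse = ", "), ")\n")
  cat("  starts:", paste(x$starts, collapse = ", "), "\n")
  invisible(x)
}

aa_of <- function(codons, table) unname(table$mapping[codons])

is_stop <- function(codon, table) codon %in% table$stops

check_codon <- function(codon, table, allow_stop = FALSE) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("'codon' must be a single 3-letter string")
  codon <- toupper(codon)
  if (!codon %in% names(table$mapping))
    stop("not a DNA codon: ", codon)
  if (!allow_stop && is_stop(codon, table))
    stop("stop codon not allowed here: ", codon)
  codon
}

#' Enumerate CpG-bearing codons of a genetic code
#'
#' Splits the codons of a genetic code by how they can participate in a CpG
#' dinucleotide: a CpG wholly within the codon at bases 1-2 (`CGN`) or at
#' bases 2-3 (`NCG`), or a CpG formed across a codon junction by a C-ending
#' codon followed by a G-starting codon.
#'
#' In the standard code the four `CGN` codons all encode arginine; the four
#' `NCG` codons encode serine, proline, threonine and alanine; 16 sense
#' codons end in C (15 distinct amino acids) and 16 start with G.
#'
#' @param table A [codon_table()].
#' @return An object of class `cpg_codon_report`: a list with codon sets
#'   `within_pos12`, `within_pos23`, `c_ending`, `g_starting` (sense codons
#'   only) and the corresponding amino-acid sets `aa_pos12`, `aa_pos23`,
#'   `aa_c_ending`, `aa_g_starting`, plus `within_all` / `aa_within_all`
#'   for the union of within-codon CpG codons.
#' @examples
#' rep <- enumerate_cpg_codons(codon_table())
#' rep$within_pos12          # CGT CGC CGA CGG
#' rep$aa_pos23              # A P S T
#' length(rep$within_all)    # 8
#' @export
enumerate_cpg_codons <- function(table = codon_table()) {
  sense <- table$sense
  within_pos12 <- sense[substr(sense, 1L, 2L) == "CG"]
  within_pos23 <- sense[substr(sense, 2L, 3L) == "CG"]
  c_ending <- sense[substr(sense, 3L, 3L) == "C"]
  g_starting <- sense[substr(sense, 1L, 1L) == "G"]
  within_all <- union(within_pos12, within_pos23)
  out <- list(
    within_pos12 = within_pos12,
    within_pos23 = within_pos23,
    within_all = within_all,
    c_ending = c_ending,
    g_starting = g_starting,
    aa_pos12 = sort(unique(aa_of(within_pos12, table))),
    aa_pos23 = sort(unique(aa_of(within_pos23, table))),
    aa_within_all = sort(unique(aa_of(within_all, table))),
    aa_c_ending = sort(unique(aa_of(c_ending, table))),
    aa_g_starting = sort(unique(aa_of(g_starting, table)))
  )
  class(out) <- "cpg_codon_report"
  out
}

#' @export
print.cpg_codon_report <- function(x, ...) {
  cat("CpG codon report\n")
  cat("  CpG at codon bases 1-2:", paste(x$within_pos12, collapse = " "),
      " -> ", paste(x$aa_pos12, collapse = ""), "\n")
  cat("  CpG at codon bases 2-3:", paste(x$within_pos23, collapse = " "),
      " -> ", paste(x$aa_pos23, collapse = ""), "\n")
  cat("  within-codon CpG total:", length(x$within_all), "codons /",
      length(x$aa_within_all), "amino acids\n")
  cat("  C-ending codons:", length(x$c_ending), "(",
      length(x$aa_c_ending), "amino acids )\n")
  cat("  G-starting codons:", length(x$g_starting), "(",
      length(x$aa_g_starting), "amino acids )\n")
  invisible(x)
}

#' Amino acids that can never sit in a CpG context
#'
#' An amino acid is CpG-context-free when none of its codons contains a CG,
#' none ends in C (so it cannot donate the C of a junction CpG) and none
#' starts with G (so it cannot donate the G). For the standard code these
#' are methionine, glutamine and tryptophan.
#'
#' @param table A [codon_table()].
#' @return Sorted character vector of single-letter amino acids.
#' @examples
#' never_cpg_amino_acids()  # "M" "Q" "W"
#' @export
never_cpg_amino_acids <- function(table = codon_table()) {
  sense <- table$sense
  bad <- grepl("CG", sense) |
    substr(sense, 3L, 3L) == "C" |
    substr(sense, 1L, 1L) == "G"
  aa <- table$amino_acids
  keep <- vapply(aa, function(a) {
    cods <- sense[table$mapping[sense] == a]
    !any(bad[match(cods, sense)])
  }, logical(1L))
  sort(aa[keep])
}

#' The CpG-free codon repertoire
#'
#' Removes from the sense codons (a) the eight codons carrying a
#' within-codon CpG and (b) the remaining C-ending codons, which could form
#' a CpG across a codon junction when followed by a G-starting codon. The
#' 38 codons that remain can be concatenated in any order without ever
#' creating a CpG dinucleotide, and still cover all 20 amino acids, so in
#' principle any protein can be encoded CpG-free.
#'
#' @param table A [codon_table()].
#' @return A list with `codons` (the retained sense codons), `complete`
#'   (`TRUE` iff every amino acid keeps at least one codon), and
#'   `removed_within` / `removed_junction` (the excluded codon sets).
#' @examples
#' fs <- cpg_free_codons()
#' length(fs$codons)  # 38
#' fs$complete        # TRUE
#' @export
cpg_free_codons <- function(table = codon_table()) {
  sense <- table$sense
  within <- sense[grepl("CG", sense)]
  rest <- setdiff(sense, within)
  junction <- rest[substr(rest, 3L, 3L) == "C"]
  keep <- setdiff(rest, junction)
  covered <- sort(unique(aa_of(keep, table)))
  list(
    codons = keep,
    complete = identical(covered, table$amino_acids),
    removed_within = within,
    removed_junction = junction
  )
}

#' Dicodon space of the full and CpG-free codon repertoires
#'
#' Counts ordered codon pairs: all sense-codon pairs (61 x 61 = 3721 for
#' the standard code) versus pairs drawn from the CpG-free repertoire
#' (38 x 38 = 1444), and the percent reduction.
#'
#' @param table A [codon_table()].
#' @return List with `all_sense_pairs`, `cpg_free_pairs`,
#'   `reduction_percent`.
#' @examples
#' dicodon_space()  # 3721, 1444, 61.2%
#' @export
dicodon_space <- function(table = codon_table()) {
  n_sense <- length(table$sense)
  n_free <- length(cpg_free_codons(table)$codons)
  list(
    all_sense_pairs = n_sense^2,
    cpg_free_pairs = n_free^2,
    reduction_percent = 100 * (1 - n_free^2 / n_sense^2)
  )
}

synonymous_neighbors <- function(codon, table) {
  # sense codons for the same amino acid reachable by one substitution
  aa <- table$mapping[codon]
  syn <- table$sense[table$mapping[table$sense] == aa]
  syn <- setdiff(syn, codon)
  hits <- vapply(syn, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(codon, "")[[1]]) == 1L
  }, logical(1L))
  syn[hits]
}

#' Minimal synonymous mutation path to a CpG-free codon
#'
#' Shortest number of single-nucleotide synonymous substitutions (every
#' intermediate a sense codon for the same amino acid) needed to turn a
#' codon into one containing no CG dinucleotide. Junction-formed CpG is
#' ignored: the question is codon-internal. `CGT` and `CGC` are the only
#' codons needing two steps; `CGA` and `CGG` escape in one (to `AGA`/`AGG`);
#' every `NCG` codon escapes in one third-position change.
#'
#' @param codon A sense codon.
#' @param table A [codon_table()].
#' @return Non-negative integer; `0` if the codon is already CpG-free;
#'   `Inf` if no synonymous path reaches a CpG-free codon.
#' @examples
#' min_synonymous_steps("CGC")  # 2
#' min_synonymous_steps("CGA")  # 1
#' min_synonymous_steps("TTT")  # 0
#' @export
min_synonymous_steps <- function(codon, table = codon_table()) {
  codon <- check_codon(codon, table)
  if (!grepl("CG", codon)) return(0L)
  # breadth-first search over the synonymous single-substitution graph
  frontier <- codon
  seen <- codon
  steps <- 0L
  while (length(frontier) > 0L) {
    steps <- steps + 1L
    nxt <- unique(unlist(lapply(frontier, synonymous_neighbors, table = table)))
    nxt <- setdiff(nxt, seen)
    if (length(nxt) == 0L) return(Inf)
    if (any(!grepl("CG", nxt))) return(steps)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

#' Effect of a methylation-driven mutation on a codon
#'
#' Methylated CpG sites deaminate to TpG (C to T on the strand carrying the
#' C) or, seen on the coding strand when the methylated C lies on the
#' complement, to CpA (G to A). Given a codon with a CpG at bases 1-2
#' (`CGN`) or bases 2-3 (`NCG`), this classifies the mutated codon as
#' synonymous, nonsynonymous or nonsense.
#'
#' @param codon Codon carrying the CpG (sense codon).
#' @param position `"1-2"` for a CpG at codon bases 1-2, `"2-3"` for bases
#'   2-3.
#' @param change `"CG>TG"` (deamination of the C) or `"CG>CA"`
#'   (deamination on the complementary strand, G to A).
#' @param table A [codon_table()].
#' @return An object of class `mutation_effect`: list with `source_codon`,
#'   `target_codon`, `position`, `change`, `kind` (one of `"synonymous"`,
#'   `"nonsynonymous"`, `"nonsense"`), `source_aa`, `target_aa` (`"*"` for
#'   a stop).
#' @examples
#' methylation_mutation_effect("CGA", "1-2", "CG>TG")$kind  # nonsense (TGA)
#' methylation_mutation_effect("ACG", "2-3", "CG>CA")$kind  # synonymous
#' methylation_mutation_effect("ACG", "2-3", "CG>TG")$kind  # nonsynonymous
#' @export
methylation_mutation_effect <- function(codon, position = c("1-2", "2-3"),
                                        change = c("CG>TG", "CG>CA"),
                                        table = codon_table()) {
  codon <- check_codon(codon, table)
  position <- match.arg(position)
  change <- match.arg(change)
  at <- if (position == "1-2") 1L else 2L
  if (substr(codon, at, at + 1L) != "CG")
    stop("codon ", codon, " has no CpG at bases ", position)
  target <- codon
  if (change == "CG>TG") substr(target, at, at) <- "T"
  else substr(target, at + 1L, at + 1L) <- "A"
  src_aa <- unname(table$mapping[codon])
  tgt_aa <- unname(table$mapping[target])
  kind <- if (tgt_aa == "*") "nonsense"
          else if (tgt_aa == src_aa) "synonymous"
          else "nonsynonymous"
  structure(list(source_codon = codon, target_codon = target,
                 position = position, change = change, kind = kind,
                 source_aa = src_aa, target_aa = tgt_aa),
            class = "mutation_effect")
}

#' @export
print.mutation_effect <- function(x, ...) {
  cat(sprintf("%s -> %s (CpG at %s, %s): %s (%s -> %s)\n",
              x$source_codon, x$target_codon, x$position, x$change,
              x$kind, x$source_aa, x$target_aa))
  invisible(x)
}

# The six possible CpG SNP polymorphism classes in protein-coding DNA:
# which are subject to GC-biased gene conversion, which arise at the
# elevated methylation-deamination rate, and whether the variant is
# synonymous when the CpG sits at a 3rd/1st codon position.
.cpg_snp_table <- data.frame(
  polymorphism = c("CpG<->GpG", "CpG<->ApG", "CpG<->TpG",
                   "CpG<->CpA", "CpG<->CpT", "CpG<->CpC"),
  gc_conversion_acting = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
  high_mutation_rate = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
  synonymous_at_3rd = c("possible", "possible", "always",
                        "always", "always", "always"),
  synonymous_at_1st = c("never", "possible", "never",
                        "never", "never", "never"),
  stringsAsFactors = FALSE
)

#' Classify a CpG SNP polymorphism
#'
#' The six possible single-nucleotide polymorphism classes involving one
#' base of a CpG dinucleotide, with whether GC-biased gene conversion acts
#' at the heterozygous site (it favours the G/C allele at G/C vs A/T
#' sites), whether the class arises at the elevated methylation-deamination
#' mutation rate (only CpG to TpG and CpG to CpA do), and whether the
#' variant is synonymous when the CpG spans 3rd-to-1st codon positions or
#' starts at a 1st position.
#'
#' @param polymorphism One of `"CpG<->GpG"`, `"CpG<->ApG"`, `"CpG<->TpG"`,
#'   `"CpG<->CpA"`, `"CpG<->CpT"`, `"CpG<->CpC"` (unicode arrows and
#'   shorthand like `"TpG"` accepted).
#' @return One-row data frame with columns `polymorphism`,
#'   `gc_conversion_acting`, `high_mutation_rate`, `synonymous_at_3rd`,
#'   `synonymous_at_1st`.
#' @examples
#' classify_cpg_snp("CpG<->TpG")
#' @export
classify_cpg_snp <- function(polymorphism) {
  key <- gsub("↔", "<->", polymorphism)
  key <- gsub("\\s", "", key)
  if (!grepl("^CpG<->", key)) key <- paste0("CpG<->", key)
  i <- match(key, .cpg_snp_table$polymorphism)
  if (is.na(i)) stop("unknown CpG polymorphism: ", polymorphism)
  .cpg_snp_table[i, , drop = FALSE]
}

#' All six CpG SNP polymorphism classes
#' @return Data frame, one row per class; see [classify_cpg_snp()].
#' @export
cpg_snp_classes <- function() .cpg_snp_table

#' Non-CpG alternative encodings
#'
#' For an amino acid whose codons can carry or contribute to a CpG site,
#' lists the CpG-free alternative codons and whether a single synonymous
#' change always suffices to reach one, and whether the alternative
#' preserves G+C count. Arginine's CGN codons fall back on AGA/AGG (only
#' CGA/CGG get there in one synonymous step, and the swap loses one G+C);
#' the NCG codons of S, P, T, A have the NCH third-position alternatives
#' (always one GC-neutral change); a junction CpG (C-ending codon before a
#' G-starting codon) is removed by a synonymous third-position C-to-T
#' change in the first codon. M, Q and W never sit in a CpG context.
#'
#' @param amino_acid Single-letter amino acid.
#' @param table A [codon_table()].
#' @return List with `amino_acid`, `site` (one of `"CGN"`, `"NCG"`,
#'   `"junction"`, `"none"`), `cpg_codons` (codons of this amino acid that
#'   contain or can contribute a CpG), `alternatives` (CpG-free codons for
#'   the same amino acid), `single_synonymous_change` (`"always"`,
#'   `"partial"`, or `NA` when not applicable) and `gc_neutral`
#'   (`"yes"`, `"no"`, `"partially"`, or `NA`).
#' @examples
#' cpg_free_alternatives("R")$alternatives  # AGA AGG
#' cpg_free_alternatives("M")$site          # "none"
#' @export
cpg_free_alternatives <- function(amino_acid, table = codon_table()) {
  aa <- toupper(amino_acid)
  if (!aa %in% table$amino_acids) stop("unknown amino acid: ", amino_acid)
  sense <- table$sense
  cods <- sense[table$mapping[sense] == aa]
  rep <- enumerate_cpg_codons(table)
  free <- cods[!grepl("CG", cods) & substr(cods, 3L, 3L) != "C" &
                 substr(cods, 1L, 1L) != "G"]
  if (any(cods %in% rep$within_pos12)) {
    list(amino_acid = aa, site = "CGN",
         cpg_codons = intersect(cods, rep$within_pos12),
         alternatives = cods[!grepl("CG", cods)],
         single_synonymous_change = "partial", gc_neutral = "no")
  } else if (any(cods %in% rep$within_pos23)) {
    ncg <- intersect(cods, rep$within_pos23)
    # NCH alternatives: same first two bases, third in {A, C, T}
    alts <- unlist(lapply(ncg, function(cd)
      paste0(substr(cd, 1L, 2L), c("T", "A", "C"))))
    alts <- intersect(unique(alts), cods)
    list(amino_acid = aa, site = "NCG", cpg_codons = ncg,
         alternatives = alts,
         single_synonymous_change = "always", gc_neutral = "yes")
  } else if (any(cods %in% rep$c_ending) || any(cods %in% rep$g_starting)) {
    contrib <- intersect(cods, union(rep$c_ending, rep$g_starting))
    list(amino_acid = aa, site = "junction", cpg_codons = contrib,
         alternatives = free,
         single_synonymous_change = "always", gc_neutral = "partially")
  } else {
    list(amino_acid = aa, site = "none", cpg_codons = character(0),
         alternatives = cods,
         single_synonymous_change = NA_character_,
         gc_neutral = NA_character_)
  }
}
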