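# Seeded synthetic-data generators: first-order Markov genomes with
# tunable GC fraction, strand bias and CpG depletion; CDS sets with
# tunable codon usage, terminal-window depletion and dicodon adjustment;
# and region fixtures with controlled overlap. Every generator is
# deterministic given (parameters, seed) and returns a truth record
# holding the parameters and the derived expectations used by tests.

#' Expected CpG content of the Markov genome model
#'
#' The genome generator draws bases from a first-order Markov chain whose
#' rows equal the stationary-style base distribution pi except after a C,
#' where the G probability is multiplied by the depletion factor lambda
#' and the row renormalised. Solving the stationary distribution of that
#' chain gives the expected value of the #CpG/(#CpG+#GpC) statistic in
#' closed form:
#'
#' content = lambda / (lambda + 1 - pi_GC (1 - lambda))
#'
#' with pi_GC the G+C fraction. The expression is independent of strand
#' bias and equals 0.5 at lambda = 1 and 0 at lambda = 0.
#'
#' @param cpg_depletion Depletion factor lambda in \[0, Inf); 1 = neutral.
#' @param gc_fraction G+C fraction pi_GC in \[0, 1\].
#' @return Expected CpG content in \[0, 1\].
#' @examples
#' expected_markov_cpg_content(0.5, 0.5)  # 0.4
#' @export
expected_markov_cpg_content <- function(cpg_depletion, gc_fraction) {
  lam <- cpg_depletion
  lam / (lam + 1 - gc_fraction * (1 - lam))
}

#' Invert the Markov-model CpG content to a depletion factor
#'
#' Closed-form inverse of [expected_markov_cpg_content()]:
#' lambda = y (1 - pi_GC) / (1 - y (1 + pi_GC)), with y the measured
#' content. Used to recover the generator's depletion parameter from an
#' observed CpG content.
#'
#' @param content Measured CpG content in \[0, 1).
#' @param gc_fraction G+C fraction in \[0, 1\].
#' @return Estimated depletion factor lambda.
#' @examples
#' lambda_from_cpg_content(0.4, 0.5)  # 0.5
#' @export
lambda_from_cpg_content <- function(content, gc_fraction) {
  content * (1 - gc_fraction) / (1 - content * (1 + gc_fraction))
}

base_probs <- function(gc_fraction, strand_bias) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction * (1 - strand_bias),
         G = gc_fraction * strand_bias, T = (1 - gc_fraction) / 2)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) stop("invalid base probabilities")
  p
}

# Simulate n bases of the depleted Markov chain. The C / not-C indicator
# is itself a two-state Markov chain (every non-C row of the transition
# matrix is identical), so its run lengths are independent geometrics and
# the identities of the non-C bases are conditionally independent given
# the indicator: only the first base after a C-run sees the
# lambda-reweighted row. This keeps generation vectorised.
simulate_markov_bases <- function(n, pi, lambda) {
  stopifnot(n >= 0, lambda >= 0)
  if (n == 0L) return(character(0))
  bases <- c("A", "C", "G", "T")
  p_c <- unname(pi["C"])
  if (p_c == 0) {             # no cytosines: i.i.d. over A, G, T
    return(sample(bases, n, replace = TRUE, prob = pi))
  }
  if (p_c == 1) return(rep("C", n))
  z_c <- 1 - unname(pi["G"]) * (1 - lambda)   # row sum after C
  p_cc <- p_c / z_c                            # P(C | C)
  # alternating geometric runs of C / not-C states
  avg_pair <- 1 / max(1 - p_cc, 1e-12) + 1 / p_c
  first_c <- stats::runif(1L) < p_c
  lens <- integer(0); states <- logical(0)
  total <- 0L; st <- first_c
  while (total < n) {
    k <- max(64L, ceiling((n - total) / avg_pair * 1.25))
    lc <- 1L + stats::rgeom(k, max(1 - p_cc, 1e-12))
    ln <- 1L + stats::rgeom(k, p_c)
    if (st) { L <- as.vector(rbind(lc, ln)); S <- rep(c(TRUE, FALSE), k) }
    else    { L <- as.vector(rbind(ln, lc)); S <- rep(c(FALSE, TRUE), k) }
    lens <- c(lens, L); states <- c(states, S)
    total <- total + sum(L)
    st <- !states[length(states)]
  }
  ind <- rep(states, times = lens)[seq_len(n)]   # TRUE where base is C
  out <- character(n)
  out[ind] <- "C"
  not_c <- which(!ind)
  prev_c <- c(FALSE, ind[-n])[not_c]             # position 1 draws from pi
  w_plain <- pi[c("A", "G", "T")]
  w_after_c <- c(pi["A"], lambda * pi["G"], pi["T"])
  abc <- c("A", "G", "T")
  n_after <- sum(prev_c)
  if (n_after > 0 && sum(w_after_c) > 0)
    out[not_c[prev_c]] <- sample(abc, n_after, replace = TRUE, prob = w_after_c)
  else if (n_after > 0)
    stop("degenerate transition row after C")
  if (length(not_c) > n_after)
    out[not_c[!prev_c]] <- sample(abc, length(not_c) - n_after,
                                  replace = TRUE, prob = w_plain)
  out
}

#' Generate a synthetic genome with tunable CpG depletion
#'
#' Chromosome sequences are drawn from a first-order Markov chain with
#' base distribution set by the G+C fraction and strand bias G/(G+C); the
#' G probability after a C is multiplied by `cpg_depletion` (lambda) and
#' the row renormalised, so lambda = 1 is neutral and lambda = 0 forbids
#' CpG entirely. Defaults emulate a CpG-depleted vertebrate genome
#' (GC 0.41, no strand bias, lambda 0.3).
#'
#' @param lengths Integer vector of chromosome lengths (names become
#'   chromosome names; default `chr1..`).
#' @param gc_fraction G+C fraction, default 0.41.
#' @param strand_bias G/(G+C), default 0.5.
#' @param cpg_depletion Depletion factor lambda, default 0.3.
#' @param seed Integer seed; generation is byte-deterministic given it.
#' @return List of class `synthetic_genome`: `sequences`
#'   (`Biostrings::DNAStringSet`) and `truth` (parameters plus
#'   `expected_cpg_content` from [expected_markov_cpg_content()]).
#' @examples
#' g <- generate_genome(lengths = c(chrA = 10000), cpg_depletion = 0,
#'                      seed = 1)
#' count_dinucleotides(g$sequences[[1]])$n_cpg  # 0
#' @export
generate_genome <- function(lengths = c(chr1 = 1e6, chr2 = 1e6),
                            gc_fraction = 0.41, strand_bias = 0.5,
                            cpg_depletion = 0.3, seed = 1L) {
  pi <- base_probs(gc_fraction, strand_bias)
  set.seed(seed)
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  seqs <- vapply(lengths, function(L)
    paste(simulate_markov_bases(as.integer(L), pi, cpg_depletion),
          collapse = ""), character(1L))
  out <- list(
    sequences = Biostrings::DNAStringSet(seqs),
    truth = list(lengths = lengths, gc_fraction = gc_fraction,
                 strand_bias = strand_bias, cpg_depletion = cpg_depletion,
                 seed = seed,
                 expected_cpg_content =
                   expected_markov_cpg_content(cpg_depletion, gc_fraction))
  )
  class(out) <- "synthetic_genome"
  out
}

uniform_codon_weights <- function(table = codon_table()) {
  w <- rep(1, length(table$sense)) / length(table$sense)
  names(w) <- table$sense
  w
}

region_weights <- function(weights, lambda) {
  w <- weights
  cg <- grepl("CG", names(w))
  w[cg] <- w[cg] * lambda
  w / sum(w)
}

#' Expected dicodon enrichment of the CDS generator
#'
#' For a codon-Markov chain with next-codon distribution
#' q(c | p) proportional to w(c) f(p, c) (w the usage weights, f the
#' dicodon adjustment factors, default 1), the stationary codon
#' distribution p solves p = p Q, and the expected observed/expected
#' enrichment of a pair (a, b) against the realised codon frequencies is
#' q(b | a) / p(b). Gene boundaries (forced ATG start, stop) perturb this
#' only at order 1/length and are ignored.
#'
#' @param weights Named codon usage weights over the sense codons.
#' @param dicodon_factors Named numeric vector, names 6-mers.
#' @param table A [codon_table()].
#' @return Named numeric vector of expected enrichments for the factored
#'   dicodons.
#' @export
expected_dicodon_enrichment <- function(weights = uniform_codon_weights(),
                                        dicodon_factors,
                                        table = codon_table()) {
  sense <- table$sense
  w <- weights[sense] / sum(weights[sense])
  Q <- matrix(rep(w, each = length(sense)), nrow = length(sense),
              dimnames = list(sense, sense))
  for (d in names(dicodon_factors)) {
    a <- substr(d, 1L, 3L); b <- substr(d, 4L, 6L)
    Q[a, b] <- Q[a, b] * dicodon_factors[[d]]
  }
  Q <- Q / rowSums(Q)
  p <- w
  for (i in 1:200) p <- as.vector(p %*% Q)   # power iteration
  names(p) <- sense
  vapply(names(dicodon_factors), function(d) {
    a <- substr(d, 1L, 3L); b <- substr(d, 4L, 6L)
    Q[a, b] / p[b]
  }, numeric(1L))
}

sample_codons_iid <- function(n, weights) {
  if (n <= 0L) return(character(0))
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a synthetic CDS set
#'
#' Coding sequences are built codon by codon from usage weights over the
#' 61 sense codons (no internal stops by construction), forced to start
#' with ATG and end with a stop codon. CpG depletion is injected by
#' multiplying the weights of CG-containing codons by a factor lambda,
#' optionally with separate factors for the first and last 33 codons
#' (terminal windows). Dicodon adjustment factors reweight the choice of
#' the next codon given the previous one, giving a codon-level Markov
#' chain whose expected enrichments are computed by
#' [expected_dicodon_enrichment()] and stored in the truth record. A
#' fraction of genes receives a RefSeq-style `LOC` placeholder symbol so
#' filtering behaviour is testable.
#'
#' @param n_genes Number of genes.
#' @param length_codons Sense-codon count per gene: a single integer, a
#'   vector recycled across genes, or a function of `n`. Default draws
#'   uniformly from 67 to 400 codons (201 to 1200 coding nt).
#' @param codon_weights Named usage weights over the sense codons,
#'   default uniform.
#' @param cpg_depletion Weight multiplier lambda for CG-containing
#'   codons, default 0.8 (coding DNA retains most of its CpG).
#' @param lambda5,lambda3 Optional overrides of `cpg_depletion` for the
#'   first / last 33 codons.
#' @param dicodon_factors Optional named numeric vector (names 6-mers) of
#'   dicodon adjustment factors.
#' @param frac_symbolless Fraction of genes given a `LOC` symbol,
#'   default 0.1.
#' @param seed Integer seed.
#' @param table A [codon_table()].
#' @return List of class `synthetic_cds`: `sequences` (`DNAStringSet`,
#'   names `"<id> <symbol>"`) and `truth` (all parameters, per-gene
#'   symbols and lengths, and `expected_enrichment` when dicodon factors
#'   are given).
#' @examples
#' cds <- generate_cds_set(n_genes = 5, length_codons = 80, seed = 1)
#' names(cds$sequences)[1]
#' @export
generate_cds_set <- function(n_genes = 500L,
                             length_codons = NULL,
                             codon_weights = NULL,
                             cpg_depletion = 0.8,
                             lambda5 = NULL, lambda3 = NULL,
                             dicodon_factors = NULL,
                             frac_symbolless = 0.1,
                             seed = 1L,
                             table = codon_table()) {
  set.seed(seed)
  if (is.null(codon_weights)) codon_weights <- uniform_codon_weights(table)
  w <- codon_weights[table$sense]
  if (any(is.na(w)) || sum(w) <= 0) stop("invalid codon weights")
  w <- w / sum(w)
  if (is.null(length_codons)) length_codons <- function(n) sample(67:400, n, replace = TRUE)
  m <- if (is.function(length_codons)) length_codons(n_genes)
       else rep_len(as.integer(length_codons), n_genes)
  if (any(m < 2L)) stop("genes need at least 2 sense codons")
  lam5 <- if (is.null(lambda5)) cpg_depletion else lambda5
  lam3 <- if (is.null(lambda3)) cpg_depletion else lambda3
  w_mid <- region_weights(w, cpg_depletion)
  w_5 <- region_weights(w, lam5)
  w_3 <- region_weights(w, lam3)
  symbolless <- stats::runif(n_genes) < frac_symbolless
  ids <- sprintf("g%05d", seq_len(n_genes))
  symbols <- ifelse(symbolless,
                    sprintf("LOC%06d", seq_len(n_genes)),
                    sprintf("SYM%05d", seq_len(n_genes)))
  fac <- dicodon_factors
  special_prev <- if (length(fac)) unique(substr(names(fac), 1L, 3L)) else character(0)
  fac_rows <- lapply(special_prev, function(a) {
    hit <- substr(names(fac), 1L, 3L) == a
    r <- stats::setNames(rep(1, length(table$sense)), table$sense)
    r[substr(names(fac)[hit], 4L, 6L)] <- fac[hit]
    r
  })
  names(fac_rows) <- special_prev
  wreg <- list(`5` = w_5, m = w_mid, `3` = w_3)
  gene_of <- rep(seq_len(n_genes), m)
  pos <- sequence(m)
  reg <- ifelse(pos <= 33L, "5", ifelse(pos > rep(m, m) - 33L, "3", "m"))
  cods <- character(length(pos))
  cods[pos == 1L] <- "ATG"
  if (length(fac) == 0L) {
    # independent draws: sample each region in one vectorised call
    for (r in c("5", "m", "3")) {
      at <- which(reg == r & pos > 1L)
      if (length(at)) cods[at] <- sample_codons_iid(length(at), wreg[[r]])
    }
  } else {
    # Markov over codons: reweight the next draw after a factored codon
    pool <- sample_codons_iid(length(pos), w_mid)
    pp <- 1L
    for (i in seq_along(pos)) {
      if (pos[i] == 1L) next
      wr <- wreg[[reg[i]]]
      if (cods[i - 1L] %in% special_prev) {
        wi <- wr * fac_rows[[cods[i - 1L]]]
        cods[i] <- sample(names(wi), 1L, prob = wi)
      } else if (reg[i] == "m") {
        cods[i] <- pool[pp]; pp <- pp + 1L
      } else {
        cods[i] <- sample(names(wr), 1L, prob = wr)
      }
    }
  }
  stop_codons <- sample(table$stops, n_genes, replace = TRUE)
  seqs <- paste0(vapply(split(cods, gene_of), paste, character(1L),
                        collapse = ""), stop_codons)
  names(seqs) <- paste(ids, symbols)
  truth <- list(n_genes = n_genes, length_codons = m,
                codon_weights = w, cpg_depletion = cpg_depletion,
                lambda5 = lam5, lambda3 = lam3,
                dicodon_factors = dicodon_factors,
                frac_symbolless = frac_symbolless, seed = seed,
                symbols = symbols, symbolless = symbolless)
  if (length(fac))
    truth$expected_enrichment <-
      expected_dicodon_enrichment(w_mid, fac, table)
  structure(list(sequences = Biostrings::DNAStringSet(seqs), truth = truth),
            class = "synthetic_cds")
}

#' Generate a region-overlap fixture with controlled enrichment
#'
#' Subject regions tile a fixed fraction of every chromosome (evenly
#' spaced blocks). Query regions start from a uniform random placement
#' and are then moved into (or out of) the subject blocks with the move
#' probability that makes the probability of landing fully inside equal
#' `enrichment_level`. With `enrichment_level` equal to the fraction of
#' uniform placements that fall inside (approximately the subject
#' coverage) placement is exactly uniform, i.e. the permutation null;
#' with `enrichment_level = 1` every query region lies inside the
#' subject and the observed overlap is maximal.
#'
#' @param genome Named integer vector of chromosome lengths.
#' @param subject_coverage Fraction of the genome covered by subject
#'   blocks, in (0, 1); default 0.1.
#' @param query_n Number of query regions, default 50.
#' @param query_length Length of each query region, default 200.
#' @param enrichment_level Probability that a query region is placed
#'   inside the subject, default equal to `subject_coverage` (null).
#' @param blocks_per_chrom Subject blocks per chromosome, default 5.
#' @param seed Integer seed.
#' @return List with `query` and `subject` ([region_set()] objects) and
#'   `truth` (parameters).
#' @examples
#' fx <- generate_region_fixture(c(chr1 = 1e5), enrichment_level = 1,
#'                               seed = 7)
#' @export
generate_region_fixture <- function(genome,
                                    subject_coverage = 0.1,
                                    query_n = 50L,
                                    query_length = 200L,
                                    enrichment_level = subject_coverage,
                                    blocks_per_chrom = 5L,
                                    seed = 1L) {
  if (subject_coverage <= 0 || subject_coverage >= 1)
    stop("subject_coverage must lie in (0, 1)")
  set.seed(seed)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  subj <- do.call(rbind, lapply(names(genome), function(ch) {
    L <- genome[[ch]]
    slot <- floor(L / blocks_per_chrom)
    # block width chosen so the fraction of query starts falling fully
    # inside equals subject_coverage (up to integer rounding): this is
    # what makes enrichment_level = subject_coverage the exact null
    k <- max(1, floor(subject_coverage * (L - query_length + 1) /
                        blocks_per_chrom))
    bw <- k + query_length - 1
    if (bw > slot) stop("subject blocks exceed their slots; lower coverage")
    data.frame(chrom = ch,
               start = (seq_len(blocks_per_chrom) - 1L) * slot,
               end = pmin((seq_len(blocks_per_chrom) - 1L) * slot + bw, L),
               stringsAsFactors = FALSE)
  }))
  if (query_n == 0L) {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    return(list(query = region_set(empty, genome),
                subject = region_set(subj, genome),
                truth = list(genome = genome,
                             subject_coverage = subject_coverage,
                             query_n = 0L, query_length = query_length,
                             enrichment_level = enrichment_level,
                             blocks_per_chrom = blocks_per_chrom,
                             seed = seed, query_inside = logical(0))))
  }
  chroms <- sample(names(genome), query_n, replace = TRUE,
                   prob = genome / sum(genome))
  # Start from a uniform draw, then move regions into (or out of) the
  # subject with the probability that makes P(fully inside) equal the
  # requested enrichment level. When enrichment_level matches the
  # fraction of uniform starts that fall fully inside, no move ever
  # happens and placement is exactly uniform: the permutation null.
  inside_starts <- function(ch) {
    blocks <- subj[subj$chrom == ch &
                     (subj$end - subj$start) >= query_length, ]
    cbind(blocks$start, blocks$end - query_length)
  }
  inside <- logical(query_n)
  qrows <- lapply(seq_len(query_n), function(i) {
    ch <- chroms[i]
    Tn <- genome[[ch]] - query_length + 1
    blk <- inside_starts(ch)
    I <- sum(blk[, 2] - blk[, 1] + 1)
    c_star <- I / Tn
    draw_inside <- function() {
      w <- blk[, 2] - blk[, 1] + 1
      b <- sample.int(nrow(blk), 1L, prob = w)
      blk[b, 1] + floor(stats::runif(1L) * w[b])
    }
    is_inside <- function(s)
      any(s >= blk[, 1] & s <= blk[, 2])
    s <- floor(stats::runif(1L) * Tn)
    e <- enrichment_level
    if (e >= c_star && !is_inside(s)) {
      if (stats::runif(1L) < (e - c_star) / (1 - c_star)) s <- draw_inside()
    } else if (e < c_star && is_inside(s)) {
      if (stats::runif(1L) < (c_star - e) / c_star) {
        repeat { s <- floor(stats::runif(1L) * Tn); if (!is_inside(s)) break }
      }
    }
    inside[i] <<- is_inside(s)
    data.frame(chrom = ch, start = s, end = s + query_length,
               stringsAsFactors = FALSE)
  })
  query <- do.call(rbind, qrows)
  list(query = region_set(query, genome),
       subject = region_set(subj, genome),
       truth = list(genome = genome, subject_coverage = subject_coverage,
                    query_n = query_n, query_length = query_length,
                    enrichment_level = enrichment_level,
                    blocks_per_chrom = blocks_per_chrom, seed = seed,
                    query_inside = inside))
}
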