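# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (character loops, boolean genome vectors,
# adjacency-matrix path search) so they share no code path with the
# package.

random_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25), alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# window-by-window dinucleotide scan
brute_dinuc <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  n_cpg <- n_gpc <- n_win <- 0L
  if (length(ch) >= 2) {
    for (i in seq_len(length(ch) - 1)) {
      w <- ch[c(i, i + 1)]
      if (all(w %in% c("A", "C", "G", "T"))) {
        n_win <- n_win + 1L
        if (w[1] == "C" && w[2] == "G") n_cpg <- n_cpg + 1L
        if (w[1] == "G" && w[2] == "C") n_gpc <- n_gpc + 1L
      }
    }
  }
  list(n_cpg = n_cpg, n_gpc = n_gpc, n_windows = n_win)
}

rev_comp <- function(s) {
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(m[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# naive in-frame dicodon tally (stop/ambiguous pairs excluded)
brute_dicodons <- function(seqs, tab = codon_table()) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n %% 3 != 0) next
    cods <- substring(s, seq(1, n - 2, 3), seq(3, n, 3))
    if (length(cods) < 2) next
    for (i in seq_len(length(cods) - 1)) {
      if (cods[i] %in% tab$sense && cods[i + 1] %in% tab$sense)
        out <- c(out, paste0(cods[i], cods[i + 1]))
    }
  }
  table(out)
}

# shortest synonymous path to a CpG-free codon via boolean adjacency
# powers (path existence at exactly k steps), independent of the BFS
brute_min_steps <- function(codon, tab = codon_table()) {
  if (!grepl("CG", codon)) return(0L)
  aa <- tab$mapping[codon]
  syn <- tab$sense[tab$mapping[tab$sense] == aa]
  k <- length(syn)
  adj <- matrix(FALSE, k, k, dimnames = list(syn, syn))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j &&
        sum(strsplit(syn[i], "")[[1]] != strsplit(syn[j], "")[[1]]) == 1)
      adj[i, j] <- TRUE
  }
  free <- !grepl("CG", syn)
  reach <- diag(k) > 0
  dimnames(reach) <- list(syn, syn)
  for (step in 1:6) {
    reach <- (reach %*% adj) > 0
    if (any(reach[codon, ] & free)) return(step)
  }
  Inf
}

# base-by-base boolean-vector overlap oracle for small genomes
brute_overlap_bases <- function(a, b) {
  tot <- 0
  for (ch in names(a$genome)) {
    L <- a$genome[[ch]]
    va <- rep(FALSE, L); vb <- rep(FALSE, L)
    da <- a$regions[a$regions$chrom == ch, ]
    db <- b$regions[b$regions$chrom == ch, ]
    for (i in seq_len(nrow(da))) va[(da$start[i] + 1):da$end[i]] <- TRUE
    for (i in seq_len(nrow(db))) vb[(db$start[i] + 1):db$end[i]] <- TRUE
    tot <- tot + sum(va & vb)
  }
  tot
}

random_region_df <- function(genome, n, max_len = 50) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome[chrom] - len))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}
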