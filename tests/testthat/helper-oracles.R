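# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# reverse complement by explicit per-base lookup over a reversed loop
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(s, "")[[1]]
  paste(comp[rev(chars)], collapse = "")
}

# overlapping substring count by checking every window position
oracle_count <- function(seq, word) {
  L <- nchar(seq); w <- nchar(word)
  if (L < w) return(0L)
  sum(vapply(seq_len(L - w + 1L),
             function(i) substr(seq, i, i + w - 1L) == word, logical(1)))
}

# GC content by tabulating characters
oracle_gc <- function(s) {
  chars <- strsplit(s, "")[[1]]
  mean(chars %in% c("G", "C"))
}

# per-k-mer recount over a gene set: named vector over all 4^k k-mers
oracle_kmer_table <- function(seqs, k) {
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                       stringsAsFactors = FALSE))
  kmers <- sort(kmers)
  counts <- vapply(kmers, function(m) {
    sum(vapply(seqs, oracle_count, integer(1), word = m))
  }, numeric(1))
  counts
}

# two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins (hypergeometric probabilities summed for tables at most
# as probable as the observed one)
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail binomial p by direct term-by-term summation
oracle_binom_upper <- function(k, n, p0) {
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# hypergeometric upper tail by direct summation of dhyper terms
oracle_hyper_upper <- function(x, K, N, n_draw) {
  sum(dhyper(x:min(K, n_draw), K, N - K, n_draw))
}

# one-sided Mann-Whitney p for members-at-lower-ranks by full enumeration of
# member-rank subsets (tiny inputs only)
oracle_mw_lower <- function(is_member) {
  n <- length(is_member); n1 <- sum(is_member)
  obs <- sum(which(is_member))
  combs <- utils::combn(n, n1)
  mean(colSums(combs) <= obs)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = "")
  }, character(1))
}

# printed reference sequences used across tests
SIL3_SENSE <- "GCCCUUCAAUUACCCAUAU"
SISCR_SENSE <- "UGGUUUACAUGUUGUGUGA"
SHL3_TARGET <- "ACUGGGCUGUACUUUGUAUAU"
SHR6_TARGET <- "GUGCAGAUGUAAACCAAACUU"
SHL3_GUIDE <- "UACAAAGUACAGCCCAGUU"
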