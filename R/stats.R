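#' One-sided Mann-Whitney rank enrichment of a subpool
#'
#' Given shRNAs ranked by fold downregulation (most depleted first), tests
#' the one-sided alternative that the members of a subpool occupy lower
#' (better, i.e. more depleted) ranks than the rest. Group sizes below 50
#' without ties use the exact Mann-Whitney distribution, otherwise the
#' normal approximation with tie correction (the behaviour of
#' [stats::wilcox.test()]).
#'
#' @param is_member Logical vector in ranked order (most depleted first),
#'   `TRUE` for subpool members. Alternatively supply `fold` and the ranking
#'   is derived by decreasing fold.
#' @param fold Optional numeric vector of fold-downregulation values aligned
#'   with `is_member` (unranked input).
#' @return One-sided p-value.
#' @export
mw_subpool_enrichment <- function(is_member, fold = NULL) {
  is_member <- as.logical(is_member)
  if (!is.null(fold)) {
    stopifnot(length(fold) == length(is_member))
    is_member <- is_member[order(-fold)]
  }
  n1 <- sum(is_member)
  if (n1 == 0L || n1 == length(is_member)) {
    stop("subpool must be a strict, non-empty subset of the ranked list")
  }
  ranks <- seq_along(is_member)
  stats::wilcox.test(ranks[is_member], ranks[!is_member],
                     alternative = "less")$p.value
}

#' Permutation Mann-Whitney test of Toxicity Index association
#'
#' Tests whether depleted (toxic) shRNAs carry higher Toxicity Index values
#' than the rest. The observed Mann-Whitney W statistic (depleted vs
#' non-depleted TI ranks) is compared to a null distribution obtained by
#' randomly shuffling the TI ranking `n_perm` times; the one-sided p-value
#' uses the add-one estimator p = (1 + #\{W_null >= W_obs\}) / (1 + n_perm),
#' which is never exactly zero.
#'
#' @param ti Numeric vector of TI values, one per shRNA.
#' @param depleted Logical vector of depletion calls (same length; at least
#'   one `TRUE` and one `FALSE`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer RNG seed; results are reproducible bit-for-bit for a
#'   given (seed, n_perm).
#' @return List of class `"perm_test"`: `w_observed`, `null_w` (length
#'   `n_perm`), `p_perm`, `n_perm`, `n_depleted`, `rng_seed`.
#' @export
ti_permutation_test <- function(ti, depleted, n_perm = 10000L, seed = 1L) {
  depleted <- as.logical(depleted)
  stopifnot(length(ti) == length(depleted), n_perm >= 1L)
  n1 <- sum(depleted)
  if (n1 == 0L || n1 == length(depleted)) {
    stop("need at least one depleted and one non-depleted shRNA")
  }
  r <- rank(ti)
  off <- n1 * (n1 + 1) / 2
  w_obs <- sum(r[depleted]) - off
  n <- length(r)
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  null_w <- vapply(seq_len(n_perm), function(i) {
    sum(r[sample.int(n, n1)]) - off
  }, numeric(1))
  p <- (1 + sum(null_w >= w_obs)) / (1 + n_perm)
  structure(list(w_observed = w_obs, null_w = null_w, p_perm = p,
                 n_perm = as.integer(n_perm), n_depleted = n1,
                 rng_seed = as.integer(seed)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation Mann-Whitney: W = %.1f, p = %.4g (%d shuffles)\n",
              x$w_observed, x$p_perm, x$n_perm))
  invisible(x)
}

#' Fisher's exact test of seed-match presence vs downregulation
#'
#' 2x2 contingency analysis of whether genes carrying at least one seed
#' match in their 3'UTR are more likely to be downregulated. Cells are
#' (a) downregulated with seed match, (b) downregulated without,
#' (c) not downregulated with, (d) not downregulated without.
#'
#' @param a,b,c,d Non-negative integer cell counts, or pass a 2x2 matrix as
#'   `a`.
#' @param alternative Passed to [stats::fisher.test()]; default two-sided.
#' @return List with `odds_ratio` (conditional MLE; `NA` for an all-zero
#'   table) and `p`.
#' @export
fisher_seed_downreg <- function(a, b = NULL, c = NULL, d = NULL,
                                alternative = "two.sided") {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L)
  stopifnot(all(tab >= 0), identical(dim(tab), c(2L, 2L)))
  if (sum(tab) == 0) return(list(odds_ratio = NA_real_, p = 1))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' One-sided binomial enrichment test
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, p0): the chance of
#' observing at least `k` successes among `n` trials at background rate
#' `p0`. Used to ask whether e.g. survival genes are over-represented among
#' downregulated genes relative to their genome-wide frequency.
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability in (0, 1).
#' @return The one-sided p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (is.na(k) || is.na(n) || k < 0 || k > n || n < 1 ||
      p0 <= 0 || p0 >= 1) {
    stop("need 0 <= k <= n, n >= 1 and p0 in (0,1)")
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Pearson correlation of seed GC content with a toxicity response
#'
#' @param gc Numeric vector of GC fractions (or percentages).
#' @param response Numeric vector of responses, e.g. log10 fold
#'   downregulation or log10(TI).
#' @return List with `r` and `p` (two-sided, via the t transform). With
#'   exactly two pairs `r` is +/-1 and `p` is `NA`; fewer than two pairs or
#'   zero variance is an error.
#' @export
gc_correlation <- function(gc, response) {
  stopifnot(length(gc) == length(response))
  ok <- is.finite(gc) & is.finite(response)
  gc <- gc[ok]; response <- response[ok]
  if (length(gc) < 2L) stop("need at least two complete pairs")
  if (stats::sd(gc) == 0 || stats::sd(response) == 0) {
    stop("zero variance in gc or response; correlation undefined")
  }
  if (length(gc) == 2L) {
    return(list(r = unname(stats::cor(gc, response)), p = NA_real_))
  }
  ct <- stats::cor.test(gc, response, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Sliding hypergeometric seed-enrichment landscape
#'
#' A simplified word-enrichment landscape over a ranked gene list (most
#' downregulated first). At every rank cutoff (multiples of `step`), the
#' occurrences of each k-mer word in the leading 3'UTRs are compared to the
#' occurrences in the universe of all listed 3'UTRs with a hypergeometric
#' test on word counts (the unit is overlapping word occurrences out of all
#' k-mer windows; set `unit = "genes"` to test genes-with-at-least-one-site
#' instead). Enrichment in the leading set is plotted on the positive y
#' axis as -log10(p); depletion on the negative axis as +log10(p).
#'
#' @param ranked_ids Character vector of gene ids, most downregulated first.
#' @param utrs Named character vector of 3'UTRs covering all ranked ids.
#' @param k Word length (e.g. 6 or 8).
#' @param step Rank increment between cutoffs (default 200). A step larger
#'   than the list yields a single cutoff at the full list length.
#' @param words `"all"` (default) for all 4^k words, or a character vector
#'   of specific words.
#' @param unit `"occurrences"` (default) or `"genes"`.
#' @param max_single_nt_fraction Optional low-complexity filter: words in
#'   which one nucleotide exceeds this fraction are dropped (off by
#'   default).
#' @return Data frame with `word`, `cutoff_rank`, `lead_count`,
#'   `total_count`, `signed_logp`; attribute `bonferroni_logp` holds
#'   -log10(0.05 / #words tested).
#' @export
sylamer_landscape <- function(ranked_ids, utrs, k, step = 200L,
                              words = "all", unit = c("occurrences", "genes"),
                              max_single_nt_fraction = NULL) {
  unit <- match.arg(unit)
  if (any(!ranked_ids %in% names(utrs))) {
    stop("missing UTR for some ranked genes")
  }
  seqs <- nuc_normalize(utrs[ranked_ids])
  n_genes <- length(seqs)
  step <- as.integer(step)
  cutoffs <- if (step > n_genes) n_genes else seq(step, n_genes, by = step)
  # per-block collapsed k-mer counts, then cumulative over cutoffs
  bounds <- c(0L, cutoffs)
  if (unit == "occurrences") {
    block <- vapply(seq_along(cutoffs), function(i) {
      .kmer_counts(seqs[(bounds[i] + 1L):bounds[i + 1L]], k)
    }, numeric(4L^k))
    tail_block <- if (bounds[length(bounds)] < n_genes) {
      .kmer_counts(seqs[(bounds[length(bounds)] + 1L):n_genes], k)
    } else numeric(4L^k)
    widths <- pmax(nchar(seqs) - k + 1L, 0L)
  } else {
    per_gene <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = k) > 0
    block <- vapply(seq_along(cutoffs), function(i) {
      colSums(per_gene[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE])
    }, numeric(4L^k))
    tail_block <- if (bounds[length(bounds)] < n_genes) {
      colSums(per_gene[(bounds[length(bounds)] + 1L):n_genes, , drop = FALSE])
    } else numeric(4L^k)
    widths <- rep(1L, n_genes)
  }
  block <- matrix(block, nrow = 4L^k)
  lead <- t(apply(block, 1L, cumsum))         # words x cutoffs
  lead <- matrix(lead, nrow = 4L^k)
  total <- lead[, length(cutoffs)] + tail_block
  all_words <- names(.kmer_counts(character(0), k))
  rownames(lead) <- all_words
  N <- sum(widths)
  n_lead <- cumsum(widths)[cutoffs]
  if (identical(words, "all")) words <- all_words
  if (!is.null(max_single_nt_fraction)) {
    frac <- vapply(c("A", "C", "G", "T"), function(b) {
      (nchar(words) - nchar(gsub(b, "", words))) / nchar(words)
    }, numeric(length(words)))
    words <- words[apply(matrix(frac, ncol = 4L), 1L,
                         max) <= max_single_nt_fraction]
  }
  wi <- match(words, all_words)
  if (any(is.na(wi))) stop("unknown word(s): ",
                           paste(words[is.na(wi)], collapse = ", "))
  x <- lead[wi, , drop = FALSE]
  K <- total[wi]
  signed <- vapply(seq_along(cutoffs), function(j) {
    # many words share the same (lead, total) counts at a cutoff; evaluate
    # each distinct pair once
    pair <- x[, j] * (max(K) + 1) + K
    u <- !duplicated(pair)
    idx <- match(pair, pair[u])
    p_enr <- stats::phyper(x[u, j] - 1, K[u], N - K[u], n_lead[j],
                           lower.tail = FALSE)[idx]
    p_dep <- stats::phyper(x[u, j], K[u], N - K[u], n_lead[j])[idx]
    s <- -log10(pmax(p_enr, .Machine$double.xmin))
    dep <- p_dep < p_enr
    s[dep] <- log10(pmax(p_dep[dep], .Machine$double.xmin))
    s
  }, numeric(length(words)))
  out <- data.frame(word = rep(words, length(cutoffs)),
                    cutoff_rank = rep(cutoffs, each = length(words)),
                    lead_count = as.integer(x),
                    total_count = rep(as.integer(K), length(cutoffs)),
                    signed_logp = as.vector(signed),
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni_logp") <- -log10(0.05 / length(words))
  attr(out, "k") <- as.integer(k)
  attr(out, "unit") <- unit
  out
}
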