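#' Classify survival and nonsurvival gene sets from CRISPR screen scores
#'
#' Survival (essential) genes are those with a CRISPR score below -0.1 at an
#' adjusted p-value below 0.05; the nonsurvival control group uses the
#' mirrored criteria (score above +0.1, adjusted p below 0.05). Everything
#' else is unclassified.
#'
#' @param genes Data frame with columns `gene_id`, `crispr_score`, `adj_p`
#'   (and optionally `expression`).
#' @return List with data frames `survival`, `nonsurvival`, `unclassified`.
#'   Genes with missing score or p-value are skipped with a warning.
#' @export
classify_gene_sets <- function(genes) {
  need <- c("gene_id", "crispr_score", "adj_p")
  if (!all(need %in% names(genes))) {
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  }
  ok <- !is.na(genes$crispr_score) & !is.na(genes$adj_p)
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) skipped for missing score or p-value")
    genes <- genes[ok, , drop = FALSE]
  }
  surv <- genes$crispr_score < -0.1 & genes$adj_p < 0.05
  nons <- genes$crispr_score > 0.1 & genes$adj_p < 0.05
  list(survival = genes[surv, , drop = FALSE],
       nonsurvival = genes[nons, , drop = FALSE],
       unclassified = genes[!surv & !nons, , drop = FALSE])
}

#' Longest 3'UTR of a gene
#'
#' Of the deposited 3'UTR isoforms of a gene only the longest is used for
#' seed-match counting; equal-length ties are broken by input order.
#'
#' @param utrs Character vector of 3'UTR isoform sequences (possibly empty).
#' @return The longest sequence, or `NA_character_` if there is none.
#' @export
longest_utr <- function(utrs) {
  if (length(utrs) == 0L) return(NA_character_)
  utrs <- nuc_normalize(utrs)
  utrs[which.max(nchar(utrs))]
}

#' Assemble a UTR gene set
#'
#' Keeps one sequence per gene (the longest deposited 3'UTR); genes without
#' any UTR are dropped.
#'
#' @param utrs Named character vector of 3'UTR sequences, one or more entries
#'   per gene (names are gene ids, repeated for isoforms), e.g. from
#'   [read_fasta()] with gene-id headers.
#' @param class_label `"survival"` or `"nonsurvival"`.
#' @param gene_ids Optional subset of gene ids to keep (e.g. from
#'   [classify_gene_sets()]).
#' @return List of class `"utr_gene_set"`: `seqs` (named character, one per
#'   gene), `class_label`, `n_genes`.
#' @export
utr_gene_set <- function(utrs, class_label = c("survival", "nonsurvival"),
                         gene_ids = NULL) {
  class_label <- match.arg(class_label)
  stopifnot(!is.null(names(utrs)))
  if (!is.null(gene_ids)) utrs <- utrs[names(utrs) %in% gene_ids]
  ids <- unique(names(utrs))
  seqs <- vapply(ids, function(g) longest_utr(utrs[names(utrs) == g]),
                 character(1))
  seqs <- seqs[!is.na(seqs)]
  structure(list(seqs = seqs, class_label = class_label,
                 n_genes = length(seqs)),
            class = "utr_gene_set")
}

#' @export
print.utr_gene_set <- function(x, ...) {
  cat(sprintf("utr_gene_set (%s): %d genes, median 3'UTR %d nt\n",
              x$class_label, x$n_genes,
              if (x$n_genes) as.integer(stats::median(nchar(x$seqs))) else 0L))
  invisible(x)
}

#' Count overlapping seed-match occurrences in a 3'UTR
#'
#' Occurrences are counted with sliding-window semantics: every position at
#' which the k-mer occurs counts, including overlapping ones, so summing the
#' counts of all 4^k k-mers over a sequence of length L gives exactly
#' L - k + 1 windows.
#'
#' @param utr Character vector of UTR sequences.
#' @param seed_match The k-mer to count (a single string).
#' @return Integer vector of occurrence counts (0 where the UTR is shorter
#'   than the k-mer).
#' @export
count_seed_matches <- function(utr, seed_match) {
  stopifnot(length(seed_match) == 1L)
  seed_match <- nuc_normalize(seed_match)
  utr <- nuc_normalize(utr)
  if (length(utr) == 0L) return(integer(0))
  out <- integer(length(utr))
  long <- nchar(utr) >= nchar(seed_match)
  if (any(long)) {
    out[long] <- Biostrings::vcountPattern(
      seed_match, Biostrings::DNAStringSet(utr[long]))
  }
  out
}

.kmer_counts <- function(seqs, k) {
  if (length(seqs) == 0L) {
    v <- integer(4L^k)
    names(v) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    return(v)
  }
  Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k, simplify.as = "collapsed")
}

#' Compute the Toxicity Index table
#'
#' For every one of the 4^k k-mers, seed matches are counted (overlapping)
#' in the longest 3'UTRs of the survival set and of the nonsurvival set;
#' each count is normalized by the number of genes in its set, and the
#' Toxicity Index is the ratio survival over nonsurvival:
#' TI = (count_S / n_S) / (max(count_NS, 1) / n_NS). A nonsurvival count of
#' zero is replaced by 1 in the denominator, mirroring the screen's global
#' zero-to-one convention, so TI is always finite and positive.
#'
#' Keying: with `key = "seed"` (default) the table row for k-mer m holds the
#' counts of m's seed match (reverse complement of m) in the UTRs, so a
#' row is looked up directly by an shRNA's guide seed (DNA form); with
#' `key = "site"` the row for m holds the counts of m itself. The two
#' tables contain the same values under reverse-complemented keys.
#'
#' @param set_S,set_NS `"utr_gene_set"` objects for the survival and
#'   nonsurvival genes (both non-empty).
#' @param k Seed-match length, 6 or 8.
#' @param key `"seed"` or `"site"` (see above).
#' @return Data frame of class `"ti_table"` with 4^k rows: `kmer`,
#'   `count_S`, `count_NS`, `ti`; attributes `k`, `key`, `n_S`, `n_NS`.
#' @export
compute_ti <- function(set_S, set_NS, k, key = c("seed", "site")) {
  key <- match.arg(key)
  stopifnot(inherits(set_S, "utr_gene_set"), inherits(set_NS, "utr_gene_set"))
  if (!k %in% c(6L, 8L)) stop("k must be 6 or 8")
  if (set_S$n_genes == 0L || set_NS$n_genes == 0L) stop("empty gene set")
  cs <- .kmer_counts(set_S$seqs, k)
  cn <- .kmer_counts(set_NS$seqs, k)
  kmers <- names(cs)
  if (key == "seed") {
    # row m <- counts of reverse_complement(m); permute counts accordingly
    idx <- match(reverse_complement(kmers), kmers)
    cs <- cs[idx]
    cn <- cn[idx]
  }
  ti <- (as.numeric(cs) / set_S$n_genes) /
    (pmax(as.numeric(cn), 1) / set_NS$n_genes)
  out <- data.frame(kmer = kmers, count_S = as.integer(cs),
                    count_NS = as.integer(cn), ti = ti,
                    stringsAsFactors = FALSE)
  class(out) <- c("ti_table", "data.frame")
  attr(out, "k") <- as.integer(k)
  attr(out, "key") <- key
  attr(out, "n_S") <- set_S$n_genes
  attr(out, "n_NS") <- set_NS$n_genes
  out
}

#' Assign Toxicity Index values to a tiled shRNA library
#'
#' Each shRNA is annotated with the TI of its guide seed and the result is
#' ranked by TI, descending (most toxic predicted first). The lookup key is
#' the DNA form of the guide seed (positions 2..k+1), matching the default
#' seed-keyed [compute_ti()] table.
#'
#' @param library Data frame from [tile_shrnas()] (needs `seed6`/`seed8`).
#' @param ti A `"ti_table"` from [compute_ti()] with `key = "seed"`.
#' @return The library rows with a `ti` column, ordered by decreasing TI.
#'   shRNAs whose seed is missing are dropped with a warning.
#' @export
assign_ti <- function(library, ti) {
  stopifnot(inherits(ti, "ti_table"))
  if (!identical(attr(ti, "key"), "seed")) {
    stop("assign_ti needs a seed-keyed ti_table (compute_ti(key = \"seed\"))")
  }
  k <- attr(ti, "k")
  seedcol <- paste0("seed", k)
  if (!seedcol %in% names(library)) stop("library lacks column ", seedcol)
  seeds <- library[[seedcol]]
  ok <- !is.na(seeds) & nzchar(seeds)
  if (any(!ok)) {
    warning(sum(!ok), " shRNA(s) without a ", k, "mer seed skipped")
    library <- library[ok, , drop = FALSE]
    seeds <- seeds[ok]
  }
  library$ti <- ti$ti[match(seeds, ti$kmer)]
  library[order(-library$ti), , drop = FALSE]
}

#' Expression-matched control selection
#'
#' For the expression-matched variant of the TI, the top `n` survival genes
#' by expression are paired with controls: survival genes are processed in
#' descending expression order and each is greedily matched to the unused
#' candidate with the nearest expression (ties to the earlier candidate).
#'
#' @param survival,candidates Data frames with columns `gene_id`,
#'   `expression`.
#' @param n Number of genes to select from each side.
#' @return List with `survival` (top-n rows) and `controls` (the n matched
#'   candidate rows, in pairing order).
#' @export
match_expression <- function(survival, candidates, n) {
  stopifnot(all(c("gene_id", "expression") %in% names(survival)),
            all(c("gene_id", "expression") %in% names(candidates)))
  if (n > nrow(survival) || n > nrow(candidates)) {
    stop("n exceeds available genes")
  }
  if (n == 0L) {
    return(list(survival = survival[0, ], controls = candidates[0, ]))
  }
  top <- survival[order(-survival$expression), , drop = FALSE][seq_len(n), ]
  used <- logical(nrow(candidates))
  pick <- integer(n)
  for (i in seq_len(n)) {
    d <- abs(candidates$expression - top$expression[i])
    d[used] <- Inf
    pick[i] <- which.min(d)
    used[pick[i]] <- TRUE
  }
  list(survival = top, controls = candidates[pick, , drop = FALSE])
}
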