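#' Normalize nucleotide sequences to the internal DNA alphabet
#'
#' All sequence-handling functions in seedtox work on a canonical internal DNA
#' alphabet \{A, C, G, T\}. RNA input (containing U) is accepted and mapped to
#' T; lowercase is uppercased. Seed matches are ultimately counted in DNA
#' 3'UTR sequences, so DNA is the single internal representation and RNA
#' rendering (see [as_rna()]) is purely a formatting concern.
#'
#' @param x Character vector of nucleotide sequences (DNA or RNA, any case).
#' @return Character vector of the same length over \{A,C,G,T\}.
#'   Normalization is idempotent. Zero-length strings are allowed.
#' @examples
#' nuc_normalize("gcccuucaauuacccauau")
#' @export
nuc_normalize <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  x
}

#' Render internal DNA sequences as RNA
#'
#' @param x Character vector of normalized DNA sequences.
#' @return The same sequences with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", nuc_normalize(x))

#' Watson-Crick reverse complement
#'
#' @param x Character vector of nucleotide sequences (RNA accepted, mapped to
#'   DNA on input).
#' @return Character vector of reverse complements in the internal DNA
#'   alphabet. Applying the function twice returns the (normalized) input;
#'   the empty string maps to itself.
#' @examples
#' reverse_complement("GCCCTTCAATTACCCATAT")
#' @export
reverse_complement <- function(x) {
  x <- nuc_normalize(x)
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Derive the guide (antisense) strand from a printed sense strand
#'
#' In an siRNA duplex the guide strand -- the one loaded into the RISC and
#' base-paired with target mRNA -- is the antisense strand, i.e. the reverse
#' complement of the printed sense/passenger sequence (overhang annotations
#' must already be stripped; see [parse_oligo()]).
#'
#' @param sense Character vector of sense-strand sequences.
#' @return Guide strands in the internal DNA alphabet.
#' @examples
#' guide_from_sense("GCCCUUCAAUUACCCAUAU")  # siL3 -> "ATATGGGTAATTGAAGGGC"
#' @export
guide_from_sense <- function(sense) {
  sense <- nuc_normalize(sense)
  if (any(nchar(sense) == 0L)) stop("empty sense strand")
  reverse_complement(sense)
}

#' GC content of a sequence
#'
#' @param x Character vector of non-empty nucleotide sequences.
#' @return Numeric vector of (G + C) / length, in \[0, 1\].
#' @examples
#' gc_content("TTGGTTTA")  # shR6 8mer seed, 0.25
#' @export
gc_content <- function(x) {
  x <- nuc_normalize(x)
  n <- nchar(x)
  if (any(n == 0L)) stop("gc_content is undefined for empty sequences")
  (n - nchar(gsub("[GC]", "", x))) / n
}

#' Extract the seed of a guide strand
#'
#' The seed is positions 2..k+1 of the guide strand (1-based, inclusive):
#' positions 2-7 for the 6mer seed and 2-9 for the 8mer seed. The seed match
#' is the reverse complement of the seed, the k-mer actually sought in 3'UTR
#' sequences.
#'
#' @param guide Guide-strand sequence (single string; RNA accepted).
#' @param k Seed length, 6 or 8.
#' @return A list of class `"seed_info"` with elements `k`, `seed`,
#'   `seed_match` (both internal DNA alphabet) and `gc_fraction` of the seed.
#' @examples
#' extract_seed("UACAAAGUACAGCCCAGUU", 6)$seed_match  # shL3: "CTTTGT"
#' @export
extract_seed <- function(guide, k) {
  stopifnot(length(guide) == 1L, length(k) == 1L)
  if (!k %in% c(6L, 8L)) stop("seed length k must be 6 or 8")
  guide <- nuc_normalize(guide)
  if (nchar(guide) < k + 1L) {
    stop("guide (", nchar(guide), " nt) too short for a ", k, "mer seed")
  }
  seed <- substr(guide, 2L, k + 1L)
  structure(
    list(k = as.integer(k), seed = seed,
         seed_match = reverse_complement(seed),
         gc_fraction = gc_content(seed)),
    class = "seed_info"
  )
}

#' @export
print.seed_info <- function(x, ...) {
  cat(sprintf("%dmer seed %s  (match %s, GC %.1f%%)\n",
              x$k, as_rna(x$seed), x$seed_match, 100 * x$gc_fraction))
  invisible(x)
}

#' Parse a printed oligonucleotide with chemistry annotations
#'
#' Vendor catalogues print small-RNA oligos with chemistry embedded in the
#' sequence string: 3' deoxyribonucleotide overhangs as `dT`, `dA`, `dC`, ...
#' and 5' phosphorylation as a `/5Phos/` prefix, optionally wrapped in
#' `5'-...-3'` decorations with whitespace. This parser splits such a string
#' into the RNA core (returned normalized to DNA), the 3' overhang
#' annotation, and the phosphorylation flag.
#'
#' @param x A single printed oligo string, e.g.
#'   `"5'-/5Phos/UACAAAGUACAGCCCAGUUdTdT-3'"`.
#' @return List with `core` (DNA string), `overhang` (e.g. `"dTdT"` or `""`),
#'   `five_prime_phos` (logical), and `display` (the canonical rendering,
#'   RNA core plus overhang).
#' @export
parse_oligo <- function(x) {
  stopifnot(length(x) == 1L)
  s <- gsub("[[:space:]]", "", x)
  s <- sub("^5'-?", "", s)
  s <- sub("-?3'$", "", s)
  phos <- grepl("^/5Phos/", s)
  s <- sub("^/5Phos/", "", s)
  m <- regmatches(s, regexpr("(d[ACGTU])+$", s))
  overhang <- if (length(m)) m else ""
  core <- if (nzchar(overhang)) substr(s, 1L, nchar(s) - nchar(overhang)) else s
  core <- nuc_normalize(core)
  list(core = core, overhang = overhang, five_prime_phos = phos,
       display = paste0(as_rna(core), overhang))
}

#' Assemble an annotated si/shRNA duplex
#'
#' @param sense,antisense Results of [parse_oligo()] (or raw strings, which
#'   are parsed). The guide strand is defined as the antisense strand.
#' @param paired_core Optional DNA string giving the exactly Watson-Crick
#'   paired region of the duplex (used by [shrna_to_sirna()], where added G
#'   prefixes and U padding sit outside the exactly complementary core).
#' @return List of class `"oligo_duplex"` with `sense`, `antisense`, `guide`
#'   (DNA form of the antisense core) and `paired_core`.
#' @export
oligo_duplex <- function(sense, antisense, paired_core = NULL) {
  if (is.character(sense)) sense <- parse_oligo(sense)
  if (is.character(antisense)) antisense <- parse_oligo(antisense)
  structure(
    list(sense = sense, antisense = antisense,
         guide = antisense$core, paired_core = paired_core),
    class = "oligo_duplex"
  )
}

#' @export
print.oligo_duplex <- function(x, ...) {
  cat("sense:     5'-", x$sense$display, "-3'\n", sep = "")
  cat("antisense: 5'-",
      if (isTRUE(x$antisense$five_prime_phos)) "/5Phos/" else "",
      x$antisense$display, "-3'\n", sep = "")
  invisible(x)
}

#' Convert a 21-nt shRNA target site to an siRNA duplex
#'
#' Implements the two printed conversion recipes used to turn toxic shRNAs
#' into mature siRNAs, mirroring the one-nucleotide-shifted guide observed
#' after cellular processing of the hairpins. For a 21-nt genomic target
#' sequence t:
#'
#' * `one_G`: sense = `G` + t\[1..18\] followed by t\[19..20\] as two 3'
#'   deoxyribonucleotides; antisense = reverse complement of t\[1..18\] padded
#'   with one U, plus a dTdT overhang, 5'-phosphorylated.
#' * `two_G`: as above with a `GG` prefix and UU padding.
#'
#' The exactly Watson-Crick paired core is the region derived from
#' t\[1..18\]; the added G prefix faces the U padding (a G:U wobble), so the
#' full 19/20-nt strands are not exact reverse complements of each other.
#'
#' @param target21 The 21-nt target site (DNA or RNA).
#' @param mode `"one_G"` (default) or `"two_G"`.
#' @return An [oligo_duplex()] object.
#' @examples
#' shrna_to_sirna("ACUGGGCUGUACUUUGUAUAU")            # shL3 -> siL3
#' shrna_to_sirna("GUGCAGAUGUAAACCAAACUU", "two_G")   # shR6 -> siR6
#' @export
shrna_to_sirna <- function(target21, mode = c("one_G", "two_G")) {
  mode <- match.arg(mode)
  t <- nuc_normalize(target21)
  if (length(t) != 1L || nchar(t) != 21L) {
    stop("target must be a single 21-nt sequence (got ",
         paste(nchar(t), collapse = ","), " nt)")
  }
  prefix <- if (mode == "one_G") "G" else "GG"
  pad <- if (mode == "one_G") "T" else "TT"
  core18 <- substr(t, 1L, 18L)
  sense_core <- paste0(prefix, core18)
  sense_over <- paste0("d", strsplit(substr(t, 19L, 20L), "")[[1]],
                       collapse = "")
  antis_core <- paste0(reverse_complement(core18), pad)
  sense <- list(core = sense_core, overhang = sense_over,
                five_prime_phos = FALSE,
                display = paste0(as_rna(sense_core), sense_over))
  antis <- list(core = antis_core, overhang = "dTdT",
                five_prime_phos = TRUE,
                display = paste0(as_rna(antis_core), "dTdT"))
  oligo_duplex(sense, antis, paired_core = core18)
}
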