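#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are normalized to the internal DNA alphabet (U mapped to T).
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param allow_duplicates If `TRUE`, repeated identifiers are kept (e.g. a
#'   3'UTR FASTA with one record per isoform, keyed by gene id, as consumed
#'   by [utr_gene_set()]). Default `FALSE`: duplicates are an error listing
#'   the offenders.
#' @return Named character vector of normalized sequences. An empty file
#'   yields an empty vector with a warning.
#' @export
read_fasta <- function(path, allow_duplicates = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(character(0))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) && !allow_duplicates) {
    stop("duplicate FASTA identifiers: ", paste(dup, collapse = ", "))
  }
  out <- nuc_normalize(as.character(ss))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @param rna If `TRUE`, render residues as RNA (T -> U).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L, rna = FALSE) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("all sequences must be named")
  }
  x <- stats::setNames(nuc_normalize(x), names(x))
  if (rna) x <- as_rna(x)
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Read/write the package's tab-separated interchange tables
#'
#' TSV (tab-delimited, header row, UTF-8, '.' decimal) is the interchange
#' dialect for all tabular outputs; JSON is used for manifests and simulation
#' truth records.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an oligo table
#'
#' Expected columns: `name`, `sense`, and optionally `antisense`. Sequences
#' may carry printed chemistry annotations (see [parse_oligo()]).
#'
#' @param path Path to a TSV file.
#' @return List of [oligo_duplex()] objects (named). When `antisense` is
#'   absent it is derived as the reverse complement of the sense core.
#' @export
read_oligo_table <- function(path) {
  tab <- read_tsv(path)
  need <- c("name", "sense")
  if (!all(need %in% names(tab))) {
    stop("oligo table must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    sense <- parse_oligo(tab$sense[i])
    anti <- if ("antisense" %in% names(tab) && nzchar(tab$antisense[i])) {
      parse_oligo(tab$antisense[i])
    } else {
      core <- reverse_complement(sense$core)
      list(core = core, overhang = "", five_prime_phos = FALSE,
           display = as_rna(core))
    }
    oligo_duplex(sense, anti)
  })
  names(out) <- tab$name
  out
}
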