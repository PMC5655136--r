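#' Subpool flank registry for the 143-nt cloning insert
#'
#' Each tiled subpool is amplified with its own 26-nt forward primer region;
#' the rest of the insert is common: a 10-nt spacer, the 21-nt sense arm, the
#' CTCGAG loop, the 21-nt antisense arm (reverse complement of the sense arm)
#' and a 59-nt terminator/backbone region, for 143 nt in total.
#'
#' @return A list with `fr_primers` (named by subpool), `spacer`, `loop`, and
#'   `backbone`.
#' @export
flank_registry <- function() {
  list(
    fr_primers = c(
      CD95L_ORF  = "TGGCTTTATATATCTCCCTATCAGTG",
      CD95L_3UTR = "GGTCGTCCTATCTATTATTATTCACG",
      CD95_ORF   = "TCTTGTGTCCAGACCAATTTATTTCG",
      CD95_3UTR  = "CTCATTGACTATCGTTTTAGCTACTG",
      VENUS_ORF  = "TATCATCTTTCATGATGACTTTCCGG"
    ),
    spacer = "ATAGAGATCG",
    loop = "CTCGAG",
    backbone = "TTTTTGTACCGAGCTCGGATCCACTAGTCCAGTGTGGGCATGCTGCGTTGACATTGATT"
  )
}

.SUBPOOLS <- c("VENUS_ORF", "CD95L_ORF", "CD95L_3UTR",
               "CD95_ORF", "CD95_3UTR", "custom")

#' Tile every 21-mer shRNA along a source sequence
#'
#' Enumerates all 21-nt windows of an ORF or 3'UTR, shifting by one
#' nucleotide, starting at `start_offset + 1` (ORFs conventionally use offset
#' 3 to start with the first 21 nucleotides after the ATG start codon; 3'UTRs
#' use 0). Each record carries the guide strand (reverse complement of the
#' sense 21-mer), its 6mer and 8mer seeds and seed matches, seed GC
#' fractions, and the multiplicity of its sense sequence within the subpool
#' (identical windows arising from sequence repeats).
#'
#' @param source Source nucleotide sequence (single string).
#' @param subpool One of `"VENUS_ORF"`, `"CD95L_ORF"`, `"CD95L_3UTR"`,
#'   `"CD95_ORF"`, `"CD95_3UTR"`, `"custom"`.
#' @param start_offset Number of leading nucleotides to skip (default 0).
#' @param id_prefix Prefix for generated positional ids (default: subpool).
#' @return Data frame with one row per shRNA: `id`, `subpool`, `start`
#'   (1-based), `sense21`, `guide`, `seed6`, `seed_match6`, `gc6`, `seed8`,
#'   `seed_match8`, `gc8`, `multiplicity`. A source shorter than
#'   `start_offset + 21` yields a zero-row frame with a warning.
#' @examples
#' tile_shrnas(strrep("A", 26))  # 6 identical records, multiplicity 6
#' @export
tile_shrnas <- function(source, subpool = "custom", start_offset = 0L,
                        id_prefix = NULL) {
  subpool <- match.arg(subpool, .SUBPOOLS)
  source <- nuc_normalize(source)
  stopifnot(length(source) == 1L, start_offset >= 0L)
  if (is.null(id_prefix)) id_prefix <- subpool
  n <- nchar(source) - start_offset - 20L
  cols <- c("id", "subpool", "start", "sense21", "guide", "seed6",
            "seed_match6", "gc6", "seed8", "seed_match8", "gc8",
            "multiplicity")
  if (n < 1L) {
    warning("source too short to tile (", nchar(source), " nt, offset ",
            start_offset, "); returning no records")
    out <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  starts <- start_offset + seq_len(n)
  sense21 <- substring(source, starts, starts + 20L)
  guide <- reverse_complement(sense21)
  seed6 <- substr(guide, 2L, 7L)
  seed8 <- substr(guide, 2L, 9L)
  mult <- as.integer(table(sense21)[sense21])
  data.frame(
    id = paste0(id_prefix, "_", starts),
    subpool = subpool,
    start = starts,
    sense21 = sense21,
    guide = guide,
    seed6 = seed6,
    seed_match6 = reverse_complement(seed6),
    gc6 = gc_content(seed6),
    seed8 = seed8,
    seed_match8 = reverse_complement(seed8),
    gc8 = gc_content(seed8),
    multiplicity = mult,
    stringsAsFactors = FALSE
  )
}

#' Assemble 143-nt cloning inserts for a tiled library
#'
#' Places each sense 21-mer and its reverse complement around the CTCGAG
#' hairpin loop between the subpool's forward-primer region and the common
#' backbone, following the fixed insert template.
#'
#' @param library Data frame from [tile_shrnas()] (needs `id`, `subpool`,
#'   `sense21`).
#' @param registry Flank registry, see [flank_registry()]. Subpool `"custom"`
#'   requires a `fr_primers` entry named `custom` (26 nt) to be added.
#' @return Named character vector of 143-nt insert sequences (names = ids).
#' @export
build_insert <- function(library, registry = flank_registry()) {
  stopifnot(all(c("id", "subpool", "sense21") %in% names(library)))
  fr <- registry$fr_primers[as.character(library$subpool)]
  if (any(is.na(fr))) {
    stop("no forward primer registered for subpool(s): ",
         paste(unique(library$subpool[is.na(fr)]), collapse = ", "))
  }
  ins <- paste0(fr, registry$spacer, library$sense21, registry$loop,
                reverse_complement(library$sense21), registry$backbone)
  stopifnot(all(nchar(ins) == 143L))
  names(ins) <- library$id
  ins
}

#' Recover the sense arm from a 143-nt insert
#'
#' Inverse of the arm placement in [build_insert()]: the sense 21-mer sits at
#' fixed positions 37-57 of the insert (after the 26-nt primer and 10-nt
#' spacer).
#'
#' @param insert Character vector of 143-nt inserts.
#' @return Character vector of sense 21-mers.
#' @export
extract_sense_arm <- function(insert) {
  stopifnot(all(nchar(insert) == 143L))
  substr(insert, 37L, 57L)
}
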