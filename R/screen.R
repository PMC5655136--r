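#' Construct a screen count table
#'
#' Container for shRNA x sample read counts from a pooled dropout screen,
#' with per-sample roles (plasmid library, uninduced -Dox cultures, induced
#' +Dox cultures) and biological/technical replicate labels.
#'
#' @param counts Numeric matrix, rows = shRNA ids, columns = sample ids.
#'   Entries are non-negative (rational after multiplicity division).
#' @param samples Data frame with columns `sample_id`, `condition` (one of
#'   `"plasmid"`, `"noDox"`, `"Dox"`), `bio_rep`, `tech_rep`. Each
#'   (condition, bio_rep, tech_rep) combination must be unique.
#' @param subpool_of Named character vector mapping shRNA id to subpool.
#' @return List of class `"screen_counts"` with elements `counts`, `samples`,
#'   `subpool_of`.
#' @export
screen_count_table <- function(counts, samples, subpool_of) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  need <- c("sample_id", "condition", "bio_rep", "tech_rep")
  if (!all(need %in% names(samples))) {
    stop("samples needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(samples$condition %in% c("plasmid", "noDox", "Dox"))) {
    stop("condition must be plasmid, noDox or Dox")
  }
  key <- paste(samples$condition, samples$bio_rep, samples$tech_rep)
  if (anyDuplicated(key)) stop("duplicate (condition, bio_rep, tech_rep)")
  if (!setequal(colnames(counts), samples$sample_id)) {
    stop("count columns and sample_id do not match")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (any(counts < 0)) stop("negative counts")
  sp <- subpool_of[rownames(counts)]
  if (any(is.na(sp))) stop("missing subpool assignment for some shRNAs")
  structure(list(counts = counts, samples = samples, subpool_of = sp),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d shRNAs x %d samples (%d subpool(s))\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$subpool_of))))
  invisible(x)
}

#' Count library shRNAs in raw screen reads
#'
#' A read is assigned to an shRNA if and only if the shRNA's sense 21-mer
#' followed immediately by the hairpin loop CTCGAG occurs in the read as an
#' exact substring (forward orientation, no mismatches). A read matching
#' several distinct sense sequences increments each matched shRNA. After
#' counting, each shRNA's count is divided by its multiplicity, so sequence
#' repeats tiled multiple times are not over-counted.
#'
#' @param read_sets Named list of character vectors of reads, one per
#'   sample (names = sample ids); a bare character vector is treated as one
#'   sample named `"sample1"`.
#' @param library Data frame from [tile_shrnas()] (needs `id`, `sense21`,
#'   `subpool`, `multiplicity`).
#' @param samples Sample metadata (see [screen_count_table()]); defaults to
#'   a single-plasmid-sample layout matching `read_sets` names.
#' @return A `"screen_counts"` object.
#' @export
count_reads <- function(read_sets, library, samples = NULL) {
  if (is.character(read_sets)) read_sets <- list(sample1 = read_sets)
  if (nrow(library) == 0L) stop("empty shRNA library")
  stopifnot(!is.null(names(read_sets)))
  patterns <- paste0(library$sense21, "CTCGAG")
  counts <- vapply(read_sets, function(reads) {
    reads <- toupper(reads)
    vapply(patterns, function(p) {
      sum(grepl(p, reads, fixed = TRUE))
    }, numeric(1))
  }, numeric(length(patterns)))
  counts <- matrix(counts, nrow = length(patterns),
                   dimnames = list(library$id, names(read_sets)))
  counts <- counts / library$multiplicity
  if (is.null(samples)) {
    samples <- data.frame(sample_id = names(read_sets),
                          condition = "plasmid",
                          bio_rep = 1L,
                          tech_rep = seq_along(read_sets),
                          stringsAsFactors = FALSE)
  }
  sp <- stats::setNames(as.character(library$subpool), library$id)
  screen_count_table(counts, samples, sp)
}

#' Read FASTQ or plain-text reads (qualities ignored)
#'
#' @param path FASTQ (`.fastq`/`.fq`) or one-read-per-line text file.
#' @return Character vector of reads.
#' @export
read_reads <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "@")) {
    if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
    lines[seq(2L, length(lines), by = 4L)]
  } else {
    lines[nzchar(lines)]
  }
}

#' Preprocess screen counts: plasmid filter and zero replacement
#'
#' shRNAs whose summed counts across all plasmid samples (before zero
#' replacement) fall below `min_plasmid_total` are removed as not represented
#' in the cloned library. Every remaining zero cell is then replaced with 1
#' so that the downstream ratio formulas never divide by zero.
#'
#' @param x A `"screen_counts"` object.
#' @param min_plasmid_total Minimum summed plasmid count (default 10).
#' @return A `"screen_counts"` object; removed ids are recorded in
#'   `attr(, "removed")` and reported via a message.
#' @export
preprocess_counts <- function(x, min_plasmid_total = 10) {
  stopifnot(inherits(x, "screen_counts"))
  plasmid <- x$samples$sample_id[x$samples$condition == "plasmid"]
  if (length(plasmid) == 0L) stop("no plasmid sample in count table")
  pre <- rowSums(x$counts[, plasmid, drop = FALSE])
  keep <- pre >= min_plasmid_total
  removed <- rownames(x$counts)[!keep]
  counts <- x$counts[keep, , drop = FALSE]
  counts[counts == 0] <- 1
  if (length(removed)) {
    message(length(removed), " shRNA(s) removed (plasmid total < ",
            min_plasmid_total, "): ",
            paste(utils::head(removed, 10L), collapse = ", "),
            if (length(removed) > 10L) ", ..." else "")
  }
  out <- screen_count_table(counts, x$samples, x$subpool_of[keep])
  attr(out, "removed") <- removed
  out
}

#' Remove flagged shRNAs from a count table
#'
#' For constructs that cannot be evaluated (e.g. a vector-backbone hairpin
#' with cloning background, or a contaminating shRNA), an explicit exclusion
#' list drops them before any statistics are computed.
#'
#' @param x A `"screen_counts"` object.
#' @param ids Character vector of shRNA ids to drop.
#' @return A `"screen_counts"` object without the flagged rows.
#' @export
exclude_shrnas <- function(x, ids) {
  stopifnot(inherits(x, "screen_counts"))
  keep <- !(rownames(x$counts) %in% ids)
  out <- screen_count_table(x$counts[keep, , drop = FALSE], x$samples,
                            x$subpool_of[keep])
  attr(out, "excluded") <- rownames(x$counts)[!keep]
  out
}

#' Average technical replicates
#'
#' Collapses the count matrix to one column per (condition, biological
#' replicate) by taking the arithmetic mean over technical replicates.
#'
#' @param x A `"screen_counts"` object.
#' @return A `"screen_counts"` object with `tech_rep = 1` per collapsed
#'   column; a missing replicate is averaged over what is available.
#' @export
average_technical <- function(x) {
  stopifnot(inherits(x, "screen_counts"))
  grp <- paste(x$samples$condition, x$samples$bio_rep, sep = ".")
  ugrp <- unique(grp)
  counts <- vapply(ugrp, function(g) {
    rowMeans(x$counts[, x$samples$sample_id[grp == g], drop = FALSE])
  }, numeric(nrow(x$counts)))
  counts <- matrix(counts, nrow = nrow(x$counts),
                   dimnames = list(rownames(x$counts), ugrp))
  first <- match(ugrp, grp)
  samples <- data.frame(sample_id = ugrp,
                        condition = x$samples$condition[first],
                        bio_rep = x$samples$bio_rep[first],
                        tech_rep = 1L,
                        stringsAsFactors = FALSE)
  screen_count_table(counts, samples, x$subpool_of)
}

#' Normalize counts to within-subpool percentages
#'
#' Each cell is expressed as a percentage of the total shRNA-assigned reads
#' of its subpool in that sample, so percentages sum to 100 within every
#' (sample, subpool) and abundances are comparable across sequencing depths.
#'
#' @param x A `"screen_counts"` object (after [preprocess_counts()], so all
#'   cells are >= 1 and subpool totals are positive).
#' @return A `"screen_counts"` object whose matrix holds percentages.
#' @export
normalize_subpool <- function(x) {
  stopifnot(inherits(x, "screen_counts"))
  pct <- x$counts
  for (sp in unique(x$subpool_of)) {
    rows <- x$subpool_of == sp
    tot <- colSums(x$counts[rows, , drop = FALSE])
    if (any(tot <= 0)) stop("zero subpool total; run preprocess_counts first")
    pct[rows, ] <- 100 * sweep(x$counts[rows, , drop = FALSE], 2L, tot, "/")
  }
  screen_count_table(pct, x$samples, x$subpool_of)
}

#' Fold downregulation after infection (plasmid vs -Dox)
#'
#' Mean over uninduced biological replicates of the plasmid-to-culture
#' percentage ratio: with two replicates, (p/d1 + p/d2) / 2. Values > 1 mean
#' the shRNA dropped out during the 9 days of uninduced culture relative to
#' the cloned plasmid library.
#'
#' @param pct_plasmid,pct_noDox1,pct_noDox2 Positive subpool percentages.
#' @return Numeric vector of fold-downregulation ratios.
#' @export
fold_down_infection <- function(pct_plasmid, pct_noDox1, pct_noDox2) {
  v <- c(pct_plasmid, pct_noDox1, pct_noDox2)
  if (any(!is.finite(v)) || any(v <= 0)) stop("percentages must be positive")
  (pct_plasmid / pct_noDox1 + pct_plasmid / pct_noDox2) / 2
}

#' Fold downregulation after induction (-Dox vs +Dox)
#'
#' Mean of the four cross-replicate ratios between uninduced and induced
#' cultures: (d1/x1 + d1/x2 + d2/x1 + d2/x2) / 4.
#'
#' @param d1,d2 Positive -Dox percentages (biological replicates 1 and 2).
#' @param x1,x2 Positive +Dox percentages.
#' @return Numeric vector of fold-downregulation ratios.
#' @export
fold_down_dox <- function(d1, d2, x1, x2) {
  v <- c(d1, d2, x1, x2)
  if (any(!is.finite(v)) || any(v <= 0)) stop("percentages must be positive")
  (d1 / x1 + d1 / x2 + d2 / x1 + d2 / x2) / 4
}

#' Depletion table: percentages, fold ratios and calls per shRNA
#'
#' Runs the percentage-normalized table through both fold-downregulation
#' formulas. Generalizes to any number of biological replicates as the mean
#' over all reference/selected replicate ratio pairs; with one plasmid sample
#' and two replicates per condition this is exactly the printed two-formula
#' procedure.
#'
#' @param x A `"screen_counts"` object of percentages with technical
#'   replicates already averaged ([average_technical()] then
#'   [normalize_subpool()]).
#' @return Data frame with one row per shRNA: `id`, `subpool`, the per-column
#'   percentages, `fold_down_infection`, `fold_down_dox`.
#' @export
screen_folds <- function(x) {
  stopifnot(inherits(x, "screen_counts"))
  s <- x$samples
  pcol <- s$sample_id[s$condition == "plasmid"]
  dcol <- s$sample_id[s$condition == "noDox"]
  xcol <- s$sample_id[s$condition == "Dox"]
  if (!length(pcol) || !length(dcol) || !length(xcol)) {
    stop("need plasmid, noDox and Dox samples to compute folds")
  }
  p <- rowMeans(x$counts[, pcol, drop = FALSE])
  dmat <- x$counts[, dcol, drop = FALSE]
  xmat <- x$counts[, xcol, drop = FALSE]
  fi <- rowMeans(p / dmat)
  ratios <- lapply(seq_along(dcol), function(i) {
    vapply(seq_along(xcol), function(j) dmat[, i] / xmat[, j],
           numeric(nrow(dmat)))
  })
  fd <- rowMeans(matrix(unlist(ratios), nrow = nrow(dmat)))
  out <- data.frame(id = rownames(x$counts),
                    subpool = unname(x$subpool_of),
                    pct_plasmid = unname(p),
                    stringsAsFactors = FALSE)
  for (cn in c(dcol, xcol)) out[[paste0("pct_", cn)]] <- unname(x$counts[, cn])
  out$fold_down_infection <- unname(fi)
  out$fold_down_dox <- unname(fd)
  out
}

#' Call depleted shRNAs
#'
#' An shRNA is called depleted (toxic) when it is at least `threshold`-fold
#' underrepresented in either the infection (plasmid vs -Dox) or the
#' induction (-Dox vs +Dox) comparison; the boundary is inclusive.
#'
#' @param folds Data frame from [screen_folds()].
#' @param threshold Fold-change cutoff (default 5).
#' @return The input with a logical `depleted` column appended.
#' @export
call_depleted <- function(folds, threshold = 5) {
  stopifnot(all(c("fold_down_infection", "fold_down_dox") %in% names(folds)))
  folds$depleted <- folds$fold_down_infection >= threshold |
    folds$fold_down_dox >= threshold
  folds
}
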