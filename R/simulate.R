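#' @keywords internal
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

.random_seqs <- function(n, lengths, composition) {
  stopifnot(abs(sum(composition) - 1) < 1e-8)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste(sample(bases, lengths[i], replace = TRUE, prob = composition),
          collapse = "")
  }, character(1))
}

# insert `copies` non-overlapping copies of `word` into `seq` at uniformly
# random positions (rejection sampling); returns the modified sequence and
# the number actually placed
.plant_word <- function(seq, word, copies) {
  L <- nchar(seq)
  w <- nchar(word)
  placed <- integer(0)
  attempts <- 0L
  while (length(placed) < copies && attempts < 50L * (copies + 1L)) {
    attempts <- attempts + 1L
    pos <- sample.int(L - w + 1L, 1L)
    if (!any(abs(placed - pos) < w)) {
      placed <- c(placed, pos)
      substr(seq, pos, pos + w - 1L) <- word
    }
  }
  list(seq = seq, n_placed = length(placed))
}

#' Simulate survival/nonsurvival 3'UTR gene sets with planted seed matches
#'
#' Generates two classes of genes with 3'UTR lengths drawn from a log-normal
#' law and i.i.d. background residues from a fixed composition (default
#' AT-rich, as is typical of 3'UTRs). Selected k-mer words are planted as a
#' Poisson number of non-overlapping copies per gene, at a class-specific
#' rate per kb, emulating survival-gene 3'UTRs being enriched for toxic seed
#' matches. The returned truth record stores the planted copy number per
#' gene so recovery can be verified (background may add further spontaneous
#' occurrences).
#'
#' @param n_survival,n_nonsurvival Number of genes per class (default 500).
#' @param utr_len_median Median 3'UTR length in nt (default 1000).
#' @param utr_len_sdlog Log-normal dispersion (sdlog, default 0.4).
#' @param composition Named nucleotide frequencies summing to 1 (default
#'   `c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)`).
#' @param planted_words Data frame with columns `word`, `rate_S`, `rate_NS`
#'   (copies per kb per class), or `NULL` for pure background.
#' @param min_len Floor for sampled UTR lengths (default 50 nt); planted
#'   words longer than this floor are an error.
#' @param seed Integer RNG seed.
#' @return List with `survival` and `nonsurvival` ([utr_gene_set()] objects)
#'   and `truth` (data frame `gene_id`, `class`, `word`, `planted`).
#' @export
gen_utr_sets <- function(n_survival = 500L, n_nonsurvival = 500L,
                         utr_len_median = 1000, utr_len_sdlog = 0.4,
                         composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                         planted_words = NULL, min_len = 50L, seed = 1L) {
  if (!is.null(planted_words)) {
    stopifnot(all(c("word", "rate_S", "rate_NS") %in% names(planted_words)))
    planted_words$word <- nuc_normalize(planted_words$word)
    if (any(planted_words$rate_S < 0 | planted_words$rate_NS < 0)) {
      stop("planting rates must be >= 0")
    }
    if (any(nchar(planted_words$word) > min_len)) {
      stop("planted word longer than the minimum UTR length")
    }
  }
  .with_seed(seed, {
    gen_class <- function(n, cls, prefix) {
      lens <- pmax(min_len,
                   round(stats::rlnorm(n, log(utr_len_median), utr_len_sdlog)))
      seqs <- .random_seqs(n, lens, composition)
      ids <- sprintf("%s%04d", prefix, seq_len(n))
      truth <- NULL
      if (!is.null(planted_words)) {
        rate_col <- if (cls == "survival") "rate_S" else "rate_NS"
        truth <- do.call(rbind, lapply(seq_len(nrow(planted_words)),
                                       function(w) {
          rate <- planted_words[[rate_col]][w]
          word <- planted_words$word[w]
          copies <- stats::rpois(n, rate * lens / 1000)
          placed <- integer(n)
          for (i in which(copies > 0L)) {
            res <- .plant_word(seqs[i], word, copies[i])
            seqs[i] <<- res$seq
            placed[i] <- res$n_placed
          }
          data.frame(gene_id = ids, class = cls, word = word,
                     planted = placed, stringsAsFactors = FALSE)
        }))
      }
      names(seqs) <- ids
      list(set = utr_gene_set(seqs, cls), truth = truth)
    }
    s <- gen_class(n_survival, "survival", "SG")
    ns <- gen_class(n_nonsurvival, "nonsurvival", "NSG")
    list(survival = s$set, nonsurvival = ns$set,
         truth = rbind(s$truth, ns$truth))
  })
}

#' Simulate pooled dropout-screen counts with toxicity-driven depletion
#'
#' Mirrors the plasmid -> uninduced (-Dox) -> induced (+Dox) design of a
#' Tet-inducible pooled shRNA screen. Per-shRNA plasmid expectations are
#' uniform at `depth_plasmid`; expected abundance in -Dox cultures is scaled
#' by `multiplier^leak_fraction` (basal promoter leakiness acting a fraction
#' of the full effect) and in +Dox cultures by the full toxicity
#' `multiplier`. All sample columns are depth-matched (rescaled to the same
#' expected total). Biological replicates draw negative-binomially
#' overdispersed counts around the expectations; technical replicates are
#' multinomial resamples of their biological replicate at equal depth
#' (sequencing-depth noise only). Depletion acts multiplicatively on
#' expectations, not on sampled counts, matching the ratio-form fold
#' statistics.
#'
#' @param library Data frame from [tile_shrnas()] (needs `id`, `subpool`).
#' @param depth_plasmid Mean reads per shRNA (default 1000).
#' @param dispersion Negative-binomial overdispersion; variance is
#'   mu + dispersion * mu^2 (default 0.05; 0 gives Poisson).
#' @param leak_fraction Fraction of full toxicity acting without Dox, in
#'   \[0, 1\] (default 0.2).
#' @param toxicity_map Named numeric vector in (0, 1\]: per-shRNA survival
#'   multiplier (1 = harmless). Must cover the library.
#' @param n_bio_rep,n_tech_rep Replicate structure (default 2 and 2; the
#'   plasmid library has one biological prep).
#' @param seed Integer RNG seed.
#' @return A `"screen_counts"` object.
#' @export
gen_screen_counts <- function(library, depth_plasmid = 1000,
                              dispersion = 0.05, leak_fraction = 0.2,
                              toxicity_map = NULL, n_bio_rep = 2L,
                              n_tech_rep = 2L, seed = 1L) {
  if (nrow(library) == 0L) stop("empty library")
  if (is.null(toxicity_map)) {
    toxicity_map <- stats::setNames(rep(1, nrow(library)), library$id)
  }
  mult <- toxicity_map[library$id]
  if (any(is.na(mult))) stop("toxicity_map does not cover the library")
  if (any(mult <= 0 | mult > 1)) stop("multipliers must be in (0, 1]")
  if (leak_fraction < 0 || leak_fraction > 1) {
    stop("leak_fraction must be in [0, 1]")
  }
  m <- nrow(library)
  target_total <- m * depth_plasmid
  rnb <- function(mu) {
    if (dispersion <= 0) return(stats::rpois(m, mu))
    stats::rnbinom(m, mu = mu, size = 1 / dispersion)
  }
  .with_seed(seed, {
    expectation <- list(
      plasmid = rep(depth_plasmid, m),
      noDox = depth_plasmid * mult^leak_fraction,
      Dox = depth_plasmid * mult
    )
    cols <- list()
    samples <- NULL
    for (cond in names(expectation)) {
      e <- expectation[[cond]] * target_total / sum(expectation[[cond]])
      nb <- if (cond == "plasmid") 1L else n_bio_rep
      for (b in seq_len(nb)) {
        bio <- rnb(e)
        for (t in seq_len(n_tech_rep)) {
          id <- sprintf("%s_b%d_r%d", cond, b, t)
          tech <- if (sum(bio) > 0) {
            as.numeric(stats::rmultinom(1L, size = sum(bio),
                                        prob = bio + 1e-9))
          } else bio
          cols[[id]] <- tech
          samples <- rbind(samples,
                           data.frame(sample_id = id, condition = cond,
                                      bio_rep = b, tech_rep = t,
                                      stringsAsFactors = FALSE))
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- library$id
    sp <- stats::setNames(as.character(library$subpool), library$id)
    screen_count_table(counts, samples, sp)
  })
}

#' Simulate a ranked gene list with a word planted in the leading genes
#'
#' Fixture generator for the seed-enrichment landscape: `n_genes` genes with
#' background 3'UTRs, ranked arbitrarily, where the top fraction of the list
#' receives elevated planting of `planted_word` (emulating the 3'UTRs of
#' downregulated genes being enriched for a toxic seed match).
#'
#' @param n_genes Number of genes (default 2000).
#' @param planted_word k-mer to plant, or `NULL` for a pure null list.
#' @param top_fraction Fraction of the list treated as leading, in (0, 1)
#'   (default 0.1).
#' @param rate_top,rate_rest Planting rates (copies per kb) in the leading
#'   and remaining genes (defaults 5 and 0.5).
#' @param utr_len_median,utr_len_sdlog,composition,min_len As in
#'   [gen_utr_sets()]; default median length 500 nt.
#' @param seed Integer RNG seed.
#' @return List with `ranked_ids`, `utrs` (named character) and `truth`
#'   (data frame `gene_id`, `leading`, `planted`).
#' @export
gen_ranked_list <- function(n_genes = 2000L, planted_word = NULL,
                            top_fraction = 0.1, rate_top = 5,
                            rate_rest = 0.5, utr_len_median = 500,
                            utr_len_sdlog = 0.4,
                            composition = c(A = 0.3, C = 0.2,
                                            G = 0.2, T = 0.3),
                            min_len = 50L, seed = 1L) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1)")
  }
  .with_seed(seed, {
    lens <- pmax(min_len,
                 round(stats::rlnorm(n_genes, log(utr_len_median),
                                     utr_len_sdlog)))
    seqs <- .random_seqs(n_genes, lens, composition)
    ids <- sprintf("g%05d", seq_len(n_genes))
    names(seqs) <- ids
    n_top <- max(1L, round(top_fraction * n_genes))
    leading <- seq_len(n_genes) <= n_top
    planted <- integer(n_genes)
    if (!is.null(planted_word)) {
      planted_word <- nuc_normalize(planted_word)
      if (nchar(planted_word) > min_len) {
        stop("planted word longer than the minimum UTR length")
      }
      rates <- ifelse(leading, rate_top, rate_rest)
      copies <- stats::rpois(n_genes, rates * lens / 1000)
      for (i in which(copies > 0L)) {
        res <- .plant_word(seqs[i], planted_word, copies[i])
        seqs[i] <- res$seq
        planted[i] <- res$n_placed
      }
    }
    list(ranked_ids = ids, utrs = seqs,
         truth = data.frame(gene_id = ids, leading = leading,
                            planted = planted, stringsAsFactors = FALSE))
  })
}
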