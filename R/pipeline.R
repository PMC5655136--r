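#' Default configuration for a synthetic end-to-end run
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed; stage seeds are derived from it and
#'   recorded in the manifest.
#' @return Named list of pipeline parameters (see [run_pipeline()]).
#' @export
default_config <- function(out_dir = tempfile("seedtox_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    source_length = 600L,       # nt of synthetic ORF/UTR to tile
    subpool = "custom",
    start_offset = 0L,
    k = 8L,
    n_survival = 150L,
    n_nonsurvival = 150L,
    utr_len_median = 500,
    planted_words = NULL,
    depth_plasmid = 300,
    dispersion = 0.05,
    leak_fraction = 0.2,
    toxic_fraction = 0.1,       # most-toxic fraction of tiled shRNAs
    toxic_multiplier = 0.1,
    threshold = 5,
    exclude = character(0),
    n_perm = 1000L
  )
}

.validate_config <- function(config) {
  required <- names(default_config())
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(config$seed) || is.na(config$seed)) {
    stop("config must set an explicit seed for stochastic stages")
  }
  config
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates all stages on simulated inputs: tile a synthetic source into
#' an shRNA library; simulate screen counts with toxicity-driven depletion
#' (the most TI-toxic shRNAs get the depletion multiplier); preprocess
#' (zero replacement, plasmid filter), average technical replicates,
#' normalize to subpool percentages; compute both fold-downregulation
#' ratios and 5-fold depletion calls; simulate survival/nonsurvival 3'UTR
#' sets, build the Toxicity Index table and assign it to the library; and
#' run the permutation Mann-Whitney TI association test. All tables are
#' written as TSV plus a machine-readable JSON manifest recording stage
#' order, parameters, seeds and filter attrition; rerunning an identical
#' config reproduces identical files.
#'
#' @param config List from [default_config()] (fields may be overridden).
#'   A config can also be a path to a JSON file with the same fields.
#' @return Invisibly, a list with the in-memory results bundle and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  config <- .validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  log <- list()
  note <- function(stage, ...) {
    stages <<- c(stages, stage)
    log[[stage]] <<- list(...)
  }
  seeds <- config$seed + 0:3   # one derived seed per stochastic stage

  # 1. tile a synthetic source sequence into the shRNA library
  src <- .with_seed(seeds[1],
                    .random_seqs(1L, config$source_length,
                                 c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)))
  lib <- tile_shrnas(src, config$subpool, config$start_offset)
  note("tile", n_shrnas = nrow(lib), seed = seeds[1])

  # 2. UTR gene sets + TI (needed to pick the toxic shRNAs for simulation)
  sets <- gen_utr_sets(n_survival = config$n_survival,
                       n_nonsurvival = config$n_nonsurvival,
                       utr_len_median = config$utr_len_median,
                       planted_words = config$planted_words,
                       seed = seeds[2])
  ti <- compute_ti(sets$survival, sets$nonsurvival, config$k)
  note("ti_build", k = config$k, entries = nrow(ti), seed = seeds[2])

  # 3. simulate screen counts: the top toxic_fraction of shRNAs by TI get
  #    the depletion multiplier
  seedcol <- paste0("seed", config$k)
  lib_ti <- assign_ti(lib, ti)
  n_toxic <- max(1L, round(config$toxic_fraction * nrow(lib_ti)))
  tox <- stats::setNames(rep(1, nrow(lib)), lib$id)
  tox[lib_ti$id[seq_len(n_toxic)]] <- config$toxic_multiplier
  counts <- gen_screen_counts(lib, depth_plasmid = config$depth_plasmid,
                              dispersion = config$dispersion,
                              leak_fraction = config$leak_fraction,
                              toxicity_map = tox, seed = seeds[3])
  note("count", n_samples = ncol(counts$counts), seed = seeds[3])

  # 4-6. preprocess, average tech reps, normalize
  if (length(config$exclude)) counts <- exclude_shrnas(counts, config$exclude)
  pre <- preprocess_counts(counts)
  note("preprocess", n_removed = length(attr(pre, "removed")),
       n_excluded = length(config$exclude))
  pct <- normalize_subpool(average_technical(pre))
  note("normalize", n_shrnas = nrow(pct$counts))

  # 7. folds + calls
  folds <- call_depleted(screen_folds(pct), config$threshold)
  note("folds", n_shrnas = nrow(folds))
  note("call", n_depleted = sum(folds$depleted),
       threshold = config$threshold)

  # 8. TI assignment + permutation test
  ann <- assign_ti(folds_merge(folds, lib, ti), ti)
  perm <- ti_permutation_test(ann$ti, ann$depleted,
                              n_perm = config$n_perm, seed = seeds[4])
  note("stats", p_perm = perm$p_perm, w = perm$w_observed,
       n_perm = config$n_perm, seed = seeds[4])

  # outputs
  o <- function(f) file.path(config$out_dir, f)
  write_tsv(lib, o("library.tsv"))
  write_tsv(data.frame(kmer = ti$kmer, count_S = ti$count_S,
                       count_NS = ti$count_NS, ti = ti$ti), o("ti_table.tsv"))
  write_tsv(ann, o("depletion.tsv"))
  write_fasta(c(sets$survival$seqs, sets$nonsurvival$seqs), o("utrs.fasta"))
  manifest <- list(
    tool = "seedtox",
    version = as.character(utils::packageVersion("seedtox")),
    config = config[setdiff(names(config), "out_dir")],
    stages = stages,
    log = log
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(library = lib, ti = ti, counts = counts, folds = ann,
                 perm = perm, manifest = manifest))
}

#' @keywords internal
folds_merge <- function(folds, lib, ti) {
  k <- attr(ti, "k")
  seedcol <- paste0("seed", k)
  folds[[seedcol]] <- lib[[seedcol]][match(folds$id, lib$id)]
  folds
}
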