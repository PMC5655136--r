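# minimal two-subpool library for counting tests
make_lib <- function() {
  set.seed(21)
  rbind(tile_shrnas(random_dna(1, 24), "CD95L_ORF"),
        tile_shrnas(random_dna(1, 23), "CD95_ORF"))
}

sample_meta <- function() {
  data.frame(
    sample_id = c("pl_1", "nd1", "nd2", "dx1", "dx2"),
    condition = c("plasmid", "noDox", "noDox", "Dox", "Dox"),
    bio_rep = c(1L, 1L, 2L, 1L, 2L),
    tech_rep = 1L,
    stringsAsFactors = FALSE
  )
}

test_that("reads count only when the sense 21-mer is followed by the CTCGAG loop", {
  lib <- make_lib()
  hit <- paste0("NNN", lib$sense21[1], "CTCGAG", "AAAT")
  no_loop <- paste0("NNN", lib$sense21[1], "TTTTTT")
  other <- paste0(lib$sense21[5], "CTCGAG")
  tab <- count_reads(c(hit, hit, no_loop, other), lib)
  expect_equal(unname(tab$counts[1, 1]), 2)
  expect_equal(unname(tab$counts[5, 1]), 1)
  expect_equal(sum(tab$counts), 3)
  expect_error(count_reads("ACGT", lib[0, ]), "empty")
})

test_that("counts are divided by sense-sequence multiplicity", {
  lib <- tile_shrnas(strrep("A", 26))  # 6 identical 21-mers, multiplicity 6
  reads <- rep(paste0(strrep("A", 21), "CTCGAG"), 12)
  tab <- count_reads(reads, lib)
  expect_equal(unname(tab$counts[, 1]), rep(2, 6))  # 12 raw / 6
})

test_that("preprocessing replaces zeros after filtering on pre-replacement plasmid sums", {
  counts <- matrix(c(3, 4, 2, 0, 0,
                     5, 0, 7, 1, 2,
                     12, 1, 1, 1, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"), sample_meta()$sample_id))
  # give s1 plasmid reps summing to 9: split plasmid into two tech reps
  meta <- rbind(sample_meta(),
                data.frame(sample_id = "pl_2", condition = "plasmid",
                           bio_rep = 1L, tech_rep = 2L))
  counts <- cbind(counts, pl_2 = c(6, 5, 1))
  counts["s1", "pl_1"] <- 3  # plasmid sum 3 + 6 = 9 -> removed
  tab <- screen_count_table(counts, meta,
                            setNames(rep("CD95L_ORF", 3), rownames(counts)))
  expect_message(pre <- preprocess_counts(tab), "removed")
  expect_identical(attr(pre, "removed"), "s1")
  expect_false("s1" %in% rownames(pre$counts))
  expect_true(all(pre$counts >= 1))          # zeros replaced
  expect_equal(unname(pre$counts["s2", "nd1"]), 1)  # was 0
  expect_equal(unname(pre$counts["s2", "pl_1"]), 5) # unchanged

  no_plasmid <- screen_count_table(
    counts[, c("nd1", "nd2")], meta[meta$condition == "noDox", ],
    setNames(rep("CD95L_ORF", 3), rownames(counts)))
  expect_error(preprocess_counts(no_plasmid), "no plasmid")
})

test_that("technical replicates average arithmetically", {
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     condition = c("noDox", "noDox", "Dox"),
                     bio_rep = 1L, tech_rep = c(1L, 2L, 1L))
  counts <- matrix(c(10, 20, 7,
                     1, 1, 3), nrow = 2, byrow = TRUE,
                   dimnames = list(c("x", "y"), meta$sample_id))
  tab <- average_technical(screen_count_table(counts, meta,
                                              c(x = "CD95_ORF", y = "CD95_ORF")))
  expect_equal(unname(tab$counts["x", "noDox.1"]), 15)
  expect_equal(unname(tab$counts["y", "noDox.1"]), 1)
  expect_equal(unname(tab$counts["x", "Dox.1"]), 7)  # single rep passes through
})

test_that("subpool normalization yields percentages summing to 100 per subpool", {
  meta <- sample_meta()
  set.seed(31)
  counts <- matrix(sample(1:50, 8 * 5, replace = TRUE), nrow = 8,
                   dimnames = list(paste0("sh", 1:8), meta$sample_id))
  sp <- setNames(rep(c("CD95L_ORF", "CD95_3UTR"), each = 4), paste0("sh", 1:8))
  pct <- normalize_subpool(screen_count_table(counts, meta, sp))
  for (s in meta$sample_id) {
    for (pool in unique(sp)) {
      expect_equal(sum(pct$counts[sp == pool, s]), 100, tolerance = 1e-9)
    }
  }
  # worked example: counts (1,1,2) -> (25,25,50)
  one <- screen_count_table(
    matrix(c(1, 1, 2), 3, dimnames = list(paste0("a", 1:3), "pl")),
    data.frame(sample_id = "pl", condition = "plasmid", bio_rep = 1L,
               tech_rep = 1L),
    setNames(rep("VENUS_ORF", 3), paste0("a", 1:3)))
  expect_equal(unname(normalize_subpool(one)$counts[, 1]), c(25, 25, 50))
})

test_that("fold formulas follow the printed cross-replicate means", {
  expect_equal(fold_down_infection(2, 1, 0.5), 3)
  expect_equal(fold_down_infection(1, 1, 1), 1)
  expect_equal(fold_down_infection(1, 2, 2), 0.5)
  expect_equal(fold_down_dox(2, 2, 1, 1), 2)
  expect_equal(fold_down_dox(4, 2, 2, 1), 2.25)
  expect_equal(fold_down_dox(3, 3, 3, 3), 1)
  expect_error(fold_down_infection(1, 0, 1), "positive")
  expect_error(fold_down_dox(1, -1, 1, 1), "positive")
})

test_that("fold ratios are invariant to rescaling a sample's percentages", {
  set.seed(41)
  p <- runif(20, 0.5, 5); d1 <- runif(20, 0.5, 5); d2 <- runif(20, 0.5, 5)
  x1 <- runif(20, 0.5, 5); x2 <- runif(20, 0.5, 5)
  expect_equal(fold_down_infection(3.7 * p, d1, d2) / 3.7,
               fold_down_infection(p, d1, d2))
  expect_equal(fold_down_dox(d1, d2, 0.21 * x1, 0.21 * x2) * 0.21,
               fold_down_dox(d1, d2, x1, x2))
})

test_that("depletion calls use an inclusive 5-fold boundary on either comparison", {
  folds <- data.frame(fold_down_infection = c(5.0, 4.9, 1.0, 0.2),
                      fold_down_dox = c(1.0, 4.9, 12.0, 5.0))
  out <- call_depleted(folds)
  expect_equal(out$depleted, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(call_depleted(folds, threshold = 13)$depleted, rep(FALSE, 4))
})

test_that("the full pipeline reproduces hand-computed folds on a 5-shRNA fixture", {
  # hand-built fixture: one subpool, 5 shRNAs, plasmid + 2x2 noDox/Dox tech reps
  ids <- paste0("sh", 1:5)
  meta <- data.frame(
    sample_id = c("pl", "nd1a", "nd1b", "nd2a", "nd2b",
                  "dx1a", "dx1b", "dx2a", "dx2b"),
    condition = c("plasmid", rep("noDox", 4), rep("Dox", 4)),
    bio_rep = c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L),
    tech_rep = c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L))
  counts <- matrix(c(
    # pl  nd1a nd1b nd2a nd2b dx1a dx1b dx2a dx2b
      20,  20,  20,  10,  10,  20,  20,  20,  20,   # sh1
      20,   2,   2,   2,   2,   2,   2,   2,   2,   # sh2 depleted on infection
      20,  20,  20,  20,  20,   1,   1,   2,   2,   # sh3 depleted on Dox
      20,  20,  20,  20,  20,  20,  20,  20,  20,   # sh4 flat
      20,  40,  60,  50,  50,  60,  60,  40,  40),  # sh5 enriched
    nrow = 5, byrow = TRUE, dimnames = list(ids, meta$sample_id))
  tab <- screen_count_table(counts, meta, setNames(rep("VENUS_ORF", 5), ids))
  pct <- normalize_subpool(average_technical(preprocess_counts(tab)))

  # spreadsheet-style recomputation, by hand:
  # tech means per bio rep, then % of column sums (per subpool), then folds
  tech <- cbind(pl = counts[, "pl"],
                nd1 = rowMeans(counts[, c("nd1a", "nd1b")]),
                nd2 = rowMeans(counts[, c("nd2a", "nd2b")]),
                dx1 = rowMeans(counts[, c("dx1a", "dx1b")]),
                dx2 = rowMeans(counts[, c("dx2a", "dx2b")]))
  pctm <- sweep(tech, 2, colSums(tech), "/") * 100
  fi_hand <- (pctm[, "pl"] / pctm[, "nd1"] + pctm[, "pl"] / pctm[, "nd2"]) / 2
  fd_hand <- (pctm[, "nd1"] / pctm[, "dx1"] + pctm[, "nd1"] / pctm[, "dx2"] +
              pctm[, "nd2"] / pctm[, "dx1"] + pctm[, "nd2"] / pctm[, "dx2"]) / 4

  folds <- call_depleted(screen_folds(pct))
  expect_equal(folds$fold_down_infection, unname(fi_hand))
  expect_equal(folds$fold_down_dox, unname(fd_hand))
  expect_equal(folds$depleted[folds$id == "sh2"], TRUE)
  expect_equal(folds$depleted[folds$id == "sh3"], TRUE)
  expect_equal(folds$depleted[folds$id == "sh4"], FALSE)
  expect_equal(folds$depleted[folds$id == "sh5"], FALSE)
})

test_that("flagged shRNAs are removable and never reappear downstream", {
  ids <- paste0("sh", 1:4)
  meta <- sample_meta()
  set.seed(51)
  counts <- matrix(sample(10:50, 20), nrow = 4,
                   dimnames = list(ids, meta$sample_id))
  tab <- screen_count_table(counts, meta, setNames(rep("CD95_ORF", 4), ids))
  # analogous to excluding a backbone hairpin and a contaminating shRNA
  cleaned <- exclude_shrnas(tab, c("sh2", "sh4"))
  expect_identical(attr(cleaned, "excluded"), c("sh2", "sh4"))
  folds <- screen_folds(normalize_subpool(average_technical(
    preprocess_counts(cleaned))))
  expect_false(any(c("sh2", "sh4") %in% folds$id))
})
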