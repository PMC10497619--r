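test_that("rank_select orders by score with deterministic id tie-breaks", {
  cand <- data.frame(id = letters[1:5], category = "CTCF",
                     score = c(9, 7, 5, 3, 1), stringsAsFactors = FALSE)
  expect_equal(rank_select(cand, "CTCF", 2, from_top = TRUE)$id, c("a", "b"))
  expect_equal(rank_select(cand, "CTCF", 2, from_top = FALSE)$id, c("e", "d"))
  expect_error(rank_select(cand, "CTCF", 6), "category 'CTCF'")

  # ties broken lexicographically by id regardless of row order
  tied <- data.frame(id = c("z", "m", "a"), category = "CTCF", score = 5,
                     stringsAsFactors = FALSE)
  expect_equal(rank_select(tied, "CTCF", 2)$id, c("a", "m"))
  expect_equal(rank_select(tied[3:1, ], "CTCF", 2)$id, c("a", "m"))
})

test_that("top-k and bottom-k partition a scored pool disjointly", {
  set.seed(7)
  cand <- data.frame(id = sprintf("c%03d", 1:500), category = "CTCF",
                     score = runif(500), stringsAsFactors = FALSE)
  top <- rank_select(cand, "CTCF", 450, from_top = TRUE)
  bot <- rank_select(cand, "CTCF", 50, from_top = FALSE)
  expect_length(intersect(top$id, bot$id), 0)
  expect_setequal(c(top$id, bot$id), cand$id)
  # brute-force sort oracle
  ord <- cand[order(-cand$score, cand$id), ]
  expect_equal(top$id, ord$id[1:450])
  expect_equal(bot$id, rev(ord$id)[1:50])
})

test_that("LAD proximity uses boundary distances with strict cutoff", {
  lads <- data.frame(chrom = "chr1", start = 4000L, end = 90000L,
                     stringsAsFactors = FALSE)
  el <- data.frame(id = c("near", "wrongchr"), chrom = c("chr1", "chr2"),
                   start = 1000L, end = 1250L, stringsAsFactors = FALSE)
  res <- lad_proximity_filter(el, lads, 5000)
  expect_equal(res$near$id, "near")
  expect_equal(res$near$boundary_dist, 2750)   # gap to the LAD start
  expect_equal(res$far$id, "wrongchr")
  expect_true(is.na(res$far$boundary_dist))
  # element spanning a boundary is at distance zero
  span <- data.frame(id = "span", chrom = "chr1", start = 3900L, end = 4100L)
  expect_equal(lad_proximity_filter(span, lads, 5000)$near$boundary_dist, 0)
  # strict '<': exactly at the cutoff is far
  at <- data.frame(id = "at", chrom = "chr1", start = 95000L, end = 95100L)
  expect_equal(nrow(lad_proximity_filter(at, lads, 5000)$near), 0)
})

test_that("LAD proximity agrees with the all-pairs distance oracle", {
  set.seed(13)
  lads <- data.frame(chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
                     start = sort(sample(seq(1e5, 9e6, by = 2e5), 10)),
                     stringsAsFactors = FALSE)
  lads$end <- lads$start + sample(50000:150000, 10)
  el <- data.frame(id = sprintf("e%03d", 1:200),
                   chrom = sample(c("chr1", "chr2", "chr3"), 200, replace = TRUE),
                   start = sample(1:9500000, 200), stringsAsFactors = FALSE)
  el$end <- el$start + 250L
  res <- lad_proximity_filter(el, lads, 5000)
  for (i in seq_len(200)) {
    d <- naive_boundary_dist(el[i, ], lads)
    in_near <- el$id[i] %in% res$near$id
    expect_identical(in_near, !is.na(d) && d < 5000, label = el$id[i])
  }
  expect_equal(nrow(res$near) + nrow(res$far), 200)
  expect_length(intersect(res$near$id, res$far$id), 0)
})

test_that("random elements avoid excluded sites on both strands", {
  out <- generate_random_elements(50, 250, seed = 1)
  expect_equal(nrow(out), 50)
  expect_true(all(nchar(out$sequence) == 250))
  expect_false(any(grepl("CGTCTC", out$sequence, fixed = TRUE)))
  expect_false(any(grepl("GAGACG", out$sequence, fixed = TRUE)))
  expect_equal(nrow(generate_random_elements(0, 250, seed = 1)), 0)
  # reproducibility
  expect_identical(out$sequence,
                   generate_random_elements(50, 250, seed = 1)$sequence)
  # impossible exclusion triggers the rejection cap
  expect_error(generate_random_elements(1, 10, excluded_sites = c("A", "C", "G", "T"),
                                        seed = 1, max_attempts = 50),
               "rejection cap")
})

test_that("random base composition is uniform within binomial error", {
  out <- generate_random_elements(1000, 30, seed = 7,
                                  excluded_sites = character(0))
  mat <- do.call(rbind, strsplit(out$sequence, "", fixed = TRUE))
  for (pos in c(1, 15, 30)) {
    freq <- table(factor(mat[, pos], levels = c("A", "C", "G", "T"))) / 1000
    sigma <- sqrt(0.25 * 0.75 / 1000)
    expect_true(all(abs(freq - 0.25) < 3 * sigma),
                label = sprintf("position %d composition", pos))
  }
})

test_that("length adjustment is a centered trim keeping the 5' extra base", {
  s260 <- paste(rep(c("A", "C"), 130), collapse = "")
  expect_identical(adjust_length(s260, 250), substr(s260, 6, 255))
  s250 <- strrep("ACGTG", 50)
  expect_identical(adjust_length(s250, 250), s250)
  s251 <- paste0(s250, "G")
  expect_identical(adjust_length(s251, 250), substr(s251, 1, 250))
  expect_error(adjust_length("ACGT", 250), "shorter than core length")
})

test_that("oligo assembly concatenates flanks around the core", {
  core <- strrep("ACGTG", 50)
  oligo <- assemble_oligo(core, strrep("G", 25), strrep("C", 25))
  expect_equal(nchar(oligo), 300)
  expect_identical(assemble_oligo(core, "", "", flank_total = 0), core)
  expect_error(assemble_oligo(core, "A", "C"), "flank_total")
  # core always sits at offset len(left_flank)
  set.seed(3)
  for (i in 1:100) {
    lf <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    rf <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    o <- assemble_oligo(core, lf, rf)
    expect_identical(substr(o, 26, 275), core)
  }
})

test_that("coverage arithmetic is exact and linear", {
  expect_equal(fold_coverage(472000, 1000), 472)
  expect_equal(fold_coverage(842000, 1000), 842)
  expect_equal(fold_coverage(0, 1000), 0)
  expect_error(fold_coverage(10, 0), "positive")
  expect_equal(expected_clones(24, 600000, 0.004), 57600)
  expect_equal(expected_clones(0, 600000, 0.004), 0)
  expect_error(expected_clones(1, 1, 1.5), "\\[0, 1\\]")
  # linearity in count arguments
  expect_equal(fold_coverage(3 * 472000, 1000), 3 * 472)
  expect_equal(expected_clones(48, 600000, 0.004),
               2 * expected_clones(24, 600000, 0.004))
})

test_that("assembled library honors quotas, lengths and exclusion rules", {
  pool <- make_candidate_pool()
  lib <- build_library(pool$candidates, pool$lads, seed = 5)
  expect_equal(nrow(lib), 1000)
  expect_equal(as.vector(table(lib$category_label)[names(DEFAULT_QUOTAS)]),
               unname(DEFAULT_QUOTAS))
  expect_true(all(nchar(lib$core_sequence) == 250))
  expect_true(all(nchar(lib$oligo_sequence) == 300))
  expect_false(any(duplicated(lib$id)))
  for (m in c("CGTCTC", "GAGACG"))
    expect_false(any(grepl(m, lib$oligo_sequence, fixed = TRUE)))
  expect_true(all(mapply(grepl, lib$core_sequence, lib$oligo_sequence,
                         MoreArgs = list(fixed = TRUE))))
  # the CTCF-High set is the top of the affinity ranking (among clean oligos)
  hi <- lib$id[lib$category_label == "CTCF-High"]
  ct <- pool$candidates[pool$candidates$category == "CTCF", ]
  expect_true(min(ct$score[ct$id %in% hi]) >
                max(ct$score[!ct$id %in% hi &
                               ct$id %in% lib$id[lib$category_label == "CTCF-Low"]]))
  # LAD-bound MIRs really are near a boundary
  mirb <- lib[lib$category_label == "MIR-LAD_bound", ]
  near_ids <- lad_proximity_filter(
    pool$candidates[pool$candidates$category == "MIR", ],
    pool$lads, 5000)$near$id
  expect_true(all(mirb$id %in% near_ids))
})

test_that("library IO round-trips through FASTA and manifest", {
  lib <- make_test_library(n = 8)
  lib$chrom <- NA_character_; lib$start <- NA_integer_
  lib$end <- NA_integer_; lib$strand <- NA_character_
  dir <- withr::local_tempdir()
  manifest <- write_library(lib, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "library_core.fasta"))
  expect_identical(as.character(fa), setNames(lib$core_sequence, lib$id))
  oligo <- Biostrings::readDNAStringSet(file.path(dir, "library_oligo.fasta"))
  expect_identical(unname(as.character(oligo)), lib$oligo_sequence)
  back <- read.table(file.path(dir, "library_manifest.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$id, lib$id)
  expect_equal(back$oligo_length, rep(300, 8))
})
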