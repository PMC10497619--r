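scheme <- scoring_scheme()

test_that("linker and quality trimming follow the documented conventions", {
  linker <- "ACACGACGCTCTTCCGATCT"
  insert <- strrep("ACGTG", 20)
  clean <- data.frame(id = "r1", sequence = paste0(linker, insert),
                      quality = phred_to_string(rep(38, 120)),
                      stringsAsFactors = FALSE)
  out <- trim_reads(clean, linker)
  expect_identical(out$sequence, insert)
  expect_equal(out$trimmed_length, 100)

  # partial linker (>= 8 bp suffix overlap) is also removed
  part <- data.frame(id = "r2", sequence = paste0(substr(linker, 11, 20), insert),
                     quality = phred_to_string(rep(38, 110)),
                     stringsAsFactors = FALSE)
  expect_identical(trim_reads(part, linker)$sequence, insert)
  # a 7 bp overlap is below the floor and kept
  short <- data.frame(id = "r3", sequence = paste0(substr(linker, 14, 20), insert),
                      quality = phred_to_string(rep(38, 107)),
                      stringsAsFactors = FALSE)
  expect_equal(trim_reads(short, linker)$trimmed_length, 107)

  # uniformly bad quality empties the read
  bad <- data.frame(id = "r4", sequence = insert,
                    quality = phred_to_string(rep(10, 100)),
                    stringsAsFactors = FALSE)
  out_bad <- trim_reads(bad, "")
  expect_equal(out_bad$trimmed_length, 0)
  expect_equal(unname(attr(out_bad, "counters")["emptied"]), 1)

  # the worked mixed-quality example: 50 high + 10 low bases keeps 50..53
  mixed <- data.frame(id = "r5", sequence = strrep("A", 60),
                      quality = phred_to_string(c(rep(38, 50), rep(20, 10))),
                      stringsAsFactors = FALSE)
  kept <- trim_reads(mixed, "")$trimmed_length
  expect_gte(kept, 50); expect_lte(kept, 53)
  expect_equal(kept, naive_trim_length(c(rep(38, 50), rep(20, 10))))
})

test_that("quality trimming equals the position-by-position scan oracle", {
  set.seed(31)
  for (i in 1:50) {
    q <- rand_phred(sample(5:80, 1))
    reads <- data.frame(id = "r", sequence = strrep("A", length(q)),
                        quality = phred_to_string(q), stringsAsFactors = FALSE)
    expect_equal(trim_reads(reads, "")$trimmed_length, naive_trim_length(q),
                 label = paste("phred case", i))
  }
})

test_that("alignment recovers identity, strand symmetry and exact scores", {
  lib <- make_test_library(n = 4)
  core <- lib$core_sequence[2]
  rec <- align_read(core, lib, scheme)
  top <- rec[which.max(rec$score), ]
  expect_equal(top$element_id, lib$id[2])
  expect_equal(top$score, 250 * 2)
  expect_equal(top$mismatches, 0)
  expect_equal(top$gaps, 0)
  expect_equal(top$mapped_length, 250)
  expect_equal(top$strand, "+")

  rc <- align_read(revcomp_chr_test(core), lib, scheme)
  top_rc <- rc[which.max(rc$score), ]
  expect_equal(top_rc$score, top$score)
  expect_equal(top_rc$element_id, lib$id[2])
  expect_equal(top_rc$strand, "-")
})

test_that("alignment agrees with the brute-force DP oracle on random instances", {
  set.seed(17)
  n_checked <- 0
  for (i in 1:220) {
    qlen <- sample(10:50, 1); slen <- sample(30:100, 1)
    q <- rand_dna(1, qlen); s <- rand_dna(1, slen)
    if (runif(1) < 0.5) {
      # plant a mutated copy so many instances have real alignments
      pos <- sample(slen - qlen + 1, 1)
      mutated <- strsplit(q, "")[[1]]
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        at <- sample(qlen, nmut)
        mutated[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      substr(s, pos, pos + qlen - 1) <- paste(mutated, collapse = "")
    }
    got <- barrierscreen:::.sw_align_cpp(q, s, 2L, -3L, -5L, -2L)
    want <- sw_oracle(q, s)
    expect_equal(got[["score"]], want$score, label = paste("score case", i))
    if (want$score > 0) {
      n_checked <- n_checked + 1
      expect_equal(got[["mismatches"]], want$mismatches,
                   label = paste("mismatches case", i))
      expect_equal(got[["gaps"]], want$gaps, label = paste("gaps case", i))
      expect_equal(got[["s_end"]] - got[["s_start"]] + 1,
                   want$s_end - want$s_start + 1,
                   label = paste("mapped length case", i))
    }
  }
  expect_gte(n_checked, 100)
})

test_that("alignment scores match Biostrings pairwiseAlignment", {
  set.seed(23)
  for (i in 1:40) {
    q <- rand_dna(1, sample(15:40, 1)); s <- rand_dna(1, sample(40:90, 1))
    pos <- sample(nchar(s) - nchar(q) + 1, 1)
    qq <- strsplit(q, "")[[1]]
    qq[sample(nchar(q), 2)] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    substr(s, pos, pos + nchar(q) - 1) <- paste(qq, collapse = "")
    got <- barrierscreen:::.sw_align_cpp(q, s, 2L, -3L, -5L, -2L)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    pw <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    expect_equal(got[["score"]], Biostrings::score(pw),
                 label = paste("biostrings case", i))
  }
})

test_that("deduplication keeps the best record with deterministic tie-breaks", {
  rec <- function(read, el, score, ev = exp(-score)) {
    data.frame(read_id = read, element_id = el, strand = "+", score = score,
               mismatches = 0L, gaps = 0L, mapped_length = 100L,
               read_length = 100L, evalue_proxy = ev, stringsAsFactors = FALSE)
  }
  x <- rbind(rec("r1", "e1", 480), rec("r1", "e2", 300), rec("r2", "e9", 50))
  d <- deduplicate(x)
  expect_equal(nrow(d), 2)
  expect_equal(d$element_id[d$read_id == "r1"], "e1")
  expect_identical(deduplicate(d), d)        # idempotent
  expect_false(any(duplicated(d$read_id)))
  # full tie: lexicographically smallest element id wins
  tie <- rbind(rec("r3", "seq801", 100, 1e-5), rec("r3", "seq268", 100, 1e-5))
  expect_equal(deduplicate(tie)$element_id, "seq268")
  # e-value breaks score ties before the id does
  ev_tie <- rbind(rec("r4", "zzz", 100, 1e-9), rec("r4", "aaa", 100, 1e-5))
  expect_equal(deduplicate(ev_tie)$element_id, "zzz")
})

test_that("post-alignment filters enforce the exact boundary semantics", {
  lib <- make_test_library(n = 3)   # 300 bp oligos
  base <- data.frame(read_id = "r", element_id = lib$id[1], strand = "+",
                     score = 400L, mismatches = 0L, gaps = 0L,
                     mapped_length = 250L, read_length = 250L,
                     evalue_proxy = 0, stringsAsFactors = FALSE)
  vary <- function(...) { x <- base; x[names(list(...))] <- list(...); x }
  cases <- rbind(
    cbind(vary(mismatches = 3L), keep = TRUE),
    cbind(vary(mismatches = 4L), keep = FALSE),
    cbind(vary(gaps = 3L), keep = TRUE),
    cbind(vary(gaps = 4L), keep = FALSE),
    # max_possible = min(250, 300) = 250; slack 10
    cbind(vary(mapped_length = 240L), keep = TRUE),
    cbind(vary(mapped_length = 239L), keep = FALSE),
    cbind(vary(read_length = 300L, mapped_length = 290L), keep = TRUE),
    cbind(vary(read_length = 300L, mapped_length = 289L), keep = FALSE))
  for (i in seq_len(nrow(cases))) {
    out <- apply_filters(cases[i, names(base)], lib)
    expect_equal(nrow(out) == 1, cases$keep[i], label = paste("filter case", i))
  }
  expect_error(apply_filters(vary(element_id = "nope"), lib), "absent")
})

test_that("filtering is a monotone subset operation", {
  set.seed(41)
  lib <- make_test_library(n = 5)
  recs <- data.frame(read_id = sprintf("r%03d", 1:120),
                     element_id = sample(lib$id, 120, replace = TRUE),
                     strand = "+", score = 100L,
                     mismatches = sample(0:6, 120, replace = TRUE),
                     gaps = sample(0:6, 120, replace = TRUE),
                     mapped_length = sample(220:250, 120, replace = TRUE),
                     read_length = 250L, evalue_proxy = 0,
                     stringsAsFactors = FALSE)
  strict <- apply_filters(recs, lib)
  expect_true(all(strict$read_id %in% recs$read_id))
  for (relax in list(c(4, 3, 10), c(3, 4, 10), c(3, 3, 15))) {
    loose <- apply_filters(recs, lib, relax[1], relax[2], relax[3])
    expect_true(all(strict$read_id %in% loose$read_id),
                label = paste(relax, collapse = "/"))
  }
  rej <- attr(strict, "rejections")
  expect_equal(unname(rej["mismatches"]), sum(recs$mismatches > 3))
})

test_that("counting covers the whole library including zeros", {
  lib <- make_test_library(n = 3)
  recs <- data.frame(read_id = sprintf("r%d", 1:10), element_id = lib$id[1],
                     stringsAsFactors = FALSE)
  expect_equal(unname(count_elements(recs, lib)), c(10L, 0L, 0L))
  expect_equal(unname(count_elements(recs[0, ], lib)), c(0L, 0L, 0L))
})

test_that("noiseless pipeline recovers simulated counts exactly", {
  lib <- make_test_library(n = 30)
  cfg <- sequencing_config(pcr_noise_sigma = 0)
  w <- setNames(runif(30, 0.3, 1.7), lib$id)
  set.seed(51)
  rp <- reads_from_population(w, lib, 5000, cfg, seed = 51)
  m <- map_reads(rp$reads, lib, linker = cfg$linker)
  expect_identical(unname(m$counts), unname(rp$true_counts))
  expect_equal(unname(m$log["surviving_reads"]), 5000)
})

test_that("error-bearing reads still map to their source elements", {
  lib <- make_test_library(n = 10)
  cfg <- sequencing_config(read_length = 120, substitution_rate = 0.004,
                           insertion_rate = 0.001, deletion_rate = 0.001)
  rp <- reads_from_population(setNames(rep(1, 10), lib$id), lib, 400, cfg,
                              seed = 61)
  m <- map_reads(rp$reads, lib, linker = cfg$linker)
  # the <= 3 mismatch / <= 3 gap / length filters may drop a few reads but
  # surviving assignments must be correct
  assigned <- m$records$element_id
  truth <- rp$reads$element_id[match(m$records$read_id, rp$reads$id)]
  expect_gt(nrow(m$records), 350)
  expect_identical(assigned, truth)
  expect_equal(sum(m$counts), nrow(m$records))
})
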