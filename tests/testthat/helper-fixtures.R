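# Fixtures are generated in code; no data files.

rand_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Small element library with assembled oligos (25 bp flanks each side).
make_test_library <- function(n = 20, core_len = 250, seed = 101) {
  cand <- generate_random_elements(n, core_len, seed = seed)
  core <- cand$sequence
  data.frame(id = sprintf("el%03d", seq_len(n)),
             category_label = "MIR-random",
             core_sequence = core,
             oligo_sequence = assemble_oligo(core, strrep("A", 25), strrep("T", 25)),
             stringsAsFactors = FALSE)
}

# Candidate pool rich enough for the full library quotas.  Sequences are
# excluded-site free at generation (the oligo-level re-screen still runs).
make_candidate_pool <- function(seed = 202) {
  lads <- data.frame(chrom = c("chr1", "chr2"),
                     start = c(1000000L, 500000L),
                     end = c(2000000L, 800000L), stringsAsFactors = FALSE)
  ctcf <- generate_random_elements(520, 250, seed = seed)
  ctcf$id <- sprintf("ctcf%03d", 1:520)
  ctcf$category <- "CTCF"
  set.seed(seed + 1)
  ctcf$score <- round(runif(520, 1, 100), 3)
  mir <- generate_random_elements(520, 250, seed = seed + 2)
  mir$id <- sprintf("mir%03d", 1:520)
  mir$category <- "MIR"
  set.seed(seed + 3)
  # 45 MIRs within 5 kb of a LAD boundary, the rest well away from any.
  near_pos <- sample(c(1000000L, 2000000L), 45, replace = TRUE) +
    sample(-4000:4000, 45, replace = TRUE)
  far_pos <- sample(3000000:9000000, 475)
  mir$chrom <- "chr1"
  mir$start <- c(near_pos, far_pos)
  mir$end <- mir$start + 250L
  mir$strand <- "+"
  list(candidates = rbind(ctcf, mir), lads = lads)
}

# Phenotype table for the headline recovery scenario: 50 strong barriers,
# 50 null (random-control-like) elements, 900 partially protective
# background elements.
make_screen_phenotypes <- function(ids, seed = 303) {
  stopifnot(length(ids) == 1000)
  set.seed(seed)
  b <- c(runif(50, 0.9, 1), rep(0, 50), runif(900, 0.5, 0.9))
  element_phenotypes(ids, b)
}
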