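## Sequence features of library elements: GC content, degenerate IUPAC
## motif counts (USF CANNTG, VEZF1 GGGG), position frequency matrices and
## information-content logos, and feature comparisons across element sets.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' GC content of DNA sequences
#'
#' Fraction `(G + C) / (A + C + G + T)`; ambiguous bases (e.g. N) are
#' excluded from both numerator and denominator.  Sequences with no
#' unambiguous base yield `NA`.
#'
#' @param sequences Character vector of DNA sequences.
#' @param as_percent Report percent instead of a fraction?
#' @return Numeric vector of GC fractions (or percentages).
#' @export
gc_content <- function(sequences, as_percent = FALSE) {
  if (any(!nzchar(sequences))) stop_input("empty sequence")
  dna <- Biostrings::DNAStringSet(sequences)
  gc <- Biostrings::letterFrequency(dna, "GC")[, 1]
  acgt <- Biostrings::letterFrequency(dna, "ACGT")[, 1]
  out <- ifelse(acgt == 0, NA_real_, gc / acgt)
  if (as_percent) out <- 100 * out
  unname(out)
}

#' Count occurrences of a degenerate IUPAC motif
#'
#' Counts overlapping start positions at which the pattern matches
#' (IUPAC codes in the pattern are expanded; sequence letters are taken
#' literally).  With `both_strands = TRUE`, matches of the
#' reverse-complement pattern are added, except for self-reverse-
#' complementary patterns (e.g. CANNTG) where that would double-count the
#' same sites.
#'
#' @param sequences Character vector of DNA sequences.
#' @param pattern IUPAC motif string (e.g. `"CANNTG"`, `"GGGG"`).
#' @param both_strands Also count the reverse-complement pattern?
#' @return Integer vector of motif counts per sequence.
#' @export
count_motif <- function(sequences, pattern, both_strands = FALSE) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern) ||
      !all(strsplit(pattern, "", fixed = TRUE)[[1]] %in% IUPAC_LETTERS))
    stop_input("pattern must be a non-empty IUPAC DNA string")
  pat <- Biostrings::DNAString(pattern)
  n <- vapply(sequences, function(s)
    Biostrings::countPattern(pat, Biostrings::DNAString(s),
                             fixed = "subject"),
    integer(1), USE.NAMES = FALSE)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    if (as.character(rc) != pattern) {   # skip palindromic double count
      n <- n + vapply(sequences, function(s)
        Biostrings::countPattern(rc, Biostrings::DNAString(s),
                                 fixed = "subject"),
        integer(1), USE.NAMES = FALSE)
    }
  }
  n
}

#' Build a position frequency matrix from equal-length sequences
#'
#' Column-wise base frequencies over A/C/G/T; ambiguous IUPAC letters are
#' distributed fractionally among their compatible bases.
#'
#' @param sequences Character vector of equal-length DNA sequences.
#' @return List of class `pfm` with `freqs` (4 x L matrix, columns sum to
#'   1), `length` and `n_sequences`.
#' @export
build_pfm <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  if (length(unique(nchar(sequences))) != 1L)
    stop_input("sequences must all have the same length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sequences))
  bases <- c("A", "C", "G", "T")
  freqs <- matrix(0, 4, ncol(cm), dimnames = list(bases, NULL))
  map <- Biostrings::IUPAC_CODE_MAP
  for (code in rownames(cm)) {
    if (!code %in% names(map)) next   # skips gap rows, which must be absent
    targets <- strsplit(map[[code]], "", fixed = TRUE)[[1]]
    for (b in targets)
      freqs[b, ] <- freqs[b, ] + cm[code, ] / length(targets)
  }
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  structure(list(freqs = freqs, length = ncol(freqs),
                 n_sequences = length(sequences)), class = "pfm")
}

#' Per-position information content of a PFM (bits)
#'
#' `IC = 2 + sum_b f_b log2 f_b` with `0 log 0 = 0`; no small-sample
#' correction.  Ranges from 0 (uniform) to 2 bits (single base).
#'
#' @param pfm A [build_pfm()] result (or a bare 4 x L frequency matrix).
#' @return Numeric vector of per-position bits.
#' @export
information_content <- function(pfm) {
  f <- if (inherits(pfm, "pfm")) pfm$freqs else pfm
  apply(f, 2, function(col) {
    nz <- col > 0
    2 + sum(col[nz] * log2(col[nz]))
  })
}

#' Compare a sequence feature across element sets
#'
#' Pairwise two-tailed unpaired (Welch) t-tests between all sets plus
#' box-plot summary statistics (min, quartiles by linear interpolation,
#' median, mean, max) per set.
#'
#' @param feature_values Named list of numeric vectors (one per element
#'   set), each of length >= 2.
#' @param top_n Optional cap: restrict every set to its `top_n` largest
#'   values before testing (used e.g. to focus on the most-enriched
#'   elements of a population).
#' @return List with `p_values` (symmetric matrix) and `summary` (data
#'   frame of per-set statistics).
#' @export
compare_feature_across_sets <- function(feature_values, top_n = NULL) {
  stopifnot(is.list(feature_values), length(feature_values) >= 2)
  if (!is.null(top_n)) {
    feature_values <- lapply(feature_values, function(v)
      head(sort(v, decreasing = TRUE), top_n))
  }
  if (any(vapply(feature_values, length, integer(1)) < 2))
    stop_input("each set needs at least 2 values")
  labs <- names(feature_values)
  k <- length(labs)
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      p[i, j] <- p[j, i] <-
        t_test_two_tailed(feature_values[[i]], feature_values[[j]])$p_value
    }
  }
  summ <- do.call(rbind, lapply(labs, function(l) {
    v <- feature_values[[l]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(set = l, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], max = max(v), mean = mean(v),
               stringsAsFactors = FALSE)
  }))
  list(p_values = p, summary = summ)
}
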