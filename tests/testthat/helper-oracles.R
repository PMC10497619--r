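# Independent brute-force oracles, implemented separately from the package
# code paths they check.

# Plain-R affine-gap local alignment (Gotoh), full matrices, with the same
# documented conventions as the package aligner: gap run of length L costs
# gap_open + L * gap_extend; end cell is the first maximal cell in
# query-major scan order; traceback prefers diagonal > gap-in-query
# (subject consumed) > gap-in-subject.
sw_oracle <- function(query, subject, match = 2, mismatch = -3,
                      gap_open = -5, gap_extend = -2) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(s)
  NEG <- -1e9; go <- gap_open + gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + go, E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + go, F[i, j + 1] + gap_extend)
      sc <- if (q[i] == s[j]) match else mismatch
      h <- max(0, H[i, j] + sc, E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0)
    return(list(score = 0, mismatches = 0, gaps = 0,
                q_start = 0, q_end = 0, s_start = 0, s_end = 0))
  i <- bi; j <- bj; state <- "H"
  mm <- 0; gaps <- 0; qs <- bi; ss <- bj
  while (i > 0 && j > 0) {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      sc <- if (q[i] == s[j]) match else mismatch
      if (h == H[i, j] + sc) {
        if (sc == mismatch) mm <- mm + 1
        qs <- i; ss <- j; i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) state <- "E" else state <- "F"
    } else if (state == "E") {
      gaps <- gaps + 1; ss <- j
      if (E[i + 1, j + 1] == H[i + 1, j] + go) state <- "H"
      j <- j - 1
    } else {
      gaps <- gaps + 1; qs <- i
      if (F[i + 1, j + 1] == H[i, j + 1] + go) state <- "H"
      i <- i - 1
    }
  }
  list(score = best, mismatches = mm, gaps = gaps,
       q_start = qs, q_end = bi, s_start = ss, s_end = bj)
}

# Closed-form Welch two-tailed p-value.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# Closed-form pooled-variance (Student) two-tailed p-value.
pooled_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), na + nb - 2)
}

# Position-by-position degenerate motif scan.
.iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
            S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
            H = "ACT", V = "ACG", N = "ACGT")
naive_motif_count <- function(sequence, pattern) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(p); n <- length(s)
  if (n < L) return(0L)
  cnt <- 0L
  for (i in seq_len(n - L + 1)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!grepl(s[i + j - 1], .iupac[[p[j]]], fixed = TRUE)) {
        ok <- FALSE
        break
      }
    }
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

# Position-by-position scan of the trailing-window quality trim rule.
naive_trim_length <- function(phred, min_phred = 25.75, window = 4) {
  for (i in seq_along(phred)) {
    w <- phred[max(1, i - window + 1):i]
    if (mean(w) <= min_phred) return(i - 1L)
  }
  length(phred)
}

# Exhaustive element-to-boundary distance scan.
naive_boundary_dist <- function(el, lads) {
  ds <- c()
  for (k in seq_len(nrow(lads))) {
    if (lads$chrom[k] != el$chrom) next
    for (b in c(lads$start[k], lads$end[k])) {
      d <- if (b < el$start) el$start - b
      else if (b > el$end) b - el$end
      else 0
      ds <- c(ds, d)
    }
  }
  if (length(ds) == 0) NA_real_ else min(ds)
}

revcomp_chr_test <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

rand_phred <- function(len, lo = 2, hi = 40) {
  sample(lo:hi, len, replace = TRUE)
}

phred_to_string <- function(q) rawToChar(as.raw(q + 33L))
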