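## Read mapping: trimming, local alignment against the element library,
## best-hit deduplication and the post-alignment filters that gate which
## alignments are counted.

#' Alignment scoring scheme
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap open -5, gap extend -2.
#' A gap run of length L scores `gap_open + L * gap_extend`.
#'
#' @param match Positive match score.
#' @param mismatch,gap_open,gap_extend Non-positive penalties.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L,
                           gap_open = -5L, gap_extend = -2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Read a FASTQ file into a reads data frame
#'
#' @param path FASTQ path.
#' @return Data frame with `id`, `sequence`, `quality` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  # the id line is kept separately; dropping XStringSet metadata is expected
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

## Decode Phred+33 quality strings into a list of integer vectors.
decode_phred <- function(quality) {
  lapply(quality, function(q) as.integer(charToRaw(q)) - 33L)
}

## Longest t >= min_overlap with suffix(linker, t) == prefix(read, t).
linker_overlap <- function(sequence, linker, min_overlap) {
  L <- nchar(linker)
  if (L - 1L < min_overlap) return(0L)
  for (t in seq(L - 1L, min_overlap)) {
    if (substr(linker, L - t + 1L, L) == substr(sequence, 1L, t)) return(t)
  }
  0L
}

#' Trim linker and low-quality tails from reads
#'
#' The linker prefix is removed on an exact match at the read start, or
#' failing that on the longest suffix-of-linker / prefix-of-read overlap of
#' at least `min_overlap` bases.  The 3' end is then cut immediately before
#' the first base at which the trailing `window`-base mean Phred (window
#' clipped at the read start) drops to `<= min_phred`.  Reads may come back
#' empty; they are counted, and dropped by [map_reads()].
#'
#' @param reads Data frame with `id`, `sequence`, `quality`.
#' @param linker Linker sequence (set `""` to skip linker removal).
#' @param min_phred Quality threshold (windows with mean `<=` this end the
#'   read).
#' @param window Sliding-window width in bases.
#' @param min_overlap Minimum linker/read overlap for partial linker removal.
#' @return The input data frame with trimmed `sequence`/`quality` and a
#'   `trimmed_length` column; attribute `counters` records how many reads
#'   had the linker removed and how many were emptied.
#' @export
trim_reads <- function(reads, linker = "", min_phred = 25.75,
                       window = 4L, min_overlap = 8L) {
  stopifnot(min_phred >= 0)
  seqs <- reads$sequence
  quals <- reads$quality
  n_linker <- 0L
  if (nzchar(linker)) {
    L <- nchar(linker)
    exact <- startsWith(seqs, linker)
    cut <- integer(length(seqs))
    cut[exact] <- L
    for (i in which(!exact)) {
      cut[i] <- linker_overlap(seqs[i], linker, min_overlap)
    }
    n_linker <- sum(cut > 0L)
    seqs <- substr(seqs, cut + 1L, nchar(seqs))
    quals <- substr(quals, cut + 1L, nchar(quals))
  }
  qlist <- decode_phred(quals)
  keep_len <- vapply(qlist, function(q) {
    n <- length(q)
    if (n == 0L) return(0L)
    cs <- cumsum(q)
    i <- seq_len(n)
    lo <- pmax(0L, i - window)
    means <- (cs - c(0, cs)[lo + 1L]) / (i - lo)
    bad <- which(means <= min_phred)
    if (length(bad) == 0L) n else bad[1L] - 1L
  }, integer(1))
  reads$sequence <- substr(seqs, 1L, keep_len)
  reads$quality <- substr(quals, 1L, keep_len)
  reads$trimmed_length <- keep_len
  attr(reads, "counters") <- c(linker_trimmed = n_linker,
                               emptied = sum(keep_len == 0L))
  reads
}

## evalue-like ranking proxy (lower = better): exp(-score) scaled by the
## search-space size.  Not a calibrated E-value; used only to order hits.
evalue_proxy <- function(score, read_bp, library_bp) {
  exp(-score) * (library_bp * read_bp)
}

#' Locally align one read against the element library
#'
#' Smith-Waterman with affine gaps against each element's oligo sequence and
#' its reverse complement; records scoring at or above `score_floor` are
#' emitted, with mismatches, gap columns and mapped length taken from the
#' traceback.
#'
#' @param sequence Read sequence (character scalar).
#' @param library Library data frame (`id`, `oligo_sequence`).
#' @param scheme A [scoring_scheme()].
#' @param read_id Identifier stored in the records.
#' @param score_floor Minimum reported score; the default is the score of a
#'   20 bp exact match under `scheme`.
#' @param candidates Optional subset of library row indices to align
#'   against (used by the seeded [map_reads()] path).
#' @return Data frame of alignment records: `read_id`, `element_id`,
#'   `strand`, `score`, `mismatches`, `gaps`, `mapped_length`,
#'   `read_length`, `evalue_proxy`.
#' @export
align_read <- function(sequence, library, scheme = scoring_scheme(),
                       read_id = "read", score_floor = 20L * scheme$match,
                       candidates = NULL) {
  stopifnot(nzchar(sequence))
  if (is.null(candidates)) candidates <- seq_len(nrow(library))
  library_bp <- sum(nchar(library$oligo_sequence))
  recs <- vector("list", 2L * length(candidates))
  k <- 0L
  for (i in candidates) {
    oligo <- library$oligo_sequence[i]
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") oligo else revcomp_chr(oligo)
      a <- .sw_align_cpp(sequence, subj, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
      if (a[["score"]] >= score_floor) {
        k <- k + 1L
        recs[[k]] <- data.frame(
          read_id = read_id, element_id = library$id[i], strand = strand,
          score = a[["score"]], mismatches = a[["mismatches"]],
          gaps = a[["gaps"]],
          mapped_length = a[["s_end"]] - a[["s_start"]] + 1L,
          read_length = nchar(sequence),
          evalue_proxy = evalue_proxy(a[["score"]], nchar(sequence), library_bp),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty_records())
  do.call(rbind, recs[seq_len(k)])
}

empty_records <- function() {
  data.frame(read_id = character(), element_id = character(),
             strand = character(), score = integer(), mismatches = integer(),
             gaps = integer(), mapped_length = integer(),
             read_length = integer(), evalue_proxy = numeric(),
             stringsAsFactors = FALSE)
}

#' Build a k-mer seed index over library oligos
#'
#' Hashes every k-mer of each oligo and of its reverse complement to the
#' originating element, for candidate prefiltering in [map_reads()].
#' Seeds occurring in more than `max_element_hits` elements are masked:
#' such k-mers (typically from the shared cloning flanks) carry no
#' element-discriminating information and would make every read a candidate
#' for the whole library.
#'
#' @param library Library data frame.
#' @param k Seed length.
#' @param max_element_hits Mask k-mers hitting more than this many distinct
#'   elements.
#' @return A list of class `kmer_index`.
#' @export
kmer_index <- function(library, k = 16L, max_element_hits = 10L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(seq, key) {
    n <- nchar(seq)
    if (n < k) return()
    starts <- seq_len(n - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    for (km in unique(kmers)) {
      env[[km]] <- c(env[[km]], key)
    }
  }
  for (i in seq_len(nrow(library))) {
    add(library$oligo_sequence[i], i)
    add(revcomp_chr(library$oligo_sequence[i]), -i)
  }
  for (km in ls(env)) {
    if (length(unique(abs(env[[km]]))) > max_element_hits) rm(list = km, envir = env)
  }
  structure(list(env = env, k = k), class = "kmer_index")
}

## Candidate library rows for a read: union of index hits over seeds
## sampled every `stride` bases.  Negative keys mark reverse-strand hits;
## candidates are returned as row indices (strand handled by align_read).
seed_candidates <- function(sequence, index, stride = 8L) {
  k <- index$k
  n <- nchar(sequence)
  if (n < k) return(integer(0))
  starts <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
  kmers <- unique(substring(sequence, starts, starts + k - 1L))
  hits <- unlist(mget(kmers, envir = index$env, ifnotfound = list(NULL)),
                 use.names = FALSE)
  unique(abs(hits))
}

#' Keep the single best alignment per read
#'
#' One record per `read_id`: maximal score, ties broken by lower
#' `evalue_proxy`, then lexicographically smallest `element_id` (so
#' deduplication is deterministic and idempotent).
#'
#' @param records Alignment record data frame.
#' @return Deduplicated records.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$read_id, -records$score, records$evalue_proxy,
               records$element_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  records[!duplicated(records$read_id), , drop = FALSE]
}

#' Apply the post-alignment filters
#'
#' Keeps records with `mismatches <= max_mismatches`, `gaps <= max_gaps`
#' and `mapped_length >= max_possible - length_slack`, where `max_possible`
#' is the smaller of the trimmed read length and the element oligo length.
#'
#' @param records Alignment record data frame (with `read_length`).
#' @param library Library data frame; every record's `element_id` must
#'   exist in it.
#' @param max_mismatches,max_gaps,length_slack Filter thresholds.
#' @return Surviving records; attribute `rejections` counts removals per
#'   rule (a record failing several rules is counted under each).
#' @export
apply_filters <- function(records, library, max_mismatches = 3L,
                          max_gaps = 3L, length_slack = 10L) {
  idx <- match(records$element_id, library$id)
  if (anyNA(idx)) stop_input("records reference elements absent from the library")
  oligo_len <- nchar(library$oligo_sequence)[idx]
  max_possible <- pmin(records$read_length, oligo_len)
  ok_mm <- records$mismatches <= max_mismatches
  ok_gap <- records$gaps <= max_gaps
  ok_len <- records$mapped_length >= (max_possible - length_slack)
  out <- records[ok_mm & ok_gap & ok_len, , drop = FALSE]
  attr(out, "rejections") <- c(mismatches = sum(!ok_mm), gaps = sum(!ok_gap),
                               mapped_length = sum(!ok_len))
  out
}

#' Count reads per library element
#'
#' @param records Deduplicated, filtered alignment records.
#' @param library Library data frame.
#' @return Named integer vector over all library elements (0 for
#'   unobserved ones), in library order.
#' @export
count_elements <- function(records, library) {
  tab <- table(factor(records$element_id, levels = library$id))
  setNames(as.integer(tab), library$id)
}

#' Map a FASTQ sample to the element library
#'
#' Full pipeline: linker/quality trimming, seeded candidate lookup, local
#' alignment (with an exact-substring fast path whose records coincide with
#' the optimal alignment), best-hit deduplication, post-alignment filters
#' and per-element counting.
#'
#' @param reads Reads data frame (`id`, `sequence`, `quality`) or a FASTQ
#'   path.
#' @param library Library data frame.
#' @param linker Linker sequence to trim.
#' @param scheme A [scoring_scheme()].
#' @param min_phred,window,min_overlap Trimming parameters
#'   (see [trim_reads()]).
#' @param max_mismatches,max_gaps,length_slack Filter thresholds
#'   (see [apply_filters()]).
#' @param index Optional prebuilt [kmer_index()]; built on the fly
#'   otherwise.
#' @param score_floor Minimum alignment score (see [align_read()]).
#' @return List with `counts` (named vector over elements), `records`
#'   (surviving alignments) and `log` (read-level counters).
#' @export
map_reads <- function(reads, library, linker = "",
                      scheme = scoring_scheme(), min_phred = 25.75,
                      window = 4L, min_overlap = 8L, max_mismatches = 3L,
                      max_gaps = 3L, length_slack = 10L, index = NULL,
                      score_floor = 20L * scheme$match) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  trimmed <- trim_reads(reads, linker, min_phred, window, min_overlap)
  trim_counters <- attr(trimmed, "counters")
  keep <- trimmed$trimmed_length > 0L
  trimmed <- trimmed[keep, , drop = FALSE]
  if (is.null(index)) index <- kmer_index(library)
  oligo_len <- nchar(library$oligo_sequence)

  rc_oligo <- vapply(library$oligo_sequence, revcomp_chr, character(1),
                     USE.NAMES = FALSE)
  library_bp <- sum(oligo_len)

  # Exact fast path accumulates plain vectors (building one data frame per
  # read would dominate the runtime); only reads without a full-length
  # exact match fall through to Smith-Waterman.
  nr <- nrow(trimmed)
  ex_read <- vector("list", nr); ex_el <- vector("list", nr)
  ex_strand <- vector("list", nr); ex_len <- vector("list", nr)
  sw_recs <- vector("list", nr)
  n_unseeded <- 0L
  for (r in seq_len(nr)) {
    s <- trimmed$sequence[r]
    cand <- seed_candidates(s, index)
    if (length(cand) == 0L) { n_unseeded <- n_unseeded + 1L; next }
    # A full-length exact substring match attains the maximal possible
    # score, so no alignment against any candidate can beat it; collect
    # all exact hits (ties resolved in deduplicate()).
    hit_el <- character(0); hit_strand <- character(0)
    for (i in cand) {
      if (grepl(s, library$oligo_sequence[i], fixed = TRUE)) {
        hit_el <- c(hit_el, library$id[i]); hit_strand <- c(hit_strand, "+")
      } else if (grepl(s, rc_oligo[i], fixed = TRUE)) {
        hit_el <- c(hit_el, library$id[i]); hit_strand <- c(hit_strand, "-")
      }
    }
    if (length(hit_el) > 0L) {
      ex_read[[r]] <- rep.int(trimmed$id[r], length(hit_el))
      ex_el[[r]] <- hit_el
      ex_strand[[r]] <- hit_strand
      ex_len[[r]] <- rep.int(nchar(s), length(hit_el))
    } else {
      sw_recs[[r]] <-
        align_read(s, library, scheme, read_id = trimmed$id[r],
                   score_floor = score_floor, candidates = cand)
    }
  }
  sw_recs <- sw_recs[!vapply(sw_recs, is.null, logical(1))]
  len <- unlist(ex_len) %||% integer(0)
  exact_records <- data.frame(
    read_id = unlist(ex_read) %||% character(0),
    element_id = unlist(ex_el) %||% character(0),
    strand = unlist(ex_strand) %||% character(0),
    score = len * scheme$match, mismatches = rep.int(0L, length(len)),
    gaps = rep.int(0L, length(len)), mapped_length = len,
    read_length = len,
    evalue_proxy = evalue_proxy(len * scheme$match, len, library_bp),
    stringsAsFactors = FALSE)
  records <- do.call(rbind, c(list(empty_records(), exact_records), sw_recs))
  records <- deduplicate(records)
  filtered <- apply_filters(records, library, max_mismatches, max_gaps,
                            length_slack)
  list(counts = count_elements(filtered, library),
       records = filtered,
       log = c(input_reads = nrow(reads), trim_counters,
               unseeded = n_unseeded,
               aligned_reads = length(unique(records$read_id)),
               surviving_reads = nrow(filtered),
               attr(filtered, "rejections")))
}
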