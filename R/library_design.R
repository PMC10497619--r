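## Library design: composition, proximity and exclusion rules for the
## screening library, plus the coverage-planning arithmetic.
##
## Coordinate convention: 0-based, half-open ([start, end)), i.e. BED.

#' Esp3I (BsmBI) recognition site and its reverse complement
#'
#' Type IIS sites excluded from library sequences because they would be cut
#' during Golden Gate cloning of the oligo pool.
#' @export
ESP3I_SITES <- c("CGTCTC", "GAGACG")

#' Default per-category quotas of the screening library
#'
#' 450 predicted high-affinity CTCF-binding sequences, 50 low-affinity ones,
#' 30 MIR elements lying within 5 kb of a LAD boundary, 420 MIRs drawn at
#' random from the source annotation, and 50 random control sequences;
#' 1000 elements in total.
#' @export
DEFAULT_QUOTAS <- c("CTCF-High" = 450L, "CTCF-Low" = 50L,
                    "MIR-LAD_bound" = 30L, "MIR-random" = 420L,
                    "RANDOM" = 50L)

#' Library design specification
#'
#' Bundles the tunable design rules: category quotas, core element length,
#' total flank length added for cloning, the LAD-proximity cutoff used to
#' stratify MIR elements, and the excluded restriction sites.
#'
#' @param quotas Named integer vector of per-category element counts.
#' @param core_length Length (bp) every element core is adjusted to.
#' @param flank_total Total flanking sequence (bp) added across both sides of
#'   the core; must be even (split across the two sides).
#' @param lad_proximity_bp Distance cutoff (bp, strict `<`) to a LAD boundary
#'   below which a MIR counts as LAD-bound.
#' @param excluded_sites DNA motifs that must not occur in any oligo (given
#'   on one strand; the reverse complements are screened too).
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(quotas = DEFAULT_QUOTAS,
                         core_length = 250L,
                         flank_total = 50L,
                         lad_proximity_bp = 5000L,
                         excluded_sites = ESP3I_SITES) {
  if (any(quotas < 0)) stop_input("quota counts must be >= 0")
  if (core_length <= 0) stop_input("core_length must be positive")
  if (flank_total %% 2L != 0L)
    stop_input("flank_total must be even (split across two sides)")
  structure(list(quotas = quotas, core_length = as.integer(core_length),
                 flank_total = as.integer(flank_total),
                 lad_proximity_bp = as.integer(lad_proximity_bp),
                 excluded_sites = toupper(excluded_sites)),
            class = "library_spec")
}

#' Select the top- or bottom-k candidates of a category by affinity score
#'
#' Ranking is by `score` descending for `from_top = TRUE` (e.g. the 450
#' highest-affinity CTCF sites) and ascending otherwise (the 50 lowest).
#' Ties are broken by `id`, lexicographically, so selection is deterministic
#' regardless of input order.
#'
#' @param candidates Candidate data frame with at least columns `id`,
#'   `category`, `score`.
#' @param category Category label to select from.
#' @param k Number of elements to pick.
#' @param from_top Pick highest-scoring (`TRUE`) or lowest-scoring elements.
#' @return The selected rows, ordered by rank.
#' @export
rank_select <- function(candidates, category, k, from_top = TRUE) {
  stopifnot(is.data.frame(candidates), nrow(candidates) > 0)
  pool <- candidates[candidates$category == category, , drop = FALSE]
  if (k > nrow(pool))
    stop_input(sprintf("requested %d elements but only %d candidates in category '%s'",
                       k, nrow(pool), category))
  ord <- order(if (from_top) -pool$score else pool$score,
               pool$id, method = "radix")
  pool[ord[seq_len(k)], , drop = FALSE]
}

## Distance (bp) from a 0-based half-open interval [s, e) to a boundary
## coordinate b: 0 when the interval spans b, otherwise the gap.
interval_boundary_distance <- function(start, end, b) {
  pmax(0L, start - b, b - end)
}

#' Partition elements by proximity to LAD boundaries
#'
#' An element is "near" when the minimum distance from its interval to any
#' LAD boundary coordinate (a LAD start or end) on the same chromosome is
#' strictly below `max_dist`; elements spanning a boundary are at distance 0.
#' Elements on chromosomes without any LAD are "far".
#'
#' @param elements Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param lads Data frame of LAD intervals with columns `chrom`, `start`,
#'   `end` (0-based half-open, non-overlapping per chromosome).
#' @param max_dist Proximity cutoff in bp (strict `<`).
#' @return `list(near = ..., far = ...)`, a disjoint partition of the input
#'   rows; each element additionally gains a `boundary_dist` column
#'   (`NA` when no same-chromosome boundary exists).
#' @export
lad_proximity_filter <- function(elements, lads, max_dist = 5000L) {
  stopifnot(is.data.frame(elements), is.data.frame(lads))
  if (any(is.na(elements$start)) || any(is.na(elements$end)))
    stop_input("all elements must carry genomic intervals")
  dist <- rep(NA_real_, nrow(elements))
  for (chr in unique(elements$chrom)) {
    idx <- which(elements$chrom == chr)
    bounds <- c(lads$start[lads$chrom == chr], lads$end[lads$chrom == chr])
    if (length(bounds) == 0L) next
    dist[idx] <- vapply(idx, function(i) {
      min(interval_boundary_distance(elements$start[i], elements$end[i], bounds))
    }, numeric(1))
  }
  elements$boundary_dist <- dist
  near <- !is.na(dist) & dist < max_dist
  list(near = elements[near, , drop = FALSE],
       far  = elements[!near, , drop = FALSE])
}

#' Generate random control sequences free of excluded sites
#'
#' Sequences are uniform i.i.d. over A/C/G/T and rejection-sampled so that no
#' excluded site occurs on either strand.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param excluded_sites Motifs that must not occur (either strand).
#' @param seed Integer seed; the output is reproducible for a fixed seed.
#' @param max_attempts Rejection cap per sequence; exceeded only when the
#'   exclusion constraint is so restrictive that acceptance is hopeless.
#' @return Candidate data frame (`id`, `category = "RANDOM"`, `score = NA`,
#'   `chrom`/`start`/`end`/`strand` absent as `NA`, `sequence`).
#' @export
generate_random_elements <- function(n, length = 250L,
                                     excluded_sites = ESP3I_SITES,
                                     seed = 1L, max_attempts = 10000L) {
  stopifnot(n >= 0, length > 0)
  banned <- unique(c(excluded_sites,
                     vapply(excluded_sites, revcomp_chr, character(1))))
  set.seed(seed)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      if (!any(vapply(banned, function(m) grepl(m, s, fixed = TRUE),
                      logical(1)))) { ok <- TRUE; break }
    }
    if (!ok)
      stop_input("rejection cap reached; excluded sites too restrictive for this length")
    seqs[i] <- s
  }
  data.frame(id = sprintf("random%03d", seq_len(n)),
             category = rep("RANDOM", n), score = rep(NA_real_, n),
             chrom = rep(NA_character_, n), start = rep(NA_integer_, n),
             end = rep(NA_integer_, n), strand = rep(NA_character_, n),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Adjust element sequences to a uniform core length by centered trimming
#'
#' The retained window is centered; when the excess is odd the extra base is
#' kept on the 5' side (i.e. one base less is trimmed from the 5' end).
#' Sequences shorter than `core_length` are rejected.
#'
#' @param x A character vector of sequences or a candidate data frame with a
#'   `sequence` column.
#' @param core_length Target length in bp.
#' @return Same shape as the input with sequences trimmed to `core_length`.
#' @export
adjust_length <- function(x, core_length = 250L) {
  if (is.data.frame(x)) {
    x$sequence <- adjust_length(x$sequence, core_length)
    return(x)
  }
  len <- nchar(x)
  if (any(len < core_length))
    stop_input(sprintf("%d sequence(s) shorter than core length %d",
                       sum(len < core_length), core_length))
  left <- (len - core_length) %/% 2L   # extra base stays on the 5' side
  substr(x, left + 1L, left + core_length)
}

#' Assemble the full synthesis oligo from a core and two flanks
#'
#' @param core Core sequence(s).
#' @param left_flank,right_flank Flanking sequences added for cloning.
#' @param flank_total Required total flank length; the two flanks must sum to
#'   it exactly.
#' @return `left_flank + core + right_flank` as a character vector.
#' @export
assemble_oligo <- function(core, left_flank, right_flank, flank_total = 50L) {
  if (nchar(left_flank) + nchar(right_flank) != flank_total)
    stop_input(sprintf("flank lengths %d + %d do not sum to flank_total = %d",
                       nchar(left_flank), nchar(right_flank), flank_total))
  paste0(left_flank, core, right_flank)
}

#' Fold coverage of a library by a clone or colony count
#'
#' @param cfu Number of clones (colony-forming units).
#' @param library_size Number of distinct library elements.
#' @return `cfu / library_size`.
#' @export
fold_coverage <- function(cfu, library_size) {
  if (any(library_size == 0)) stop_input("library_size must be positive")
  cfu / library_size
}

#' Expected number of stably integrated clones from a transfection campaign
#'
#' @param n_transfections Number of parallel transfections.
#' @param cells_per_transfection Cells per transfection at transfection time.
#' @param integration_efficiency Absolute integration efficiency in `[0, 1]`.
#' @return Expected clone count, rounded to the nearest integer.
#' @export
expected_clones <- function(n_transfections, cells_per_transfection,
                            integration_efficiency) {
  if (any(integration_efficiency < 0 | integration_efficiency > 1))
    stop_input("integration_efficiency must lie in [0, 1]")
  stopifnot(n_transfections >= 0, cells_per_transfection >= 0)
  round(n_transfections * cells_per_transfection * integration_efficiency)
}

#' Assemble the screening library under the composition rules
#'
#' Applies the full design procedure: rank-select CTCF candidates (top and
#' bottom of the affinity ranking), stratify MIR candidates by distance to
#' LAD boundaries, draw the random-MIR quota (seeded), generate random
#' control sequences, trim every core to `core_length` centered, add flanks,
#' and drop any candidate whose assembled oligo carries an excluded site on
#' either strand (replacements are taken from the remaining ranked pool where
#' available).
#'
#' @param candidates Candidate data frame (`id`, `category` in
#'   `{CTCF, MIR}`, `score`, `chrom`, `start`, `end`, `strand`, `sequence`).
#' @param lads LAD interval data frame (`chrom`, `start`, `end`).
#' @param spec A [library_spec()].
#' @param left_flank,right_flank Flank sequences; must sum to
#'   `spec$flank_total`.
#' @param seed Seed controlling the random-MIR draw and the random controls.
#' @return Library data frame: `id`, `category_label`, `core_sequence`,
#'   `oligo_sequence`, `chrom`, `start`, `end`, `strand`.
#' @export
build_library <- function(candidates, lads, spec = library_spec(),
                          left_flank = strrep("A", 25),
                          right_flank = strrep("T", 25),
                          seed = 1L) {
  q <- spec$quotas
  banned <- unique(c(spec$excluded_sites,
                     vapply(spec$excluded_sites, revcomp_chr, character(1))))
  has_site <- function(s) {
    vapply(s, function(x) any(vapply(banned, function(m)
      grepl(m, x, fixed = TRUE), logical(1))), logical(1), USE.NAMES = FALSE)
  }

  pick <- function(df, label) {
    if (nrow(df) == 0L)
      return(data.frame(id = character(), category_label = character(),
                        core_sequence = character(), oligo_sequence = character(),
                        chrom = character(), start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    core <- adjust_length(df$sequence, spec$core_length)
    oligo <- assemble_oligo(core, left_flank, right_flank, spec$flank_total)
    data.frame(id = df$id, category_label = label, core_sequence = core,
               oligo_sequence = oligo, chrom = df$chrom, start = df$start,
               end = df$end, strand = df$strand, stringsAsFactors = FALSE)
  }

  take_clean <- function(df, label, k) {
    out <- pick(df, label)
    keep <- !has_site(out$oligo_sequence)
    if (sum(keep) < k)
      stop_input(sprintf("category '%s': only %d of %d candidates clean of excluded sites",
                         label, sum(keep), k))
    out[which(keep)[seq_len(k)], , drop = FALSE]
  }

  ctcf <- candidates[candidates$category == "CTCF", , drop = FALSE]
  mir  <- candidates[candidates$category == "MIR", , drop = FALSE]

  # Walk the full affinity ranking so excluded-site casualties are
  # back-filled from the next-ranked candidates.
  n_hi <- q[["CTCF-High"]]; n_lo <- q[["CTCF-Low"]]
  top_pool <- rank_select(ctcf, "CTCF", nrow(ctcf), TRUE)
  hi <- take_clean(top_pool, "CTCF-High", n_hi)
  bot_pool <- rank_select(ctcf, "CTCF", nrow(ctcf), FALSE)
  bot_pool <- bot_pool[!bot_pool$id %in% hi$id, , drop = FALSE]
  lo <- take_clean(bot_pool, "CTCF-Low", n_lo)

  strat <- lad_proximity_filter(mir, lads, spec$lad_proximity_bp)
  near <- strat$near[order(strat$near$id), , drop = FALSE]
  bound <- take_clean(near, "MIR-LAD_bound", q[["MIR-LAD_bound"]])
  far <- strat$far[order(strat$far$id), , drop = FALSE]
  far <- far[!has_site(assemble_oligo(adjust_length(far$sequence, spec$core_length),
                                      left_flank, right_flank, spec$flank_total)), ,
             drop = FALSE]
  if (nrow(far) < q[["MIR-random"]])
    stop_input("not enough clean far-from-LAD MIR candidates for the MIR-random quota")
  set.seed(seed)
  rnd_mir <- far[sort(sample(nrow(far), q[["MIR-random"]])), , drop = FALSE]
  rnd_mir <- pick(rnd_mir, "MIR-random")

  # Random controls: core is exclusion-screened at generation; re-screen the
  # full oligo so flank/core junctions cannot recreate a site.
  rand <- generate_random_elements(q[["RANDOM"]] * 2L, spec$core_length,
                                   spec$excluded_sites, seed = seed + 1L)
  rand <- pick(rand, "RANDOM")
  rand <- rand[!has_site(rand$oligo_sequence), , drop = FALSE]
  if (nrow(rand) < q[["RANDOM"]])
    stop_input("flank sequences recreate excluded sites in random controls")
  rand <- rand[seq_len(q[["RANDOM"]]), , drop = FALSE]

  lib <- rbind(hi, lo, bound, rnd_mir, rand)
  rownames(lib) <- NULL
  lib
}

#' Read a candidate element table
#'
#' Expects a tab-separated file with header columns `id`, `category`,
#' `score`, `chrom`, `start`, `end`, `strand`, `sequence` (BED-style 0-based
#' half-open coordinates).
#' @param path File path.
#' @return Candidate data frame.
#' @export
read_candidates_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "category", "score", "sequence")
  if (!all(need %in% names(df)))
    stop_input("candidate table must contain columns: ",
               paste(need, collapse = ", "))
  df
}

#' Read LAD intervals from a BED3(+) file
#'
#' Only the first three columns (chrom, start, end; 0-based half-open) are
#' used.
#' @param path File path.
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
read_lads_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop_input("BED file must have at least 3 columns")
  setNames(df[, 1:3], c("chrom", "start", "end"))
}

#' Write library FASTA files and a manifest TSV
#'
#' Emits `library_core.fasta` (core sequences), `library_oligo.fasta` (full
#' synthesis oligos) and `library_manifest.tsv` (id, category label, origin
#' coordinates, lengths) into `dir`.
#'
#' @param library Library data frame from [build_library()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  core <- Biostrings::DNAStringSet(setNames(library$core_sequence, library$id))
  oligo <- Biostrings::DNAStringSet(setNames(library$oligo_sequence, library$id))
  Biostrings::writeXStringSet(core, file.path(dir, "library_core.fasta"))
  Biostrings::writeXStringSet(oligo, file.path(dir, "library_oligo.fasta"))
  manifest <- data.frame(id = library$id,
                         category_label = library$category_label,
                         chrom = library$chrom, start = library$start,
                         end = library$end, strand = library$strand,
                         core_length = nchar(library$core_sequence),
                         oligo_length = nchar(library$oligo_sequence),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "library_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

## Reverse complement of a plain character DNA string (ACGT upper case).
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}
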