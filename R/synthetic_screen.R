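## Synthetic sort-seq screen: per-element silencing dynamics, FACS gating,
## PCR/sequencing noise and plasmid-pool (pDNA) baselines.
##
## Silencing model: two superposed processes per element.  An all-or-none
## switch turns cells OFF with hazard lambda = lambda_max * (1 - b) per day
## (b = barrier strength in [0, 1]); OFF cells fall back to the
## autofluorescence distribution.  Cells still ON decay gradually in mean
## intensity at rate k = k_max * (1 - b), i.e. I(t) = I0 * exp(-k t), with
## multiplicative lognormal cell-to-cell noise.  This reproduces the two
## observed signatures of LAD silencing: an emerging reporter-negative
## population and a reporter-positive population of gradually lower
## intensity.

#' Construct per-element silencing phenotypes
#'
#' @param element_id Element identifiers.
#' @param b Barrier strengths in `[0, 1]` (1 = full protection).
#' @param lambda_max Maximal all-or-none silencing hazard (per day), reached
#'   at `b = 0`.  The default leaves an unprotected reporter ~32% ON after
#'   15 days, matching the observed decay of the reporter-positive fraction
#'   at a strongly repressive LAD locus.
#' @param k_max Maximal graded intensity decay rate (per day), reached at
#'   `b = 0`; ON cells of an unprotected element decay into the
#'   autofluorescence range within two weeks.
#' @param I0 Baseline ON-cell intensity (arbitrary units).
#' @return Data frame with `element_id`, `b`, `lambda`, `k`, `I0`.
#' @export
element_phenotypes <- function(element_id, b, lambda_max = 0.075,
                               k_max = 0.3, I0 = 1e4) {
  stopifnot(all(b >= 0 & b <= 1), lambda_max >= 0, k_max >= 0, I0 > 0)
  data.frame(element_id = element_id, b = b,
             lambda = lambda_max * (1 - b), k = k_max * (1 - b),
             I0 = I0, stringsAsFactors = FALSE)
}

#' Default FACS gates
#'
#' The Negative gate is bounded above by the autofluorescence threshold;
#' the positive range up to the baseline intensity is split into log-spaced
#' tertiles (Low / Medium / High), the High gate being open-ended.
#'
#' @param neg_boundary Autofluorescence boundary (upper bound of Negative).
#' @param top Baseline ON intensity used to anchor the positive range.
#' @return Data frame with `label`, `lower`, `upper` (half-open
#'   `[lower, upper)` gates jointly covering `[0, Inf)`).
#' @export
default_gates <- function(neg_boundary = 200, top = 1e4) {
  cuts <- 10^seq(log10(neg_boundary), log10(top), length.out = 4)
  data.frame(label = c("Negative", "Low", "Medium", "High"),
             lower = c(0, cuts[1:3]), upper = c(cuts[1:3], Inf),
             stringsAsFactors = FALSE)
}

validate_gates <- function(gates) {
  stopifnot(is.data.frame(gates), all(c("label", "lower", "upper") %in% names(gates)))
  g <- gates[order(gates$lower), , drop = FALSE]
  if (g$lower[1] != 0 || !is.infinite(g$upper[nrow(g)]) ||
      any(g$upper[-nrow(g)] != g$lower[-1]))
    stop_input("gates must be non-overlapping, ordered and jointly cover [0, Inf)")
  g
}

#' Simulate per-cell reporter intensities at a given day
#'
#' Each cell is OFF with probability `1 - exp(-lambda * day)` (intensity
#' drawn from the lognormal autofluorescence distribution); otherwise ON with
#' intensity `I0 * exp(-k * day)` times multiplicative lognormal noise.
#'
#' @param phenotypes Data frame from [element_phenotypes()].
#' @param cells_per_element Cells simulated per element: a scalar, or a
#'   vector along `phenotypes` (e.g. clone numbers drawn from the plasmid
#'   pool composition; elements may get 0 cells).
#' @param day Days since silencing onset (>= 0).
#' @param seed Integer seed.
#' @param noise_sdlog Lognormal sdlog of ON-cell intensity noise (meanlog 0).
#' @param autofluor_meanlog,autofluor_sdlog Lognormal parameters of the
#'   autofluorescence (OFF-cell) distribution.
#' @return Data frame with `element_id`, `intensity`, `on` (logical).
#' @export
simulate_population <- function(phenotypes, cells_per_element, day, seed = 1L,
                                noise_sdlog = 0.3,
                                autofluor_meanlog = log(50),
                                autofluor_sdlog = 0.5) {
  stopifnot(day >= 0, all(cells_per_element >= 0), any(cells_per_element > 0))
  set.seed(seed)
  n_el <- nrow(phenotypes)
  times <- rep_len(as.integer(cells_per_element), n_el)
  n <- sum(times)
  eid <- rep(phenotypes$element_id, times = times)
  lambda <- rep(phenotypes$lambda, times = times)
  k <- rep(phenotypes$k, times = times)
  I0 <- rep(phenotypes$I0, times = times)
  off <- runif(n) < (1 - exp(-lambda * day))
  intensity <- numeric(n)
  if (any(off))
    intensity[off] <- rlnorm(sum(off), autofluor_meanlog, autofluor_sdlog)
  if (any(!off))
    intensity[!off] <- I0[!off] * exp(-k[!off] * day) *
      rlnorm(sum(!off), 0, noise_sdlog)
  data.frame(element_id = eid, intensity = intensity, on = !off,
             stringsAsFactors = FALSE)
}

#' Assign cells to FACS gates
#'
#' Gate boundaries are half-open `[lower, upper)`; every cell falls in
#' exactly one gate.
#'
#' @param cells Data frame with `element_id` and `intensity`.
#' @param gates Gate data frame as from [default_gates()].
#' @return The input with an added `gate` factor column (levels in gate
#'   order).
#' @export
apply_gates <- function(cells, gates = default_gates()) {
  g <- validate_gates(gates)
  idx <- findInterval(cells$intensity, g$lower)
  cells$gate <- factor(g$label[idx], levels = g$label)
  cells
}

#' Per-element cell counts in each gate
#'
#' @param cells Output of [apply_gates()].
#' @param element_ids Full library element order (so unobserved elements get
#'   zero rows).
#' @return Integer matrix, elements x gates.
#' @export
gate_counts <- function(cells, element_ids = NULL) {
  if (is.null(element_ids)) element_ids <- unique(cells$element_id)
  tab <- table(factor(cells$element_id, levels = element_ids), cells$gate)
  m <- matrix(as.integer(tab), nrow = length(element_ids),
              dimnames = list(element_ids, colnames(tab)))
  m
}

#' Closed-form expected gate occupancy per element
#'
#' Mixture of the OFF (autofluorescence) and ON (decayed, lognormal-noised)
#' components, evaluated with lognormal tail probabilities.  Used for
#' power/monotonicity reasoning and as an analytic oracle in tests.
#'
#' @inheritParams simulate_population
#' @param gates Gate data frame.
#' @return Matrix of probabilities, elements x gates (rows sum to 1).
#' @export
expected_gate_occupancy <- function(phenotypes, gates = default_gates(), day = 15,
                                    noise_sdlog = 0.3,
                                    autofluor_meanlog = log(50),
                                    autofluor_sdlog = 0.5) {
  g <- validate_gates(gates)
  p_off <- 1 - exp(-phenotypes$lambda * day)
  mean_on <- log(phenotypes$I0) - phenotypes$k * day
  occ <- matrix(0, nrow(phenotypes), nrow(g),
                dimnames = list(phenotypes$element_id, g$label))
  for (j in seq_len(nrow(g))) {
    lo <- g$lower[j]; hi <- g$upper[j]
    p_int <- function(meanlog, sdlog) {
      plo <- if (lo <= 0) 0 else stats::plnorm(lo, meanlog, sdlog)
      phi <- if (is.infinite(hi)) 1 else stats::plnorm(hi, meanlog, sdlog)
      phi - plo
    }
    occ[, j] <- p_off * p_int(autofluor_meanlog, autofluor_sdlog) +
      (1 - p_off) * p_int(mean_on, noise_sdlog)
  }
  occ
}

#' Sequencing and amplification noise configuration
#'
#' @param read_length Read length in bp (includes the linker prefix).
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   probabilities applied to the insert.
#' @param linker Constant linker sequence prefixed to every read.
#' @param phred_mean,phred_sd Gaussian model of per-base Phred scores
#'   (clamped to `[2, 40]`).
#' @param pcr_noise_sigma Lognormal sigma of per-element amplification
#'   jitter.
#' @return A list of class `sequencing_config`.
#' @export
sequencing_config <- function(read_length = 250L, substitution_rate = 0,
                              insertion_rate = 0, deletion_rate = 0,
                              linker = "ACACGACGCTCTTCCGATCT",
                              phred_mean = 37, phred_sd = 2,
                              pcr_noise_sigma = 0.05) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  stopifnot(all(rates >= 0 & rates <= 1), read_length > 0)
  structure(list(read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 linker = toupper(linker), phred_mean = phred_mean,
                 phred_sd = phred_sd, pcr_noise_sigma = pcr_noise_sigma),
            class = "sequencing_config")
}

## Multinomial read counts over elements with lognormal PCR jitter.
sample_read_counts <- function(weights, n_reads, pcr_sigma = 0) {
  w <- weights
  if (pcr_sigma > 0) w <- w * rlnorm(length(w), 0, pcr_sigma)
  if (sum(w) <= 0) stop_input("no positive sampling weight: empty gate?")
  counts <- as.integer(rmultinom(1, n_reads, w))
  names(counts) <- names(weights)
  counts
}

## Apply substitution / insertion / deletion noise to one sequence.
mutate_sequence <- function(s, sub, ins, del) {
  if (sub == 0 && ins == 0 && del == 0) return(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(bases)
  keep <- runif(n) >= del
  subst <- runif(n) < sub
  alphabet <- c("A", "C", "G", "T")
  if (any(subst)) {
    for (i in which(subst)) {
      bases[i] <- sample(setdiff(alphabet, bases[i]), 1)
    }
  }
  out <- bases[keep]
  n_ins <- rbinom(1, length(out) + 1L, ins)
  if (n_ins > 0) {
    # gap index g inserts before out[g]; g = length(out) + 1 appends
    gaps <- sample.int(length(out) + 1L, n_ins, replace = TRUE)
    ins_bases <- sample(alphabet, n_ins, replace = TRUE)
    res <- character(0)
    for (g in seq_len(length(out) + 1L)) {
      res <- c(res, ins_bases[gaps == g],
               if (g <= length(out)) out[g] else character(0))
    }
    out <- res
  }
  paste(out, collapse = "")
}

phred_string <- function(len, mean, sd) {
  q <- round(rnorm(len, mean, sd))
  q[q < 2] <- 2L; q[q > 40] <- 40L
  rawToChar(as.raw(q + 33L))
}

#' Generate FASTQ records for a sorted population
#'
#' Per-element read counts are drawn multinomially with probabilities
#' proportional to the element's cell frequency in the gate times lognormal
#' PCR jitter.  Each read is the linker followed by a contiguous window of
#' the element's oligo sequence, mutated according to the error rates, with
#' synthetic quality strings.
#'
#' @param gated_cells Cells of one gate (data frame with `element_id`), or a
#'   named numeric vector of per-element cell counts/frequencies.
#' @param library Library data frame (`id`, `oligo_sequence`).
#' @param n_reads Number of reads to emit.
#' @param cfg A [sequencing_config()].
#' @param seed Integer seed.
#' @param sample_name Prefix used in read identifiers.
#' @return List with `reads` (data frame: `id`, `sequence`, `quality`,
#'   `element_id`) and `true_counts` (named integer vector over the full
#'   library).
#' @export
reads_from_population <- function(gated_cells, library, n_reads,
                                  cfg = sequencing_config(), seed = 1L,
                                  sample_name = "sample") {
  stopifnot(n_reads > 0)
  set.seed(seed)
  if (is.data.frame(gated_cells)) {
    freq <- table(factor(gated_cells$element_id, levels = library$id))
    weights <- as.numeric(freq)
  } else {
    weights <- as.numeric(gated_cells[match(library$id, names(gated_cells))])
    weights[is.na(weights)] <- 0
  }
  names(weights) <- library$id
  counts <- sample_read_counts(weights, n_reads, cfg$pcr_noise_sigma)

  insert_len <- max(1L, cfg$read_length - nchar(cfg$linker))
  ids <- character(n_reads); seqs <- character(n_reads)
  quals <- character(n_reads); src <- character(n_reads)
  r <- 0L
  for (i in which(counts > 0L)) {
    oligo <- library$oligo_sequence[i]
    olen <- nchar(oligo)
    wlen <- min(insert_len, olen)
    starts <- sample.int(olen - wlen + 1L, counts[i], replace = TRUE)
    for (s0 in starts) {
      r <- r + 1L
      insert <- substr(oligo, s0, s0 + wlen - 1L)
      insert <- mutate_sequence(insert, cfg$substitution_rate,
                                cfg$insertion_rate, cfg$deletion_rate)
      seqs[r] <- paste0(cfg$linker, insert)
      quals[r] <- phred_string(nchar(seqs[r]), cfg$phred_mean, cfg$phred_sd)
      ids[r] <- sprintf("%s_%06d", sample_name, r)
      src[r] <- library$id[i]
    }
  }
  ord <- sample.int(n_reads)   # shuffle so file order carries no signal
  list(reads = data.frame(id = ids[ord], sequence = seqs[ord],
                          quality = quals[ord], element_id = src[ord],
                          stringsAsFactors = FALSE),
       true_counts = counts)
}

#' Simulate plasmid-library (pDNA) sequencing counts
#'
#' A `dropout_fraction` of elements receive zero reads; remaining element
#' weights are gamma-distributed with coefficient of variation `dispersion`,
#' then reads are drawn multinomially.  Two technical replicates are
#' emitted, mirroring the treatment of forward and reverse reads of a single
#' plasmid pool.
#'
#' @param library Library data frame.
#' @param dropout_fraction Fraction of elements absent from the pool.
#' @param dispersion CV of the gamma abundance weights (0 = uniform pool).
#' @param n_reads Reads per technical replicate.
#' @param seed Integer seed.
#' @return List with `counts` (elements x 2 integer matrix) and `weights`.
#' @export
simulate_pdna <- function(library, dropout_fraction = 0.015, dispersion = 0.3,
                          n_reads = 1e5, seed = 1L) {
  stopifnot(dropout_fraction >= 0, dropout_fraction < 1)
  set.seed(seed)
  n <- nrow(library)
  w <- if (dispersion > 0) {
    shape <- 1 / dispersion^2
    rgamma(n, shape = shape, rate = shape)
  } else rep(1, n)
  n_drop <- floor(dropout_fraction * n)
  if (n_drop > 0) w[sample.int(n, n_drop)] <- 0
  names(w) <- library$id
  counts <- cbind(rep1 = sample_read_counts(w, n_reads),
                  rep2 = sample_read_counts(w, n_reads))
  list(counts = counts, weights = w)
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with `id`, `sequence`, `quality`.
#' @param path Output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Write the ground-truth manifest of a simulated screen
#'
#' Records each element's phenotype parameters and the realized per-gate
#' cell frequencies, enabling parameter-recovery tests downstream.
#'
#' @param phenotypes Data frame from [element_phenotypes()].
#' @param gated_cells Output of [apply_gates()] for the same elements.
#' @param path Optional TSV output path.
#' @return The manifest data frame (one row per element; gate-frequency
#'   columns sum to 1).
#' @export
ground_truth_manifest <- function(phenotypes, gated_cells, path = NULL) {
  counts <- gate_counts(gated_cells, phenotypes$element_id)
  freq <- counts / pmax(1L, rowSums(counts))
  colnames(freq) <- paste0("freq_", colnames(freq))
  manifest <- cbind(phenotypes, as.data.frame(freq))
  if (!is.null(path))
    write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Simulate a full sort-seq screen at the counts level
#'
#' The plasmid pool (pDNA) is simulated first; each biological replicate
#' then draws its integrated-clone numbers multinomially from the pool
#' composition (so an element over-represented in the pool is equally
#' over-represented among clones, and the bias cancels in fold changes —
#' as in the real screen design).  Cells are simulated per element, gated,
#' and per-gate element read counts are drawn multinomially with PCR
#' jitter; the pDNA baseline contributes two technical replicates.
#'
#' @param library Library data frame.
#' @param phenotypes Data frame from [element_phenotypes()] (same elements).
#' @param day Sorting day.
#' @param gates Gate data frame.
#' @param replicates Number of biological replicates.
#' @param cells_per_element Average cells per element per replicate.
#' @param reads_per_sample Reads per sorted sample.
#' @param cfg A [sequencing_config()] (only `pcr_noise_sigma` is used at the
#'   counts level).
#' @param pdna_reads Reads per pDNA technical replicate.
#' @param pdna_dropout,pdna_dispersion Passed to [simulate_pdna()].
#' @param seed Integer seed; replicates use consecutive seed offsets.
#' @param populations Gate labels to sequence (default all).
#' @return List with `counts` (elements x samples), `sample_sheet`
#'   (`sample`, `population`, `day`, `replicate`, `role`), `manifest`
#'   (ground truth of replicate 1) and `pdna_weights`.
#' @export
simulate_screen <- function(library, phenotypes, day = 15,
                            gates = default_gates(), replicates = 2L,
                            cells_per_element = 500L, reads_per_sample = 1e5,
                            cfg = sequencing_config(), pdna_reads = reads_per_sample,
                            pdna_dropout = 0.015, pdna_dispersion = 0.3,
                            seed = 1L, populations = NULL) {
  g <- validate_gates(gates)
  if (is.null(populations)) populations <- g$label
  pdna <- simulate_pdna(library, dropout_fraction = pdna_dropout,
                        dispersion = pdna_dispersion, n_reads = pdna_reads,
                        seed = seed + 99L)
  n_cells_total <- nrow(phenotypes) * cells_per_element
  counts <- NULL; sheet <- NULL; manifest <- NULL
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + 1000L * rep_i + 500L)
    clone_counts <- as.integer(rmultinom(1, n_cells_total, pdna$weights))
    cells <- simulate_population(phenotypes, clone_counts, day,
                                 seed = seed + 1000L * rep_i)
    cells <- apply_gates(cells, g)
    if (rep_i == 1L) manifest <- ground_truth_manifest(phenotypes, cells)
    gc_mat <- gate_counts(cells, phenotypes$element_id)
    for (pop in populations) {
      set.seed(seed + 1000L * rep_i + match(pop, g$label))
      cnt <- sample_read_counts(gc_mat[, pop], reads_per_sample,
                                cfg$pcr_noise_sigma)
      nm <- sprintf("%s_d%d_rep%d", pop, day, rep_i)
      col <- setNames(data.frame(cnt), nm)
      counts <- if (is.null(counts)) col else cbind(counts, col)
      sheet <- rbind(sheet, data.frame(sample = nm, population = pop,
                                       day = day, replicate = rep_i,
                                       role = "sorted", stringsAsFactors = FALSE))
    }
  }
  for (j in 1:2) {
    nm <- sprintf("pDNA_rep%d", j)
    counts <- cbind(counts, setNames(data.frame(pdna$counts[, j]), nm))
    sheet <- rbind(sheet, data.frame(sample = nm, population = "pDNA",
                                     day = NA_integer_, replicate = j,
                                     role = "pdna", stringsAsFactors = FALSE))
  }
  counts <- as.matrix(counts)
  rownames(counts) <- phenotypes$element_id
  list(counts = counts, sample_sheet = sheet, manifest = manifest,
       pdna_weights = pdna$weights)
}
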