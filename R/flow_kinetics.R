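## Flow-cytometry normalization and silencing kinetics: bead adjustment of
## reporter MFI, fold changes between conditions, exponential decay fits
## and percent-positive summaries.

#' Bead-adjust a mean fluorescence intensity
#'
#' Normalizes day-to-day cytometer drift against standard fluorescent beads
#' run alongside each sample:
#' `adjusted = mfi * beads_mfi / beads_day1`, with the day-1 bead reading
#' as the reference.  The multiplier direction (same-day beads in the
#' numerator) is kept exactly as the screen formulated it; see the methods
#' vignette for a note on this convention.
#'
#' @param mfi Sample mean fluorescence intensity (same-day run).
#' @param beads_mfi Bead MFI from the same run.
#' @param beads_day1 Bead MFI of the day-1 reference run.
#' @return Adjusted MFI.
#' @export
bead_adjust <- function(mfi, beads_mfi, beads_day1) {
  if (any(beads_mfi <= 0) || any(beads_day1 <= 0))
    stop_input("bead intensities must be positive")
  mfi * beads_mfi / beads_day1
}

## Replicate-averaged bead-adjusted MFI of one series at one day.
series_adjusted_mfi <- function(series, day) {
  stopifnot(all(c("day", "mfi", "beads_mfi") %in% names(series)))
  ref <- series$beads_mfi[series$day == min(series$day)][1]
  rows <- series$day == day
  if (!any(rows)) stop_input("requested day absent from series")
  mean(bead_adjust(series$mfi[rows], series$beads_mfi[rows], ref))
}

#' MFI fold change between two flow series at a given day
#'
#' Ratio of replicate-averaged, bead-adjusted MFIs (treated / control).
#' Any bead rescaling common to both series cancels.
#'
#' @param treated,control Flow sample data frames with columns `day`,
#'   `mfi`, `beads_mfi` (one row per replicate and day); the earliest day
#'   of each series provides its bead reference.
#' @param day Day to compare at.
#' @return Fold change (scalar).
#' @export
mfi_fold_change <- function(treated, control, day) {
  series_adjusted_mfi(treated, day) / series_adjusted_mfi(control, day)
}

#' Fit an exponential decay to an MFI time series
#'
#' Ordinary least squares of `log(MFI)` on day, i.e. the model
#' `I(t) = I0 * exp(-k t)`.
#'
#' @param day Numeric vector of days (>= 3 distinct values).
#' @param mfi Positive MFIs, same length.
#' @return List of class `decay_fit` with `I0_hat`, `k_hat` (per day) and
#'   `residual_sse` (on the log scale).
#' @export
fit_exponential_decay <- function(day, mfi) {
  if (length(unique(day)) < 3L)
    stop_input("need at least 3 distinct days to fit a decay")
  if (any(mfi <= 0)) stop_input("MFIs must be positive")
  fit <- lm(log(mfi) ~ day)
  structure(list(I0_hat = unname(exp(coef(fit)[1])),
                 k_hat = unname(-coef(fit)[2]),
                 residual_sse = sum(residuals(fit)^2)),
            class = "decay_fit")
}

#' Fraction of reporter-positive cells
#'
#' @param intensities Per-cell intensity vector (non-empty).
#' @param threshold Autofluorescence boundary; cells at or above it count
#'   as positive.
#' @return Fraction in `[0, 1]`.
#' @export
percent_positive <- function(intensities, threshold) {
  if (length(intensities) == 0L) stop_input("empty intensity vector")
  stopifnot(threshold > 0)
  mean(intensities >= threshold)
}

#' Read a flow-cytometry summary table
#'
#' Tab-separated with header; expected columns include `sample_id`, `day`,
#' `mfi`, `egfp_pos_fraction`, `beads_mfi`.
#' @param path File path.
#' @return Data frame.
#' @export
read_flow_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("day", "mfi", "beads_mfi")
  if (!all(need %in% names(df)))
    stop_input("flow table must contain columns: ", paste(need, collapse = ", "))
  df
}
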