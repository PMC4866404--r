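# Diverticulum-shortening pipeline: six raw length measurements per organ
# per time point (three per side), averaged; the shortening is the difference
# of the two time-point means, also expressed as a percentage of the
# baseline mean.

#' Build per-trial shortening records from raw length measurements
#'
#' @param lengths long data frame `trial_id, species, timepoint, side, rep,
#'   length_mm` with timepoints `"t0"` and `"t15"` (the measurement before
#'   mucus addition and 15 min after).
#' @return Data frame with one row per trial: `trial_id`, `species`,
#'   `mean_L0`, `mean_L15`, `delta_mm` (`mean_L0 - mean_L15`) and
#'   `delta_pct` (`100 * delta_mm / mean_L0`).
#' @export
shortening_records <- function(lengths) {
  need <- c("trial_id", "species", "timepoint", "length_mm")
  stopifnot(all(need %in% names(lengths)))
  if (any(lengths$length_mm <= 0))
    stop("non-positive length measurement")
  if (!all(lengths$timepoint %in% c("t0", "t15")))
    stop("timepoint must be 't0' or 't15'")
  out <- lapply(split(lengths, lengths$trial_id), function(tr) {
    l0 <- tr$length_mm[tr$timepoint == "t0"]
    l15 <- tr$length_mm[tr$timepoint == "t15"]
    if (!length(l0) || !length(l15))
      stop("trial ", tr$trial_id[1], ": both time points are required")
    if (length(l0) != 6 || length(l15) != 6)
      warning("trial ", tr$trial_id[1], ": expected 6 measurements per ",
              "time point, found ", length(l0), "/", length(l15))
    m0 <- mean(l0); m15 <- mean(l15)
    data.frame(trial_id = tr$trial_id[1], species = tr$species[1],
               mean_L0 = m0, mean_L15 = m15, delta_mm = m0 - m15,
               delta_pct = 100 * (m0 - m15) / m0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Species-level shortening summary
#'
#' @param records per-trial records from [shortening_records()].
#' @return Data frame `species`, `n`, `mean_delta_mm`, `se_delta_mm`,
#'   `mean_delta_pct`, `se_delta_pct`.
#' @export
summarize_shortening <- function(records) {
  stopifnot(all(c("species", "delta_mm", "delta_pct") %in% names(records)))
  out <- lapply(split(records, records$species), function(r) {
    n <- nrow(r)
    data.frame(species = r$species[1], n = n,
               mean_delta_mm = mean(r$delta_mm),
               se_delta_mm = stats::sd(r$delta_mm) / sqrt(n),
               mean_delta_pct = mean(r$delta_pct),
               se_delta_pct = stats::sd(r$delta_pct) / sqrt(n),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Long-format log-length table for the repeated-measures ANOVA
#'
#' Expands per-trial shortening records into the two-rows-per-trial table
#' (`trial_id`, `species`, `timepoint`, `log_length`) the mixed ANOVA
#' consumes: the log of the six-measurement mean length at each time point.
#'
#' @param records per-trial records from [shortening_records()].
#' @return Long data frame with `2 * nrow(records)` rows.
#' @export
shortening_long <- function(records) {
  stopifnot(all(c("trial_id", "species", "mean_L0", "mean_L15") %in%
                  names(records)))
  data.frame(
    trial_id = rep(records$trial_id, 2),
    species = rep(records$species, 2),
    timepoint = rep(c("t0", "t15"), each = nrow(records)),
    log_length = log(c(records$mean_L0, records$mean_L15)),
    stringsAsFactors = FALSE)
}

#' Check that the diverticulum regains its baseline length across trials
#'
#' One-way ANOVA of the baseline (t = 0) mean length on the trial-order
#' group: a significant order effect would mean the organ did not recover
#' between trials and the measurements do not share a baseline.
#'
#' @param records per-trial records from [shortening_records()].
#' @param order vector of trial-order groups, parallel to `records`.
#' @param alpha significance level for the recovery flag.
#' @return List with `F`, `df1`, `df2`, `p.value` and logical `recovered`
#'   (`p >= alpha`).
#' @export
baseline_recovery_check <- function(records, order, alpha = 0.05) {
  stopifnot(nrow(records) == length(order))
  a <- one_way_anova(records$mean_L0, order)
  a$recovered <- a$p.value >= alpha
  a
}

#' Length of a traced polyline, in mm
#'
#' Helper converting a digitized polyline of image coordinates into a length
#' measurement, given the image scale.
#'
#' @param x,y polyline vertex coordinates, pixels.
#' @param mm_per_px image scale.
#' @return Length in mm.
#' @export
polyline_length_mm <- function(x, y, mm_per_px = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(sqrt(diff(x)^2 + diff(y)^2)) * mm_per_px
}
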