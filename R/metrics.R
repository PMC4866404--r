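# Daily-control normalization and species-level summaries.
# The two bracketing positive controls of each experimental day define the
# reference against which every trial of that day is expressed.

#' Express trial scores relative to the day's positive controls
#'
#' The response of each trial is expressed as relative response: the induced
#' contraction count minus the mean induced count of that day's two
#' positive-control trials, and the intensity as a percentage of the control
#' species' response (the per-day control mean intensity anchors 100 %, a
#' configured zero-response baseline anchors 0 %).
#'
#' @param scores per-trial score table (from [score_trial()] /
#'   [simulate_study()]), one organ stream at a time or with an `organ`
#'   column (normalization is done per day within organ).
#' @param control_species species serving as positive control.
#' @param zero_baseline displacement value anchoring 0 % intensity (taken
#'   from zero-response preparations; 0 for synthetic data).
#' @param exclude_organs organ streams dropped before normalization (the
#'   atrium by default, whose reaction is too weak to be meaningful).
#' @param drop_nonresponding_days drop day-organ strata in which no trial of
#'   the day responded to any species' mucus.
#' @return `scores` restricted to the kept rows, with columns `induced_rel`
#'   and `intensity_rel_pct` appended.
#' @export
relative_response <- function(scores, control_species = "C_aspersum",
                              zero_baseline = 0,
                              exclude_organs = "atrium",
                              drop_nonresponding_days = FALSE) {
  need <- c("trial_id", "species", "day", "induced", "intensity",
            "responded")
  stopifnot(all(need %in% names(scores)))
  if (!"organ" %in% names(scores)) scores$organ <- "organ"
  scores <- scores[!scores$organ %in% exclude_organs, , drop = FALSE]
  out <- list()
  for (org in unique(scores$organ)) {
    so <- scores[scores$organ == org, , drop = FALSE]
    for (d in unique(so$day)) {
      sd_ <- so[so$day == d, , drop = FALSE]
      ctrl <- sd_[sd_$species == control_species, , drop = FALSE]
      if (nrow(ctrl) != 2)
        stop("day ", d, " (", org, "): expected exactly 2 control trials, ",
             "found ", nrow(ctrl))
      if (drop_nonresponding_days && !any(sd_$responded)) next
      m_ind <- mean(ctrl$induced)
      m_int <- mean(ctrl$intensity)
      if (zero_baseline >= m_int)
        stop("day ", d, " (", org, "): zero-response baseline (",
             zero_baseline, ") is not below the control mean intensity (",
             signif(m_int, 4), ")")
      sd_$induced_rel <- sd_$induced - m_ind
      sd_$intensity_rel_pct <- 100 * (sd_$intensity - zero_baseline) /
        (m_int - zero_baseline)
      out[[paste(org, d)]] <- sd_
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentage of trials in which each organ responded to each mucus type
#'
#' A trial counts as a response when the response segment had strictly more
#' contractions than the control segment.  For the control species, whose
#' mucus is tested twice per day, the percentage reported is the average of
#' the two time-point percentages (first vs last trial of the day).
#'
#' @inheritParams relative_response
#' @return Data frame `species`, `organ`, `n_trials`, `n_responded`, `pct`.
#' @export
percent_responders <- function(scores, control_species = "C_aspersum") {
  stopifnot(all(c("species", "responded", "day", "order_index") %in%
                  names(scores)))
  if (!"organ" %in% names(scores)) scores$organ <- "organ"
  out <- list()
  for (org in unique(scores$organ)) {
    so <- scores[scores$organ == org, , drop = FALSE]
    for (sp in unique(so$species)) {
      ss <- so[so$species == sp, , drop = FALSE]
      if (sp == control_species) {
        # first and last trial of each day are the two control time points
        pos1 <- unlist(lapply(split(ss, ss$day), function(x)
          x$responded[which.min(x$order_index)]))
        pos2 <- unlist(lapply(split(ss, ss$day), function(x)
          x$responded[which.max(x$order_index)]))
        pct <- mean(c(100 * mean(pos1), 100 * mean(pos2)))
      } else {
        pct <- 100 * mean(ss$responded)
      }
      out[[paste(org, sp)]] <- data.frame(
        species = sp, organ = org, n_trials = nrow(ss),
        n_responded = sum(ss$responded), pct = pct,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
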