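# Contraction scoring: the study's displacement -> detection -> trial-score
# procedure.  Counting rules: a 25 % min-max relative threshold per trial,
# contractions lasting more than 3 min are not counted, and retained peaks
# must be at least 15 s apart.

#' Displacement series of a marker track
#'
#' Converts a marker track on the 5-s grid into per-interval displacement
#' magnitudes: `d[k]` is the Euclidean distance between the marker positions
#' at consecutive grid points.  Samples are labelled `control` or `response`
#' by the segment windows; intervals falling in the exposure pause (or
#' crossing a window edge) are dropped.
#'
#' @param track marker-track data frame on the regular `dt` grid.
#' @param control_window,response_window `c(start, end)` in seconds.
#' @param dt grid spacing, seconds.
#' @param trial_id,organ,species,day,order_index metadata carried as
#'   attributes into downstream scoring.
#' @return A `displacement_trace` data frame with columns `time_s` (interval
#'   end time), `d` and `segment`.
#' @examples
#' tr <- data.frame(marker_id = "diverticulum", time_s = seq(0, 1500, 5),
#'                  x = 0, y = 0)
#' tr$x[50] <- 3; tr$y[50] <- 4   # a single step of length 5
#' dtr <- displacement_series(tr)
#' max(dtr$d)
#' @export
displacement_series <- function(track, control_window = c(0, 600),
                                response_window = c(900, 1500), dt = 5,
                                trial_id = NULL, organ = NULL,
                                species = NULL, day = NULL,
                                order_index = NULL) {
  stopifnot(all(c("time_s", "x", "y") %in% names(track)))
  t <- track$time_s
  need <- sort(unique(c(seq(control_window[1], control_window[2], by = dt),
                        seq(response_window[1], response_window[2], by = dt))))
  if (!all(need %in% t))
    stop("track is missing required grid points; resample to the ", dt,
         "-s grid first")
  if (any(abs(diff(t) - dt) > 1e-9))
    stop("track is not on a regular ", dt, "-s grid")
  d <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  te <- t[-1]                                   # interval end times
  tb <- t[-length(t)]                           # interval start times
  seg <- rep(NA_character_, length(d))
  seg[tb >= control_window[1] & te <= control_window[2]] <- "control"
  seg[tb >= response_window[1] & te <= response_window[2]] <- "response"
  keep <- !is.na(seg)
  out <- data.frame(time_s = te[keep], d = d[keep], segment = seg[keep],
                    stringsAsFactors = FALSE)
  if (is.null(organ) && "marker_id" %in% names(track))
    organ <- track$marker_id[1]
  attr(out, "trial_id") <- trial_id
  attr(out, "organ") <- organ
  attr(out, "species") <- species
  attr(out, "day") <- day
  attr(out, "order_index") <- order_index
  attr(out, "dt") <- dt
  class(out) <- c("displacement_trace", "data.frame")
  out
}

#' Detect contractions on a displacement trace
#'
#' Implements the study's counting rules.  A relative threshold
#' `T = d_min + threshold_frac * (d_max - d_min)` is computed over the whole
#' trial (control and response segments jointly).  Candidate events are
#' maximal runs of consecutive samples with `d > T` within a segment; runs
#' that stay above the threshold for more than `max_dur` seconds are not
#' counted; within each run the peak is the largest `d`; retained peaks
#' closer than `min_sep` seconds are merged, keeping the larger peak and the
#' union of the run extents.
#'
#' @param trace a [displacement_series()] result covering both segments of
#'   one trial.
#' @param threshold_frac relative threshold as a fraction of the min-max
#'   range (0.25 = the study's 25 % rule).
#' @param min_sep minimum separation of retained peaks, seconds.
#' @param max_dur maximum duration of a counted contraction, seconds
#'   (180 s = the study's 3-min rule).
#' @param range_epsilon absolute range below which the trace is treated as
#'   degenerate (no events, with a warning).
#' @param keep_boundary keep runs truncated by a segment edge (provided their
#'   observed duration passes the `max_dur` filter)?
#' @return Data frame of contraction events: `segment`, `start_s`, `end_s`,
#'   `peak_time_s`, `peak_value`.
#' @export
detect_contractions <- function(trace, threshold_frac = 0.25, min_sep = 15,
                                max_dur = 180, range_epsilon = 1e-8,
                                keep_boundary = TRUE) {
  stopifnot(all(c("time_s", "d", "segment") %in% names(trace)))
  empty <- data.frame(segment = character(0), start_s = numeric(0),
                      end_s = numeric(0), peak_time_s = numeric(0),
                      peak_value = numeric(0), stringsAsFactors = FALSE)
  dmin <- min(trace$d); dmax <- max(trace$d)
  if (!is.finite(dmax - dmin) || dmax - dmin < range_epsilon) {
    warning("degenerate displacement range (d_max - d_min < ",
            format(range_epsilon), "); no events detected")
    return(empty)
  }
  thr <- dmin + threshold_frac * (dmax - dmin)
  dt <- attr(trace, "dt"); if (is.null(dt)) dt <- 5

  out <- list()
  for (seg in unique(trace$segment)) {
    s <- trace[trace$segment == seg, , drop = FALSE]
    above <- s$d > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    ev <- lapply(runs, function(i) {
      ii <- starts[i]:ends[i]
      pk <- ii[which.max(s$d[ii])]
      data.frame(segment = seg, start_s = s$time_s[starts[i]],
                 end_s = s$time_s[ends[i]],
                 peak_time_s = s$time_s[pk], peak_value = s$d[pk],
                 at_boundary = starts[i] == 1 || ends[i] == nrow(s),
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, ev)
    ev <- ev[ev$end_s - ev$start_s <= max_dur, , drop = FALSE]
    if (!keep_boundary) ev <- ev[!ev$at_boundary, , drop = FALSE]
    # merge peaks closer than min_sep, keeping the larger peak
    while (nrow(ev) > 1) {
      gaps <- diff(ev$peak_time_s)
      if (all(gaps >= min_sep)) break
      i <- which.min(gaps)
      keep <- if (ev$peak_value[i] >= ev$peak_value[i + 1]) i else i + 1
      merged <- ev[keep, , drop = FALSE]
      merged$start_s <- min(ev$start_s[i:(i + 1)])
      merged$end_s <- max(ev$end_s[i:(i + 1)])
      merged$at_boundary <- any(ev$at_boundary[i:(i + 1)])
      ev <- rbind(if (i > 1) ev[1:(i - 1), ], merged,
                  if (i + 1 < nrow(ev)) ev[(i + 2):nrow(ev), ])
    }
    out[[seg]] <- ev
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$at_boundary <- NULL
  res
}

#' Score one trial from its detected contractions
#'
#' Fills the per-trial score: contraction counts in the control and response
#' segments, the induced count (response minus control), the intensity
#' (maximum displacement reached anywhere in the trial) and the responder
#' flag (strictly more response- than control-segment contractions).
#'
#' @param events result of [detect_contractions()] for the trial.
#' @param trace the [displacement_series()] the events came from.
#' @return One-row data frame: `trial_id`, `organ`, `species`, `day`,
#'   `order_index`, `n_control`, `n_response`, `induced`, `intensity`,
#'   `responded`.
#' @export
score_trial <- function(events, trace) {
  n_c <- sum(events$segment == "control")
  n_r <- sum(events$segment == "response")
  meta <- function(a) {
    v <- attr(trace, a)
    if (is.null(v)) NA else v
  }
  data.frame(trial_id = as.character(meta("trial_id")),
             organ = as.character(meta("organ")),
             species = as.character(meta("species")),
             day = as.integer(meta("day")),
             order_index = as.integer(meta("order_index")),
             n_control = n_c, n_response = n_r,
             induced = n_r - n_c,
             intensity = max(trace$d),
             responded = n_r > n_c,
             stringsAsFactors = FALSE)
}
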