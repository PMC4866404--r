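#' Simulation parameters for the synthetic cross-reactivity study
#'
#' Bundles every constant the synthetic-data generator needs to emulate one
#' organ-bath cross-reactivity study: the recording protocol (a 10-min control
#' recording, a 5-min exposure pause, a 10-min response recording, analysed on
#' a 5-s grid), the per-species contraction event rates, the event shape, the
#' measurement noise, the daily trial design, and the diverticulum-shortening
#' effect sizes.
#'
#' Default event rates and shortening fractions encode the study conditions
#' the pipeline is calibrated against: spontaneous activity of about 2
#' contractions per 10 min, mucus of most species roughly doubling that (the
#' focal-species positive control induces a mean of ~1.98 extra contractions),
#' three species (\emph{H. pomatia}, \emph{H. lucorum}, \emph{F. fruticum})
#' inducing no extra diverticulum contractions, and fractional length
#' reductions of the diverticulum ranging from 0 to 0.196
#' (\emph{E. vermiculata}).
#'
#' @param seed default integer seed carried with the parameter set; individual
#'   generator calls may override it.
#' @param dt_sample analysis sampling interval, seconds.
#' @param control_duration,pause_duration,response_duration segment durations
#'   in seconds; each must be a positive multiple of `dt_sample`.
#' @param frame_interval native video frame interval in seconds (must divide
#'   into `dt_sample`); the recording protocol only fixes the 5-s analysis
#'   grid, so the frame rate is a free parameter.
#' @param species_labels character vector of species; the first is the focal
#'   (positive-control) species whose own mucus brackets each day.
#' @param event_rate_control spontaneous contraction events per 10-min control
#'   segment (scalar, applies to all trials).
#' @param event_rate_response named numeric vector, events per 10-min response
#'   segment for each species' mucus.
#' @param amplitude_mean,amplitude_sd contraction peak amplitude on the 5-s
#'   displacement series, abstract displacement units.
#' @param event_duration_mean mean planted event duration, seconds (< 180 s so
#'   events survive the 3-min duration filter).
#' @param event_duration_sd sd of event duration, seconds.
#' @param min_event_gap minimum gap between planted events, seconds (> 15 s so
#'   distinct events are not merged by the peak-separation rule).
#' @param noise_sd coordinate measurement noise sd, displacement units.
#' @param drift_slope slow linear baseline drift, displacement units per
#'   second.
#' @param drift_sine_amp,drift_sine_period amplitude (units) and period (s) of
#'   an additional low-frequency baseline oscillation.
#' @param atrium_activity multiplier on both event rates for the atrium
#'   marker, emulating its consistently low reactivity.
#' @param control2_inflation extra response-segment events added to the second
#'   daily positive control (0 disables; emulates the drift by which the
#'   second control responds more strongly than the first).
#' @param n_days number of experimental days in a full study.
#' @param n_test_slots maximum number of non-control extracts tested between
#'   the two daily positive controls.
#' @param shortening_effect named fractional length reduction of the
#'   diverticulum per species, in `[0, 1)`.
#' @param baseline_length_mean,baseline_length_sd true diverticulum length
#'   distribution across preparations, mm.
#' @param length_noise_sd sd of a single caliper/polyline length measurement,
#'   mm.
#' @param bm_sigma2 Brownian-motion rate for trait simulation on a phylogeny.
#'
#' @return An object of class `"sim_params"` (a validated list).
#' @examples
#' p <- sim_params(seed = 1)
#' p$event_rate_response[["C_aspersum"]]
#' @export
sim_params <- function(seed = 1L,
                       dt_sample = 5,
                       control_duration = 600,
                       pause_duration = 300,
                       response_duration = 600,
                       frame_interval = 1,
                       species_labels = c("C_aspersum", "C_nemoralis",
                                          "C_hortensis", "A_arbustorum",
                                          "H_pomatia", "H_lucorum",
                                          "T_pisana", "E_vermiculata",
                                          "F_fruticum"),
                       event_rate_control = 2,
                       event_rate_response = NULL,
                       amplitude_mean = 10,
                       amplitude_sd = 2,
                       event_duration_mean = 30,
                       event_duration_sd = 6,
                       min_event_gap = 20,
                       noise_sd = 0.5,
                       drift_slope = 0.002,
                       drift_sine_amp = 0.2,
                       drift_sine_period = 300,
                       atrium_activity = 0.25,
                       control2_inflation = 0,
                       n_days = 29,
                       n_test_slots = 5,
                       shortening_effect = NULL,
                       baseline_length_mean = 29.1,
                       baseline_length_sd = 2,
                       length_noise_sd = 0.4,
                       bm_sigma2 = 1) {
  if (is.null(event_rate_response)) {
    event_rate_response <- c(
      C_aspersum = 3.98, C_nemoralis = 4, C_hortensis = 4, A_arbustorum = 4,
      H_pomatia = 2, H_lucorum = 2, T_pisana = 4, E_vermiculata = 4,
      F_fruticum = 2
    )[species_labels]
    names(event_rate_response) <- species_labels
    event_rate_response[is.na(event_rate_response)] <- 4
  }
  if (is.null(shortening_effect)) {
    shortening_effect <- c(
      C_aspersum = 0.077, C_nemoralis = 0, C_hortensis = 0.066,
      A_arbustorum = 0, H_pomatia = 0.054, H_lucorum = 0.065,
      T_pisana = 0.155, E_vermiculata = 0.196, F_fruticum = 0
    )[species_labels]
    names(shortening_effect) <- species_labels
    shortening_effect[is.na(shortening_effect)] <- 0
  }
  p <- list(seed = as.integer(seed), dt_sample = dt_sample,
            control_duration = control_duration,
            pause_duration = pause_duration,
            response_duration = response_duration,
            frame_interval = frame_interval,
            species_labels = species_labels,
            focal_species = species_labels[1],
            event_rate_control = event_rate_control,
            event_rate_response = event_rate_response,
            amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
            event_duration_mean = event_duration_mean,
            event_duration_sd = event_duration_sd,
            min_event_gap = min_event_gap,
            noise_sd = noise_sd, drift_slope = drift_slope,
            drift_sine_amp = drift_sine_amp,
            drift_sine_period = drift_sine_period,
            atrium_activity = atrium_activity,
            control2_inflation = control2_inflation,
            n_days = as.integer(n_days), n_test_slots = as.integer(n_test_slots),
            shortening_effect = shortening_effect,
            baseline_length_mean = baseline_length_mean,
            baseline_length_sd = baseline_length_sd,
            length_noise_sd = length_noise_sd,
            bm_sigma2 = bm_sigma2)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  durs <- c(control = p$control_duration, pause = p$pause_duration,
            response = p$response_duration)
  if (any(durs <= 0))
    stop("segment durations must be positive")
  if (any(durs %% p$dt_sample != 0))
    stop("segment durations must be multiples of dt_sample (",
         p$dt_sample, " s)")
  if (p$dt_sample %% p$frame_interval != 0)
    stop("frame_interval must divide dt_sample")
  if (p$event_rate_control < 0 || any(p$event_rate_response < 0))
    stop("event rates must be non-negative")
  if (p$event_duration_mean >= 180)
    warning("event_duration_mean >= 180 s: planted events will be discarded ",
            "by the 3-min duration filter")
  if (any(p$shortening_effect < 0) || any(p$shortening_effect >= 1))
    stop("shortening_effect fractions must lie in [0, 1)")
  if (length(p$species_labels) < 2)
    stop("need the focal species plus at least one other species")
  if (anyDuplicated(p$species_labels))
    stop("species_labels must be unique")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cross-reactivity study parameters\n")
  cat(sprintf("  protocol: %g s control / %g s pause / %g s response, %g s grid\n",
              x$control_duration, x$pause_duration, x$response_duration,
              x$dt_sample))
  cat(sprintf("  %d species (focal: %s), %d days, <=%d test slots/day\n",
              length(x$species_labels), x$focal_species, x$n_days,
              x$n_test_slots))
  cat(sprintf("  control rate %g /10 min; amplitude %g +/- %g; noise sd %g\n",
              x$event_rate_control, x$amplitude_mean, x$amplitude_sd,
              x$noise_sd))
  invisible(x)
}
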