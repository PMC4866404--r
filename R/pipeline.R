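# End-to-end synthetic study: design -> traces -> displacement -> detection
# -> trial scores (+ paired length measurements), with the planted ground
# truth carried along.

#' Score the three marker tracks of one simulated trial
#'
#' Resamples each native track to the 5-s grid, builds the displacement
#' trace, runs the contraction detector and scores the trial, per organ.
#'
#' @param trial a [simulate_trace()] result.
#' @param params the [sim_params()] used to generate it.
#' @param ... passed to [detect_contractions()].
#' @return Data frame with one row per organ (marker).
#' @export
score_simulated_trial <- function(trial, params, ...) {
  ts <- trial$trial_spec
  ctrl_win <- c(0, params$control_duration)
  resp_win <- c(params$control_duration + params$pause_duration,
                params$control_duration + params$pause_duration +
                  params$response_duration)
  rows <- lapply(trial$tracks, function(tr) {
    tr5 <- resample_5s(tr, dt = params$dt_sample)
    trace <- displacement_series(tr5, control_window = ctrl_win,
                                 response_window = resp_win,
                                 dt = params$dt_sample,
                                 trial_id = ts$trial_id,
                                 organ = tr$marker_id[1],
                                 species = ts$species, day = ts$day,
                                 order_index = ts$order_index)
    ev <- suppressWarnings(detect_contractions(trace, ...))
    score_trial(ev, trace)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate and score a complete cross-reactivity study
#'
#' Generates the daily trial designs, simulates every trial's marker tracks
#' with planted contraction events, pushes them through the tracking-grid
#' resampling, displacement, detection and scoring steps, and simulates the
#' paired diverticulum length measurements for each trial.
#'
#' @param params a [sim_params()] object.
#' @param seed master seed; defaults to `params$seed`.
#' @param markers which markers to simulate and score.
#' @return List with `design`, `scores` (per trial x organ), `truth`
#'   (planted per-trial counts), `lengths` (raw length measurements) and
#'   `params`.
#' @examples
#' \donttest{
#' p <- sim_params(seed = 1, n_days = 3)
#' st <- simulate_study(p)
#' head(st$scores)
#' }
#' @export
simulate_study <- function(params, seed = NULL, markers = MARKERS) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  params$seed <- as.integer(seed)
  design <- simulate_design(params)
  scores <- list(); truth <- list(); lengths <- list()
  for (i in seq_len(nrow(design))) {
    spec <- design[i, ]
    trial <- simulate_trace(params, spec, markers = markers)
    scores[[i]] <- score_simulated_trial(trial, params)
    truth[[i]] <- trial$truth$counts
    lengths[[i]] <- simulate_lengths(
      params, spec$species, trial_id = spec$trial_id,
      seed = derive_seed(params$seed, spec$day, spec$order_index + 50L))
  }
  scores <- do.call(rbind, scores)
  scores <- add_previous_species(scores, design)
  list(design = design, scores = scores,
       truth = do.call(rbind, truth),
       lengths = do.call(rbind, lengths),
       params = params)
}

#' Annotate scores with the species tested immediately before
#'
#' Adds the `prev_species` factor used by the order-effect GLMs: within each
#' day, the species whose extract preceded the trial (NA for the first trial
#' of a day).
#'
#' @param scores per-trial (x organ) score table.
#' @param design trial design with `trial_id`, `day`, `order_index`,
#'   `species`.
#' @return `scores` with a `prev_species` column.
#' @export
add_previous_species <- function(scores, design) {
  design <- design[order(design$day, design$order_index), ]
  prev <- unlist(lapply(split(design, design$day), function(d)
    c(NA_character_, d$species[-nrow(d)])), use.names = FALSE)
  map <- stats::setNames(prev, design$trial_id)
  scores$prev_species <- unname(map[scores$trial_id])
  scores
}
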