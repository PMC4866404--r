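MARKERS <- c("diverticulum", "copulatory_canal", "atrium")

# base marker positions in the rendered frame / abstract coordinate plane
marker_base_positions <- function() {
  data.frame(marker_id = MARKERS,
             x = c(40, 60, 45),
             y = c(30, 55, 75))
}

# deterministic per-trial seed derived from the master seed (kept < 2^31)
derive_seed <- function(seed, day = 0L, order_index = 0L) {
  (abs(as.integer(seed)) %% 19999L) * 100000L + as.integer(day) * 100L +
    as.integer(order_index) + 1L
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# place `n` events of widths w inside [margin, seg_len - margin] keeping at
# least `gap` seconds between them; events that cannot be placed are dropped
place_events <- function(n, w, seg_len, gap, margin = 10) {
  starts <- numeric(0); widths <- numeric(0)
  for (i in seq_len(n)) {
    lo <- margin; hi <- seg_len - margin - w[i]
    if (hi <= lo) next
    ok <- FALSE
    for (try in 1:60) {
      s <- stats::runif(1, lo, hi)
      if (!length(starts) ||
          all(s > starts + widths + gap | s + w[i] + gap < starts)) {
        ok <- TRUE; break
      }
    }
    if (ok) { starts <- c(starts, s); widths <- c(widths, w[i]) }
  }
  o <- order(starts)
  list(start = starts[o], width = widths[o])
}

# raised-cosine displacement pulse: contribution to the marker x-offset at the
# 5-s knots, with alternating sign so that consecutive knot-to-knot
# displacements peak at ~`amp` displacement units
event_offsets <- function(knot_times, start, width, amp) {
  env <- numeric(length(knot_times))
  inside <- knot_times >= start & knot_times <= start + width
  tau <- (knot_times[inside] - start) / width
  env[inside] <- 0.5 * (1 - cos(2 * pi * tau))
  (amp / 2) * env
}

#' Simulate one cross-reactivity trial with planted ground truth
#'
#' Generates marker coordinate tracks for a single mucus-application trial:
#' a control segment, an exposure pause and a response segment, sampled at the
#' native frame interval.  Contraction events are planted as raised-cosine
#' displacement pulses (alternating in direction, so the 5-s displacement
#' series shows a smooth single-peaked excursion of known amplitude) on a
#' noisy, slowly drifting baseline.  The planted event list and per-segment
#' true counts are returned alongside the tracks.
#'
#' @param params a [sim_params()] object.
#' @param trial_spec a list or one-row data frame with fields `trial_id`,
#'   `day`, `order_index`, `species` and optionally `control_position`
#'   (1 or 2 for the bracketing positive controls).
#' @param seed integer; if `NULL`, derived deterministically from
#'   `params$seed`, the day and the order position.
#' @param markers which of the three markers to simulate.
#' @return A list with components `tracks` (named list of marker-track data
#'   frames with columns `marker_id`, `time_s`, `x`, `y`), `truth` (list with
#'   `events` and per-marker `counts`, the planted ground truth) and
#'   `trial_spec`.
#' @examples
#' p <- sim_params(seed = 2)
#' tr <- simulate_trace(p, list(trial_id = "d01_t1", day = 1,
#'                              order_index = 1, species = "C_aspersum"))
#' head(tr$tracks$diverticulum)
#' tr$truth$counts
#' @export
simulate_trace <- function(params, trial_spec, seed = NULL,
                           markers = MARKERS) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  ts <- as.list(trial_spec)
  for (f in c("trial_id", "day", "order_index", "species"))
    if (is.null(ts[[f]])) stop("trial_spec is missing field '", f, "'")
  if (!ts$species %in% params$species_labels)
    stop("unknown species '", ts$species, "'")
  if (is.null(seed)) seed <- derive_seed(params$seed, ts$day, ts$order_index)
  set.seed(seed)

  dt <- params$dt_sample
  t_ctrl_end <- params$control_duration
  t_resp_start <- t_ctrl_end + params$pause_duration
  t_end <- t_resp_start + params$response_duration
  knots <- seq(0, t_end, by = dt)
  native_t <- seq(0, t_end, by = params$frame_interval)

  rate_resp <- params$event_rate_response[[ts$species]] *
    (params$response_duration / 600)
  if (identical(ts$control_position, 2) || identical(ts$control_position, 2L))
    rate_resp <- rate_resp + params$control2_inflation
  rate_ctrl <- params$event_rate_control * (params$control_duration / 600)

  base <- marker_base_positions()
  tracks <- list(); ev_all <- list(); cnt_all <- list()
  for (m in markers) {
    act <- if (m == "atrium") params$atrium_activity else 1
    n_c <- stats::rpois(1, rate_ctrl * act)
    n_r <- stats::rpois(1, rate_resp * act)
    w_c <- rtrunc_norm(n_c, params$event_duration_mean,
                       params$event_duration_sd, 20, 175)
    w_r <- rtrunc_norm(n_r, params$event_duration_mean,
                       params$event_duration_sd, 20, 175)
    pc <- place_events(n_c, w_c, params$control_duration,
                       params$min_event_gap)
    pr <- place_events(n_r, w_r, params$response_duration,
                       params$min_event_gap)
    starts <- c(pc$start, t_resp_start + pr$start)
    widths <- c(pc$width, pr$width)
    segs <- rep(c("control", "response"),
                c(length(pc$start), length(pr$start)))
    n_ev <- length(starts)
    # amplitudes truncated to [0.45, 1.4] x mean (and widths to >= 20 s above)
    # so that even the weakest, worst-phased planted event peaks above the
    # 25 % relative threshold set by the strongest one
    amps <- if (n_ev) rtrunc_norm(n_ev, params$amplitude_mean,
                                  params$amplitude_sd,
                                  0.45 * params$amplitude_mean,
                                  1.4 * params$amplitude_mean) else numeric(0)

    off <- numeric(length(knots))
    for (e in seq_len(n_ev))
      off <- off + event_offsets(knots, starts[e], widths[e], amps[e])
    # baseline jitter is planted in the displacement domain, like the events:
    # alternating-direction increments whose knot-to-knot displacement floor
    # scales with noise_sd (iid positional jitter would be differenced into a
    # heavy-tailed displacement floor instead)
    off <- off + abs(stats::rnorm(length(knots), 0, params$noise_sd)) / 2
    off <- off * (-1)^(seq_along(knots) - 1)

    drift <- params$drift_slope * knots +
      params$drift_sine_amp * sin(2 * pi * knots / params$drift_sine_period)
    bx <- base$x[base$marker_id == m]
    by <- base$y[base$marker_id == m]
    x5 <- bx + drift + off
    y5 <- rep(by, length(knots))

    tracks[[m]] <- data.frame(
      marker_id = m, time_s = native_t,
      x = stats::approx(knots, x5, xout = native_t)$y,
      y = stats::approx(knots, y5, xout = native_t)$y,
      stringsAsFactors = FALSE)

    ev_all[[m]] <- if (n_ev) data.frame(
      trial_id = ts$trial_id, marker_id = m, segment = segs,
      start_s = starts, end_s = starts + widths, peak_amplitude = amps,
      stringsAsFactors = FALSE) else NULL
    cnt_all[[m]] <- data.frame(
      trial_id = ts$trial_id, marker_id = m,
      n_control_true = length(pc$start), n_response_true = length(pr$start),
      induced_true = length(pr$start) - length(pc$start),
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev_all)
  if (is.null(events))
    events <- data.frame(trial_id = character(0), marker_id = character(0),
                         segment = character(0), start_s = numeric(0),
                         end_s = numeric(0), peak_amplitude = numeric(0))
  rownames(events) <- NULL
  out <- list(tracks = tracks,
              truth = list(events = events,
                           counts = do.call(rbind, cnt_all)),
              trial_spec = ts, seed = seed)
  class(out) <- "sim_trial"
  out
}

#' Simulate the trial order of one experimental day
#'
#' The focal species' mucus is used as positive control once at the beginning
#' and once at the end of the day; between the two controls, up to
#' `n_test_slots` other species are drawn without replacement in random order,
#' so each extract is used only once per day.
#'
#' @inheritParams simulate_trace
#' @param day_id integer day number.
#' @return Data frame with one row per trial: `trial_id`, `day`,
#'   `order_index`, `species`, `is_control`, `control_position`.
#' @examples
#' d <- simulate_day(sim_params(seed = 3), day_id = 1)
#' d$species
#' @export
simulate_day <- function(params, day_id, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) seed <- derive_seed(params$seed, day_id, 99L)
  set.seed(seed)
  pool <- setdiff(params$species_labels, params$focal_species)
  k <- min(params$n_test_slots, length(pool))
  mid <- sample(pool, k)
  species <- c(params$focal_species, mid, params$focal_species)
  n <- length(species)
  data.frame(
    trial_id = sprintf("d%02d_t%d", day_id, seq_len(n)),
    day = as.integer(day_id),
    order_index = seq_len(n),
    species = species,
    is_control = species == params$focal_species,
    control_position = c(1L, rep(NA_integer_, k), 2L),
    stringsAsFactors = FALSE)
}

#' Simulate a full multi-day trial design
#'
#' @inheritParams simulate_trace
#' @return Row-bound [simulate_day()] designs for `params$n_days` days.
#' @export
simulate_design <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  days <- lapply(seq_len(params$n_days), function(d)
    simulate_day(params, d, seed = derive_seed(seed, d, 99L)))
  do.call(rbind, days)
}

#' Simulate paired diverticulum length measurements
#'
#' Emulates the shortening assay: the diverticulum length is measured three
#' times on each side of the organ, before mucus addition (t = 0) and 15 min
#' later, around a true length that shrinks by the species' fractional
#' shortening effect.
#'
#' @inheritParams simulate_trace
#' @param species species whose mucus was applied.
#' @param trial_id identifier stored with the record.
#' @param L0_true optional true baseline length in mm (default drawn from the
#'   preparation-level distribution in `params`).
#' @param noise_sd optional override of the per-measurement noise sd, mm.
#' @return Long data frame `trial_id, species, timepoint, side, rep,
#'   length_mm` with 12 rows (2 time points x 2 sides x 3 replicates).
#' @examples
#' simulate_lengths(sim_params(), "E_vermiculata", L0_true = 29.1,
#'                  noise_sd = 0)
#' @export
simulate_lengths <- function(params, species, trial_id = "t1", seed = NULL,
                             L0_true = NULL, noise_sd = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!species %in% names(params$shortening_effect))
    stop("no shortening effect configured for species '", species, "'")
  eff <- params$shortening_effect[[species]]
  if (eff < 0 || eff >= 1) stop("shortening effect must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(L0_true))
    L0_true <- stats::rnorm(1, params$baseline_length_mean,
                            params$baseline_length_sd)
  if (is.null(noise_sd)) noise_sd <- params$length_noise_sd
  L15_true <- L0_true * (1 - eff)
  grid <- expand.grid(rep = 1:3, side = c("left", "right"),
                      timepoint = c("t0", "t15"), stringsAsFactors = FALSE)
  true_len <- ifelse(grid$timepoint == "t0", L0_true, L15_true)
  data.frame(trial_id = trial_id, species = species,
             timepoint = grid$timepoint, side = grid$side, rep = grid$rep,
             length_mm = true_len + stats::rnorm(nrow(grid), 0, noise_sd),
             stringsAsFactors = FALSE)
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Draws tip values from the multivariate normal with covariance
#' `sigma2 * V`, where `V[i, j]` is the shared root-to-tip path length of tips
#' i and j — the distribution a trait evolving by Brownian motion along the
#' tree attains.  Used to calibrate Blomberg's K (expected value 1 under
#' Brownian evolution).
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param seed optional integer seed.
#' @param root_state trait value at the root.
#' @return Named numeric vector of tip trait values.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' simulate_bm_traits(tr, sigma2 = 1, seed = 1)
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, seed = NULL,
                               root_state = 0) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (sum(tree$edge.length) == 0) stop("tree has zero total branch length")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  V <- ape::vcv(tree)
  n <- nrow(V)
  if (sigma2 == 0)
    return(stats::setNames(rep(root_state, n), rownames(V)))
  L <- tryCatch(chol(V), error = function(e)
    chol(V + diag(1e-10 * mean(diag(V)), n)))
  x <- root_state + sqrt(sigma2) * drop(t(L) %*% stats::rnorm(n))
  stats::setNames(x, rownames(V))
}

#' Render marker tracks into a synthetic grayscale frame stack
#'
#' Draws each marker as a dark square on a light background, with sub-pixel
#' edge anti-aliasing so that the intensity-weighted centroid of the square
#' equals the requested coordinate.  Image convention: origin top-left, `x`
#' along columns, `y` along rows.
#'
#' @param tracks list of marker-track data frames sharing the same `time_s`.
#' @param frame_size `c(width, height)` in pixels.
#' @param marker_px side of the marker square, pixels.
#' @param bg,fg background and marker intensities in `[0, 1]`.
#' @return A numeric array `[height, width, n_frames]` with attribute
#'   `time_s`.
#' @export
render_frames <- function(tracks, frame_size = c(80, 100), marker_px = 5,
                          bg = 0.9, fg = 0.1) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  times <- tracks[[1]]$time_s
  for (tr in tracks)
    if (!isTRUE(all.equal(tr$time_s, times)))
      stop("all tracks must share the same time grid")
  w <- frame_size[1]; h <- frame_size[2]; half <- marker_px / 2
  for (tr in tracks)
    if (any(tr$x - half < 0.5) || any(tr$x + half > w + 0.5) ||
        any(tr$y - half < 0.5) || any(tr$y + half > h + 0.5))
      stop("marker coordinates fall outside the frame")
  n <- length(times)
  stack <- array(bg, dim = c(h, w, n))
  cols <- seq_len(w); rows <- seq_len(h)
  for (k in seq_len(n)) {
    cov <- matrix(0, h, w)
    for (tr in tracks) {
      cx <- tr$x[k]; cy <- tr$y[k]
      ox <- pmin(cols + 0.5, cx + half) - pmax(cols - 0.5, cx - half)
      oy <- pmin(rows + 0.5, cy + half) - pmax(rows - 0.5, cy - half)
      ox <- pmin(pmax(ox, 0), 1); oy <- pmin(pmax(oy, 0), 1)
      cov <- pmax(cov, outer(oy, ox))
    }
    stack[, , k] <- bg - (bg - fg) * cov
  }
  attr(stack, "time_s") <- times
  stack
}
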