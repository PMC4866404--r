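# Marker tracking: dark-blob segmentation + nearest-neighbour linking.
# Stand-in for the GUI auto-tracker used on the original webcam recordings.

# segment dark markers in one frame; returns data.frame(x, y, size) of
# intensity-weighted component centroids (weights = darkness below background)
segment_markers <- function(frame, min_px = 2) {
  rng <- range(frame)
  if (diff(rng) == 0) return(data.frame(x = numeric(0), y = numeric(0),
                                        size = numeric(0)))
  inv <- (rng[2] - frame) / diff(rng)           # dark -> high, in [0, 1]
  th <- EBImage::otsu(EBImage::Image(inv))
  mask <- inv > th
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(lab)
  keep <- lab > 0
  if (!any(keep)) return(data.frame(x = numeric(0), y = numeric(0),
                                    size = numeric(0)))
  idx <- which(matrix(keep, nrow(frame)), arr.ind = TRUE)
  l <- lab[keep]
  w <- inv[keep]
  sw <- tapply(w, l, sum)
  xc <- tapply(w * idx[, 2], l, sum) / sw
  yc <- tapply(w * idx[, 1], l, sum) / sw
  sz <- tapply(w, l, length)
  out <- data.frame(x = as.numeric(xc), y = as.numeric(yc),
                    size = as.numeric(sz))
  out[out$size >= min_px, , drop = FALSE]
}

# one-to-one greedy assignment of detections to predicted positions
assign_nearest <- function(pred, det, radius) {
  n <- nrow(pred)
  res <- rep(NA_integer_, n)
  if (!nrow(det)) return(res)
  D <- outer(pred$x, det$x, "-")^2 + outer(pred$y, det$y, "-")^2
  D <- sqrt(D)
  repeat {
    m <- which(D == min(D), arr.ind = TRUE)[1, , drop = FALSE]
    if (D[m] > radius || !is.finite(D[m])) break
    res[m[1]] <- m[2]
    D[m[1], ] <- Inf
    D[, m[2]] <- Inf
    if (all(!is.finite(D))) break
  }
  res
}

#' Track dark markers through a frame stack
#'
#' Per frame, dark pixels are segmented with a relative (Otsu) threshold on
#' inverted intensity, connected components are reduced to intensity-weighted
#' centroids, and detections are linked to the previous marker positions by
#' one-to-one nearest-neighbour assignment, preserving marker identity across
#' frames.  A marker with no detection within `search_radius` is a gap; gaps
#' of up to `max_gap` consecutive frames are filled by linear interpolation,
#' and a track with more than 10 % gap frames is flagged unusable.
#'
#' @param stack numeric array `[height, width, n_frames]` (as produced by
#'   [render_frames()]), with optional attribute `time_s`.
#' @param n_markers number of markers to track (3 in the standard
#'   preparation: diverticulum, copulatory canal, atrium).
#' @param init_positions optional data frame `x, y` of first-frame positions;
#'   defaults to the `n_markers` largest components of the first frame.
#' @param search_radius maximum per-frame displacement in pixels.
#' @param max_gap longest run of lost frames bridged by interpolation.
#' @param marker_ids labels attached to the tracks, in `init_positions`
#'   order.
#' @return Named list of marker-track data frames (`marker_id`, `time_s`,
#'   `x`, `y`); each carries attributes `n_gaps` and `usable`.
#' @export
track_markers <- function(stack, n_markers = 3, init_positions = NULL,
                          search_radius = 10, max_gap = 3,
                          marker_ids = NULL) {
  stopifnot(length(dim(stack)) == 3)
  n <- dim(stack)[3]
  times <- attr(stack, "time_s")
  if (is.null(times)) times <- seq_len(n) - 1
  if (is.null(marker_ids))
    marker_ids <- if (n_markers == 3) MARKERS else
      paste0("marker", seq_len(n_markers))

  det0 <- segment_markers(stack[, , 1])
  if (nrow(det0) < n_markers)
    stop("first frame contains only ", nrow(det0), " markers, expected ",
         n_markers)
  if (is.null(init_positions)) {
    det0 <- det0[order(-det0$size), , drop = FALSE][seq_len(n_markers), ]
    det0 <- det0[order(det0$y, det0$x), ]
    cur <- det0[, c("x", "y")]
  } else {
    stopifnot(nrow(init_positions) == n_markers)
    hit <- assign_nearest(init_positions, det0, radius = Inf)
    cur <- det0[hit, c("x", "y")]
  }

  X <- matrix(NA_real_, n, n_markers)
  Y <- matrix(NA_real_, n, n_markers)
  X[1, ] <- cur$x; Y[1, ] <- cur$y
  last <- cur
  for (k in 2:n) {
    det <- segment_markers(stack[, , k])
    hit <- assign_nearest(last, det, search_radius)
    ok <- !is.na(hit)
    X[k, ok] <- det$x[hit[ok]]
    Y[k, ok] <- det$y[hit[ok]]
    last$x[ok] <- X[k, ok]
    last$y[ok] <- Y[k, ok]
  }

  out <- list()
  for (j in seq_len(n_markers)) {
    x <- X[, j]; y <- Y[, j]
    gaps <- is.na(x)
    if (any(gaps)) {
      runs <- rle(gaps)
      if (any(runs$values & runs$lengths > max_gap) ||
          gaps[1] || gaps[n]) {
        usable <- FALSE
      } else usable <- mean(gaps) <= 0.10
      x <- stats::approx(times[!gaps], x[!gaps], xout = times, rule = 2)$y
      y <- stats::approx(times[!gaps], y[!gaps], xout = times, rule = 2)$y
    } else usable <- TRUE
    tr <- data.frame(marker_id = marker_ids[j], time_s = times, x = x, y = y,
                     stringsAsFactors = FALSE)
    attr(tr, "n_gaps") <- sum(gaps)
    attr(tr, "usable") <- usable
    if (!usable)
      warning("marker '", marker_ids[j], "': ", sum(gaps),
              " gap frames; track flagged unusable")
    out[[marker_ids[j]]] <- tr
  }
  out
}

#' Resample a marker track onto the 5-s analysis grid
#'
#' The recording protocol analyses marker displacement every 5 s; this
#' resamples a natively sampled track onto the `0, dt, 2 dt, ...` grid by
#' linear interpolation (default) or nearest-sample lookup.
#'
#' @param track marker-track data frame (`time_s`, `x`, `y`).
#' @param dt grid spacing, seconds.
#' @param method `"linear"` or `"nearest"`.
#' @return Marker-track data frame on the regular grid.
#' @export
resample_5s <- function(track, dt = 5, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(all(c("time_s", "x", "y") %in% names(track)))
  t <- track$time_s
  if (any(diff(t) <= 0)) stop("track times must be strictly increasing")
  if (max(diff(t)) > dt)
    stop("native sampling interval exceeds the target grid spacing")
  if (max(t) - min(t) < dt) stop("track shorter than one grid interval")
  grid <- seq(0, floor(max(t) / dt) * dt, by = dt)
  grid <- grid[grid >= min(t)]
  if (method == "linear") {
    x <- stats::approx(t, track$x, xout = grid)$y
    y <- stats::approx(t, track$y, xout = grid)$y
  } else {
    idx <- vapply(grid, function(g) which.min(abs(t - g)), integer(1))
    x <- track$x[idx]; y <- track$y[idx]
  }
  data.frame(marker_id = track$marker_id[1], time_s = grid, x = x, y = y,
             stringsAsFactors = FALSE)
}
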