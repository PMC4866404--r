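# Shared fixtures and independent oracles used across the suite.

# displacement trace built directly from given control/response displacement
# values (5-s grid, standard protocol windows)
make_trace <- function(d_control, d_response, dt = 5, ...) {
  out <- data.frame(
    time_s = c(seq(dt, by = dt, length.out = length(d_control)),
               seq(900 + dt, by = dt, length.out = length(d_response))),
    d = c(d_control, d_response),
    segment = rep(c("control", "response"),
                  c(length(d_control), length(d_response))),
    stringsAsFactors = FALSE)
  attr(out, "dt") <- dt
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("displacement_trace", "data.frame")
  out
}

# flat-baseline displacement segment with raised-cosine bumps added at given
# sample indices (bump width in samples), used to plant unambiguous events
plant_bumps <- function(n, at, amp, width = 7) {
  d <- rep(0, n)
  for (i in seq_along(at)) {
    k <- seq(-(width %/% 2), width %/% 2)
    idx <- at[i] + k
    ok <- idx >= 1 & idx <= n
    d[idx[ok]] <- d[idx[ok]] +
      amp[i] * 0.5 * (1 + cos(pi * k[ok] / (width %/% 2 + 1)))
  }
  d
}

# independent brute-force contraction detector: plain scan over samples,
# quadratic merge loop; deliberately structured differently from the
# production rle-based implementation
brute_detect <- function(trace, threshold_frac = 0.25, min_sep = 15,
                         max_dur = 180) {
  rng <- range(trace$d)
  if (diff(rng) < 1e-8) return(NULL)
  thr <- rng[1] + threshold_frac * diff(rng)
  res <- NULL
  for (seg in unique(trace$segment)) {
    s <- trace[trace$segment == seg, ]
    ev <- list()
    i <- 1
    while (i <= nrow(s)) {
      if (s$d[i] > thr) {
        j <- i
        while (j < nrow(s) && s$d[j + 1] > thr) j <- j + 1
        ev[[length(ev) + 1]] <- list(start = s$time_s[i], end = s$time_s[j],
                                     peak = max(s$d[i:j]),
                                     pt = s$time_s[i:j][which.max(s$d[i:j])])
        i <- j + 1
      } else i <- i + 1
    }
    ev <- Filter(function(e) e$end - e$start <= max_dur, ev)
    repeat {
      if (length(ev) < 2) break
      merged <- FALSE
      gaps <- sapply(seq_len(length(ev) - 1), function(q)
        ev[[q + 1]]$pt - ev[[q]]$pt)
      if (min(gaps) < min_sep) {
        q <- which.min(gaps)
        a <- ev[[q]]; b <- ev[[q + 1]]
        keep <- if (a$peak >= b$peak) a else b
        keep$start <- min(a$start, b$start)
        keep$end <- max(a$end, b$end)
        ev[[q]] <- keep
        ev[[q + 1]] <- NULL
        merged <- TRUE
      }
      if (!merged) break
    }
    if (length(ev))
      res <- rbind(res, data.frame(
        segment = seg,
        start_s = sapply(ev, `[[`, "start"),
        end_s = sapply(ev, `[[`, "end"),
        peak_time_s = sapply(ev, `[[`, "pt"),
        peak_value = sapply(ev, `[[`, "peak")))
  }
  res
}

# brute-force Brownian covariance by explicit root-to-tip path sums
brute_vcv <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1
  path_edges <- function(tip) {
    e <- integer(0)
    node <- tip
    while (node != root) {
      row <- which(tree$edge[, 2] == node)
      e <- c(e, row)
      node <- tree$edge[row, 1]
    }
    e
  }
  paths <- lapply(seq_len(nt), path_edges)
  V <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt))
    for (j in seq_len(nt))
      V[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  V
}

# brute-force Blomberg K via brute_vcv and direct inversion
brute_k <- function(tree, x) {
  x <- x[tree$tip.label]
  V <- brute_vcv(tree)
  Vi <- solve(V)
  n <- length(x)
  a <- sum(Vi %*% x) / sum(Vi)
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(t(r) %*% Vi %*% r) / (n - 1)
  (mse0 / mse) / ((sum(diag(V)) - n / sum(Vi)) / (n - 1))
}

# minimal per-trial score table covering one day, for metrics tests
day_scores <- function(day = 1, organ = "diverticulum",
                       control_induced = c(1, 3),
                       test_species = c("T_pisana", "H_lucorum"),
                       test_induced = c(2, 0),
                       control_intensity = c(10, 14),
                       test_intensity = c(8, 5)) {
  k <- length(test_species)
  data.frame(
    trial_id = sprintf("d%02d_t%d", day, seq_len(k + 2)),
    organ = organ,
    species = c("C_aspersum", test_species, "C_aspersum"),
    day = day,
    order_index = seq_len(k + 2),
    n_control = 1,
    n_response = 1 + c(control_induced[1], test_induced, control_induced[2]),
    induced = c(control_induced[1], test_induced, control_induced[2]),
    intensity = c(control_intensity[1], test_intensity, control_intensity[2]),
    responded = c(control_induced[1], test_induced, control_induced[2]) > 0,
    stringsAsFactors = FALSE)
}
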