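test_that("parameter invariants are enforced", {
  expect_error(sim_params(control_duration = 601), "multiples")
  expect_error(sim_params(control_duration = 0), "positive")
  expect_error(sim_params(event_rate_control = -1), "non-negative")
  expect_error(sim_params(event_rate_response = c(C_aspersum = -2)),
               "non-negative")
  p <- sim_params()
  p$shortening_effect[1] <- 1
  expect_error(validate_sim_params(p), "\\[0, 1\\)")
  expect_warning(sim_params(event_duration_mean = 200), "180")
})

test_that("a rate-free noise-free simulation is flat and scores zero", {
  p <- sim_params(seed = 4, noise_sd = 0, drift_slope = 0,
                  drift_sine_amp = 0,
                  event_rate_control = 0,
                  event_rate_response = c(C_aspersum = 0))
  p$event_rate_response[] <- 0
  tr <- simulate_trace(p, list(trial_id = "t", day = 1, order_index = 1,
                               species = "C_aspersum"))
  expect_equal(nrow(tr$truth$events), 0)
  for (m in names(tr$tracks)) {
    expect_equal(diff(range(tr$tracks[[m]]$x)), 0)
    expect_equal(diff(range(tr$tracks[[m]]$y)), 0)
  }
  sc <- score_simulated_trial(tr, p)
  expect_equal(sc$n_control, rep(0L, 3))
  expect_equal(sc$n_response, rep(0L, 3))
})

test_that("the 10-min control segment yields 121 coordinate samples", {
  p <- sim_params(seed = 1)
  tr <- simulate_trace(p, list(trial_id = "t", day = 1, order_index = 1,
                               species = "C_aspersum"),
                       markers = "diverticulum")
  tr5 <- resample_5s(tr$tracks$diverticulum)
  expect_equal(sum(tr5$time_s <= 600), 121)
  trace <- displacement_series(tr5)
  expect_equal(sum(trace$segment == "control"), 120)
  expect_equal(sum(trace$segment == "response"), 120)
})

test_that("noise-free detection recovers planted counts exactly", {
  p <- sim_params(seed = 10, noise_sd = 0, drift_slope = 0,
                  drift_sine_amp = 0)
  seen_2_3 <- FALSE
  for (i in 1:30) {
    tr <- simulate_trace(p, list(trial_id = "t", day = i, order_index = 1,
                                 species = "C_aspersum"),
                         markers = "diverticulum")
    sc <- score_simulated_trial(tr, p)
    tru <- tr$truth$counts
    expect_equal(sc$n_control, tru$n_control_true)
    expect_equal(sc$n_response, tru$n_response_true)
    expect_equal(sc$induced, tru$induced_true)
    if (tru$n_control_true == 2 && tru$n_response_true == 3) {
      seen_2_3 <- TRUE
      expect_equal(sc$induced, 1L)
    }
  }
  expect_true(seen_2_3)  # the canonical 2-control / 3-response case occurred
})

test_that("daily design brackets unique random species with controls", {
  p <- sim_params(seed = 5)
  orders <- character(100)
  for (s in 1:100) {
    d <- simulate_day(p, day_id = 1, seed = s)
    expect_identical(d$species[1], p$focal_species)
    expect_identical(d$species[nrow(d)], p$focal_species)
    mid <- d$species[-c(1, nrow(d))]
    expect_lte(length(mid), p$n_test_slots)
    expect_false(any(duplicated(mid)))
    expect_false(p$focal_species %in% mid)
    expect_identical(d$control_position[c(1, nrow(d))], c(1L, 2L))
    orders[s] <- paste(mid, collapse = ",")
  }
  expect_gt(length(unique(orders)), 1)  # order really is randomized
})

test_that("generation is deterministic for identical parameters", {
  p <- sim_params(seed = 42, n_days = 2)
  a <- simulate_trace(p, list(trial_id = "t", day = 1, order_index = 2,
                              species = "T_pisana"))
  b <- simulate_trace(p, list(trial_id = "t", day = 1, order_index = 2,
                              species = "T_pisana"))
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_design(p), simulate_design(p))
  expect_identical(simulate_lengths(p, "T_pisana", seed = 3),
                   simulate_lengths(p, "T_pisana", seed = 3))
})

test_that("length simulation reproduces configured shortening exactly and in expectation", {
  p <- sim_params()
  # zero effect, zero noise: both time points identical
  p0 <- p; p0$shortening_effect["C_nemoralis"] <- 0
  rec <- shortening_records(simulate_lengths(p0, "C_nemoralis",
                                             L0_true = 25, noise_sd = 0))
  expect_equal(rec$delta_mm, 0)
  expect_equal(rec$delta_pct, 0)
  # the strongest configured effect: 0.196 of a 29.1 mm organ is a 5.7 mm,
  # 19.6 % reduction
  rec <- shortening_records(simulate_lengths(p, "E_vermiculata",
                                             L0_true = 29.1, noise_sd = 0))
  expect_equal(rec$delta_mm, 29.1 * 0.196, tolerance = 1e-12)
  expect_equal(rec$delta_mm, 5.7, tolerance = 0.01)
  expect_equal(rec$delta_pct, 19.6, tolerance = 1e-9)
  # Monte-Carlo: a 10 % effect is recovered within 2 SE over 200 organs
  p1 <- p; p1$shortening_effect["T_pisana"] <- 0.10
  set.seed(77)
  pct <- replicate(200, shortening_records(
    simulate_lengths(p1, "T_pisana", trial_id = "x"))$delta_pct)
  expect_lt(abs(mean(pct) - 10), 2 * stats::sd(pct) / sqrt(200))
})

test_that("Brownian trait simulation has the tree-implied covariance", {
  tree <- ape::read.tree(text = paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);"))
  expect_named(simulate_bm_traits(tree, sigma2 = 0, seed = 1),
               tree$tip.label)
  expect_equal(unname(simulate_bm_traits(tree, sigma2 = 0, root_state = 3)),
               rep(3, 8))
  set.seed(123)
  X <- t(replicate(4000, simulate_bm_traits(tree, sigma2 = 2)))
  V <- 2 * ape::vcv(tree)
  err <- max(abs(stats::cov(X) - V))
  expect_lt(err / max(V), 0.08)
  expect_error(simulate_bm_traits(ape::read.tree(text = "(A:0,B:0);")),
               "zero total branch length")
})

test_that("rendered frames are faithful and reject out-of-frame tracks", {
  tr <- data.frame(marker_id = "diverticulum", time_s = 0:4,
                   x = rep(10.3, 5), y = rep(12.7, 5))
  st <- render_frames(list(tr), frame_size = c(24, 24), marker_px = 5)
  expect_equal(dim(st), c(24, 24, 5))
  for (k in 2:5) expect_identical(st[, , k], st[, , 1])
  bad <- tr; bad$x <- 23.5
  expect_error(render_frames(list(bad), frame_size = c(24, 24)),
               "outside the frame")
  # three markers as in the standard preparation
  p <- sim_params(seed = 2, noise_sd = 0.2)
  sim <- simulate_trace(p, list(trial_id = "t", day = 1, order_index = 1,
                                species = "C_aspersum"))
  short <- lapply(sim$tracks, function(x) x[1:20, ])
  st3 <- render_frames(short, frame_size = c(100, 100))
  expect_equal(nrow(segment_markers(st3[, , 1])), 3)
})
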