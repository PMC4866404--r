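test_that("Steel test: null, sign and degenerate behaviour", {
  # treatment with the very same values as the control: Z = 0, p = 1
  s <- steel_many_one(c(1, 2, 3, 4), list(t = c(1, 2, 3, 4)), mode = "normal")
  expect_equal(s$table$Z, 0)
  expect_equal(s$table$p_adj, 1)
  # a treatment shifted below the control carries a negative Z
  set.seed(51)
  ctrl <- rnorm(19)
  s2 <- steel_many_one(ctrl, list(lo = rnorm(19, -2), same = rnorm(19)),
                       mode = "normal")
  expect_lt(s2$table$Z[s2$table$treatment == "lo"], 0)
  expect_lt(s2$table$p_adj[s2$table$treatment == "lo"], 0.001)
  expect_gt(s2$table$p_adj[s2$table$treatment == "same"], 0.2)
  # all pooled values identical: Z reported as 0 with a warning
  expect_warning(s3 <- steel_many_one(c(2, 2, 2), list(t = c(2, 2, 2)),
                                      mode = "normal"), "identical")
  expect_equal(s3$table$Z, 0)
  # contract violations
  expect_error(steel_many_one(c(1, 2), list()), "non-empty")
  expect_error(steel_many_one(c(1), list(t = c(1, 2))), "at least 2")
})

test_that("Steel permutation mode matches exhaustive enumeration", {
  # control {1,2,3} vs treatment {4,5,6}: of the 20 equally likely splits of
  # the pooled sample, only the observed one and its mirror reach |Z| as
  # large, so the exact two-sided p is 2/20 = 0.10
  combs <- utils::combn(6, 3)
  pool <- 1:6
  zs <- apply(combs, 2, function(idx) {
    st <- dartpulse:::steel_one(pool[-idx], pool[idx])
    (st$R - st$E) / sqrt(st$V)
  })
  obs <- zs[ncol(combs)]          # treatment = {4,5,6}
  p_exact <- mean(abs(zs) >= abs(obs) - 1e-12)
  expect_equal(p_exact, 0.10)
  sp <- steel_many_one(c(1, 2, 3), list(t = c(4, 5, 6)),
                       mode = "permutation", n_perm = 4000, seed = 7)
  expect_lt(abs(sp$table$p_adj - p_exact), 0.02)
  # normal approximation agrees roughly (it is crude at n = 3 + 3, about
  # one enumeration step of 1/20)
  sn <- steel_many_one(c(1, 2, 3), list(t = c(4, 5, 6)), mode = "normal")
  expect_lt(abs(sn$table$p_adj - p_exact), 0.06)
})

test_that("Steel normal and permutation modes agree on continuous data", {
  set.seed(52)
  ctrl <- rnorm(15)
  trts <- list(a = rnorm(15, 0.8), b = rnorm(15), c = rnorm(15, -0.5))
  sn <- steel_many_one(ctrl, trts, mode = "normal")
  sp <- steel_many_one(ctrl, trts, mode = "permutation", n_perm = 4000,
                       seed = 1)
  expect_equal(sn$table$Z, sp$table$Z)       # statistic is mode-independent
  expect_lt(max(abs(sn$table$p_adj - sp$table$p_adj)), 0.05)
  # Sidak fallback is at least as conservative as the MVN bound
  ss <- steel_many_one(ctrl, trts, mode = "normal", adjust = "sidak")
  expect_true(all(ss$table$p_adj >= sn$table$p_adj - 1e-10))
})

test_that("rank tests are invariant to strictly monotone transforms", {
  set.seed(53)
  ctrl <- rnorm(12)
  trts <- list(a = rnorm(12, 1), b = rnorm(12))
  f <- function(x) exp(x) + x^3
  s1 <- steel_many_one(ctrl, trts, mode = "normal")
  s2 <- steel_many_one(f(ctrl), lapply(trts, f), mode = "normal")
  expect_equal(s1$table$Z, s2$table$Z, tolerance = 1e-12)
  g <- list(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, f))$H,
               tolerance = 1e-12)
})

test_that("paired Wilcoxon matches the exact signed-rank distribution", {
  # identical pairs: p = 1
  x <- c(5, 3, 8, 1)
  expect_equal(wilcoxon_paired(x, x)$p.value, 1)
  # classic 10-pair data, no ties: enumerate all 2^10 sign assignments
  x <- c(125, 115, 130, 140, 140, 115, 140, 125, 140, 135)
  y <- c(110, 122, 125, 120, 140, 124, 123, 137, 135, 145)
  d <- (x - y)[x != y]
  m <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), m))
  W_all <- as.matrix(signs) %*% r
  E <- m * (m + 1) / 4
  p_exact <- mean(abs(W_all - E) >= abs(W_obs - E) - 1e-12)
  w <- wilcoxon_paired(x, y)
  expect_equal(w$statistic, W_obs)
  expect_lt(abs(w$p.value - p_exact), 0.05)
  # agrees with the base-R normal approximation without correction
  wb <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = FALSE)
  expect_equal(w$p.value, wb$p.value, tolerance = 1e-10)
  # direction: x below y gives negative Z
  set.seed(54)
  a <- rnorm(20); b <- a + abs(rnorm(20, 1))
  expect_lt(wilcoxon_paired(a, b)$Z, 0)
})

test_that("Kruskal-Wallis wrapper reproduces the rank formula", {
  g <- list(rep(4, 3), rep(4, 3))
  expect_equal(kruskal_wallis(g)$H, 0)
  # hand-computable 3-group example, no ties
  g <- list(c(1, 2, 5), c(3, 7, 8), c(4, 6, 9))
  r <- rank(unlist(g))
  Rj <- c(sum(r[1:3]), sum(r[4:6]), sum(r[7:9]))
  N <- 9
  H_hand <- 12 / (N * (N + 1)) * sum(Rj^2 / 3) - 3 * (N + 1)
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, H_hand, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_error(kruskal_wallis(list(1:5)), "2 groups")
})

test_that("chi-square responder test matches the closed form", {
  eq <- suppressWarnings(chi_square_responders(c(10, 10), c(20, 20)))
  expect_equal(eq$chisq, 0)
  # closed form on a hand-built 2x2 table
  a <- 3; b <- 16; c <- 33; d <- 25
  n <- a + b + c + d
  chi_hand <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  out <- chi_square_responders(c(a, b), c(c, d))
  expect_equal(out$chisq, chi_hand, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_warning(chi_square_responders(c(0, 10), c(0, 20)), "zero margin")
})

test_that("mixed ANOVA reproduces hand-computed split-plot sums of squares", {
  # balanced toy: 2 species x 4 subjects x 2 time points
  y0 <- c(10, 12, 11, 13,  9, 10, 11, 10)
  y15 <- c(8, 11, 10, 11,  9, 11, 10, 10)
  sp <- rep(c("A", "B"), each = 4)
  dat <- data.frame(trial_id = rep(paste0("s", 1:8), 2),
                    species = rep(sp, 2),
                    timepoint = rep(c("t0", "t15"), each = 8),
                    log_length = c(y0, y15))
  ma <- mixed_anova(dat)
  # hand decomposition: subject sums/differences
  u <- (y0 + y15) / 2
  d <- y15 - y0
  ss_between_sp <- 4 * sum((tapply(u, sp, mean) - mean(u))^2)
  ss_between_err <- sum((u - tapply(u, sp, mean)[sp])^2)
  F_sp_hand <- (ss_between_sp / 1) / (ss_between_err / 6)
  dbar <- tapply(d, sp, mean)
  sse_d <- sum((d - dbar[sp])^2)
  F_time_hand <- mean(dbar)^2 / ((sse_d / 6) * (1 / 4 + 1 / 4) / 4)
  F_int_hand <- (4 * sum((dbar - mean(dbar))^2)) / (sse_d / 6)
  expect_equal(ma$table$F[ma$table$effect == "Species"], F_sp_hand,
               tolerance = 1e-8)
  expect_equal(ma$table$F[ma$table$effect == "Time"], F_time_hand,
               tolerance = 1e-8)
  expect_equal(ma$table$F[ma$table$effect == "Time:Species"], F_int_hand,
               tolerance = 1e-8)
  expect_equal(ma$table$df1, c(1, 1, 1))
  expect_equal(ma$table$df2, c(6, 6, 6))
  # and against the base-R split-plot fit (balanced case)
  aa <- summary(stats::aov(log_length ~ species * timepoint +
                             Error(factor(trial_id)), data = dat))
  wi <- aa[["Error: Within"]][[1]]
  expect_equal(ma$table$F[2], wi["timepoint", "F value"], tolerance = 1e-8)
  expect_equal(ma$table$F[3], wi["species:timepoint", "F value"],
               tolerance = 1e-8)
})

test_that("mixed ANOVA simple effects give per-species paired LSD contrasts", {
  set.seed(55)
  n_per <- c(A = 6, B = 9, C = 5)
  dat <- do.call(rbind, lapply(names(n_per), function(s) {
    n <- n_per[[s]]
    base <- rnorm(n, 10)
    shift <- c(A = 0, B = -1, C = 0)[[s]]
    data.frame(trial_id = paste0(s, 1:n),
               species = s,
               timepoint = rep(c("t0", "t15"), each = n),
               log_length = c(base, base + shift + rnorm(n, 0, 0.2)))
  }))
  ma <- mixed_anova(dat)
  se <- ma$simple_effects
  expect_equal(se$n, unname(n_per[se$species]))
  expect_lt(se$p[se$species == "B"], 0.001)
  expect_gt(min(se$p[se$species != "B"]), 0.05)
  expect_lt(se$mean_diff[se$species == "B"], 0)
  # a subject missing one time point is dropped with a warning
  expect_warning(mixed_anova(dat[-1, ]), "missing a time point")
  # zero within-subject change: F_Time is exactly 0
  d2 <- dat
  d2$log_length[d2$timepoint == "t15"] <-
    d2$log_length[d2$timepoint == "t0"]
  expect_equal(mixed_anova(d2)$table$F[2], 0)
})

test_that("log-link GLMs have the analytic closed forms and AICc", {
  # one-level Poisson: intercept = log of the sample mean
  d1 <- data.frame(y = c(0, 1, 2, 3, 6), g = "a")
  f1 <- glm_fit(y ~ 1, d1, family = "poisson")
  expect_equal(unname(coef(f1)), log(mean(d1$y)), tolerance = 1e-8)
  # two-level Poisson: fitted means equal group means
  d2 <- data.frame(y = c(1, 2, 3, 7, 9, 11), g = rep(c("a", "b"), each = 3))
  f2 <- glm_fit(y ~ g, d2, family = "poisson")
  expect_equal(unname(coef(f2)), c(log(2), log(9) - log(2)),
               tolerance = 1e-8)
  # AICc identity
  k <- attr(stats::logLik(f2), "df")
  expect_equal(attr(f2, "aicc"),
               stats::AIC(f2) + 2 * k * (k + 1) / (nrow(d2) - k - 1))
  # gaussian log-link recovers log group means
  d3 <- data.frame(y = c(2, 2.2, 1.8, 9.5, 10.5, 10),
                   g = rep(c("a", "b"), each = 3))
  f3 <- glm_fit(y ~ g, d3, family = "gaussian-log")
  expect_equal(unname(coef(f3)[1]), log(2), tolerance = 1e-6)
  expect_equal(unname(sum(coef(f3))), log(10), tolerance = 1e-6)
  expect_error(glm_fit(y ~ 1, data.frame(y = c(-1, 2)), family = "poisson"),
               "negative counts")
})

test_that("AICc model comparison discards a pure-noise order factor", {
  set.seed(56)
  sp <- sample(LETTERS[1:8], 150, replace = TRUE)
  prev <- sample(LETTERS[1:8], 150, replace = TRUE)
  y <- rpois(150, exp(0.5 + 0.3 * (sp %in% c("A", "B"))))
  d <- data.frame(n_response = y, species = sp, prev_species = prev)
  cmp <- compare_order_models(d, "n_response", family = "poisson")
  expect_equal(cmp$preferred, "n_response ~ species")
  expect_lt(cmp$table$aicc[1], cmp$table$aicc[2])
})

test_that("one-way ANOVA matches its closed form and is well calibrated", {
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(one_way_anova(rep(c(1, 2, 3), 3), g)$F, 0)
  set.seed(57)
  y <- rnorm(9)
  a <- one_way_anova(y, g)
  gm <- tapply(y, g, mean)
  ssb <- 3 * sum((gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  expect_equal(a$F, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
  expect_equal(c(a$df1, a$df2), c(2, 6))
  # null p-values are uniform
  ps <- replicate(400, one_way_anova(rnorm(30), rep(1:5, each = 6))$p.value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
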