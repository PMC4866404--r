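# Inference layer.  The Steel many-one rank test (the nonparametric analogue
# of Dunnett's many-to-one comparison) and the paired signed-rank Z are
# implemented from first principles; textbook tests (Kruskal-Wallis,
# chi-square, one-way ANOVA, GLM fitting) delegate to stats.

# rank-sum statistic, expectation and tie-corrected variance for one
# control-vs-treatment midrank comparison
steel_one <- function(control, treatment) {
  pooled <- c(control, treatment)
  N <- length(pooled)
  n0 <- length(control); n1 <- length(treatment)
  r <- rank(pooled)
  R <- sum(r[(n0 + 1):N])
  E <- n1 * (N + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  V <- n0 * n1 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  list(R = R, E = E, V = V)
}

# P(max_j |Z_j| <= c) for k equicorrelated standard normals (correlation rho),
# by integrating out the shared factor
pmax_abs_equicorr <- function(c, k, rho) {
  if (k == 1 || rho <= 0)
    return((2 * stats::pnorm(c) - 1)^k)
  s <- sqrt(1 - rho)
  f <- function(u)
    stats::dnorm(u) *
      (stats::pnorm((c - sqrt(rho) * u) / s) -
         stats::pnorm((-c - sqrt(rho) * u) / s))^k
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
}

pmax_one_sided_equicorr <- function(c, k, rho) {
  if (k == 1 || rho <= 0) return(stats::pnorm(c)^k)
  s <- sqrt(1 - rho)
  f <- function(u)
    stats::dnorm(u) * stats::pnorm((c - sqrt(rho) * u) / s)^k
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
}

#' Steel many-one rank test (nonparametric comparison with a control)
#'
#' Compares each of several treatment samples with a shared control by
#' midranking each pooled (control, treatment) pair and standardizing the
#' treatment rank sum with its tie-corrected null moments.  The sign
#' convention follows the rank sum: a treatment stochastically smaller than
#' the control yields a negative Z.  Family-wise adjusted p-values account for
#' the k simultaneous comparisons sharing one control, either through the
#' equicorrelated multivariate-normal bound (`mode = "normal"`, correlation
#' `sqrt(n_i n_j / ((n0 + n_i)(n0 + n_j)))` averaged over pairs; a
#' conservative Sidak adjustment is available via `adjust = "sidak"`) or by
#' joint permutation of the group labels (`mode = "permutation"`, which also
#' serves as the small-sample oracle).
#'
#' @param control numeric vector, control sample (n >= 2).
#' @param treatments named list of numeric treatment samples (each n >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param mode `"auto"` (normal approximation unless any sample has fewer
#'   than 6 observations), `"normal"` or `"permutation"`.
#' @param adjust `"mvn"` for the multivariate-normal bound, `"sidak"` for the
#'   Sidak fallback (normal mode only).
#' @param n_perm permutations for `mode = "permutation"`.
#' @param seed optional seed for the permutation mode.
#' @return Object of class `steel_test`: a list with a per-treatment `table`
#'   (`treatment`, `n`, `rank_sum`, `Z`, `p_adj`) and metadata.
#' @examples
#' set.seed(1)
#' ctrl <- rnorm(10)
#' trts <- list(shifted = rnorm(10, -1.5), same = rnorm(10))
#' steel_many_one(ctrl, trts)
#' @export
steel_many_one <- function(control, treatments,
                           alternative = c("two.sided", "less", "greater"),
                           mode = c("auto", "normal", "permutation"),
                           adjust = c("mvn", "sidak"),
                           n_perm = 5000, seed = NULL) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (!is.list(treatments) || length(treatments) == 0)
    stop("'treatments' must be a non-empty named list")
  if (is.null(names(treatments)) || any(names(treatments) == ""))
    names(treatments) <- paste0("trt", seq_along(treatments))
  if (length(control) < 2 || any(lengths(treatments) < 2))
    stop("control and every treatment need at least 2 observations")
  k <- length(treatments)
  n0 <- length(control)
  if (mode == "auto")
    mode <- if (min(n0, min(lengths(treatments))) < 6) "permutation" else
      "normal"

  zs <- numeric(k); Rs <- numeric(k); degenerate <- logical(k)
  for (i in seq_len(k)) {
    st <- steel_one(control, treatments[[i]])
    Rs[i] <- st$R
    if (st$V <= 0) {
      warning("all pooled values identical for treatment '",
              names(treatments)[i], "'; Z reported as 0")
      zs[i] <- 0; degenerate[i] <- TRUE
    } else zs[i] <- (st$R - st$E) / sqrt(st$V)
  }

  ni <- lengths(treatments)
  lam <- sqrt(ni / (ni + n0))
  rho <- if (k > 1) mean(tcrossprod(lam)[upper.tri(diag(k))]) else 0

  if (mode == "normal") {
    p <- vapply(seq_len(k), function(i) {
      z <- zs[i]
      if (degenerate[i]) return(1)
      switch(alternative,
        two.sided = {
          p1 <- 2 * stats::pnorm(-abs(z))
          if (adjust == "sidak") 1 - (1 - p1)^k
          else 1 - pmax_abs_equicorr(abs(z), k, rho)
        },
        less = {
          p1 <- stats::pnorm(z)
          if (adjust == "sidak") 1 - (1 - p1)^k
          else 1 - pmax_one_sided_equicorr(-z, k, rho)
        },
        greater = {
          p1 <- stats::pnorm(-z)
          if (adjust == "sidak") 1 - (1 - p1)^k
          else 1 - pmax_one_sided_equicorr(z, k, rho)
        })
    }, numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pooled <- c(control, unlist(treatments, use.names = FALSE))
    sizes <- c(n0, ni)
    idx_end <- cumsum(sizes)
    idx_start <- idx_end - sizes + 1
    stat_perm <- function(v) {
      ctl <- v[idx_start[1]:idx_end[1]]
      vapply(seq_len(k), function(i) {
        st <- steel_one(ctl, v[idx_start[i + 1]:idx_end[i + 1]])
        if (st$V <= 0) 0 else (st$R - st$E) / sqrt(st$V)
      }, numeric(1))
    }
    extreme <- switch(alternative,
                      two.sided = function(zp) max(abs(zp)),
                      less = function(zp) min(zp),
                      greater = function(zp) max(zp))
    obs_stat <- switch(alternative,
                       two.sided = abs(zs), less = zs, greater = zs)
    perm_max <- vapply(seq_len(n_perm), function(b)
      extreme(stat_perm(sample(pooled))), numeric(1))
    p <- vapply(seq_len(k), function(i) {
      hit <- switch(alternative,
                    two.sided = perm_max >= obs_stat[i] - 1e-12,
                    less = perm_max <= obs_stat[i] + 1e-12,
                    greater = perm_max >= obs_stat[i] - 1e-12)
      (1 + sum(hit)) / (n_perm + 1)
    }, numeric(1))
  }

  out <- list(table = data.frame(treatment = names(treatments), n = ni,
                                 rank_sum = Rs, Z = zs,
                                 p_adj = pmin(p, 1), row.names = NULL,
                                 stringsAsFactors = FALSE),
              control_n = n0, k = k, mode = mode, adjust = adjust,
              rho = rho, alternative = alternative)
  class(out) <- "steel_test"
  out
}

#' @export
print.steel_test <- function(x, ...) {
  cat("Steel many-one rank test (", x$k, " treatments vs control, n0 = ",
      x$control_n, ")\n", sep = "")
  cat("mode:", x$mode,
      if (x$mode == "normal") paste0("(", x$adjust, ", rho = ",
                                     signif(x$rho, 3), ")"),
      " alternative:", x$alternative, "\n")
  tab <- x$table
  tab$Z <- round(tab$Z, 3)
  tab$p_adj <- signif(tab$p_adj, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Paired Wilcoxon signed-rank test with normal approximation
#'
#' Signed-rank test for paired observations reporting the standardized Z the
#' study's software prints: zero differences are dropped, absolute
#' differences are midranked, and the positive-rank sum is standardized with
#' the tie-corrected variance.  Negative Z means `x` tends to be smaller than
#' `y`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return List with `statistic` (positive-rank sum), `Z`, `p.value`
#'   (two-sided) and `n_used` (non-zero differences).
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(list(statistic = 0, Z = 0, p.value = 1, n_used = 0))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  E <- m * (m + 1) / 4
  ties <- table(abs(d))
  V <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  if (V <= 0) return(list(statistic = W, Z = 0, p.value = 1, n_used = m))
  Z <- (W - E) / sqrt(V)
  list(statistic = W, Z = Z, p.value = 2 * stats::pnorm(-abs(Z)),
       n_used = m)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, chi-square
#' reference with k - 1 d.f.), returning the pieces the pipeline reports.
#'
#' @param values numeric vector, or a list of group samples.
#' @param groups grouping factor (ignored when `values` is a list).
#' @return List with `H`, `df` and `p.value`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    if (length(values) < 2) stop("need at least 2 groups")
    k <- length(values)
    all_tied <- length(unique(unlist(values))) == 1
    kt <- if (!all_tied) stats::kruskal.test(values)
  } else {
    if (length(unique(groups)) < 2) stop("need at least 2 groups")
    k <- length(unique(groups))
    all_tied <- length(unique(values)) == 1
    kt <- if (!all_tied) stats::kruskal.test(values, as.factor(groups))
  }
  if (all_tied)   # every observation identical: no rank variation at all
    return(list(H = 0, df = k - 1, p.value = 1))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Chi-square comparison of responder percentages
#'
#' Pearson chi-square (1 d.f., no continuity correction) on the 2x2 table of
#' (responded, did not respond) counts for one species' mucus versus the
#' pooled positive controls.
#'
#' @param species_counts `c(responded, not_responded)` for the species.
#' @param control_counts `c(responded, not_responded)` for the control.
#' @return List with `chisq`, `df` (= 1) and `p.value`.
#' @export
chi_square_responders <- function(species_counts, control_counts) {
  stopifnot(length(species_counts) == 2, length(control_counts) == 2)
  tab <- rbind(species = species_counts, control = control_counts)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in the 2x2 responder table; chi-square undefined")
    return(list(chisq = NA_real_, df = 1L, p.value = NA_real_))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}

#' Split-plot (mixed) ANOVA for two repeated measurements
#'
#' Mixed ANOVA with one between-subject factor (Species) and one
#' within-subject factor (Time, two levels), as used for the paired
#' diverticulum lengths.  With two time points the design decomposes exactly:
#' the between stratum is a one-way ANOVA on the subject means, the within
#' stratum tests the per-subject differences.  Unbalanced group sizes are
#' handled with Type-III-style hypotheses (the Time main effect tests the
#' unweighted mean of the species' Time effects).  When the interaction is of
#' interest, per-species simple effects of Time are reported as Fisher-LSD
#' contrasts: unadjusted t-tests against the pooled within-subject error.
#'
#' @param data data frame in long format.
#' @param response,time,species,subject column names.
#' @return Object of class `mixed_anova`: `table` with rows Species, Time and
#'   Time:Species (`df1`, `df2`, `F`, `p`), and `simple_effects` with the
#'   per-species Time contrasts (`species`, `n`, `mean_diff`, `t`, `df`,
#'   `p`).  `mean_diff` is second time level minus first (factor order).
#' @export
mixed_anova <- function(data, response = "log_length", time = "timepoint",
                        species = "species", subject = "trial_id") {
  stopifnot(all(c(response, time, species, subject) %in% names(data)))
  tl <- sort(unique(as.character(data[[time]])))
  if (length(tl) != 2) stop("the Time factor must have exactly 2 levels")
  w <- stats::reshape(
    data.frame(subj = data[[subject]], sp = as.character(data[[species]]),
               tp = as.character(data[[time]]), y = data[[response]],
               stringsAsFactors = FALSE),
    idvar = c("subj", "sp"), timevar = "tp", direction = "wide")
  y1 <- w[[paste0("y.", tl[1])]]
  y2 <- w[[paste0("y.", tl[2])]]
  ok <- stats::complete.cases(y1, y2)
  if (any(!ok))
    warning(sum(!ok), " subject(s) missing a time point dropped")
  w <- w[ok, ]; y1 <- y1[ok]; y2 <- y2[ok]
  sp <- factor(w$sp)
  s <- nlevels(sp); N <- length(y1)
  if (N <= s) stop("no residual degrees of freedom")

  u <- (y1 + y2) / 2                # carries the between-subject information
  d <- y2 - y1                      # carries the within-subject information

  a_b <- stats::anova(stats::lm(u ~ sp))
  F_sp <- a_b$`F value`[1]; df_b <- a_b$Df

  dbar <- tapply(d, sp, mean)
  n_s <- as.numeric(table(sp))
  sse_d <- sum((d - dbar[sp])^2)
  mse_d <- sse_d / (N - s)
  # Type-III Time main effect: unweighted mean of per-species Time effects
  mhat <- mean(dbar)
  F_time <- if (mse_d > 0)
    mhat^2 / (mse_d * sum(1 / n_s) / s^2) else
      if (mhat == 0) 0 else Inf
  ss_int <- sum(n_s * (dbar - stats::weighted.mean(dbar, n_s))^2)
  F_int <- if (mse_d > 0) (ss_int / (s - 1)) / mse_d else
    if (ss_int == 0) 0 else Inf

  tab <- data.frame(
    effect = c("Species", "Time", "Time:Species"),
    df1 = c(s - 1, 1, s - 1),
    df2 = c(N - s, N - s, N - s),
    F = c(F_sp, F_time, F_int),
    stringsAsFactors = FALSE)
  tab$p <- stats::pf(tab$F, tab$df1, tab$df2, lower.tail = FALSE)

  t_s <- dbar / sqrt(mse_d / n_s)
  se_tab <- data.frame(species = names(dbar), n = n_s,
                       mean_diff = as.numeric(dbar),
                       t = as.numeric(t_s), df = N - s,
                       p = 2 * stats::pt(-abs(t_s), N - s),
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- list(table = tab, simple_effects = se_tab, time_levels = tl,
              n_subjects = N, mse_within = mse_d)
  class(out) <- "mixed_anova"
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed (split-plot) ANOVA:", x$n_subjects, "subjects, Time =",
      paste(x$time_levels, collapse = " vs "), "\n")
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("Simple effects of Time (Fisher LSD, unadjusted):\n")
  se <- x$simple_effects
  se$mean_diff <- round(se$mean_diff, 4)
  se$t <- round(se$t, 3); se$p <- signif(se$p, 3)
  print(se, row.names = FALSE)
  invisible(x)
}

#' Second-order Akaike information criterion
#'
#' `AICc = AIC + 2k(k + 1)/(n - k - 1)` with `k` the number of estimated
#' parameters (including the dispersion for Gaussian models).
#'
#' @param fit a fitted model with [stats::logLik()] and [stats::AIC()]
#'   methods.
#' @return Numeric AICc.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) stop("too few observations for AICc")
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Log-link GLM for contraction counts or intensities
#'
#' Fits the order-effect models: a Poisson GLM with log link for contraction
#' counts, or a Gaussian GLM with log link for intensities (initialized at
#' the log response clipped below at `epsilon`, since intensities can be
#' arbitrarily close to zero).
#'
#' @param formula model formula.
#' @param data data frame.
#' @param family `"poisson"` (log link) or `"gaussian-log"`.
#' @param epsilon lower clip applied to the response when initializing the
#'   Gaussian log-link fit.
#' @return The fitted [stats::glm()] object with an `aicc` attribute.
#' @export
glm_fit <- function(formula, data, family = c("poisson", "gaussian-log"),
                    epsilon = 1e-6) {
  family <- match.arg(family)
  y <- stats::model.response(stats::model.frame(formula, data))
  if (family == "poisson") {
    if (any(y < 0)) stop("negative counts are not allowed for the Poisson model")
    fit <- stats::glm(formula, data = data, family = stats::poisson("log"))
  } else {
    fit <- do.call(stats::glm, list(formula = formula, data = data,
                                    family = stats::gaussian("log"),
                                    etastart = log(pmax(y, epsilon))))
  }
  if (!fit$converged)
    stop("IRLS did not converge after ", fit$iter, " iterations")
  attr(fit, "aicc") <- aicc(fit)
  fit
}

#' Compare order-effect models by AICc
#'
#' Fits the response with Species alone and with Species plus the species
#' tested immediately before (the order-effect factor), and reports both
#' AICc values; a lower AICc for the simpler model indicates the data points
#' are independent of testing order.
#'
#' @param data score table with columns named by `species_col` and
#'   `prev_col`.
#' @param response response column name.
#' @param family passed to [glm_fit()].
#' @param species_col,prev_col factor column names.
#' @return List with both fits and a `table` of `model`, `df`, `aicc`,
#'   `delta` plus the name of the preferred (lower-AICc) model.
#' @export
compare_order_models <- function(data, response, family = "poisson",
                                 species_col = "species",
                                 prev_col = "prev_species") {
  f1 <- stats::as.formula(paste(response, "~", species_col))
  f2 <- stats::as.formula(paste(response, "~", species_col, "+", prev_col))
  keep <- !is.na(data[[prev_col]])
  d <- data[keep, , drop = FALSE]
  m1 <- glm_fit(f1, d, family = family)
  m2 <- glm_fit(f2, d, family = family)
  tab <- data.frame(
    model = c(paste(response, "~", species_col),
              paste(response, "~", species_col, "+", prev_col)),
    df = c(attr(stats::logLik(m1), "df"), attr(stats::logLik(m2), "df")),
    aicc = c(attr(m1, "aicc"), attr(m2, "aicc")),
    stringsAsFactors = FALSE)
  tab$delta <- tab$aicc - min(tab$aicc)
  list(without_prev = m1, with_prev = m2, table = tab,
       preferred = tab$model[which.min(tab$aicc)])
}

#' One-way ANOVA
#'
#' Standard between/within decomposition via [stats::lm()]; used e.g. to
#' check that baseline diverticulum length does not drift across trials.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @return List with `F`, `df1`, `df2` and `p.value`.
#' @export
one_way_anova <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  a <- stats::anova(stats::lm(values ~ g))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p.value = a$`Pr(>F)`[1])
}
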