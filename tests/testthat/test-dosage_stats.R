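test_that("log-log slope estimates dosage sensitivity", {
  d <- rep(c(0.5, 1, 2), each = 5)
  y <- 3 * d^0.2
  fit <- suppressWarnings(loglog_sensitivity(d, y))  # exact fit warns in lm
  expect_equal(fit$slope, 0.2, tolerance = 1e-10)
  expect_equal(fit$ci68, 0, tolerance = 1e-8)

  # measured mean gradient widths across the three dosages (frozen OLS value)
  fit <- loglog_sensitivity(c(0.5, 1, 2), c(0.13, 0.15, 0.17))
  expect_equal(fit$slope, 0.1935116, tolerance = 1e-6)

  # dosage-scaling null: a width independent of dosage
  fit <- suppressWarnings(loglog_sensitivity(d, rep(0.15, length(d))))
  expect_equal(fit$slope, 0, tolerance = 1e-12)

  expect_warning(loglog_sensitivity(c(0.5, 1, 2), c(1, -1, 2)),
                 "non-positive")
  expect_error(loglog_sensitivity(c(1, 1), c(2, 3)), "distinct")
})

test_that("qPCR weighted summaries follow the stated formulas", {
  # equal technical SDs: weighted mean reduces to the arithmetic mean
  tab <- data.frame(genotype = "2x",
                    replicate = rep(c("a", "b", "c"), each = 3),
                    delta_ct = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
  st <- qpcr_weighted_stats(tab)
  expect_equal(st$mean, mean(c(2, 3, 7)))
  expect_equal(st$n, 3L)

  # hand-substituted two-replicate case: y = (1, 3), s = (1, 1)
  # w = (1/2, 1/2); ybar = 2; S = sqrt( sum w (y-ybar)^2 / (n-1) / (sum(w)/n) )
  #   = sqrt( (0.5 + 0.5) / 1 / 0.5 ) = sqrt(2)
  tab <- data.frame(genotype = "g",
                    replicate = rep(c("a", "b"), each = 2),
                    delta_ct = c(1 - 0.5, 1 + 0.5, 3 - 0.5, 3 + 0.5))
  st <- qpcr_weighted_stats(tab)
  expect_equal(st$mean, 2)
  expect_equal(st$sem, sqrt(2))
  # the conventional alternative drops the 1/(mean weight) factor
  st2 <- qpcr_weighted_stats(tab, sem = "conventional")
  expect_equal(st2$sem, 1)

  # single retained replicate: s.e.m. undefined
  tab1 <- data.frame(genotype = "g", replicate = "a", delta_ct = c(1, 2))
  expect_true(is.na(qpcr_weighted_stats(tab1)$sem))

  # replicates with fewer than two valid wells are discarded
  tab <- data.frame(genotype = "g",
                    replicate = c("a", "a", "b", "b"),
                    delta_ct = c(1, 2, 3, NA))
  expect_equal(qpcr_weighted_stats(tab)$n, 1L)
})

test_that("relative abundance follows the two-to-the-minus-ddCT rule", {
  st <- data.frame(genotype = c("1x", "2x", "4x"), mean = c(1, 0, -1),
                   sem = c(0.2, 0.1, 0.3), n = 9L)
  ra <- relative_abundance(st)
  expect_equal(ra$fold, c(0.5, 1, 2))
  expect_equal(ra$fold_sem[2], 0)
  expect_equal(ra$fold_sem[1], 0.5 * log(2) * sqrt(0.2^2 + 0.1^2))
  expect_error(relative_abundance(st, reference = "8x"), "reference")
})

test_that("canonical amplitude curve recovers planted peaks and stretches time", {
  shape <- function(tau) sin(pi * tau / 2)^2
  mk <- function(peak, Tnc, t0 = 10) {
    time <- seq(t0 - 3, t0 + Tnc + 3, by = 0.5)
    tau <- pmin(1, pmax(0, (time - t0) / Tnc))
    list(time = time, amplitude = peak * shape(tau), t_start = t0,
         t_gastr = t0 + Tnc)
  }
  # identical traces: canonical equals the normalized trace (up to the
  # linear interpolation of the sampled curve), peak is the max
  cc <- canonical_amplitude_curve(list(mk(2, 60), mk(2, 60)))
  expect_lt(max(abs(cc$curve$value - shape(cc$curve$tau))), 1e-3)
  expect_equal(cc$peaks, c(2, 2), tolerance = 1e-3)

  # a 30-minute nc14 is stretched onto the same unit axis
  cc <- canonical_amplitude_curve(list(mk(1, 30), mk(1, 60)))
  expect_lt(max(abs(cc$curve$value - shape(cc$curve$tau))), 2e-3)

  # planted peaks with shared shape and 5% noise recovered within 3%
  set.seed(4)
  traces <- lapply(c(1, 2, 4), function(pk) {
    tr <- mk(pk, runif(1, 40, 70))
    tr$amplitude <- tr$amplitude + rnorm(length(tr$amplitude), 0, 0.05 * pk)
    tr
  })
  cc <- canonical_amplitude_curve(traces)
  expect_equal(cc$peaks, c(1, 2, 4), tolerance = 0.03)

  # traces without demarcations are excluded
  bad <- mk(1, 50)
  bad$t_gastr <- NULL
  cc <- canonical_amplitude_curve(list(mk(1, 50), mk(1, 60), bad))
  expect_equal(cc$excluded, 1L)
})

test_that("bootstrap ratios behave on degenerate and planted inputs", {
  b <- bootstrap_amplitude_ratios(c(2, 2, 2), c(4, 4, 4), n_boot = 100)
  expect_equal(b$mean, 0.5)
  expect_equal(b$sd, 0)

  set.seed(6)
  peaks <- rnorm(12, 1, 0.1)
  b <- bootstrap_amplitude_ratios(peaks, peaks, n_boot = 2000, seed = 2)
  expect_equal(b$mean, 1, tolerance = 0.05)

  # bootstrap-mean variability shrinks like 1/sqrt(n_boot)
  num <- rnorm(10, 0.5, 0.05)
  den <- rnorm(10, 1, 0.05)
  sd_of_mean <- function(nb) {
    sd(vapply(1:30, function(s)
      bootstrap_amplitude_ratios(num, den, n_boot = nb, seed = s)$mean,
      numeric(1)))
  }
  expect_equal(sd_of_mean(100) / sd_of_mean(1600), 4, tolerance = 0.5)
})

test_that("normal interval mass matches closed forms", {
  expect_equal(normal_range_probability(0, 1, -1, 1), 0.6826895,
               tolerance = 1e-6)
  expect_equal(normal_range_probability(1.7, 0.4, 1, 1.5), 0.27,
               tolerance = 0.01)
  expect_equal(normal_range_probability(3, 0.5, 3 - 5, 3), 0.5,
               tolerance = 1e-6)
  expect_error(normal_range_probability(0, -1, 0, 1), "sd")
})

test_that("amplitude-pair optimization recovers planted scalings", {
  x <- seq(0, 1, length.out = 301)
  curve <- data.frame(x = x, mean = exp(-x^2 / (2 * 0.15^2)) + 0.05)
  curves <- list("1x" = curve, "2x" = curve, "4x" = curve)
  obs <- border_observations()
  # identical curves and identical observations: optimum at (1, 1), SSE 0
  obs_same <- obs
  for (g in unique(obs$gene))
    obs_same$x_exp[obs_same$gene == g] <-
      obs$x_exp[obs$gene == g & obs$genotype == "2x"]
  fit <- optimize_amplitude_pair(curves, obs_same)
  expect_equal(fit$alpha_1x, 1)
  expect_equal(fit$alpha_4x, 1)
  expect_lt(fit$sse, 1e-12)

  # planted scalings (0.8, 1.1) recovered to grid resolution
  thetas <- vapply(unique(obs$gene), function(g)
    approx(x, curve$mean,
           xout = obs$x_exp[obs$gene == g & obs$genotype == "2x"])$y,
    numeric(1))
  obs_pl <- obs
  for (gi in seq_along(unique(obs$gene))) {
    g <- unique(obs$gene)[gi]
    for (geno in c("1x", "4x")) {
      a <- if (geno == "1x") 0.8 else 1.1
      b <- extract_border(a * curve$mean, thetas[gi], x = x)
      obs_pl$x_exp[obs_pl$gene == g & obs_pl$genotype == geno] <- b$x_b
    }
  }
  fit <- optimize_amplitude_pair(curves, obs_pl)
  expect_equal(fit$alpha_1x, 0.8, tolerance = 0.011)
  expect_equal(fit$alpha_4x, 1.1, tolerance = 0.011)

  # joint rescaling of every curve leaves the surface unchanged
  curves2 <- lapply(curves, function(cu) {
    cu$mean <- 3 * cu$mean
    cu
  })
  fit2 <- optimize_amplitude_pair(curves2, obs_pl)
  expect_equal(fit2$surface, fit$surface, tolerance = 1e-9)

  # infeasible region marks alpha_1x > 1 or alpha_4x < 1
  at <- function(a) which.min(abs(fit$alpha_grid - a))
  expect_false(fit$feasible[at(1.5), at(1.2)])
  expect_true(fit$feasible[at(0.8), at(1.2)])
})
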