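test_that("Gaussian-with-tail fit recovers noiseless parameters exactly", {
  truth <- empirical_params(alpha = 1, sigma = 0.15, m = -0.1, b = 0.4)
  prof <- grid_profile(truth)
  fit <- fit_dl_gradient(prof)
  expect_true(fit$converged)
  expect_equal(fit$A, 1, tolerance = 1e-6)
  expect_equal(fit$B, 0.4, tolerance = 1e-6)
  expect_equal(fit$M, -0.1, tolerance = 1e-6)
  expect_equal(fit$sigma, 0.15, tolerance = 1e-6)
  expect_equal(fit$mu, 0, tolerance = 1e-5)
  expect_equal(fit$gof, 1, tolerance = 1e-9)

  # pure noise never earns a usable goodness of fit
  set.seed(2)
  noise <- data.frame(x = seq(-1, 1, length.out = 101),
                      intensity = rnorm(101))
  expect_lt(fit_dl_gradient(noise)$gof, 0.7)

  expect_error(fit_dl_gradient(data.frame(x = 1:5 / 10, intensity = 1:5)),
               "at least 10")
})

test_that("fitting is equivariant under shifts and intensity scalings", {
  truth <- empirical_params(alpha = 1, sigma = 0.12, m = -0.08, b = 0.3)
  base <- fit_dl_gradient(grid_profile(truth))
  shifted <- fit_dl_gradient(grid_profile(truth, mu = 0.07))
  expect_equal(shifted$mu, base$mu + 0.07, tolerance = 1e-4)
  expect_equal(shifted$sigma, base$sigma, tolerance = 1e-4)

  scaled <- fit_dl_gradient(grid_profile(truth, scale = 3))
  expect_equal(scaled$A, 3 * base$A, tolerance = 1e-5)
  expect_equal(scaled$B, 3 * base$B, tolerance = 1e-5)
  expect_equal(scaled$M, 3 * base$M, tolerance = 1e-4)
  # normalized profiles coincide after scaling
  n1 <- normalize_profile(grid_profile(truth), base)
  n2 <- normalize_profile(grid_profile(truth, scale = 3), scaled)
  expect_equal(n1$intensity, n2$intensity, tolerance = 1e-5)
})

test_that("width estimation stays unbiased under multiplicative noise", {
  cfg <- synth_config(seed = 8, n_embryos = 30L, noise_cv = 0.05,
                      noise_add = 0, jitter_sd = 0)
  profs <- synth_embryo_profiles(cfg)
  p2x <- profs[profs$genotype == "2x", ]
  sigmas <- vapply(split(p2x, p2x$embryo_id),
                   function(p) fit_dl_gradient(p)$sigma, numeric(1))
  expect_equal(mean(sigmas), 0.15, tolerance = 0.02)
})

test_that("normalization maps the fitted landmarks to one and zero", {
  truth <- empirical_params(alpha = 2, sigma = 0.15, m = -0.1, b = 0.5)
  prof <- grid_profile(truth)
  fit <- fit_dl_gradient(prof)
  norm <- normalize_profile(prof, fit)
  # hand-computed: X = (I - B - 0.7 M) / A on a five-point check
  idx <- c(1, 51, 101, 151, 201)
  expect_equal(norm$intensity[idx],
               (prof$intensity[idx] - fit$B - 0.7 * fit$M) / fit$A)
  # peak-adjusted and basal-adjusted intensities
  expect_equal((fit$A + fit$B + 0.7 * fit$M - fit$B - 0.7 * fit$M) / fit$A, 1)
  bad <- fit
  bad$A <- -1
  expect_error(normalize_profile(prof, bad), "A <= 0")
})

test_that("grid averaging aligns by midline on the 301-point axis", {
  truth <- empirical_params()
  prof <- grid_profile(truth)
  fit <- fit_dl_gradient(prof)
  n <- normalize_profile(prof, fit)
  avg <- average_gradients(list(n, n, n))
  expect_equal(nrow(avg), 301L)
  inner <- abs(avg$x) <= 0.99
  expect_equal(avg$mean[inner],
               approx(n$x, n$intensity, xout = avg$x[inner])$y,
               tolerance = 1e-8)
  expect_true(all(avg$sd[inner] < 1e-12))

  # two profiles symmetric about a common mean average to the midpoint curve
  up <- n
  dn <- n
  up$intensity <- n$intensity + 0.1
  dn$intensity <- n$intensity - 0.1
  avg2 <- average_gradients(list(up, dn))
  expect_equal(avg2$mean[inner], avg$mean[inner], tolerance = 1e-12)

  # alignment: profiles with opposite midline offsets average to the aligned one
  pa <- grid_profile(truth, mu = 0.05)
  pb <- grid_profile(truth, mu = -0.05)
  fa <- fit_dl_gradient(pa)
  fb <- fit_dl_gradient(pb)
  avg3 <- average_gradients(list(normalize_profile(pa, fa),
                                 normalize_profile(pb, fb)))
  mid <- abs(avg3$x) <= 0.9
  expect_equal(avg3$mean[mid],
               approx(n$x, n$intensity, xout = avg3$x[mid])$y,
               tolerance = 1e-3)
  expect_true(any(avg3$edge))   # shifted profiles cannot cover both ends
})

test_that("canonical-template fits return half-max borders and honour the gof cutoff", {
  x <- seq(-1, 1, length.out = 201)
  # sharp sna-like pulse from the midline to 0.2
  sna <- data.frame(x = x,
                    intensity = canonical_profile(x, -0.2, 0.2, 0.005))
  fit <- fit_gene_borders(sna, "sna")
  expect_false(fit$excluded)
  expect_equal(fit$borders, 0.2, tolerance = 3e-3)

  # sog-like pulse spanning the measured wildtype domain
  sog <- data.frame(x = x,
                    intensity = 2 * canonical_profile(x, 0.19, 0.47, 0.005) + 0.1)
  fit <- fit_gene_borders(sog, "sog")
  expect_false(fit$excluded)
  expect_equal(fit$borders, c(0.19, 0.47), tolerance = 1e-3)

  # heavy noise is excluded by the goodness-of-fit cutoff
  set.seed(3)
  noisy <- data.frame(x = x, intensity = rnorm(201, 1, 1))
  expect_true(fit_gene_borders(noisy, "sna")$excluded)

  # equivariance: scaling intensity leaves the borders unchanged
  sog2 <- sog
  sog2$intensity <- 5 * sog$intensity
  expect_equal(fit_gene_borders(sog2, "sog")$borders, fit$borders,
               tolerance = 1e-6)
})

test_that("planted gene borders survive noise and are stable to the gof cutoff", {
  cfg <- synth_config(seed = 12, n_embryos = 10L, noise_cv = 0.10,
                      noise_add = 0.02)
  profs <- synth_gene_profiles(cfg)
  sna2x <- profs[profs$gene == "sna" & profs$genotype == "2x", ]
  ests <- lapply(c(0.7, 0.8, 0.9), function(cut) {
    fits <- lapply(split(sna2x, sna2x$embryo_id), fit_gene_borders,
                   gene = "sna", gof_cutoff = cut)
    keep <- !vapply(fits, function(f) f$excluded, logical(1))
    median(vapply(fits[keep], function(f) f$borders[1], numeric(1)))
  })
  expect_equal(ests[[2]], 0.20, tolerance = 0.05)
  # conclusions are insensitive to the exact cutoff
  expect_lt(max(abs(unlist(ests) - ests[[2]])), 0.005)
})
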