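test_that("Toll profile is Gaussian and ventrally restricted", {
  expect_equal(toll_profile(5, 0.15, 0), 5)
  expect_equal(toll_profile(5, 0.15, 0.15), 5 * exp(-1))
  expect_lt(toll_profile(5, 0.15, 1), 1e-15)
  expect_error(toll_profile(5, 0, 0.1), "phi_toll")
})

test_that("right-hand side reproduces limiting behaviours", {
  p <- mech_params(beta_o = 0, gamma = 0, n_compartments = 11L)
  d <- dl_rhs(rep(2, 11), rep(3, 11), p)
  expect_equal(d$du, rep(0, 11))
  expect_equal(d$dw, rep(0, 11))

  # saturated Toll: source into u is a2 * beta(x), independent of w
  p <- mech_params(beta_o = 4, kappa = 1e-8, gamma = 0, lambda_d = 0,
                   lambda_dc = 0, n_compartments = 11L)
  x <- seq(0, 1, length.out = 11L)
  d1 <- dl_rhs(rep(0, 11), rep(5, 11), p)
  d2 <- dl_rhs(rep(0, 11), rep(50, 11), p)
  expect_equal(d1$du, toll_profile(4, 0.15, x), tolerance = 1e-6)
  expect_equal(d1$du, d2$du, tolerance = 1e-6)

  # with a2 = a5 and a3 = a6 the elementwise sum telescopes to pure transport
  set.seed(7)
  p <- mech_params(lambda_d = 2, lambda_dc = 5, beta_o = 3, gamma = 0.7,
                   n_compartments = 21L)
  u <- runif(21)
  w <- runif(21)
  d <- dl_rhs(u, w, p)
  expect_equal(sum(d$du + d$dw), 0, tolerance = 1e-12)

  # transport operator is reflection-symmetric without the Toll source
  p0 <- mech_params(lambda_d = 2, lambda_dc = 5, beta_o = 0, gamma = 0.7,
                    n_compartments = 21L)
  d <- dl_rhs(u, w, p0)
  dr <- dl_rhs(rev(u), rev(w), p0)
  expect_equal(dr$du, rev(d$du))
  expect_equal(dr$dw, rev(d$dw))

  expect_error(dl_rhs(replace(u, 3, NA_real_), w, p), "non-finite")
})

test_that("simulation honours conservation, initial conditions and both engines", {
  # no Toll, no re-association: nothing happens
  p <- mech_params(beta_o = 0, gamma = 0, lambda_d = 1, lambda_dc = 1,
                   dosage = 1.5)
  s <- simulate_dl(p)
  expect_equal(s$final_free_dl, rep(0, 51))
  expect_equal(s$w[nrow(s$w), ], rep(1.5, 51), tolerance = 1e-8)

  # zeroth-order Toll release with frozen transport: u_h ~ min(beta(x) t, dose)
  p <- mech_params(lambda_d = 0, lambda_dc = 0, gamma = 0, beta_o = 0.05,
                   kappa = 1e-8, dosage = 1, t_end = 10)
  s <- simulate_dl(p)
  expected <- pmin(toll_profile(0.05, 0.15, s$x) * 10, 1)
  expect_equal(s$final_free_dl, expected, tolerance = 2e-3)

  # compiled and R right-hand sides integrate to the same solution
  p <- mech_params(lambda_d = 2, lambda_dc = 8, beta_o = 5, gamma = 1,
                   kappa = 0.1)
  sc <- simulate_dl(p)
  sr <- simulate_dl(p, engine = "R")
  expect_equal(sc$final_free_dl, sr$final_free_dl, tolerance = 1e-6)

  # mass conservation and non-negativity across random rate constants
  set.seed(11)
  for (i in 1:10) {
    p <- mech_params(lambda_d = runif_log(1), lambda_dc = runif_log(1),
                     beta_o = runif_log(1), gamma = runif_log(1),
                     kappa = runif_log(1))
    s <- simulate_dl(p)
    total <- rowSums(s$u + s$w)
    expect_lt(max(abs(total - total[1])) / total[1], 1e-5)
    expect_gt(min(s$u, s$w), -1e-8)
  }
})

test_that("grid refinement leaves the final gradient essentially unchanged", {
  # lambda are per-compartment exchange rates: refining the grid at fixed
  # physical diffusivity scales them by (dx_old/dx_new)^2 = 4
  p51 <- mech_params(lambda_d = 2, lambda_dc = 8, beta_o = 5, gamma = 1,
                     kappa = 0.1, n_compartments = 51L)
  p101 <- mech_params(lambda_d = 2 * 4, lambda_dc = 8 * 4, beta_o = 5,
                      gamma = 1, kappa = 0.1, n_compartments = 101L)
  s51 <- simulate_dl(p51)
  s101 <- simulate_dl(p101)
  interp <- approx(s101$x, s101$final_free_dl, xout = s51$x)$y
  expect_lt(max(abs(interp - s51$final_free_dl)) / max(s51$final_free_dl),
            0.02)
})

test_that("large-kappa limit converges to the linear dissociation model", {
  # kappa -> Inf with beta_o/kappa fixed: Toll term -> (beta_o/kappa) beta-shape * w,
  # a linear ODE system solved in closed form by the matrix exponential
  n <- 3L
  rate <- 0.4
  lam_d <- 0.3
  lam_dc <- 0.7
  gam <- 0.2
  p <- mech_params(lambda_d = lam_d, lambda_dc = lam_dc, beta_o = rate * 1e7,
                   kappa = 1e7, gamma = gam, n_compartments = n, t_end = 5,
                   dosage = 1)
  s <- simulate_dl(p)

  x <- seq(0, 1, length.out = n)
  bx <- rate * exp(-(x / 0.15)^2)
  L <- matrix(0, n, n)   # zero-flux discrete Laplacian
  for (h in seq_len(n)) {
    L[h, h] <- -2
    L[h, max(1, h - 1)] <- L[h, max(1, h - 1)] + 1
    L[h, min(n, h + 1)] <- L[h, min(n, h + 1)] + 1
  }
  A <- rbind(cbind(lam_d * L - gam * diag(n), diag(bx)),
             cbind(gam * diag(n), lam_dc * L - diag(bx)))
  y5 <- as.numeric(Matrix::expm(A * 5) %*% c(rep(0, n), rep(1, n)))
  expect_equal(s$final_free_dl, y5[1:3], tolerance = 1e-4)
  expect_equal(s$w[nrow(s$w), ], y5[4:6], tolerance = 1e-4)
})

test_that("length-scale ratio and nuclear gradient follow their definitions", {
  p <- mech_params(lambda_d = 1, lambda_dc = 2)
  expect_equal(length_scale_ratio(p), 2)
  expect_equal(length_scale_ratio(mech_params(lambda_d = 3, lambda_dc = 3),
                                  geometry_params(keq_d = 0.4, keq_dc = 0.4)),
               1)
  # direct arithmetic: 2*(1*1+1) / (1*(1*3+1)) = 1
  expect_equal(length_scale_ratio(
    mech_params(lambda_d = 1, lambda_dc = 2),
    geometry_params(v_nuc = 1, v_cyt = 1, keq_dc = 1, keq_d = 3)), 1)
  expect_error(length_scale_ratio(mech_params(lambda_d = 0, lambda_dc = 1)),
               "lambda_d")

  s <- simulate_dl(mech_params(lambda_d = 2, lambda_dc = 8, beta_o = 5,
                               gamma = 1, kappa = 0.1))
  expect_equal(nuclear_gradient(s, geometry_params(keq_d = 1)),
               s$final_free_dl)
  g3 <- nuclear_gradient(s, geometry_params(keq_d = 3))
  expect_equal(max(g3), 3 * s$amplitude)
  # border positions are invariant under the nuclear scaling
  b1 <- extract_border(s$final_free_dl, 0.5 * s$amplitude, x = s$x)
  b3 <- extract_border(g3, 0.5 * max(g3), x = s$x)
  expect_equal(b1$x_b, b3$x_b)
})
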