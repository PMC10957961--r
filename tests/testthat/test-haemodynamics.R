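dp <- 1e-3
h <- 1.4 * dp
ks <- kernel_spec(h, 2)

test_that("strain rate: rigid rotation gives zero, simple shear the
           textbook tensor, quadratic field within 3%", {
  sys <- lattice_system(26, 26, dp)
  pl <- build_neighbor_list(sys, 2 * h)
  ctr <- c(13 * dp, 13 * dp)
  ids <- which(sys$pos[, 1] > 4 * h & sys$pos[, 1] < 26 * dp - 4 * h &
                 sys$pos[, 2] > 4 * h & sys$pos[, 2] < 26 * dp - 4 * h)
  # rigid rotation u = omega x r: S = 0
  om <- 3
  sys$vel <- cbind(-om * (sys$pos[, 2] - ctr[2]), om * (sys$pos[, 1] - ctr[1]))
  S <- strain_rate_tensor(sys, ids, pl, ks)
  expect_true(all(S$ok[ids]))
  expect_lt(max(abs(S$S[ids, ])), 1e-8 * om)
  # simple shear u = (gdot y, 0): S12 = S21 = gdot/2
  gdot <- 40
  sys$vel <- cbind(gdot * sys$pos[, 2], 0)
  S <- strain_rate_tensor(sys, ids, pl, ks)
  expect_equal(S$S[ids, 2], rep(gdot / 2, length(ids)), tolerance = 1e-10)
  expect_equal(S$S[ids, 3], S$S[ids, 2])
  expect_lt(max(abs(S$S[ids, c(1, 4)])), 1e-8 * gdot)
  # resolved quadratic field u = (a y^2, 0): du/dy = 2 a y, within 3%
  a <- 2e3
  sys$vel <- cbind(a * sys$pos[, 2]^2, 0)
  S <- strain_rate_tensor(sys, ids, pl, ks)
  exact <- a * sys$pos[ids, 2]          # S12 = du_x/dy / 2 = a y
  expect_lt(max(abs(S$S[ids, 2] - exact) / max(abs(exact))), 0.03)
})

test_that("wall shear vector: zero strain gives zero, Poiseuille analytic
           value, LES reduces to laminar and never falls below it", {
  mu <- 0.003
  n <- c(0, 1)
  expect_equal(wall_shear_vector(matrix(0, 2, 2), n, "laminar", mu),
               c(0, 0))
  # plane Poiseuille at the wall: du/dy = 4 U / H, tau = mu du/dy = 1.2 Pa
  U <- 0.1; H <- 1e-3
  dudy <- 4 * U / H
  S <- matrix(c(0, dudy / 2, dudy / 2, 0), 2, 2)
  tau <- wall_shear_vector(S, n, "laminar", mu)
  expect_equal(sqrt(sum(tau^2)), 4 * mu * U / H)
  expect_equal(sqrt(sum(tau^2)), 1.2)
  expect_equal(tau[2], 0)  # purely tangential
  # LES mode with Cs -> 0 (and k = CI = 0) reduces to laminar
  cfg0 <- sps_config(Cs = 1e-12, CI = 0, k = 0, dl = dp)
  tau_les0 <- wall_shear_vector(S, n, "les", mu, sps = cfg0, rho = 1060)
  expect_equal(tau_les0, tau, tolerance = 1e-6)
  # with finite Cs the LES magnitude is >= laminar (mu_T >= 0)
  cfg <- sps_config(Cs = 0.12, CI = 0, k = 0, dl = dp)
  tau_les <- wall_shear_vector(S, n, "les", mu, sps = cfg, rho = 1060)
  expect_gte(sqrt(sum(tau_les^2)), sqrt(sum(tau^2)))
  expect_error(wall_shear_vector(S, c(0, 2), "laminar", mu), "unit")
})

test_that("projection to the wall: direct transfer, constants exact,
           linear fields within 2%, missing samples flagged", {
  # single fluid particle next to a single sample: direct transfer
  s1 <- wall_samples(matrix(c(0, 0), 1), c(0, 1))
  pr <- project_to_wall(matrix(c(1.5, 0), 1), matrix(c(0, dp / 2), 1),
                        s1, ks)
  expect_equal(pr$taux, 1.5)
  # uniform tau over a layer transfers exactly; empty samples are NA
  xs <- seq(0, 10 * dp, by = dp)
  samples <- wall_samples(cbind(c(xs, 99), 0),
                          matrix(c(0, 1), length(xs) + 1, 2, byrow = TRUE))
  fp <- as.matrix(expand.grid(x = xs, y = c(dp / 2, 1.5 * dp)))[, 1:2]
  tau_u <- matrix(c(2, 0), nrow(fp), 2, byrow = TRUE)
  pr <- project_to_wall(tau_u, fp, samples, ks)
  expect_equal(pr$taux[seq_along(xs)], rep(2, length(xs)))
  expect_true(pr$missing[length(xs) + 1])
  expect_true(is.na(pr$taux[length(xs) + 1]))
  # linear tau(x): wall values match the linear field within 2%
  tau_l <- cbind(1 + 50 * fp[, 1], 0)
  pr <- project_to_wall(tau_l, fp, samples, ks)
  inner <- 3:(length(xs) - 2)
  expect_equal(pr$taux[inner], 1 + 50 * xs[inner], tolerance = 0.02)
  # all-empty association is an error
  expect_error(project_to_wall(tau_u, fp,
                               wall_samples(matrix(c(5, 5), 1), c(0, 1)), ks),
               "empty field")
  # linear method: a shear profile linear in wall distance is extrapolated
  # to the wall exactly (plain averaging is biased low by construction)
  fp3 <- as.matrix(expand.grid(x = xs, y = c(0.5, 1.5, 2.5) * dp))[, 1:2]
  tau_w <- 1.2
  tau_s <- cbind(tau_w * (1 - 0.3 * fp3[, 2] / dp), 0)  # decays off the wall
  pr_lin <- project_to_wall(tau_s, fp3, samples, ks, method = "linear")
  pr_avg <- project_to_wall(tau_s, fp3, samples, ks, method = "kernel")
  inner <- 3:(length(xs) - 2)
  expect_equal(pr_lin$taux[inner], rep(tau_w, length(inner)),
               tolerance = 1e-6)
  expect_true(all(pr_avg$taux[inner] < tau_w))
})

test_that("TAWSS: constants, analytic |sin| mean, quadrature convergence", {
  T <- 0.8
  t1 <- seq(0, T, length.out = 401)
  # constant 2 Pa
  expect_equal(tawss(list(t = t1, tau = cbind(2, 0 * t1)), period = T), 2)
  # A sin(2 pi t / T): mean of |tau| = 2A/pi
  A <- 1.7
  tau <- cbind(A * sin(2 * pi * t1 / T), 0)
  expect_equal(tawss(list(t = t1, tau = tau), period = T), 2 * A / pi,
               tolerance = 1e-4)
  # halving the sampling interval changes the result < 0.1%
  t2 <- seq(0, T, length.out = 801)
  v1 <- tawss(list(t = t1, tau = cbind(A * sin(2 * pi * t1 / T), 0)), T)
  v2 <- tawss(list(t = t2, tau = cbind(A * sin(2 * pi * t2 / T), 0)), T)
  expect_lt(abs(v2 - v1) / v1, 1e-3)
  # insufficient coverage errors
  expect_error(tawss(list(t = t1[1:100], tau = tau[1:100, ]), period = T),
               "insufficient coverage")
})

test_that("OSI: unidirectional 0, full reversal 0.5, bounds and
           dense-quadrature oracle on random series", {
  T <- 0.8
  t1 <- seq(0, T, length.out = 1001)
  # constant direction -> 0
  expect_equal(osi(list(t = t1, tau = cbind(1 + 0.5 * sin(2 * pi * t1 / T)^2,
                                            0)), T), 0)
  # complete reversal with equal magnitudes -> exactly 0.5
  expect_equal(osi(list(t = t1, tau = cbind(sin(2 * pi * t1 / T), 0)), T),
               0.5, tolerance = 1e-12)
  # degenerate zero series -> 0 by definition
  expect_equal(osi(list(t = t1, tau = cbind(0 * t1, 0)), T), 0)
  # random Fourier series: bounds + agreement with a dense oracle
  set.seed(33)
  for (k in 1:60) {
    cf <- matrix(rnorm(12), 2)
    tau_fn <- function(t) {
      w <- 2 * pi * t / T
      cbind(cf[1, 1] + cf[1, 2] * sin(w) + cf[1, 3] * cos(w) +
              cf[1, 4] * sin(2 * w) + cf[1, 5] * cos(2 * w) + cf[1, 6] * sin(3 * w),
            cf[2, 1] + cf[2, 2] * sin(w) + cf[2, 3] * cos(w) +
              cf[2, 4] * sin(2 * w) + cf[2, 5] * cos(2 * w) + cf[2, 6] * sin(3 * w))
    }
    val <- osi(list(t = t1, tau = tau_fn(t1)), T)
    expect_gte(val, 0)
    expect_lte(val, 0.5)
    oracle <- osi_oracle(tau_fn, T)
    expect_equal(val, oracle$osi, tolerance = 1e-3)
    expect_equal(tawss(list(t = t1, tau = tau_fn(t1)), T), oracle$tawss,
                 tolerance = 1e-3)
  }
})

test_that("ECAP: threshold arithmetic, homogeneity, degenerate flag;
           PSWSS degenerate consistency", {
  # paper-style threshold: max OSI 0.5 over min TAWSS 0.36 Pa
  expect_equal(ecap(0.5, 0.36), 1.389, tolerance = 1e-3)
  expect_equal(ecap(0, 2), 0)
  expect_true(is.na(ecap(0.3, 0)))
  # scaling TAWSS by c scales ECAP by 1/c
  expect_equal(ecap(0.25, 2 * 0.7), ecap(0.25, 0.7) / 2)
  # steady series: PSWSS = TAWSS = |tau|
  T <- 0.8
  t1 <- seq(0, T, length.out = 101)
  ser <- list(t = t1, tau = cbind(rep(1.4, 101), 0))
  expect_equal(pswss(ser, T), 1.4)
  expect_equal(tawss(ser, T), 1.4)
})

test_that("haemodynamic maps assemble per-sample metrics with tidy/glance
           methods", {
  T <- 0.8
  t1 <- seq(0, T, length.out = 201)
  rec <- rbind(
    tibble::tibble(sample = 1L, t = t1, taux = sin(2 * pi * t1 / T),
                   tauy = 0),
    tibble::tibble(sample = 2L, t = t1, taux = 2, tauy = 0))
  ser <- shear_series(rec, period = T)
  maps <- haemodynamic_maps(ser)
  expect_equal(maps$osi[maps$sample == 1], 0.5, tolerance = 1e-9)
  expect_equal(maps$osi[maps$sample == 2], 0)
  expect_equal(maps$tawss[maps$sample == 2], 2)
  expect_equal(maps$ecap, maps$osi / maps$tawss)
  expect_equal(maps$pswss[maps$sample == 2], 2)
  td <- tidy(maps)
  expect_identical(nrow(td), 8L)
  gl <- glance(maps)
  expect_identical(gl$n_samples, 2L)
  expect_equal(gl$max_osi, 0.5, tolerance = 1e-9)
  p <- autoplot(maps)
  expect_s3_class(p, "ggplot")
})

test_that("effective orifice area: open lumen, occluded plane, resolution
           convergence", {
  W <- 0.02
  # no leaflets: EOA = full lumen width
  fl <- as.matrix(expand.grid(x = seq(0, 0.04, by = dp),
                              y = seq(0, W, by = dp)))[, 1:2]
  sys <- particle_system(fl, tag = 0L, dp = dp)
  eoa <- effective_orifice_area(sys, c(0.02, 0), c(1, 0), c(0, W), dp)
  expect_equal(eoa, W, tolerance = 0.03)
  # a solid bar across the whole lumen: EOA <= 5% of the lumen
  bar <- cbind(0.02, seq(0, W, by = 0.5 * dp))
  sys2 <- haemosph:::append_particles(sys, bar, matrix(0, nrow(bar), 2),
                                      rho = 1060, p = 0, mass = 1,
                                      tag = 2L)
  eoa2 <- effective_orifice_area(sys2, c(0.02, 0), c(1, 0), c(0, W), dp)
  expect_lte(eoa2, 0.05 * W)
  # half occlusion
  half <- cbind(0.02, seq(0, W / 2, by = 0.5 * dp))
  sys3 <- haemosph:::append_particles(sys, half, matrix(0, nrow(half), 2),
                                      rho = 1060, p = 0, mass = 1,
                                      tag = 2L)
  eoa3 <- effective_orifice_area(sys3, c(0.02, 0), c(1, 0), c(0, W), dp)
  expect_equal(eoa3, W / 2, tolerance = 0.08)
  # halving the raster resolution changes the result < 2%
  eoa_f <- effective_orifice_area(sys3, c(0.02, 0), c(1, 0), c(0, W), dp,
                                  resolution = dp / 4)
  expect_lt(abs(eoa_f - eoa3) / eoa3, 0.02)
  expect_error(effective_orifice_area(sys, c(0.02, 0), c(1, 0), c(0, W),
                                      dp, slab = dp), "slab")
})
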