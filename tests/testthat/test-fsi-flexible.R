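# small reference block reused across cases
.block_body <- function(nx = 12, ny = 6, dp = 1e-3, E = 1e6, nu = 0.3,
                        ...) {
  X <- as.matrix(expand.grid(x = (seq_len(nx) - 0.5) * dp,
                             y = (seq_len(ny) - 0.5) * dp))[, 1:2]
  flexible_body(X, dp, E = E, nu = nu, ...)
}

test_that("deformation gradient: identity, uniform stretch, random affine
           (patch test, exact with kernel-gradient correction)", {
  b <- .block_body()
  F0 <- deformation_gradient(b)
  expect_equal(F0, matrix(rep(c(1, 0, 0, 1), each = nrow(F0)), nrow(F0)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # uniform stretch x = lambda X
  lam <- 1.07
  F1 <- deformation_gradient(b, x = lam * b$X)
  expect_equal(F1[, 1], rep(lam, nrow(F1)), tolerance = 1e-10)
  expect_equal(F1[, 4], rep(lam, nrow(F1)), tolerance = 1e-10)
  expect_equal(haemosph:::.det_rows(F1, 2L), rep(lam^2, nrow(F1)),
               tolerance = 1e-9)
  # random affine map: F = A everywhere, to 1e-10
  set.seed(21)
  A <- diag(2) + matrix(rnorm(4, sd = 0.1), 2, 2)
  bvec <- rnorm(2)
  xa <- b$X %*% t(A) + matrix(bvec, nrow(b$X), 2, byrow = TRUE)
  FA <- deformation_gradient(b, x = xa)
  for (i in sample(nrow(FA), 10))
    expect_equal(matrix(FA[i, ], 2, 2, byrow = TRUE), A, tolerance = 1e-10)
})

test_that("degenerate (collinear) reference neighbourhood is rejected", {
  X <- cbind(seq(0, 10) * 1e-3, 0)  # single line: singular correction
  expect_error(flexible_body(X, 1e-3), "ill-conditioned")
})

test_that("PK1 stress: stress-free reference, plane-stress uniaxial limit,
           frame indifference", {
  E <- 1e6; nu <- 0.49
  expect_equal(pk1_stress(diag(2), E, nu), matrix(0, 2, 2))
  # small uniaxial strain with free lateral contraction: P11 ~ E eps
  eps <- 1e-4
  F <- diag(c(1 + eps, 1 - nu * eps))
  P <- pk1_stress(F, E, nu)
  expect_equal(P[1, 1], E * eps, tolerance = 0.01)
  expect_lt(abs(P[2, 2]), 0.02 * abs(P[1, 1]))  # lateral ~ stress-free
  # frame indifference P(R F) = R P(F)
  set.seed(4)
  for (k in 1:10) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    F <- diag(2) + matrix(rnorm(4, sd = 0.05), 2, 2)
    expect_equal(pk1_stress(R %*% F, E, nu), R %*% pk1_stress(F, E, nu),
                 tolerance = 1e-9)
  }
  expect_error(pk1_stress(diag(2), E, nu = 0.5), "non-physical")
  expect_error(pk1_stress(diag(c(-1, 1)), E, 0.3), "inversion")
})

test_that("solid density from the Jacobian: rho J = rho0", {
  b <- .block_body()
  expect_equal(solid_density_from_J(b, J = rep(1, 3)), rep(b$rho0, 3))
  expect_equal(solid_density_from_J(b, J = 1.1), b$rho0 / 1.1)
  expect_error(solid_density_from_J(b, J = c(1, -0.2)), "inversion")
  # leaflet default density 1100 kg/m^3 at J = 1
  leaf <- .block_body(E = 1e6, nu = 0.49)
  expect_equal(leaf$rho0, 1100)
  expect_equal(solid_density_from_J(leaf, J = 1), 1100)
})

test_that("solid momentum: divergence of uniform stress vanishes, pairwise
           momentum conservation, affine patch equilibrium", {
  b <- .block_body(nx = 22, ny = 18, nu = 0.3)
  b$alpha_visc <- 0
  n <- nrow(b$X)
  # deep-interior particles: the pairwise form needs both the particle and
  # all its neighbours to carry full support (free-surface particles feel
  # the physically correct unbalanced boundary traction)
  rng <- apply(b$X, 2, range)
  interior <- b$X[, 1] > rng[1, 1] + 4 * b$h & b$X[, 1] < rng[2, 1] - 4 * b$h &
    b$X[, 2] > rng[1, 2] + 4 * b$h & b$X[, 2] < rng[2, 2] - 4 * b$h
  expect_gt(sum(interior), 0)
  # uniform P field on the undeformed body: zero interior internal force
  Pu <- matrix(rep(c(123, 45, 45, -67), each = n), n)
  acc <- solid_momentum_rate(b, P = Pu)
  expect_lt(max(abs(acc[interior, ])),
            1e-7 * max(abs(Pu)) / (b$rho0 * b$dp))
  # gravity passes straight through
  accg <- solid_momentum_rate(b, P = Pu, gravity = c(0, -9.81))
  expect_equal(accg - acc, matrix(c(0, -9.81), n, 2, byrow = TRUE),
               ignore_attr = TRUE)
  # free body with random stresses: total momentum rate = 0
  set.seed(9)
  Pr <- matrix(rnorm(4 * n, sd = 100), n)
  accr <- solid_momentum_rate(b, P = Pr)
  expect_lt(max(abs(colSums(accr * b$mass_solid))), 1e-9)
  # affine patch: uniform F -> uniform P -> zero interior internal force
  A <- diag(2) + matrix(c(0.05, 0.02, -0.01, 0.03), 2, 2)
  b$x <- b$X %*% t(A)
  F <- deformation_gradient(b)
  P <- pk1_stress(F, b$E, b$nu, dim = 2)
  acc_p <- solid_momentum_rate(b, P = P)
  scale <- max(abs(P)) / (b$rho0 * b$dp)
  expect_lt(max(abs(acc_p[interior, ])) / scale, 1e-8)
})

test_that("cantilever: static tip deflection approaches Euler-Bernoulli
           (coarse smoke run; the strict 10% check runs at higher
           resolution in the acceptance suite)", {
  L <- 0.1; th <- 0.01; dp <- th / 8
  Ftip <- 1
  cc <- make_cantilever_case(L, th, dp, tip_load = Ftip, E = 1e6, nu = 0.49)
  body <- cc$body
  f_tip <- matrix(0, nrow(body$X), 2)
  f_tip[cc$tip_ids, 2] <- Ftip / (length(cc$tip_ids) * body$mass_solid)
  body <- relax_flexible_body(body, f_tip, n_steps = 80000, tol = 1e-10)
  tipy <- mean(body$x[cc$tip_ids, 2] - body$X[cc$tip_ids, 2])
  expect_equal(tipy, cc$analytic$tip_deflection, tolerance = 0.15)
})

test_that("cantilever: first bending frequency within 10%, energy drift
           below 2% over 5 free periods", {
  L <- 0.1; th <- 0.01; dp <- th / 10
  cc <- make_cantilever_case(L, th, dp, tip_load = 0.5, E = 1e6, nu = 0.49,
                             alpha_visc = 0)
  body <- cc$body
  f_tip <- matrix(0, nrow(body$X), 2)
  f_tip[cc$tip_ids, 2] <- 0.5 / (length(cc$tip_ids) * body$mass_solid)
  body <- relax_flexible_body(body, f_tip, n_steps = 60000)
  body$v[] <- 0
  dt <- 0.3 * body$h / body$c0s
  T1 <- 1 / cc$analytic$first_frequency
  nstep <- ceiling(5 * T1 / dt)
  tip <- numeric(0); es <- numeric(0)
  for (s in seq_len(nstep)) {
    body <- step_flexible_body(body, dt)
    if (s %% 20 == 0) {
      tip <- c(tip, mean(body$x[cc$tip_ids, 2] - body$X[cc$tip_ids, 2]))
      es <- c(es, flexible_energy(body)$total)
    }
  }
  # frequency from mean-crossing intervals of the tip trace
  tt <- seq_along(tip) * 20 * dt
  cr <- which(diff(sign(tip - mean(tip))) != 0)
  f_est <- 1 / (2 * mean(diff(tt[cr])))
  expect_equal(f_est, cc$analytic$first_frequency, tolerance = 0.10)
  # bounded energy (no artificial viscosity): drift < 2%
  expect_lt(max(abs(es - es[1])) / es[1], 0.02)
})

test_that("fluid-solid coupling conserves combined linear momentum in a
           closed box", {
  dp <- 1e-3
  h <- 1.4 * dp
  # fluid block with a flexible plate inside, closed periodic box, no
  # gravity: one coupled step must conserve total momentum
  nx <- 20
  L <- nx * dp
  g <- expand.grid(x = (seq_len(nx) - 0.5) * dp, y = (seq_len(nx) - 0.5) * dp)
  pos <- as.matrix(g)[, 1:2]
  plate <- pos[, 1] > 8 * dp & pos[, 1] < 11.5 * dp &
    pos[, 2] > 6 * dp & pos[, 2] < 14 * dp
  tag <- ifelse(plate, 3L, 0L)
  sys <- particle_system(pos, tag = tag, dp = dp, mu = 0)
  set.seed(14)
  sys$vel[tag == 0L, ] <- matrix(rnorm(sum(tag == 0L) * 2, sd = 0.05),
                                 ncol = 2)
  mem <- which(plate)
  fb <- flexible_body(pos[mem, ], dp, E = 1e5, nu = 0.3, rho0 = 1100,
                      members = mem, alpha_visc = 0)
  dom <- sph_domain(c(0, 0), c(L, L), periodic = c(TRUE, TRUE))
  case <- sph_case(sys, kernel_spec(h, 2), state_equation(c0 = 2),
                   domain = dom, flexible_bodies = list(fb))
  mom <- function(cs) {
    s <- cs$system
    m_f <- colSums(s$vel[s$tag == 0L, ] * s$mass[s$tag == 0L])
    fb <- cs$flexible_bodies[[1]]
    m_s <- colSums(fb$v * fb$mass_solid)
    m_f + m_s
  }
  m0 <- mom(case)
  dt <- 0.25 * stable_dt(case)
  case <- advance_timestep(case, dt)
  m1 <- mom(case)
  # impulse scale of the step for a relative comparison
  scale <- max(sum(abs(m0)), 1e-8)
  expect_lt(max(abs(m1 - m0)) / scale, 0.01)
})
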