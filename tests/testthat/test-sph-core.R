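dp <- 0.001
h <- 1.4 * dp
ks <- kernel_spec(h, 2)

test_that("neighbour list equals the brute-force oracle", {
  set.seed(42)
  pos <- cbind(runif(500, 0, 0.02), runif(500, 0, 0.02))
  sys <- particle_system(pos, dp = dp)
  pl <- build_neighbor_list(sys, 2 * h)
  oracle <- brute_pairs(pos, 2 * h)
  got <- data.frame(i = pl$i, j = pl$j)
  expect_equal(nrow(got), nrow(oracle))
  key <- function(df) sort(paste(df$i, df$j))
  expect_identical(key(got), key(oracle))
  # pair geometry is consistent
  k <- sample(length(pl$i), 50)
  expect_equal(pl$r[k],
               sqrt(rowSums((pos[pl$i[k], ] - pos[pl$j[k], ])^2)))
  # degenerate cases
  one <- particle_system(matrix(c(0, 0), 1), dp = dp)
  expect_length(build_neighbor_list(one, 2 * h)$i, 0)
  two <- particle_system(rbind(c(0, 0), c(2 * h + 1e-9, 0)), dp = dp)
  expect_length(build_neighbor_list(two, 2 * h)$i, 0)
  bad <- particle_system(rbind(c(0, 0), c(NA, 0)), dp = dp)
  expect_error(build_neighbor_list(bad, 2 * h), "non-finite")
})

test_that("periodic neighbour search uses the minimum image", {
  set.seed(11)
  L <- 0.01
  pos <- cbind(runif(200, 0, L), runif(200, 0, L))
  sys <- particle_system(pos, dp = dp)
  dom <- sph_domain(c(0, 0), c(L, L), periodic = c(TRUE, TRUE))
  pl <- build_neighbor_list(sys, 2 * h, dom)
  oracle <- brute_pairs(pos, 2 * h, c(0, 0), c(L, L), c(TRUE, TRUE))
  key <- function(i, j) sort(paste(i, j))
  expect_identical(key(pl$i, pl$j), key(oracle$i, oracle$j))
})

test_that("equation of state: reference state, monotonicity, closed form", {
  eos <- state_equation(rho0 = 1060, c0 = 10, gamma = 7)
  expect_equal(equation_of_state(1060, eos), 0)
  rho <- 1.01 * 1060
  expect_equal(equation_of_state(rho, eos),
               (10^2 * 1060 / 7) * (1.01^7 - 1))
  grid <- seq(900, 1300, by = 10)
  expect_true(all(diff(equation_of_state(grid, eos)) > 0))
  expect_error(equation_of_state(-1, eos), "invalid density")
})

test_that("continuity: uniform translation gives zero, linear field the
           analytic divergence", {
  sys <- lattice_system(30, 30, dp)
  pl <- build_neighbor_list(sys, 2 * h)
  # uniform translation
  sys$vel[, 1] <- 0.3; sys$vel[, 2] <- -0.1
  expect_equal(max(abs(continuity_rate(sys, pl, ks))), 0)
  # linear velocity field u = a x: div u = a, drho/dt = -rho a
  a <- 5
  sys$vel[, 1] <- a * sys$pos[, 1]
  sys$vel[, 2] <- 0
  drho <- continuity_rate(sys, pl, ks)
  interior <- sys$pos[, 1] > 4 * h & sys$pos[, 1] < 30 * dp - 4 * h &
    sys$pos[, 2] > 4 * h & sys$pos[, 2] < 30 * dp - 4 * h
  expect_equal(mean(drho[interior]), -sys$rho0 * a, tolerance = 0.02)
})

test_that("momentum: pairwise antisymmetry conserves global momentum", {
  sys <- lattice_system(20, 20, dp)
  pl <- build_neighbor_list(sys, 2 * h)
  sys$p <- rep(50, n_particles(sys))   # uniform pressure
  sys$mu <- 0                          # no viscosity
  acc <- momentum_rate(sys, pl, ks)
  mom_rate <- colSums(acc * sys$mass)
  expect_lt(max(abs(mom_rate)), 1e-12)
  # with random pressures momentum is still conserved pairwise
  set.seed(3)
  sys$p <- runif(n_particles(sys), 0, 100)
  acc <- momentum_rate(sys, pl, ks)
  expect_lt(max(abs(colSums(acc * sys$mass))), 1e-9)
  # single particle: du/dt = body force
  one <- particle_system(matrix(c(0, 0), 1), dp = dp)
  acc1 <- momentum_rate(one, build_neighbor_list(one, 2 * h), ks,
                        body_force = c(0, -9.81))
  expect_equal(drop(acc1), c(0, -9.81))
})

test_that("hydrostatic balance: pressure gradient cancels gravity", {
  g <- -9.81
  ny <- 40
  sys <- lattice_system(30, ny, dp)
  H <- ny * dp
  eos <- state_equation(rho0 = sys$rho0, c0 = design_sound_speed(0.1, 9.81, H))
  # hydrostatic pressure and the EOS-consistent density profile
  depth <- H - sys$pos[, 2]
  p_hyd <- sys$rho0 * abs(g) * depth
  B <- eos$c0^2 * eos$rho0 / eos$gamma
  sys$rho <- eos$rho0 * (1 + p_hyd / B)^(1 / eos$gamma)
  sys$p <- equation_of_state(sys$rho, eos)
  sys$mu <- 0
  pl <- build_neighbor_list(sys, 2 * h)
  acc <- momentum_rate(sys, pl, ks, body_force = c(0, g))
  interior <- sys$pos[, 1] > 4 * h & sys$pos[, 1] < 30 * dp - 4 * h &
    sys$pos[, 2] > 4 * h & sys$pos[, 2] < H - 4 * h
  expect_lt(max(sqrt(rowSums(acc[interior, ]^2))), 0.05 * abs(g))
})

test_that("SPS closure: zero at rest, analytic eddy viscosity in shear,
           symmetric tensor", {
  sys <- lattice_system(24, 24, dp)
  pl <- build_neighbor_list(sys, 2 * h)
  cfg <- sps_config(dl = dp, k = 0, CI = 0)
  tau0 <- sps_stress_tensor(sys, pl, ks, cfg)
  expect_equal(max(abs(tau0)), 0)
  # simple shear du_x/dy = gdot: sqrt(2 S:S) = gdot, mu_T = rho (Cs dl)^2 gdot
  gdot <- 120
  sys$vel[, 1] <- gdot * sys$pos[, 2]
  tau <- sps_stress_tensor(sys, pl, ks, cfg)
  interior <- which(sys$pos[, 1] > 4 * h & sys$pos[, 1] < 24 * dp - 4 * h &
                      sys$pos[, 2] > 4 * h & sys$pos[, 2] < 24 * dp - 4 * h)
  muT <- sys$rho0 * (cfg$Cs * dp)^2 * gdot
  # tau_12 = 2 mu_T S_12 = mu_T gdot
  expect_equal(mean(tau[interior, 2]), muT * gdot, tolerance = 0.02)
  expect_equal(tau[interior, 2], tau[interior, 3])  # symmetry
  # random velocity field: still symmetric
  set.seed(5)
  sys$vel[] <- rnorm(length(sys$vel))
  tau <- sps_stress_tensor(sys, pl, ks, cfg)
  expect_equal(tau[, 2], tau[, 3], tolerance = 1e-12)
})

test_that("still fluid in a periodic box stays still; uniform flow is
           Galilean-invariant; mass and momentum conserved", {
  L <- 20 * dp
  sys <- lattice_system(20, 20, dp)
  eos <- state_equation(rho0 = sys$rho0, c0 = 1)
  dom <- sph_domain(c(0, 0), c(L, L), periodic = c(TRUE, TRUE))
  case <- sph_case(sys, ks, eos, domain = dom)
  mass0 <- sum(sys$mass)
  st <- advance_steps(case, 100, dt = 1e-4)
  expect_lt(max(abs(st$system$vel)), 1e-10)
  expect_lt(max(abs(st$system$rho - sys$rho0)), 1e-10)
  expect_identical(sum(st$system$mass), mass0)

  # uniform free stream, inviscid: velocities unchanged, momentum conserved
  sys2 <- sys
  sys2$vel[, 1] <- 0.25
  sys2$mu <- 0
  case2 <- sph_case(sys2, ks, eos, domain = dom)
  st2 <- advance_steps(case2, 50, dt = 1e-4)
  expect_lt(max(abs(st2$system$vel[, 1] - 0.25)), 1e-8)
  expect_lt(max(abs(st2$system$vel[, 2])), 1e-8)
  expect_equal(colSums(st2$system$vel * st2$system$mass),
               colSums(sys2$vel * sys2$mass), tolerance = 1e-12)
})

test_that("advance_timestep refuses an unstable dt and keeps masses fixed", {
  sys <- lattice_system(10, 10, dp)
  eos <- state_equation(rho0 = sys$rho0, c0 = 5)
  case <- sph_case(sys, ks, eos)
  expect_error(advance_timestep(case, 1), "stability")
  st <- advance_timestep(case, 0.5 * stable_dt(case))
  expect_identical(st$system$mass, sys$mass)
})

test_that("3D solver path: still fluid stays still, momentum conserved,
           linear-field continuity matches the analytic divergence", {
  dp3 <- 1e-3
  h3 <- 1.4 * dp3
  ks3 <- kernel_spec(h3, 3)
  n <- 10
  g <- as.matrix(expand.grid(x = (1:n - 0.5) * dp3, y = (1:n - 0.5) * dp3,
                             z = (1:n - 0.5) * dp3))
  L <- n * dp3
  sys <- particle_system(g, dp = dp3, mu = 0)
  dom <- sph_domain(c(0, 0, 0), c(L, L, L), periodic = rep(TRUE, 3))
  eos <- state_equation(c0 = 1)
  case <- sph_case(sys, ks3, eos, domain = dom)
  st <- advance_steps(case, 20, dt = 1e-4)
  expect_lt(max(abs(st$system$vel)), 1e-12)
  # random velocities: momentum conserved in the periodic box
  set.seed(12)
  sys$vel[] <- matrix(rnorm(length(sys$vel), sd = 0.01), ncol = 3)
  case <- sph_case(sys, ks3, eos, domain = dom)
  mom0 <- colSums(sys$vel * sys$mass)
  st <- advance_steps(case, 30, dt = 1e-4)
  expect_lt(max(abs(colSums(st$system$vel * st$system$mass) - mom0)), 1e-12)
  # linear field u = (a x, 0, 0): interior drho/dt = -rho a
  sys2 <- particle_system(g, dp = dp3)
  a <- 4
  sys2$vel[, 1] <- a * sys2$pos[, 1]
  pl <- build_neighbor_list(sys2, 2 * h3)
  drho <- continuity_rate(sys2, pl, ks3)
  interior <- apply(sys2$pos, 1, function(p) all(p > 2 * h3 & p < L - 2 * h3))
  expect_equal(mean(drho[interior]), -sys2$rho0 * a, tolerance = 0.02)
})

test_that("clinical pressure conversion: 1 mmHg = 133.322 Pa", {
  expect_equal(mmhg_to_pa(1), 133.322)
  expect_equal(pa_to_mmhg(mmhg_to_pa(17.64)), 17.64)
})
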