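test_that("pulsatile waveform: peak at peak time, periodic, Reynolds link", {
  prof <- inlet_profile(peak_speed = 0.5)
  expect_equal(pulsatile_inlet_velocity(0.1, prof), 0.5)
  tg <- seq(0, 0.8, length.out = 2001)
  u <- pulsatile_inlet_velocity(tg, prof)
  expect_lte(max(u), 0.5 + 1e-12)
  expect_equal(tg[which.max(u)], 0.1, tolerance = 1e-3)
  # periodicity value(t) = value(t + T)
  set.seed(1)
  tr <- runif(50, 0, 5)
  expect_equal(pulsatile_inlet_velocity(tr, prof),
               pulsatile_inlet_velocity(tr + 0.8, prof))
  # diastolic plateau
  expect_equal(pulsatile_inlet_velocity(0.5, prof), 0.05 * 0.5)
  # peak Reynolds number 7000 in a 25 mm tube with blood properties
  nu <- 0.003 / 1060
  u_re <- 7000 * nu / 0.025
  expect_equal(u_re, 0.79, tolerance = 0.01)
  expect_error(pulsatile_inlet_velocity(-1, prof), "non-negative")
})

test_that("DBC: wall density rises on fluid approach, static walls never
           move, isolated walls keep rho0", {
  dp <- 1e-3
  h <- 1.4 * dp
  ks <- kernel_spec(h, 2)
  # wall row at y = 0, fluid particle approaching head-on from above
  wall <- cbind(seq(-3 * dp, 3 * dp, by = dp), 0)
  pos <- rbind(wall, c(0, 1.2 * dp), c(0, 10 * dp))  # near + far fluid
  sys <- particle_system(pos, tag = c(rep(1L, nrow(wall)), 0L, 0L), dp = dp)
  sys$vel[nrow(wall) + 1, 2] <- -0.5  # closing velocity
  pl <- build_neighbor_list(sys, 2 * h)
  sys2 <- dbc_density_update(sys, pl, ks, dt = 1e-4)
  mid <- which(wall[, 1] == 0)
  expect_gt(sys2$rho[mid], sys$rho[mid])         # compression on approach
  # far fluid: no wall within 2h keeps rho0
  far_wall <- which(abs(wall[, 1]) > 2 * h)
  expect_equal(sys2$rho[far_wall], rep(1060, length(far_wall)))
  # wall positions unchanged by a full step
  eos <- state_equation(rho0 = 1060, c0 = 5)
  case <- sph_case(sys, ks, eos)
  st <- advance_timestep(case, 0.5 * stable_dt(case))
  expect_identical(st$system$pos[seq_len(nrow(wall)), ], sys$pos[seq_len(nrow(wall)), ])
})

test_that("ghost extrapolation reproduces linear fields exactly at buffer
           particles", {
  dp <- 1e-3
  h <- 1.4 * dp
  ks <- kernel_spec(h, 2)
  # fluid block x in [0, 12 dp], buffer slab x in [-5 dp, 0)
  fx <- (seq_len(12) - 0.5) * dp
  fy <- (seq_len(12) - 0.5) * dp
  fpos <- as.matrix(expand.grid(x = fx, y = fy))[, 1:2]
  bpos <- as.matrix(expand.grid(x = -(seq_len(5) - 0.5) * dp, y = fy))[, 1:2]
  sys <- particle_system(rbind(fpos, bpos),
                         tag = c(rep(0L, nrow(fpos)), rep(4L, nrow(bpos))),
                         dp = dp)
  # linear fields: rho = a0 + a.x, u = B x
  a0 <- 1060; av <- c(3000, -1500)
  B <- matrix(c(5, 2, -1, 4), 2, 2)
  sys$rho <- a0 + drop(sys$pos %*% av)
  sys$vel <- sys$pos %*% t(B)
  zone <- buffer_zone("outlet", origin = c(0, 0), normal = c(1, 0), dp = dp)
  ex <- extrapolate_ghost_fields(sys, zone, ks)
  buf <- which(sys$tag == 4L)
  expect_equal(ex[, 1], a0 + drop(sys$pos[buf, ] %*% av), tolerance = 1e-9)
  expect_equal(ex[, 2:3], unname(sys$pos[buf, ] %*% t(B)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("open boundaries: inlet deletion, outlet conversion, buffer
           crossing injects a replacement", {
  dp <- 1e-3
  case <- make_channel_case(20 * dp, 20 * dp, dp, "inlet-outlet",
                            u_max = 0.05)
  sys <- case$system
  n0 <- n_particles(sys)
  # plant a fluid particle inside the inlet buffer: must be removed
  sys <- haemosph:::append_particles(
    sys, matrix(c(-2.2 * dp, 10 * dp), 1), matrix(0, 1, 2),
    rho = 1060, p = 0, mass = 1060 * dp^2, tag = 0L)
  # move one fluid particle past the outlet plane: becomes buffer
  fl <- which(sys$tag == 0L)
  conv <- fl[which.max(sys$pos[fl, 1])]
  sys$pos[conv, 1] <- 20 * dp + 0.3 * dp
  # move one inlet buffer particle across the inlet plane: becomes fluid
  bf <- which(sys$tag == 4L & sys$pos[, 1] < 0)
  cross <- bf[which.max(sys$pos[bf, 1])]
  old_buffer_count <- sum(sys$tag == 4L)
  sys$pos[cross, 1] <- 0.2 * dp
  case$system <- sys
  case2 <- update_open_boundaries(case)
  s2 <- case2$system
  expect_identical(n_particles(s2), n0 + 1L)  # planted one deleted, clone added
  expect_identical(s2$tag[conv], 4L)          # outlet conversion
  expect_identical(s2$tag[cross], 0L)         # inlet buffer became fluid
  # a replacement buffer particle appeared one buffer length upstream
  # (crossing: -1 buffer +1 clone; outlet conversion: +1 buffer)
  expect_identical(sum(s2$tag == 4L), old_buffer_count + 1L)
  newb <- which(s2$tag == 4L)
  expect_true(any(abs(s2$pos[newb, 1] - (0.2 * dp - 5 * dp)) < 1e-12))
  expect_gt(case2$io_log$mass_in, 0)
  expect_gt(case2$io_log$mass_out, 0)
})

test_that("steady open channel keeps count and mass balance over a period", {
  # uniform frictionless stream: inflow exactly matches outflow
  dp <- 1e-3
  ny <- 8; L <- 30 * dp
  u0 <- 0.05
  fy <- (seq_len(ny) - 0.5) * dp
  fx <- (seq_len(30) - 0.5) * dp
  fpos <- as.matrix(expand.grid(x = fx, y = fy))[, 1:2]
  bin <- as.matrix(expand.grid(x = -(seq_len(5) - 0.5) * dp, y = fy))[, 1:2]
  bout <- as.matrix(expand.grid(x = L + (seq_len(5) - 0.5) * dp, y = fy))[, 1:2]
  sys <- particle_system(rbind(fpos, bin, bout),
                         tag = c(rep(0L, nrow(fpos)), rep(4L, nrow(bin)),
                                 rep(4L, nrow(bout))),
                         mu = 0, dp = dp)
  sys$vel[, 1] <- u0
  prof <- inlet_profile(peak_speed = u0, diastolic_fraction = 1)  # constant
  zones <- list(
    buffer_zone("inlet", c(0, 0), c(1, 0), dp, profile = prof),
    buffer_zone("outlet", c(L, 0), c(-1, 0), dp, pressure = 0))
  dom <- sph_domain(c(-6 * dp, 0), c(L + 6 * dp, ny * dp),
                    periodic = c(FALSE, TRUE))
  case <- sph_case(sys, kernel_spec(1.4 * dp, 2),
                   state_equation(c0 = 10 * u0), zones = zones, domain = dom)
  dt <- 0.5 * stable_dt(case)
  period <- dp / u0              # one particle-row crossing period
  nstep <- ceiling(6 * period / dt)
  counts <- integer(0)
  for (s in seq_len(nstep)) {
    case <- advance_timestep(case, dt, check_dt = FALSE)
    counts <- c(counts, sum(case$system$tag == 0L))
  }
  warm <- counts[-(seq_len(ceiling(nstep / 3)))]
  # after warm-up the fluid count is steady within one injected row
  expect_lte(max(warm) - min(warm), ny)
  # net drift per period ~ 0 (compare same phase one period apart)
  per_steps <- round(period / dt)
  drift <- abs(tail(warm, 1) - warm[length(warm) - per_steps])
  expect_lte(drift, 1)
  # injected mass matches the prescribed inflow within 2%
  expect_equal(case$io_log$mass_in,
               1060 * u0 * (ny * dp) * case$t, tolerance = 0.02)
  # bookkeeping identity: total mass change = in - out
  m_now <- sum(case$system$mass[case$system$tag != 4L])
  m_start <- 1060 * dp^2 * nrow(fpos)
  expect_equal(m_now - m_start, case$io_log$mass_in - case$io_log$mass_out,
               tolerance = 1e-9)
})
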