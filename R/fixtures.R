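#' Case specification record
#'
#' Deterministic description of a test case: geometry, resolution, material
#' constants, waveform and run controls.  The smoothing length is always
#' `h = h_ratio * dp` (default ratio 1.4 for both fluid and structure).
#' Identical spec (plus seed) regenerates bit-identical initial states: the
#' generators use no randomness.
#'
#' @param name Case name.
#' @param dp Particle spacing (m).
#' @param h_ratio Smoothing ratio (default 1.4).
#' @param seed Random seed recorded for reproducibility bookkeeping.
#' @param ... Further named fields stored verbatim.
#' @return An object of class `case_spec`.
#' @export
case_spec <- function(name, dp, h_ratio = 1.4, seed = 1L, ...) {
  stopifnot(dp > 0, h_ratio > 0)
  structure(c(list(name = name, dp = dp, h_ratio = h_ratio,
                   seed = as.integer(seed)), list(...)),
            class = "case_spec")
}

# staggered 3-layer wall lattice below/above a channel (2D)
.wall_rows <- function(x0, x1, dp, y_surface, side = c("below", "above"),
                       layers = 3L) {
  side <- match.arg(side)
  sgn <- if (side == "below") -1 else 1
  pts <- NULL
  for (l in seq_len(layers)) {
    y <- y_surface + sgn * (l - 0.5) * dp
    xs <- seq(x0 + dp / 2, x1 - dp / 4, by = dp)
    if (l %% 2L == 0L) xs <- xs + dp / 2  # staggered layers (same count:
    # under x-periodicity the overhanging particle wraps onto the start)
    pts <- rbind(pts, cbind(xs, y))
  }
  pts
}

#' Plane-channel fixture (Poiseuille flow)
#'
#' 2D plane channel of the given height and length filled with blood-like
#' fluid (`rho0 = 1060`, `mu = 0.003`) between two 3-layer DBC walls.
#' `drive = "body-force"` yields a streamwise-periodic channel driven by the
#' constant acceleration that produces the requested steady centreline speed
#' `u_max` (`f = 8 nu u_max / H^2`); `drive = "inlet-outlet"` attaches
#' 5-layer inlet/outlet buffer zones with a pulsatile inlet waveform.
#'
#' @param height Channel height H (m); must be at least `20 dp`.
#' @param length Channel length (m).
#' @param dp Particle spacing (m).
#' @param drive `"body-force"` or `"inlet-outlet"`.
#' @param u_max Target steady centreline speed (m/s, body-force drive).
#' @param profile An [inlet_profile()] (inlet-outlet drive); default peak
#'   speed `u_max`.
#' @param inlet_shape Transverse shape of the prescribed inlet velocity:
#'   `"ramped-plug"` (plug with a 3 dp near-wall ramp, default),
#'   `"parabolic"` (developed profile, peak at the centreline) or `"plug"`.
#' @param sps Enable the SPS turbulence closure (default `TRUE`).
#' @param delta_sph delta-SPH density diffusion coefficient (default 0).
#' @param seed Seed recorded in the spec.
#' @return An [sph_case()] with `case$samples` (wall surface samples),
#'   `case$spec` and, for body-force drive, `case$body_force`.
#' @export
make_channel_case <- function(height, length, dp,
                              drive = c("body-force", "inlet-outlet"),
                              u_max = 0.1, profile = NULL,
                              inlet_shape = c("ramped-plug", "parabolic",
                                              "plug"),
                              sps = TRUE, delta_sph = 0, seed = 1L) {
  drive <- match.arg(drive)
  inlet_shape <- match.arg(inlet_shape)
  if (height < 20 * dp)
    stop("resolution error: channel height must be at least 20 dp",
         call. = FALSE)
  rho0 <- 1060; mu <- 0.003
  h <- 1.4 * dp
  nu <- mu / rho0
  ny <- round(height / dp)
  nx <- round(length / dp)

  fy <- (seq_len(ny) - 0.5) * dp
  fx <- (seq_len(nx) - 0.5) * dp
  fluid_pos <- as.matrix(expand.grid(x = fx, y = fy))[, 1:2]

  if (drive == "body-force") {
    wx0 <- 0; wx1 <- length
  } else {
    buf_len <- 5 * dp
    wx0 <- -buf_len - dp; wx1 <- length + buf_len + dp
  }
  walls <- rbind(.wall_rows(wx0, wx1, dp, 0, "below"),
                 .wall_rows(wx0, wx1, dp, height, "above"))

  pos <- rbind(fluid_pos, walls)
  tag <- c(rep(0L, nrow(fluid_pos)), rep(1L, nrow(walls)))

  profile_used <- NULL
  zones <- list()
  if (drive == "inlet-outlet") {
    if (is.null(profile)) profile <- inlet_profile(peak_speed = u_max)
    profile_used <- profile
    buf_len <- 5 * dp
    bx_in <- -(seq_len(5) - 0.5) * dp
    bx_out <- length + (seq_len(5) - 0.5) * dp
    buf_in <- as.matrix(expand.grid(x = bx_in, y = fy))[, 1:2]
    buf_out <- as.matrix(expand.grid(x = bx_out, y = fy))[, 1:2]
    pos <- rbind(pos, buf_in, buf_out)
    tag <- c(tag, rep(4L, nrow(buf_in) + nrow(buf_out)))
    # transverse inlet shape; the near-wall ramp/parabola keeps the
    # advancing plug from jamming no-slip corner fluid
    shape_fn <- local({
      Hh <- height; dd <- dp; kind <- inlet_shape
      switch(kind,
        "ramped-plug" = function(pos)
          pmin(1, pos[, 2] / (3 * dd), (Hh - pos[, 2]) / (3 * dd)),
        "parabolic" = function(pos)
          pmax(0, 4 * pos[, 2] * (Hh - pos[, 2]) / Hh^2),
        "plug" = NULL)
    })
    zones <- list(
      buffer_zone("inlet", origin = c(0, 0), normal = c(1, 0), dp = dp,
                  profile = profile, shape = shape_fn),
      buffer_zone("outlet", origin = c(length, 0), normal = c(-1, 0),
                  dp = dp, pressure = 0))
  }

  sys <- particle_system(pos, tag = tag, rho0 = rho0, mu = mu, dp = dp)
  if (drive == "inlet-outlet") {
    buf <- sys$tag == 4L & sys$pos[, 1] < 0
    u0 <- pulsatile_inlet_velocity(0, profile)
    sys$vel[buf, 1] <- u0
  }

  u_ref <- if (drive == "body-force") u_max else profile$peak_speed
  eos <- state_equation(rho0 = rho0, c0 = design_sound_speed(u_ref))
  kern <- kernel_spec(h, 2L)
  spscfg <- if (sps) sps_config(dl = dp) else NULL
  body_force <- if (drive == "body-force") c(8 * nu * u_max / height^2, 0)
                else NULL
  domain <- if (drive == "body-force") {
    sph_domain(lo = c(0, -(3.5) * dp), hi = c(length, height + 3.5 * dp),
               periodic = c(TRUE, FALSE))
  } else NULL

  case <- sph_case(sys, kern, eos, sps = spscfg, domain = domain,
                   body_force = body_force, zones = zones,
                   delta_sph = delta_sph,
                   spec = case_spec("channel", dp, seed = seed,
                                    height = height, length = length,
                                    drive = drive, u_max = u_max,
                                    rho0 = rho0, mu = mu))
  # wall-surface samples at each interior fluid column, both walls
  sx <- fx[fx > 2 * h & fx < length - 2 * h]
  if (!length(sx)) sx <- fx
  case$samples <- wall_samples(
    rbind(cbind(sx, 0), cbind(sx, height)),
    rbind(matrix(c(0, 1), length(sx), 2, byrow = TRUE),
          matrix(c(0, -1), length(sx), 2, byrow = TRUE)))
  case
}

# 3-layer rectangular plate lattice along direction dvec from a base point;
# the plate starts one spacing behind the base so it covers a pivot there
.plate_lattice <- function(base, dvec, length, dp, layers = 3L) {
  dvec <- dvec / sqrt(sum(dvec^2))
  nvec <- c(-dvec[2], dvec[1])
  nl <- max(2L, round(length / dp)) + 1L
  along <- (seq_len(nl) - 1.5) * dp
  across <- (seq_len(layers) - (layers + 1) / 2) * dp
  g <- expand.grid(a = along, b = across)
  cbind(base[1] + g$a * dvec[1] + g$b * nvec[1],
        base[2] + g$a * dvec[2] + g$b * nvec[2])
}

#' Bi-leaflet valve fixture (2D analogue)
#'
#' A 2D straight channel (analogue of a 25 mm bi-leaflet mechanical valve in
#' a straight tube: a geometric analogue, not an equivalent of the 3D
#' device) with mounting-ring stubs on both walls and two hinged leaflets,
#' pulsatile inlet buffer and constant-pressure outlet buffer.  Rigid
#' leaflets carry a hinge constraint with stops at 30 degrees (closed,
#' initial) and 85 degrees (open) and leaflet density 1100 kg/m^3; flexible
#' leaflets are clamped elastic plates with `E = 1` MPa and `nu = 0.49`.
#'
#' @param tube_width Channel width W (m), at least `40 dp` (default 0.025,
#'   the nominal 25 mm device).
#' @param dp Particle spacing (m).
#' @param leaflet `"rigid"` or `"flexible"`.
#' @param length Channel length (m), default `2.4 * tube_width`.
#' @param leaflet_length Leaflet length (m), default `0.42 * tube_width`;
#'   must not exceed half the width.
#' @param u_peak Peak inlet speed (m/s); default gives peak Reynolds number
#'   7000 for a 25 mm tube (about 0.79 m/s).
#' @param profile Optional [inlet_profile()] overriding the default.
#' @param theta0 Initial opening angle (degrees), default 30 (fully closed).
#' @param seed Seed recorded in the spec.
#' @return An [sph_case()] with rigid or flexible bodies attached, plus
#'   `case$valve` (hinge geometry, valve plane, lumen) and `case$samples`.
#' @export
make_bileaflet_valve_case <- function(tube_width = 0.025, dp,
                                      leaflet = c("rigid", "flexible"),
                                      length = 2.4 * tube_width,
                                      leaflet_length = 0.42 * tube_width,
                                      u_peak = NULL, profile = NULL,
                                      theta0 = 30, seed = 1L) {
  leaflet <- match.arg(leaflet)
  if (tube_width < 40 * dp)
    stop("resolution error: tube width must be at least 40 dp", call. = FALSE)
  if (leaflet_length > tube_width / 2)
    stop("geometry error: leaflet longer than half the tube width",
         call. = FALSE)
  rho0 <- 1060; mu <- 0.003
  if (is.null(u_peak)) u_peak <- 7000 * (mu / rho0) / 0.025
  if (is.null(profile)) profile <- inlet_profile(peak_speed = u_peak)

  base <- make_channel_case(height = tube_width, length = length, dp = dp,
                            drive = "inlet-outlet", u_max = u_peak,
                            profile = profile, inlet_shape = "parabolic",
                            delta_sph = 0.1, seed = seed)
  # the valve jet runs ~3x faster than the inlet plug (area contraction);
  # the weak-compressibility contract is set against the jet speed
  base$eos <- state_equation(rho0 = rho0,
                             c0 = design_sound_speed(3 * u_peak))
  sys <- base$system
  W <- tube_width
  x_v <- 0.3 * length               # valve plane
  stub_h <- 0.06 * W                # mounting-ring stub height
  th0 <- theta0 * pi / 180

  # mounting stubs: small boundary blocks on each wall at the valve plane
  sxs <- x_v + (-2:2) * dp
  stub <- function(ys) as.matrix(expand.grid(x = sxs, y = ys))[, 1:2]
  ys_b <- seq(dp / 2, stub_h, by = dp)
  ys_t <- W - ys_b
  stubs <- rbind(stub(ys_b), stub(ys_t))

  # hinges sit clear of the stub top: the plate extends 1.5 dp behind the
  # pivot, so a 3 dp offset keeps the swept circle (angle-independent) from
  # scissoring fluid against the stub
  hinge_b <- c(x_v, stub_h + 3 * dp)
  hinge_t <- c(x_v, W - stub_h - 3 * dp)
  dir_b <- c(sin(th0), cos(th0))    # bottom leaflet: towards centre, downstream
  dir_t <- c(sin(th0), -cos(th0))
  leaf_b <- .plate_lattice(hinge_b, dir_b, leaflet_length, dp)
  leaf_t <- .plate_lattice(hinge_t, dir_t, leaflet_length, dp)

  clear <- function(pos, pts, rad) {
    keep <- rep(TRUE, nrow(pos))
    for (k in seq_len(nrow(pts)))
      keep <- keep & ((pos[, 1] - pts[k, 1])^2 +
                        (pos[, 2] - pts[k, 2])^2 > rad^2)
    keep
  }
  fluid <- sys$tag == 0L
  drop_f <- fluid & !clear(sys$pos, rbind(stubs, leaf_b, leaf_t), 0.8 * dp)
  sys <- subset_system(sys, !drop_f)

  n0 <- n_particles(sys)
  sys <- append_particles(sys, stubs, matrix(0, nrow(stubs), 2),
                          rho = rho0, p = 0, mass = rho0 * dp^2, tag = 1L)
  nb <- n_particles(sys)
  id_b <- nb + seq_len(nrow(leaf_b))
  sys <- append_particles(sys, leaf_b, matrix(0, nrow(leaf_b), 2),
                          rho = rho0, p = 0, mass = rho0 * dp^2,
                          tag = if (leaflet == "rigid") 2L else 3L, body = 1L)
  nb <- n_particles(sys)
  id_t <- nb + seq_len(nrow(leaf_t))
  sys <- append_particles(sys, leaf_t, matrix(0, nrow(leaf_t), 2),
                          rho = rho0, p = 0, mass = rho0 * dp^2,
                          tag = if (leaflet == "rigid") 2L else 3L, body = 2L)

  base$system <- sys
  rho_leaf <- 1100
  if (leaflet == "rigid") {
    # bottom leaflet opens clockwise (tip swings from the centreline towards
    # downstream), the mirrored top one counter-clockwise
    cb <- hinge_constraint(hinge_b, theta_closed = 30, theta_open = 85,
                           sense = -1)
    ct <- hinge_constraint(hinge_t, theta_closed = 30, theta_open = 85,
                           sense = 1)
    base$rigid_bodies <- list(
      rigid_body(leaf_b, masses = rho_leaf * dp^2, members = id_b,
                 constraint = cb, theta = theta0),
      rigid_body(leaf_t, masses = rho_leaf * dp^2, members = id_t,
                 constraint = ct, theta = theta0))
  } else {
    clamp_b <- sqrt(rowSums(sweep(leaf_b, 2, hinge_b, "-")^2)) < 1.6 * dp
    clamp_t <- sqrt(rowSums(sweep(leaf_t, 2, hinge_t, "-")^2)) < 1.6 * dp
    base$flexible_bodies <- list(
      flexible_body(leaf_b, dp, E = 1e6, nu = 0.49, rho0 = rho_leaf,
                    clamped = clamp_b, members = id_b),
      flexible_body(leaf_t, dp, E = 1e6, nu = 0.49, rho0 = rho_leaf,
                    clamped = clamp_t, members = id_t))
  }
  base$valve <- list(plane_origin = c(x_v, 0), plane_normal = c(1, 0),
                     lumen = c(0, W), hinge_bottom = hinge_b,
                     hinge_top = hinge_t, leaflet_length = leaflet_length)
  base$spec <- case_spec("bileaflet_valve", dp, seed = seed,
                         tube_width = W, length = length,
                         leaflet = leaflet, leaflet_length = leaflet_length,
                         u_peak = u_peak, theta0 = theta0)
  base
}

#' Cantilever-beam fixture (flexible-solid validation)
#'
#' Clamped-free 2D elastic beam with no fluid, for validating the
#' total-Lagrangian solid scheme against Euler-Bernoulli theory.  The clamp
#' is the first three particle columns; `analytic$tip_deflection` is
#' `F L_f^3 / (3 E I)` with `L_f` the free length and `I = t^3/12` (per
#' unit depth), and `analytic$first_frequency` the clamped-free first
#' bending frequency `(1.875^2 / 2 pi) sqrt(E I / (rho A L_f^4))`.
#'
#' @param length Total beam length (m); at least `5 * thickness`.
#' @param thickness Beam thickness (m); at least `3 dp`.
#' @param dp Particle spacing (m).
#' @param tip_load Transverse tip force F (N per unit depth), default 0.
#' @param E Young's modulus (Pa), default 1e6.
#' @param nu Poisson ratio, default 0.49.
#' @param rho0 Solid density (kg/m^3), default 1100.
#' @param alpha_visc Solid artificial viscosity (default 0.1).
#' @return List with the [flexible_body()] (`body`), `tip_ids`, `tip_load`,
#'   `analytic` targets and the `case_spec`.
#' @export
make_cantilever_case <- function(length, thickness, dp, tip_load = 0,
                                 E = 1e6, nu = 0.49, rho0 = 1100,
                                 alpha_visc = 0.1) {
  if (length < 5 * thickness)
    stop("geometry error: slenderness violated (length < 5 thickness)",
         call. = FALSE)
  if (thickness < 3 * dp)
    stop("geometry error: thickness must be at least 3 dp", call. = FALSE)
  nxc <- round(length / dp)
  nyc <- round(thickness / dp)
  xs <- (seq_len(nxc) - 0.5) * dp
  ys <- (seq_len(nyc) - (nyc + 1) / 2) * dp
  X <- as.matrix(expand.grid(x = xs, y = ys))[, 1:2]
  col_id <- rep(seq_len(nxc), times = nyc)
  clamped <- col_id <= 3L
  body <- flexible_body(X, dp, E = E, nu = nu, rho0 = rho0,
                        clamped = clamped, alpha_visc = alpha_visc)
  tip_ids <- which(col_id == nxc)
  Lf <- length - 3 * dp
  I_beam <- thickness^3 / 12
  A <- thickness
  analytic <- list(
    tip_deflection = tip_load * Lf^3 / (3 * E * I_beam),
    first_frequency = 1.875104^2 / (2 * pi) *
      sqrt(E * I_beam / (rho0 * A * Lf^4)))
  list(body = body, tip_ids = tip_ids, tip_load = tip_load,
       free_length = Lf, analytic = analytic,
       spec = case_spec("cantilever", dp, length = length,
                        thickness = thickness, tip_load = tip_load,
                        E = E, nu = nu, rho0 = rho0))
}
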