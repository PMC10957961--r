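#' Sub-particle-scale (SPS) turbulence closure configuration
#'
#' Smagorinsky-type large-eddy closure evaluated on the SPH velocity
#' gradient: eddy viscosity `mu_T = rho (C_s dl)^2 sqrt(2 S:S)` and SPS
#' stress `tau = 2 mu_T S - (2/3) rho k I - (2/3) C_I rho dl^2 (2 S:S) I`.
#'
#' @param Cs Smagorinsky constant (default 0.12).
#' @param CI Isotropic closure constant (default 0.0066).
#' @param k SPS turbulent kinetic energy (m^2/s^2, default 0).
#' @param dl Filter length scale (m); defaults to the initial particle
#'   spacing when built by a fixture.
#' @param enabled Logical; turn the closure off for laminar-only runs.
#' @return An object of class `sps_config`.
#' @export
sps_config <- function(Cs = 0.12, CI = 0.0066, k = 0, dl, enabled = TRUE) {
  stopifnot(Cs > 0, dl > 0)
  structure(list(Cs = Cs, CI = CI, k = k, dl = dl, enabled = enabled),
            class = "sps_config")
}

# shared low-level rate evaluation; returns drho, acc, gradu, tau
.fluid_rates <- function(system, pairs, kernel, sps = NULL,
                         delta_sph = 0, c0 = 0) {
  sps_on <- !is.null(sps) && isTRUE(sps$enabled)
  cpp_fluid_rates(system$pos, system$vel, system$rho, system$p, system$mass,
                  .interaction_tag(system$tag),
                  pairs$i, pairs$j, pairs$dx, pairs$r,
                  kernel$h, kernel$dim, system$mu,
                  sps_on,
                  if (sps_on) sps$Cs else 0.12,
                  if (sps_on) sps$CI else 0,
                  if (sps_on) sps$k else 0,
                  if (sps_on) sps$dl else kernel$h,
                  delta_sph, c0)
}

#' Continuity-equation density rate
#'
#' SPH discrete continuity:
#' `D rho_i / Dt = rho_i sum_j (m_j / rho_j) (u_i - u_j) . grad W_ij`.
#' Fluid particles sum over all neighbours; Dynamic Boundary Condition
#' particles (walls, rigid and flexible body members) sum over fluid and
#' buffer neighbours only, which is what generates their repulsive pressure
#' as fluid approaches; buffer densities are never integrated (they are
#' prescribed by ghost-point extrapolation).
#'
#' @param system A [particle_system()].
#' @param adjacency A [build_neighbor_list()] pair list for the current
#'   positions.
#' @param kernel A [kernel_spec()].
#' @return Numeric vector `drho/dt` (kg/m^3/s) per particle.
#' @export
continuity_rate <- function(system, adjacency, kernel) {
  .fluid_rates(system, adjacency, kernel, sps = NULL)$drho
}

#' Momentum-equation acceleration
#'
#' Symmetric pressure-gradient form plus dissipation and body force:
#' `Du_i/Dt = - sum_j m_j (p_i + p_j)/(rho_i rho_j) grad W_ij + Gamma + f`.
#' The dissipative term `Gamma` combines a Morris-type laminar operator with
#' the SPS sub-particle stresses when `sps` is enabled.  Forces act on every
#' pair with at least one fluid (or buffer) side; the accelerations
#' accumulated on boundary-like particles are the fluid loads used by the
#' FSI coupling.
#'
#' @inheritParams continuity_rate
#' @param sps Optional [sps_config()].
#' @param body_force Optional acceleration vector (m/s^2) applied to fluid
#'   particles, or an n x d matrix.
#' @return n x d matrix of accelerations (m/s^2).
#' @export
momentum_rate <- function(system, adjacency, kernel, sps = NULL,
                          body_force = NULL) {
  acc <- .fluid_rates(system, adjacency, kernel, sps = sps)$acc
  if (!is.null(body_force)) {
    fb <- if (is.matrix(body_force)) body_force else
      matrix(body_force, n_particles(system), sys_dim(system), byrow = TRUE)
    fluid <- system$tag == 0L
    acc[fluid, ] <- acc[fluid, , drop = FALSE] + fb[fluid, , drop = FALSE]
  }
  acc
}

#' SPS sub-particle stress tensors
#'
#' Evaluates the Smagorinsky closure per fluid particle from the (raw) SPH
#' velocity gradient.  Returned tensors are symmetric; rows of non-fluid
#' particles are zero.
#'
#' @inheritParams momentum_rate
#' @param sps An [sps_config()].
#' @return n x (d*d) matrix, each row a row-major flattened stress tensor
#'   (Pa).
#' @export
sps_stress_tensor <- function(system, adjacency, kernel, sps) {
  stopifnot(inherits(sps, "sps_config"))
  .fluid_rates(system, adjacency, kernel, sps = sps)$tau
}

#' Stable timestep bound
#'
#' Conservative CFL/viscous/body-force bound:
#' `dt = min(0.3 h/(c0 + U_max), 0.125 h^2 rho0 / mu, 0.25 sqrt(h/|f|))`.
#'
#' @param case An [sph_case()].
#' @return Timestep (s).
#' @export
stable_dt <- function(case) {
  sys <- case$system
  h <- case$kernel$h
  umax <- if (n_particles(sys)) max(sqrt(rowSums(sys$vel^2))) else 0
  dt <- 0.3 * h / (case$eos$c0 + umax)
  if (sys$mu > 0) dt <- min(dt, 0.125 * h^2 * sys$rho0 / sys$mu)
  fmag <- sqrt(sum(case$gravity^2))
  if (!is.null(case$body_force)) fmag <- fmag + sqrt(sum(case$body_force^2))
  if (fmag > 0) dt <- min(dt, 0.25 * sqrt(h / fmag))
  dt
}

#' Assemble a simulation case
#'
#' Container tying together the particle state and every model ingredient a
#' time step needs: kernel, state equation, turbulence closure, domain,
#' body forces, open-boundary zones and coupled rigid/flexible bodies.
#'
#' @param system A [particle_system()].
#' @param kernel A [kernel_spec()].
#' @param eos A [state_equation()].
#' @param sps An [sps_config()] or `NULL`.
#' @param domain An [sph_domain()] or `NULL` (padded bounding box).
#' @param gravity Gravity vector (m/s^2).
#' @param body_force Constant driving acceleration applied to fluid (m/s^2),
#'   or `NULL`.
#' @param zones List of [buffer_zone()] objects.
#' @param rigid_bodies List of [rigid_body()] objects (with `constraint`
#'   attached).
#' @param flexible_bodies List of [flexible_body()] objects.
#' @param delta_sph delta-SPH density-diffusion coefficient (0 = off).
#' @param spec Optional case metadata (a `case_spec` list from the fixture
#'   generators).
#' @return An object of class `sph_case`.
#' @export
sph_case <- function(system, kernel, eos, sps = NULL, domain = NULL,
                     gravity = rep(0, sys_dim(system)), body_force = NULL,
                     zones = list(), rigid_bodies = list(),
                     flexible_bodies = list(), delta_sph = 0, spec = NULL) {
  if (is.null(domain)) domain <- default_domain(system, kernel$support_radius)
  structure(
    list(system = system, kernel = kernel, eos = eos, sps = sps,
         domain = domain, gravity = gravity, body_force = body_force,
         zones = zones, rigid_bodies = rigid_bodies,
         flexible_bodies = flexible_bodies, delta_sph = delta_sph,
         spec = spec, t = 0,
         io_log = list(mass_in = 0, mass_out = 0)),
    class = "sph_case")
}

#' @export
print.sph_case <- function(x, ...) {
  cat(sprintf("<sph_case> t = %.4g s, %d particles, %d zones, %d rigid, %d flexible\n",
              x$t, n_particles(x$system), length(x$zones),
              length(x$rigid_bodies), length(x$flexible_bodies)))
  invisible(x)
}

#' Advance one timestep
#'
#' Symplectic position-Verlet style update: refresh open-boundary buffer
#' states, evaluate continuity and momentum rates, kick velocities, drift
#' positions with the mid-step velocity, integrate densities, update
#' pressures through the state equation, integrate coupled rigid and
#' flexible bodies with the fluid loads, then apply the open-boundary
#' particle bookkeeping.  Masses never change; the particle count changes
#' only through inlet/outlet zones.
#'
#' @param case An [sph_case()].
#' @param dt Timestep (s); must satisfy [stable_dt()].
#' @param check_dt Refuse `dt` above the stability bound (default `TRUE`).
#' @return The advanced `sph_case`.
#' @export
advance_timestep <- function(case, dt, check_dt = TRUE) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  if (check_dt && dt > 1.0001 * stable_dt(case))
    stop(sprintf("stability error: dt = %g exceeds the stable bound %g",
                 dt, stable_dt(case)), call. = FALSE)
  sys <- case$system
  kernel <- case$kernel

  pairs <- build_neighbor_list(sys, kernel$support_radius, case$domain)

  if (length(case$zones)) {
    sys <- refresh_buffer_states(sys, case$zones, kernel, case$eos, case$t)
    case$system <- sys
  }

  rates <- .fluid_rates(sys, pairs, kernel, sps = case$sps,
                        delta_sph = case$delta_sph, c0 = case$eos$c0)
  acc <- rates$acc
  fluid <- sys$tag == 0L
  d <- sys_dim(sys)
  bf <- case$gravity
  if (!is.null(case$body_force)) bf <- bf + case$body_force
  if (any(bf != 0))
    acc[fluid, ] <- acc[fluid, , drop = FALSE] +
      matrix(bf, sum(fluid), d, byrow = TRUE)

  # fluid kick-drift
  u_old <- sys$vel
  sys$vel[fluid, ] <- sys$vel[fluid, , drop = FALSE] +
    dt * acc[fluid, , drop = FALSE]
  sys$pos[fluid, ] <- sys$pos[fluid, , drop = FALSE] +
    dt * 0.5 * (sys$vel[fluid, , drop = FALSE] + u_old[fluid, , drop = FALSE])

  # buffer particles advect with their prescribed/extrapolated velocity
  buf <- sys$tag == 4L
  if (any(buf))
    sys$pos[buf, ] <- sys$pos[buf, , drop = FALSE] +
      dt * sys$vel[buf, , drop = FALSE]

  # wrap positions on periodic axes back into the box
  for (a in which(case$domain$periodic)) {
    span <- case$domain$hi[a] - case$domain$lo[a]
    sys$pos[, a] <- case$domain$lo[a] +
      (sys$pos[, a] - case$domain$lo[a]) %% span
  }

  # densities: fluid + DBC boundary-like, integrated semi-implicitly with
  # the end-of-step velocities (keeps the acoustic u-rho coupling stable)
  drho <- cpp_continuity(sys$vel, sys$rho, sys$mass,
                         .interaction_tag(sys$tag),
                         pairs$i, pairs$j, pairs$dx, pairs$r,
                         kernel$h, d, case$delta_sph, case$eos$c0)
  dbc <- fluid | .boundary_like(sys$tag)
  sys$rho[dbc] <- sys$rho[dbc] + dt * drho[dbc]
  # DBC pressure floor at 0: through the monotone EOS this is a density
  # floor at rho0 (walls never pull on the fluid)
  blike <- .boundary_like(sys$tag)
  sys$rho[blike] <- pmax(sys$rho[blike], sys$rho0)
  sys$p <- equation_of_state(sys$rho, case$eos)

  case$system <- sys

  # rigid bodies: hinge dynamics driven by the fluid loads on members
  if (length(case$rigid_bodies)) {
    for (bi in seq_along(case$rigid_bodies)) {
      body <- case$rigid_bodies[[bi]]
      fk <- acc[body$members, , drop = FALSE]  # fluid force per unit mass
      if (body$gravity_on)
        fk <- fk + matrix(case$gravity, nrow(fk), d, byrow = TRUE)
      loads <- aggregate_rigid_loads(body, fk)
      body <- integrate_hinged_body(body, body$constraint, loads, dt)
      case$system$pos[body$members, ] <- body$member_pos
      case$system$vel[body$members, ] <- rigid_boundary_velocities(body)
      case$rigid_bodies[[bi]] <- body
    }
  }

  # flexible bodies: sub-cycled total-Lagrangian dynamics with frozen
  # fluid coupling accelerations over the fluid step
  if (length(case$flexible_bodies)) {
    for (bi in seq_along(case$flexible_bodies)) {
      fb <- case$flexible_bodies[[bi]]
      # reaction: fluid-side force on member boundary particles, converted to
      # acceleration on the (denser) structural particles
      f_couple <- acc[fb$members, , drop = FALSE] *
        (case$system$mass[fb$members] / fb$mass_solid)
      fb <- step_flexible_body(fb, dt, f_couple, case$gravity)
      case$system$pos[fb$members, ] <- fb$x
      case$system$vel[fb$members, ] <- fb$v
      case$flexible_bodies[[bi]] <- fb
    }
  }

  case$t <- case$t + dt
  if (length(case$zones)) case <- update_open_boundaries(case)
  case
}

#' Advance many timesteps
#'
#' Convenience loop over [advance_timestep()] with a fixed `dt`.
#'
#' @param case An [sph_case()].
#' @param n Number of steps.
#' @param dt Timestep (s); defaults to [stable_dt()] evaluated at entry.
#' @return The advanced `sph_case`.
#' @export
advance_steps <- function(case, n, dt = NULL) {
  if (is.null(dt)) dt <- stable_dt(case)
  for (s in seq_len(n)) case <- advance_timestep(case, dt, check_dt = FALSE)
  case
}
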