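#' Pulsatile inlet waveform
#'
#' Parameterised synthetic cardiac waveform: a C1-smooth systolic pulse
#' (squared half-sine rise to `peak_speed` at `peak_time`, matching decay to
#' the end of systole) on top of a low diastolic plateau, periodic with the
#' cardiac period `T`.
#'
#' @param period Cardiac period T (s), default 0.8.
#' @param peak_time Time of peak systole within the cycle (s), default 0.1.
#' @param peak_speed Peak inlet speed U_peak (m/s).
#' @param systolic_fraction Fraction of the cycle occupied by systole
#'   (default 0.35).
#' @param diastolic_fraction Diastolic plateau speed as a fraction of
#'   `peak_speed` (default 0.05).
#' @return An object of class `inlet_profile`.
#' @export
inlet_profile <- function(period = 0.8, peak_time = 0.1, peak_speed,
                          systolic_fraction = 0.35,
                          diastolic_fraction = 0.05) {
  stopifnot(period > 0, peak_time > 0, peak_time < systolic_fraction * period,
            peak_speed > 0)
  structure(list(period = period, peak_time = peak_time,
                 peak_speed = peak_speed,
                 systolic_fraction = systolic_fraction,
                 diastolic_fraction = diastolic_fraction),
            class = "inlet_profile")
}

#' Inlet speed at a given time
#'
#' Evaluates the pulsatile waveform; vectorised over `t`.  The maximum over
#' one period is exactly `peak_speed`, attained at `peak_time`, and the
#' function is periodic: `value(t) = value(t + period)`.
#'
#' @param t Time(s) (s), non-negative.
#' @param profile An [inlet_profile()].
#' @return Inlet speed(s) (m/s).
#' @export
pulsatile_inlet_velocity <- function(t, profile) {
  stopifnot(inherits(profile, "inlet_profile"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  T <- profile$period
  tp <- profile$peak_time
  ts <- profile$systolic_fraction * T
  base <- profile$diastolic_fraction * profile$peak_speed
  amp <- profile$peak_speed - base
  tm <- t %% T
  u <- rep(base, length(tm))
  rise <- tm <= tp
  u[rise] <- base + amp * sin(pi * tm[rise] / (2 * tp))^2
  decay <- tm > tp & tm < ts
  u[decay] <- base + amp * sin(pi / 2 * (1 - (tm[decay] - tp) / (ts - tp)))^2
  u
}

#' Inlet/outlet buffer zone
#'
#' Open boundaries are emulated with a slab of buffer particles, `layers`
#' particle rows deep (default 5, enough for full kernel support), behind the
#' boundary plane.  The inlet prescribes the (plug) velocity from the
#' pulsatile waveform; the outlet prescribes a constant pressure.  All other
#' buffer fields are extrapolated from interior ghost points with first-order
#' consistency.
#'
#' @param role `"inlet"` or `"outlet"`.
#' @param origin Point on the boundary plane (m).
#' @param normal Unit vector normal to the plane, pointing into the fluid
#'   domain.
#' @param dp Particle spacing (m); layer thickness is `layers * dp`.
#' @param layers Number of buffer layers (default 5).
#' @param profile An [inlet_profile()] (inlet role).
#' @param pressure Prescribed gauge pressure (Pa, outlet role, default 0).
#' @param shape Optional function of an n x d position matrix returning a
#'   multiplier in `[0, 1]` applied to the inlet plug speed (used by the
#'   fixtures to ramp the plug down over a few particle spacings at the
#'   walls, which avoids jamming no-slip corner fluid).
#' @return An object of class `buffer_zone`.
#' @export
buffer_zone <- function(role = c("inlet", "outlet"), origin, normal, dp,
                        layers = 5L, profile = NULL, pressure = 0,
                        shape = NULL) {
  role <- match.arg(role)
  normal <- normal / sqrt(sum(normal^2))
  if (role == "inlet" && is.null(profile))
    stop("inlet zones need an `inlet_profile`", call. = FALSE)
  structure(list(role = role, origin = as.numeric(origin),
                 normal = as.numeric(normal), dp = dp,
                 layers = as.integer(layers),
                 thickness = layers * dp,
                 profile = profile, pressure = pressure, shape = shape),
            class = "buffer_zone")
}

# signed distance from the boundary plane, positive inside the fluid domain
.zone_s <- function(zone, pos) {
  sweep(pos, 2, zone$origin, "-") %*% zone$normal
}

# membership test for the zone's buffer slab
.in_zone_slab <- function(zone, pos, pad = 0.51 * zone$dp) {
  s <- .zone_s(zone, pos)
  s < pad & s > -(zone$thickness + pad)
}

# density consistent with a prescribed pressure (inverse Tait)
.rho_from_p <- function(p, eos) {
  B <- eos$c0^2 * eos$rho0 / eos$gamma
  eos$rho0 * (1 + p / B)^(1 / eos$gamma)
}

#' Ghost-point field extrapolation for a buffer zone
#'
#' The raw first-order consistent extrapolation behind the open-boundary
#' treatment: each buffer particle is mirrored across the boundary plane to
#' a ghost point inside the fluid; density and velocity are fitted there by
#' a moving-least-squares linear interpolant over nearby fluid particles
#' and extrapolated linearly back to the buffer particle.  A field that is
#' linear in space is reproduced exactly.
#'
#' @param system A [particle_system()].
#' @param zone A [buffer_zone()].
#' @param kernel A [kernel_spec()].
#' @param ids Buffer particle indices to fill (defaults to all buffer
#'   particles inside the zone slab).
#' @return Matrix with one row per `id`: column 1 density, columns 2..d+1
#'   velocity; or `NULL` if too few fluid sources are in reach.
#' @export
extrapolate_ghost_fields <- function(system, zone, kernel, ids = NULL) {
  d <- sys_dim(system)
  if (is.null(ids)) {
    buf <- which(system$tag == 4L)
    ids <- buf[.in_zone_slab(zone, system$pos[buf, , drop = FALSE])]
  }
  if (!length(ids)) return(NULL)
  fluid <- which(system$tag == 0L)
  s <- drop(.zone_s(zone, system$pos[ids, , drop = FALSE]))
  ghost <- system$pos[ids, , drop = FALSE] -
    2 * s %o% zone$normal  # mirror across the plane, inside the fluid
  # restrict MLS sources to fluid within reach of any ghost point
  sf <- drop(.zone_s(zone, system$pos[fluid, , drop = FALSE]))
  src <- fluid[sf > -zone$dp & sf < zone$thickness + 2 * kernel$h]
  if (length(src) < 3) return(NULL)
  fields <- cbind(system$rho[src], system$vel[src, , drop = FALSE])
  mls <- cpp_mls_eval(ghost, system$pos[src, , drop = FALSE],
                      fields, particle_volumes(system)[src],
                      kernel$h, d)
  off <- system$pos[ids, , drop = FALSE] - ghost
  ex <- mls$val
  for (f in seq_len(ncol(fields))) {
    gr <- mls$grad[, ((f - 1) * d + 1):(f * d), drop = FALSE]
    ex[, f] <- ex[, f] + rowSums(gr * off)
  }
  ex
}

#' Refresh buffer-particle states by ghost-point extrapolation
#'
#' For every buffer particle a ghost point is placed at its mirror image
#' inside the fluid domain; density, pressure and velocity are fitted there
#' with a first-order consistent moving-least-squares interpolant over the
#' fluid particles and extrapolated linearly back to the buffer particle.
#' Inlets then override the velocity with the prescribed plug waveform;
#' outlets override the pressure (and the EOS-consistent density) with the
#' prescribed constant value.
#'
#' @param system A [particle_system()].
#' @param zones List of [buffer_zone()] objects.
#' @param kernel A [kernel_spec()].
#' @param eos A [state_equation()].
#' @param t Current time (s), for the inlet waveform.
#' @return The updated `particle_system`.
#' @export
refresh_buffer_states <- function(system, zones, kernel, eos, t) {
  d <- sys_dim(system)
  buf <- which(system$tag == 4L)
  if (!length(buf)) return(system)
  claimed <- logical(length(buf))
  for (zone in zones) {
    inz <- which(!claimed & .in_zone_slab(zone, system$pos[buf, , drop = FALSE]))
    if (!length(inz)) next
    claimed[inz] <- TRUE
    ids <- buf[inz]
    ex <- extrapolate_ghost_fields(system, zone, kernel, ids)
    if (!is.null(ex)) {
      bad <- !is.finite(ex[, 1])
      ex[bad, 1] <- eos$rho0
      ex[is.na(ex)] <- 0
      # clamp the linear extrapolation to physically plausible ranges: the
      # WCSPH contract keeps |rho - rho0| small, and buffer speeds cannot
      # exceed the interior flow scale
      system$rho[ids] <- pmin(pmax(ex[, 1], 0.9 * eos$rho0), 1.1 * eos$rho0)
      vmax <- 0.3 * eos$c0  # fixed cap: flow stays well below sound speed
      system$vel[ids, ] <- pmin(pmax(ex[, 2:(1 + d), drop = FALSE], -vmax),
                                vmax)
    }
    if (zone$role == "inlet") {
      u_in <- pulsatile_inlet_velocity(t, zone$profile)
      fac <- if (is.null(zone$shape)) rep(1, length(ids))
             else rep_len(zone$shape(system$pos[ids, , drop = FALSE]),
                          length(ids))
      system$vel[ids, ] <- (u_in * fac) %o% zone$normal
    } else {
      system$rho[ids] <- .rho_from_p(zone$pressure, eos)
      # outlet buffers advect as a plug moving with the adjacent fluid's
      # mean normal (discharge) velocity: per-particle extrapolation noise
      # otherwise feeds back as spurious tension spikes, and a faster
      # buffer column would drain the slab when the outflow stalls
      fl <- which(system$tag == 0L)
      sfl <- drop(.zone_s(zone, system$pos[fl, , drop = FALSE]))
      near <- fl[sfl > 0 & sfl <= 2 * kernel$h]
      un_mean <- if (length(near))
        min(mean(drop(system$vel[near, , drop = FALSE] %*% zone$normal)), 0)
      else 0
      system$vel[ids, ] <- matrix(un_mean * zone$normal, length(ids), d,
                                  byrow = TRUE)
    }
    system$p[ids] <- equation_of_state(system$rho[ids], eos)
  }
  system
}

#' DBC boundary density update
#'
#' Dynamic Boundary Condition: wall particles never move (their velocity is
#' the wall's, zero for static walls) but their densities evolve by the same
#' continuity equation using fluid neighbours, so an approaching fluid
#' particle compresses the wall field and feels a repulsive pressure.
#'
#' @param system A [particle_system()].
#' @param adjacency A [build_neighbor_list()] pair list.
#' @param kernel A [kernel_spec()].
#' @param dt Timestep (s).
#' @return The `particle_system` with updated boundary densities (fluid
#'   densities untouched).
#' @export
dbc_density_update <- function(system, adjacency, kernel, dt) {
  drho <- continuity_rate(system, adjacency, kernel)
  blike <- .boundary_like(system$tag)
  system$rho[blike] <- pmax(system$rho[blike] + dt * drho[blike],
                            system$rho0)
  system
}

#' Open-boundary particle bookkeeping
#'
#' Applies the inlet/outlet conversion rules after a step: inlet buffer
#' particles that cross the boundary plane become fluid and a replacement
#' buffer particle is injected one buffer length upstream; fluid particles
#' that enter an inlet buffer are removed; fluid particles that enter an
#' outlet buffer become buffer particles; buffer particles leaving the
#' downstream end of an outlet are removed.  Injected/removed masses are
#' accumulated in `case$io_log` for mass-balance auditing.
#'
#' @param case An [sph_case()] whose system has already been advanced.
#' @return The updated `sph_case`.
#' @export
update_open_boundaries <- function(case) {
  sys <- case$system
  d <- sys_dim(sys)
  drop_mask <- logical(n_particles(sys))
  pad <- function(mask, n) c(mask, logical(max(0L, n - length(mask))))
  for (zone in case$zones) {
    drop_mask <- pad(drop_mask, n_particles(sys))
    s_all <- drop(.zone_s(zone, sys$pos))
    if (zone$role == "inlet") {
      # buffer -> fluid on crossing; clone a replacement upstream
      conv <- which(sys$tag == 4L & s_all >= 0 &
                      s_all < zone$thickness)  # guard against other zones
      if (length(conv)) {
        sys$tag[conv] <- 0L
        case$io_log$mass_in <- case$io_log$mass_in + sum(sys$mass[conv])
        newpos <- sys$pos[conv, , drop = FALSE] -
          matrix(zone$thickness * zone$normal, length(conv), d, byrow = TRUE)
        sys <- append_particles(sys, newpos,
                                sys$vel[conv, , drop = FALSE],
                                rho = sys$rho[conv], p = sys$p[conv],
                                mass = sys$mass[conv], tag = 4L)
        s_all <- drop(.zone_s(zone, sys$pos))
      }
      # fluid that backed into the inlet buffer is removed
      gone <- sys$tag == 0L & s_all < 0 & s_all > -(zone$thickness + zone$dp)
      if (any(gone)) {
        case$io_log$mass_out <- case$io_log$mass_out + sum(sys$mass[gone])
        drop_mask <- pad(drop_mask, n_particles(sys)) | gone
      }
    } else {
      # fluid crossing the outlet plane becomes buffer
      conv <- which(sys$tag == 0L & s_all < 0 &
                      s_all > -(zone$thickness + zone$dp))
      if (length(conv)) {
        sys$tag[conv] <- 4L
        case$io_log$mass_out <- case$io_log$mass_out + sum(sys$mass[conv])
      }
      # buffer beyond the downstream end is removed
      gone <- sys$tag == 4L & s_all <= -(zone$thickness)
      drop_mask <- pad(drop_mask, n_particles(sys)) | gone
    }
  }
  drop_mask <- pad(drop_mask, n_particles(sys))
  if (any(drop_mask)) {
    sys <- subset_system(sys, !drop_mask)
    # particle deletion shifts indices: remap body membership
    newpos <- cumsum(!drop_mask)
    for (bi in seq_along(case$rigid_bodies))
      case$rigid_bodies[[bi]]$members <-
        newpos[case$rigid_bodies[[bi]]$members]
    for (bi in seq_along(case$flexible_bodies))
      case$flexible_bodies[[bi]]$members <-
        newpos[case$flexible_bodies[[bi]]$members]
  }
  # sanity: each zone still fully populated
  for (zone in case$zones) {
    nb <- sum(sys$tag == 4L & .in_zone_slab(zone, sys$pos))
    if (nb == 0)
      stop("replenishment failure: ", zone$role, " buffer underflow",
           call. = FALSE)
  }
  case$system <- sys
  case
}
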