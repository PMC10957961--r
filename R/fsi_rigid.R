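#' Hinge constraint for a mechanical leaflet
#'
#' A single rotational degree of freedom about a fixed pivot axis with hard
#' angular stops.  Angles follow the bi-leaflet mechanical valve convention:
#' fully closed at 30 degrees, fully open at 85 degrees.
#'
#' @param pivot Pivot point (m).
#' @param axis Rotation axis unit vector (3D); in 2D the axis is implicitly
#'   the out-of-plane z axis and this argument is ignored.
#' @param theta_closed,theta_open Angular limits (degrees), defaults 30
#'   and 85.
#' @param sense +1 if increasing opening angle is a positive (right-handed)
#'   rotation about the axis, -1 otherwise (two mirrored leaflets of one
#'   valve open with opposite senses).
#' @return An object of class `hinge_constraint`.
#' @export
hinge_constraint <- function(pivot, axis = c(0, 0, 1),
                             theta_closed = 30, theta_open = 85,
                             sense = 1) {
  stopifnot(theta_open > theta_closed, sense %in% c(-1, 1))
  axis <- axis / sqrt(sum(axis^2))
  structure(list(pivot = as.numeric(pivot), axis = axis,
                 theta_closed = theta_closed, theta_open = theta_open,
                 sense = sense),
            class = "hinge_constraint")
}

#' Rigid body built from member particles
#'
#' Aggregates member particles into a rigid body: total mass `M = sum m_k`,
#' mass-weighted centroid `R0`, and (for hinged integration) the moment of
#' inertia about the hinge axis by direct summation over members.  Member
#' masses are structural masses (leaflet density, default 1100 kg/m^3, times
#' particle volume), independent of the fluid-interaction masses the same
#' particles carry in the particle system.
#'
#' @param member_pos n_k x d matrix of member particle positions (m).
#' @param masses Structural member masses (kg), scalar or per particle.
#' @param members Optional indices of the members in the host
#'   [particle_system()].
#' @param constraint A [hinge_constraint()], or `NULL` for a free body.
#' @param theta Current opening angle (degrees); defaults to
#'   `constraint$theta_closed`.
#' @param gravity_on Apply the case gravity to the body (default `FALSE`:
#'   valve orientation unspecified).
#' @return An object of class `rigid_body`.
#' @export
rigid_body <- function(member_pos, masses, members = NULL, constraint = NULL,
                       theta = NULL, gravity_on = FALSE) {
  member_pos <- as.matrix(member_pos)
  nk <- nrow(member_pos)
  if (nk == 0L) stop("empty body: a rigid body needs member particles",
                     call. = FALSE)
  masses <- rep_len(masses, nk)
  M <- sum(masses)
  R0 <- colSums(member_pos * masses) / M
  if (!is.null(constraint) && is.null(theta)) theta <- constraint$theta_closed
  structure(list(member_pos = member_pos, masses = masses,
                 members = members, M = M, R0 = R0,
                 V = numeric(ncol(member_pos)), omega = 0,
                 constraint = constraint, theta = theta,
                 gravity_on = gravity_on),
            class = "rigid_body")
}

# z-component (2D) or full 3-vector cross product
.cross <- function(a, b) {
  if (length(a) == 2L) a[1] * b[2] - a[2] * b[1]
  else c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
}

#' Aggregate fluid loads on a rigid body
#'
#' Newton's equations for particle-built rigid bodies: total force
#' `F = sum_k m_k f_k` and torque about the centre of mass
#' `tau = sum_k m_k (r_k - R0) x f_k`, where `f_k` is the fluid-exerted
#' acceleration on member particle `k`.
#'
#' @param body A [rigid_body()].
#' @param fk n_k x d matrix of per-member accelerations (m/s^2).
#' @return List with `force` (N, length d) and `torque` (N m; scalar
#'   z-component in 2D, 3-vector in 3D).
#' @export
aggregate_rigid_loads <- function(body, fk) {
  stopifnot(inherits(body, "rigid_body"))
  fk <- as.matrix(fk)
  stopifnot(nrow(fk) == nrow(body$member_pos))
  d <- ncol(body$member_pos)
  Fk <- fk * body$masses
  force <- colSums(Fk)
  arm <- sweep(body$member_pos, 2, body$R0, "-")
  if (d == 2L) {
    torque <- sum(arm[, 1] * Fk[, 2] - arm[, 2] * Fk[, 1])
  } else {
    torque <- c(sum(arm[, 2] * Fk[, 3] - arm[, 3] * Fk[, 2]),
                sum(arm[, 3] * Fk[, 1] - arm[, 1] * Fk[, 3]),
                sum(arm[, 1] * Fk[, 2] - arm[, 2] * Fk[, 1]))
  }
  list(force = force, torque = torque)
}

# inertia about the hinge axis (parallel-axis by direct member summation)
.hinge_inertia <- function(body, constraint) {
  d <- ncol(body$member_pos)
  rel <- sweep(body$member_pos, 2, constraint$pivot, "-")
  if (d == 2L) {
    sum(body$masses * rowSums(rel^2))
  } else {
    ax <- constraint$axis
    along <- drop(rel %*% ax)
    perp2 <- rowSums(rel^2) - along^2
    sum(body$masses * perp2)
  }
}

# rotate points about pivot/axis by angle dtheta (radians)
.rotate_about <- function(pts, pivot, axis, dtheta) {
  d <- ncol(pts)
  rel <- sweep(pts, 2, pivot, "-")
  co <- cos(dtheta); si <- sin(dtheta)
  if (d == 2L) {
    rot <- cbind(co * rel[, 1] - si * rel[, 2],
                 si * rel[, 1] + co * rel[, 2])
  } else {
    ax <- axis / sqrt(sum(axis^2))
    dotp <- drop(rel %*% ax)
    crossp <- cbind(ax[2] * rel[, 3] - ax[3] * rel[, 2],
                    ax[3] * rel[, 1] - ax[1] * rel[, 3],
                    ax[1] * rel[, 2] - ax[2] * rel[, 1])
    rot <- rel * co + crossp * si + (dotp %o% ax) * (1 - co)
  }
  sweep(rot, 2, pivot, "+")
}

#' Integrate a hinged rigid body
#'
#' Generalised-coordinate reduction to the single hinge angle: the axial
#' torque (transferred from the centre of mass to the pivot) drives
#' `theta_ddot = tau_axis / I_axis`; semi-implicit integration; hard stops
#' are perfectly inelastic (angular velocity zeroed on contact).  Member
#' positions are rotated rigidly, so intra-body distances are preserved to
#' machine precision.
#'
#' @param body A [rigid_body()].
#' @param constraint A [hinge_constraint()]; `NULL` uses `body$constraint`.
#' @param loads Output of [aggregate_rigid_loads()].
#' @param dt Timestep (s), positive.
#' @return The updated `rigid_body`.
#' @export
integrate_hinged_body <- function(body, constraint, loads, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(constraint)) constraint <- body$constraint
  stopifnot(inherits(constraint, "hinge_constraint"))
  d <- ncol(body$member_pos)
  # torque about the pivot = torque about R0 + (R0 - pivot) x F
  arm <- body$R0 - constraint$pivot
  if (d == 2L) {
    tau_axis <- loads$torque + .cross(arm, loads$force)
  } else {
    tau_p <- loads$torque + .cross(arm, loads$force)
    tau_axis <- sum(tau_p * constraint$axis)
  }
  I_axis <- .hinge_inertia(body, constraint)
  sense <- if (is.null(constraint$sense)) 1 else constraint$sense
  # generalized coordinate is the opening angle: theta_ddot = sense tau / I
  omega <- body$omega + dt * sense * tau_axis / I_axis
  theta_new <- body$theta + dt * omega * 180 / pi
  if (theta_new >= constraint$theta_open) {
    theta_new <- constraint$theta_open
    omega <- 0
  } else if (theta_new <= constraint$theta_closed) {
    theta_new <- constraint$theta_closed
    omega <- 0
  }
  dtheta <- sense * (theta_new - body$theta) * pi / 180  # physical rotation
  if (dtheta != 0) {
    axis <- if (d == 2L) c(0, 0, 1) else constraint$axis
    body$member_pos <- .rotate_about(body$member_pos, constraint$pivot,
                                     axis, dtheta)
    body$R0 <- drop(.rotate_about(matrix(body$R0, 1), constraint$pivot,
                                  axis, dtheta))
  }
  body$theta <- theta_new
  body$omega <- omega
  body$constraint <- constraint
  # centre-of-mass velocity from the hinge rotation (physical rate)
  om_phys <- sense * omega
  relR <- body$R0 - constraint$pivot
  if (d == 2L) {
    body$V <- om_phys * c(-relR[2], relR[1])
  } else {
    body$V <- .cross(om_phys * constraint$axis, relR)
  }
  body
}

#' Member-particle velocities of a rigid body
#'
#' `u_k = V + Omega x (r_k - R0)` for every member particle, with `Omega`
#' the hinge angular velocity about the constraint axis.
#'
#' @param body A [rigid_body()].
#' @return n_k x d matrix of velocities (m/s).
#' @export
rigid_boundary_velocities <- function(body) {
  d <- ncol(body$member_pos)
  sense <- if (is.null(body$constraint) || is.null(body$constraint$sense)) 1
           else body$constraint$sense
  om_phys <- sense * body$omega
  arm <- sweep(body$member_pos, 2, body$R0, "-")
  if (d == 2L) {
    u <- cbind(-om_phys * arm[, 2], om_phys * arm[, 1])
  } else {
    Om <- om_phys * body$constraint$axis
    u <- cbind(Om[2] * arm[, 3] - Om[3] * arm[, 2],
               Om[3] * arm[, 1] - Om[1] * arm[, 3],
               Om[1] * arm[, 2] - Om[2] * arm[, 1])
  }
  sweep(u, 2, body$V, "+")
}
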