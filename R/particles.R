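#' Particle tag codes
#'
#' Integer codes for particle roles: `fluid` (0) free-moving fluid,
#' `boundary` (1) Dynamic Boundary Condition wall particles, `rigid` (2)
#' members of a rigid body, `flexible` (3) members of a flexible body and
#' `buffer` (4) inlet/outlet buffer particles.
#'
#' @return Named integer vector of tag codes.
#' @export
particle_tags <- function() {
  c(fluid = 0L, boundary = 1L, rigid = 2L, flexible = 3L, buffer = 4L)
}

# tags that behave as DBC boundary-like particles towards the fluid
.boundary_like <- function(tag) tag %in% c(1L, 2L, 3L)

# collapse tags to the 3-way interaction code used by the C++ kernels:
# 0 fluid, 1 boundary-like, 2 buffer
.interaction_tag <- function(tag) {
  out <- integer(length(tag))
  out[.boundary_like(tag)] <- 1L
  out[tag == 4L] <- 2L
  out
}

#' Create a particle system
#'
#' The arrays-of-record state shared by all solver modules: one row per
#' particle.  Masses are fixed at construction and never change during a
#' simulation (the WCSPH contract); densities evolve through the continuity
#' equation and pressures follow from the equation of state.
#'
#' @param positions n x d numeric matrix of positions (m), d in `{1, 2, 3}`.
#' @param velocities n x d matrix (m/s); defaults to zero.
#' @param rho Densities (kg/m^3); defaults to `rho0`.
#' @param mass Particle masses (kg); defaults to `rho0 * dp^d` (requires
#'   `dp`).
#' @param tag Integer tags, see [particle_tags()]; scalar or length n.
#' @param body Integer body id per particle (0 = none).
#' @param rho0 Reference density (kg/m^3).  Default 1060 (blood).
#' @param mu Dynamic viscosity (Pa s).  Default 0.003 (blood, Newtonian).
#' @param dp Initial particle spacing (m), used for default masses and kept
#'   as metadata.
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, velocities = NULL, rho = NULL,
                            mass = NULL, tag = 0L, body = 0L,
                            rho0 = 1060, mu = 0.003, dp = NULL) {
  pos <- as.matrix(positions)
  n <- nrow(pos)
  d <- ncol(pos)
  stopifnot(d %in% 1:3)
  if (is.null(velocities)) velocities <- matrix(0, n, d)
  vel <- as.matrix(velocities)
  stopifnot(nrow(vel) == n, ncol(vel) == d)
  if (is.null(rho)) rho <- rep(rho0, n)
  if (any(rho <= 0)) stop("densities must be positive", call. = FALSE)
  if (is.null(mass)) {
    if (is.null(dp)) stop("either `mass` or `dp` must be given", call. = FALSE)
    mass <- rep(rho0 * dp^d, n)
  }
  mass <- rep_len(mass, n)
  tag <- rep_len(as.integer(tag), n)
  body <- rep_len(as.integer(body), n)
  structure(
    list(pos = pos, vel = vel, rho = rep_len(as.numeric(rho), n),
         p = numeric(n), mass = mass, tag = tag, body = body,
         rho0 = rho0, mu = mu, dp = dp),
    class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  tg <- particle_tags()
  counts <- vapply(tg, function(code) sum(x$tag == code), integer(1))
  cat(sprintf("<particle_system> %d particles, dim %d (%s)\n",
              nrow(x$pos), ncol(x$pos),
              paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

#' Number of particles / dimension helpers
#' @param system A [particle_system()].
#' @return Integer.
#' @export
n_particles <- function(system) nrow(system$pos)

#' @rdname n_particles
#' @export
sys_dim <- function(system) ncol(system$pos)

#' Particle volumes V = m / rho
#' @param system A [particle_system()].
#' @return Numeric vector of volumes (m^dim).
#' @export
particle_volumes <- function(system) system$mass / system$rho

#' Coerce a particle system to a tibble
#'
#' One row per particle with columns `x`, `y` (, `z`), `vx`, `vy` (, `vz`),
#' `rho`, `p`, `mass`, `tag` (labelled) and `body`.
#'
#' @param x A `particle_system`.
#' @param ... Unused.
#' @return A [tibble::tibble()].
#' @method as_tibble particle_system
#' @export
as_tibble.particle_system <- function(x, ...) {
  d <- ncol(x$pos)
  axes <- c("x", "y", "z")[seq_len(d)]
  out <- c(
    stats::setNames(lapply(seq_len(d), function(a) x$pos[, a]), axes),
    stats::setNames(lapply(seq_len(d), function(a) x$vel[, a]),
                    paste0("v", axes)),
    list(rho = x$rho, p = x$p, mass = x$mass,
         tag = names(particle_tags())[match(x$tag, particle_tags())],
         body = x$body))
  tibble::as_tibble(out)
}

# subset a particle system (used by open-boundary particle bookkeeping)
subset_system <- function(system, keep) {
  system$pos <- system$pos[keep, , drop = FALSE]
  system$vel <- system$vel[keep, , drop = FALSE]
  for (f in c("rho", "p", "mass", "tag", "body"))
    system[[f]] <- system[[f]][keep]
  system
}

# append rows to a particle system
append_particles <- function(system, pos, vel, rho, p, mass, tag, body = 0L) {
  k <- nrow(pos)
  system$pos <- rbind(system$pos, pos)
  system$vel <- rbind(system$vel, vel)
  system$rho <- c(system$rho, rep_len(rho, k))
  system$p <- c(system$p, rep_len(p, k))
  system$mass <- c(system$mass, rep_len(mass, k))
  system$tag <- c(system$tag, rep_len(as.integer(tag), k))
  system$body <- c(system$body, rep_len(as.integer(body), k))
  system
}
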