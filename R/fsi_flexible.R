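#' Lame constants from Young's modulus and Poisson ratio
#'
#' In two dimensions a plane-stress reduction is used (free lateral
#' contraction through the thickness), so that uniaxial stretching of a 2D
#' body reproduces the axial stiffness `E` exactly.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio, `nu < 0.5`.
#' @param dim Spatial dimension (2 or 3).
#' @return List with `lambda`, `mu` (Pa) and the dilatational wave speed
#'   factor `lambda + 2 mu`.
#' @export
lame_constants <- function(E, nu, dim = 2L) {
  if (nu >= 0.5) stop("non-physical material: nu must be < 0.5", call. = FALSE)
  mu <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  if (dim == 2L) lambda <- 2 * lambda * mu / (lambda + 2 * mu)  # plane stress
  list(lambda = lambda, mu = mu, p_wave = lambda + 2 * mu)
}

#' Flexible body (total-Lagrangian SPH solid)
#'
#' An elastic body discretised by particles in a fixed reference
#' configuration.  The neighbour adjacency and the kernel-gradient
#' correction matrices are built once on the undeformed configuration (the
#' total-Lagrangian contract); deformation gradients, St Venant-Kirchhoff
#' PK1 stresses and internal forces are then evaluated against that
#' reference at every step.
#'
#' @param X n x d matrix of reference particle positions (m).
#' @param dp Particle spacing (m).
#' @param E Young's modulus (Pa), default 1e6 (native-leaflet tissue scale).
#' @param nu Poisson ratio, default 0.49 (nearly incompressible tissue).
#' @param rho0 Reference solid density (kg/m^3), default 1100 (leaflet).
#' @param clamped Logical mask of kinematically fixed particles.
#' @param members Optional indices of these particles in a host
#'   [particle_system()] (for fluid coupling).
#' @param h_ratio Smoothing length ratio, `h = h_ratio * dp` (default 1.4).
#' @param alpha_visc Monaghan artificial-viscosity coefficient inside the
#'   solid (default 0.1; set 0 for energy-conservation studies).
#' @return An object of class `flexible_body`.
#' @export
flexible_body <- function(X, dp, E = 1e6, nu = 0.49, rho0 = 1100,
                          clamped = rep(FALSE, nrow(X)), members = NULL,
                          h_ratio = 1.4, alpha_visc = 0.1) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  lam <- lame_constants(E, nu, d)
  h <- h_ratio * dp
  ref_sys <- list(pos = X)
  lo <- apply(X, 2, min) - 2 * h
  hi <- apply(X, 2, max) + 2 * h
  pairs0 <- cpp_cell_pairs(X, 2 * h, lo, hi, rep(FALSE, d))
  V0 <- rep(dp^d, n)
  corr <- cpp_ref_correction(X, V0, pairs0$i, pairs0$j, pairs0$dx, pairs0$r,
                             h, d)
  if (!all(corr$ok))
    stop("ill-conditioned support: singular reference correction matrix ",
         "(degenerate particle neighbourhood)", call. = FALSE)
  structure(
    list(X = X, x = X, v = matrix(0, n, d), dp = dp, h = h,
         E = E, nu = nu, rho0 = rho0,
         lambda = lam$lambda, mu_s = lam$mu,
         c0s = sqrt(lam$p_wave / rho0),
         V0 = V0, mass_solid = rho0 * V0[1],
         clamped = clamped, members = members,
         pairs0 = pairs0, Minv = corr$Minv,
         F = NULL, J = rep(1, n),
         alpha_visc = alpha_visc),
    class = "flexible_body")
}

#' Per-particle deformation gradient
#'
#' First-order consistent SPH estimate on the reference adjacency:
#' `F_i = [sum_j V0_j (x_j - x_i) (x) grad0 W_ij] L_i`, with `L_i` the
#' reference kernel-gradient correction matrix, exact for affine maps.
#'
#' @param body A [flexible_body()].
#' @param x Current positions (defaults to `body$x`).
#' @return n x (d*d) matrix of row-major flattened deformation gradients.
#' @export
deformation_gradient <- function(body, x = body$x) {
  p0 <- body$pairs0
  cpp_deformation_gradient(as.matrix(x), body$V0, body$Minv,
                           p0$i, p0$j, p0$dx, p0$r,
                           body$h, ncol(body$X))
}

# det of row-major flattened tensors
.det_rows <- function(F, d) {
  if (d == 2L) {
    F[, 1] * F[, 4] - F[, 2] * F[, 3]
  } else {
    F[, 1] * (F[, 5] * F[, 9] - F[, 6] * F[, 8]) -
      F[, 2] * (F[, 4] * F[, 9] - F[, 6] * F[, 7]) +
      F[, 3] * (F[, 4] * F[, 8] - F[, 5] * F[, 7])
  }
}

#' First Piola-Kirchhoff stress (St Venant-Kirchhoff material)
#'
#' `P = F (lambda tr(Eg) I + 2 mu Eg)` with the Green-Lagrange strain
#' `Eg = (FtF - I)/2`.  Zero at `F = I`; frame-indifferent
#' (`P(RF) = R P(F)`).  In 2D the plane-stress Lame constant is used.
#'
#' @param F n x (d*d) matrix of flattened deformation gradients (or a single
#'   d x d matrix).
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio (< 0.5).
#' @param dim Spatial dimension (2 or 3); inferred for a single square
#'   matrix.
#' @return PK1 stresses, same layout as `F` (Pa).
#' @export
pk1_stress <- function(F, E, nu, dim = NULL) {
  single <- is.matrix(F) && nrow(F) == ncol(F) && nrow(F) %in% 2:3 &&
    (is.null(dim) || ncol(F) == dim)
  if (single) {
    d <- nrow(F)
    Fm <- matrix(as.numeric(t(F)), 1)  # row-major flatten
  } else {
    stopifnot(!is.null(dim))
    d <- as.integer(dim)
    Fm <- as.matrix(F)
    stopifnot(ncol(Fm) == d * d)
  }
  lam <- lame_constants(E, nu, d)
  J <- .det_rows(Fm, d)
  if (any(J <= 0))
    stop("inversion error: deformation gradient with J <= 0", call. = FALSE)
  n <- nrow(Fm)
  P <- matrix(0, n, d * d)
  if (d == 2L) {
    F11 <- Fm[, 1]; F12 <- Fm[, 2]; F21 <- Fm[, 3]; F22 <- Fm[, 4]
    C11 <- F11^2 + F21^2
    C12 <- F11 * F12 + F21 * F22
    C22 <- F12^2 + F22^2
    E11 <- (C11 - 1) / 2; E12 <- C12 / 2; E22 <- (C22 - 1) / 2
    tr <- E11 + E22
    S11 <- lam$lambda * tr + 2 * lam$mu * E11
    S12 <- 2 * lam$mu * E12
    S22 <- lam$lambda * tr + 2 * lam$mu * E22
    P[, 1] <- F11 * S11 + F12 * S12
    P[, 2] <- F11 * S12 + F12 * S22
    P[, 3] <- F21 * S11 + F22 * S12
    P[, 4] <- F21 * S12 + F22 * S22
  } else {
    I3 <- diag(3)
    for (i in seq_len(n)) {
      Fi <- matrix(Fm[i, ], 3, 3, byrow = TRUE)
      Eg <- (crossprod(Fi) - I3) / 2
      S2 <- lam$lambda * sum(diag(Eg)) * I3 + 2 * lam$mu * Eg
      P[i, ] <- as.numeric(t(Fi %*% S2))
    }
  }
  if (single) matrix(P[1, ], d, d, byrow = TRUE) else P
}

#' Solid density from the Jacobian
#'
#' Exact mass conservation of the total-Lagrangian scheme:
#' `rho J = rho0`, so `rho = rho0 / J` with `J = det F`.
#'
#' @param body A [flexible_body()] (with `body$J` current), or pass `J`.
#' @param J Optional Jacobian determinants overriding `body$J`.
#' @return Densities (kg/m^3).
#' @export
solid_density_from_J <- function(body, J = body$J) {
  if (any(J <= 0))
    stop("inversion error: J must be positive", call. = FALSE)
  body$rho0 / J
}

#' Solid momentum rate
#'
#' Pairwise, linear-momentum-conserving SPH divergence of the PK1 stress in
#' the reference frame, `dv/dt = (1/rho0) div0 P + g`, plus a small Monaghan
#' artificial viscosity for shock-free stability.
#'
#' @param body A [flexible_body()].
#' @param P n x (d*d) PK1 stresses; computed from the current configuration
#'   when omitted.
#' @param gravity Body-force vector (m/s^2), default zero.
#' @return n x d matrix of accelerations (m/s^2).  Clamped particles get
#'   zero.
#' @export
solid_momentum_rate <- function(body, P = NULL, gravity = NULL) {
  d <- ncol(body$X)
  if (is.null(P)) {
    F <- deformation_gradient(body)
    P <- pk1_stress(F, body$E, body$nu, dim = d)
  }
  p0 <- body$pairs0
  acc <- cpp_solid_accel(body$x, body$v, body$V0,
                         rep(body$mass_solid, nrow(body$X)),
                         P, body$Minv,
                         p0$i, p0$j, p0$dx, p0$r,
                         body$h, d, body$alpha_visc, body$c0s, body$rho0)
  if (!is.null(gravity))
    acc <- acc + matrix(gravity, nrow(acc), d, byrow = TRUE)
  acc[body$clamped, ] <- 0
  acc
}

#' Advance a flexible body over one fluid step
#'
#' Sub-cycles the stiff solid dynamics (timestep `0.3 h / c0s`, with `c0s`
#' the dilatational wave speed) inside one fluid timestep, holding the
#' fluid-coupling accelerations frozen.  Semi-implicit (symplectic Euler)
#' update per sub-step; clamped particles stay fixed.
#'
#' @param body A [flexible_body()].
#' @param dt Fluid timestep (s).
#' @param f_couple n x d matrix of fluid-reaction accelerations (m/s^2), or
#'   `NULL`.
#' @param gravity Body-force vector (m/s^2).
#' @return The advanced `flexible_body` (updated `x`, `v`, `F`, `J`).
#' @export
step_flexible_body <- function(body, dt, f_couple = NULL, gravity = NULL) {
  d <- ncol(body$X)
  dt_s <- 0.3 * body$h / body$c0s
  n_sub <- max(1L, ceiling(dt / dt_s))
  dt_s <- dt / n_sub
  ext <- matrix(0, nrow(body$X), d)
  if (!is.null(f_couple)) ext <- ext + f_couple
  if (!is.null(gravity)) ext <- ext + matrix(gravity, nrow(ext), d, byrow = TRUE)
  for (s in seq_len(n_sub)) {
    F <- deformation_gradient(body)
    J <- .det_rows(F, d)
    if (any(J <= 0))
      stop("inversion error: deformation gradient with J <= 0", call. = FALSE)
    P <- pk1_stress(F, body$E, body$nu, dim = d)
    acc <- solid_momentum_rate(body, P = P) + ext
    acc[body$clamped, ] <- 0
    body$v <- body$v + dt_s * acc
    body$v[body$clamped, ] <- 0
    body$x <- body$x + dt_s * body$v
    body$F <- F
    body$J <- J
  }
  body
}

#' Dynamic relaxation to a static equilibrium
#'
#' Damped pseudo-time integration of the solid under a constant external
#' acceleration field until the kinetic energy settles: used for static
#' validation problems (tip-loaded cantilever) and for initialising
#' pre-stressed configurations.  The damping rate defaults to an estimate
#' of critical damping from the first-mode frequency scale.
#'
#' @param body A [flexible_body()].
#' @param ext_acc n x d matrix (or d-vector) of external accelerations
#'   (m/s^2).
#' @param n_steps Maximum pseudo-time steps.
#' @param damping_rate Velocity damping rate (1/s); `NULL` for the
#'   automatic estimate.
#' @param tol Stop when kinetic energy falls below `tol` times the peak
#'   kinetic energy seen (default 1e-8).
#' @return The relaxed `flexible_body`.
#' @export
relax_flexible_body <- function(body, ext_acc, n_steps = 50000L,
                                damping_rate = NULL, tol = 1e-8) {
  d <- ncol(body$X)
  n <- nrow(body$X)
  if (is.null(dim(ext_acc))) ext_acc <- matrix(ext_acc, n, d, byrow = TRUE)
  dt <- 0.3 * body$h / body$c0s
  if (is.null(damping_rate)) {
    # first-mode scale: bending wave across the free length
    L <- diff(range(body$X[, 1]))
    th <- diff(range(body$X[, 2])) + body$dp
    f1 <- 1.875104^2 / (2 * pi) *
      sqrt(body$E * th^2 / (12 * body$rho0 * L^4))
    damping_rate <- 4 * pi * f1  # ~critical for the first mode
  }
  damp <- max(0, 1 - damping_rate * dt)
  ke_peak <- 0
  for (s in seq_len(n_steps)) {
    F <- deformation_gradient(body)
    P <- pk1_stress(F, body$E, body$nu, dim = d)
    acc <- solid_momentum_rate(body, P = P) + ext_acc
    acc[body$clamped, ] <- 0
    body$v <- (body$v + dt * acc) * damp
    body$v[body$clamped, ] <- 0
    body$x <- body$x + dt * body$v
    body$F <- F
    if (s %% 500L == 0L) {
      ke <- 0.5 * body$mass_solid * sum(body$v^2)
      ke_peak <- max(ke_peak, ke)
      if (ke_peak > 0 && ke < tol * ke_peak) break
    }
  }
  body$J <- .det_rows(deformation_gradient(body), d)
  body
}

#' Total mechanical energy of a flexible body
#'
#' Kinetic plus St Venant-Kirchhoff strain energy
#' `psi = lambda/2 tr(Eg)^2 + mu Eg:Eg` integrated over reference volumes.
#'
#' @param body A [flexible_body()] with current `x`, `v`.
#' @return List with `kinetic`, `strain` and `total` (J).
#' @export
flexible_energy <- function(body) {
  d <- ncol(body$X)
  F <- deformation_gradient(body)
  n <- nrow(F)
  psi <- numeric(n)
  for (i in seq_len(n)) {
    Fi <- matrix(F[i, ], d, d, byrow = TRUE)
    Eg <- (crossprod(Fi) - diag(d)) / 2
    psi[i] <- body$lambda / 2 * sum(diag(Eg))^2 + body$mu_s * sum(Eg^2)
  }
  strain <- sum(psi * body$V0)
  kinetic <- 0.5 * body$mass_solid * sum(body$v^2)
  list(kinetic = kinetic, strain = strain, total = kinetic + strain)
}
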