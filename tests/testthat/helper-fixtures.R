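# Shared in-code fixtures and independent oracles.

# uniform 2D lattice of fluid particles in a box, spacing dp
lattice_system <- function(nx, ny, dp, rho0 = 1060, mu = 0.003,
                           jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(x = (seq_len(nx) - 0.5) * dp,
                   y = (seq_len(ny) - 0.5) * dp)
  pos <- as.matrix(g)[, 1:2]
  if (jitter > 0) pos <- pos + matrix(stats::runif(2 * nrow(pos),
                                                   -jitter, jitter) * dp,
                                      ncol = 2)
  particle_system(pos, rho0 = rho0, mu = mu, dp = dp)
}

# brute-force O(N^2) neighbour oracle (optionally periodic box)
brute_pairs <- function(pos, rcut, lo = NULL, hi = NULL,
                        periodic = c(FALSE, FALSE)) {
  n <- nrow(pos)
  I <- integer(0); J <- integer(0)
  span <- if (!is.null(lo)) hi - lo else NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- pos[i, ] - pos[j, ]
      if (any(periodic)) {
        for (a in which(periodic)) {
          if (dx[a] > span[a] / 2) dx[a] <- dx[a] - span[a]
          if (dx[a] < -span[a] / 2) dx[a] <- dx[a] + span[a]
        }
      }
      if (sum(dx^2) < rcut^2) { I <- c(I, i); J <- c(J, j) }
    }
  }
  data.frame(i = I, j = J)
}

# analytic transient plane-Poiseuille wall shear for body-force startup
# from rest: tau_w(t) = (rho f H / 2) (1 - (8/pi^2) sum_odd exp(-n^2 pi^2
# nu t / H^2) / n^2)
poiseuille_wall_shear <- function(t, f, H, rho = 1060, mu = 0.003,
                                  nmax = 199) {
  nu <- mu / rho
  n <- seq(1, nmax, by = 2)
  sapply(t, function(tt) {
    s <- sum(exp(-n^2 * pi^2 * nu * tt / H^2) / n^2)
    (rho * f * H / 2) * (1 - 8 / pi^2 * s)
  })
}

# analytic transient centreline velocity for the same startup
poiseuille_centre_speed <- function(t, f, H, rho = 1060, mu = 0.003,
                                    nmax = 199) {
  nu <- mu / rho
  y <- H / 2
  n <- seq(1, nmax, by = 2)
  u_inf <- f / (2 * nu) * y * (H - y)
  sapply(t, function(tt) {
    s <- sum(4 * f * H^2 / (nu * pi^3 * n^3) * sin(n * pi * y / H) *
               exp(-n^2 * pi^2 * nu * tt / H^2))
    u_inf - s
  })
}

# dense-quadrature OSI/TAWSS oracle for an analytic shear series tau(t)
# (function returning a k x d matrix), independent of the package's
# trapezoidal implementation
osi_oracle <- function(tau_fn, T, n_dense = 20000) {
  t <- seq(0, T, length.out = n_dense)
  tau <- tau_fn(t)
  dt <- t[2] - t[1]
  mag <- sqrt(rowSums(tau^2))
  den <- sum((mag[-1] + mag[-length(mag)]) / 2) * dt
  comp <- colSums((tau[-1, , drop = FALSE] +
                     tau[-nrow(tau), , drop = FALSE]) / 2) * dt
  num <- sqrt(sum(comp^2))
  if (den <= 0) return(list(osi = 0, tawss = 0))
  list(osi = 0.5 * (1 - num / den), tawss = den / T)
}
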