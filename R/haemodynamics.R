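#' Wall samples for shear-stress estimation
#'
#' Points on the wall surface (normally the innermost wall-particle layer)
#' where wall shear stress is reported, each carrying an outward-pointing
#' unit normal (pointing into the fluid).
#'
#' @param pos n x d matrix of wall sample positions (m).
#' @param normal n x d matrix (or single vector) of unit normals.
#' @return A tibble of class `wall_samples` with columns `sample`, the
#'   position axes and the normal components.
#' @export
wall_samples <- function(pos, normal) {
  pos <- as.matrix(pos)
  d <- ncol(pos)
  if (is.null(dim(normal))) normal <- matrix(normal, nrow(pos), d, byrow = TRUE)
  normal <- as.matrix(normal)
  len <- sqrt(rowSums(normal^2))
  if (any(abs(len - 1) > 1e-8))
    stop("wall normals must have unit length", call. = FALSE)
  axes <- c("x", "y", "z")[seq_len(d)]
  out <- tibble::as_tibble(c(
    list(sample = seq_len(nrow(pos))),
    stats::setNames(lapply(seq_len(d), function(a) pos[, a]), axes),
    stats::setNames(lapply(seq_len(d), function(a) normal[, a]),
                    paste0("n", axes))))
  class(out) <- c("wall_samples", class(out))
  out
}

.sample_pos <- function(samples) {
  axes <- intersect(c("x", "y", "z"), names(samples))
  as.matrix(samples[axes])
}

.sample_normal <- function(samples) {
  axes <- paste0("n", intersect(c("x", "y", "z"),
                                sub("^n", "", grep("^n[xyz]$", names(samples),
                                                   value = TRUE))))
  as.matrix(samples[axes])
}

#' Fluid particles of the last layer adjacent to a wall
#'
#' Under the Dynamic Boundary Condition the no-slip condition at the wall is
#' imperfect, so wall shear stress is evaluated at the last fluid layer
#' adjacent to the wall: all fluid particles within `cutoff` (default
#' `1.5 dp`) of any wall sample.
#'
#' @param system A [particle_system()].
#' @param samples A [wall_samples()] tibble.
#' @param dp Particle spacing (m).
#' @param cutoff Association distance (m), default `1.5 * dp`.
#' @return Integer indices of last-layer fluid particles.
#' @export
last_fluid_layer <- function(system, samples, dp, cutoff = 1.5 * dp) {
  sp <- .sample_pos(samples)
  fluid <- which(system$tag == 0L)
  if (!length(fluid)) return(integer())
  comb <- rbind(sp, system$pos[fluid, , drop = FALSE])
  d <- ncol(comb)
  lo <- apply(comb, 2, min) - cutoff; hi <- apply(comb, 2, max) + cutoff
  pl <- cpp_cell_pairs(comb, cutoff, lo, hi, rep(FALSE, d))
  ns <- nrow(sp)
  hit <- (pl$i <= ns) != (pl$j <= ns)   # sample-fluid pairs only
  fl <- unique(pmax(pl$i[hit], pl$j[hit]) - ns)
  sort(fluid[fl])
}

#' SPH strain-rate tensor
#'
#' `S = (grad u + grad u^T) / 2` evaluated per selected particle from a
#' first-order consistent (kernel-gradient corrected) SPH velocity gradient.
#' By default both fluid and boundary particles contribute neighbour data
#' (the wall's velocity is exact Dirichlet data), which is what the
#' last-fluid-layer wall-shear scheme uses.
#'
#' @param system A [particle_system()].
#' @param ids Particle indices at which to evaluate.
#' @param adjacency A [build_neighbor_list()] pair list.
#' @param kernel A [kernel_spec()].
#' @param include_boundary Use boundary-like particles as neighbour data
#'   (default `TRUE`).
#' @return List with `S` (n x d*d, rows valid at `ids`, row-major flattened
#'   symmetric tensors, 1/s) and logical `ok` flagging well-conditioned
#'   evaluations.
#' @export
strain_rate_tensor <- function(system, ids, adjacency, kernel,
                               include_boundary = TRUE) {
  n <- n_particles(system)
  d <- sys_dim(system)
  eval <- logical(n); eval[ids] <- TRUE
  use <- system$tag == 0L | system$tag == 4L
  if (include_boundary) use <- use | .boundary_like(system$tag)
  res <- cpp_corrected_gradient(system$pos, system$vel,
                                particle_volumes(system),
                                eval, use,
                                adjacency$i, adjacency$j, adjacency$dx,
                                adjacency$r, kernel$h, d)
  G <- res$G
  S <- G
  for (a in seq_len(d))
    for (b in seq_len(d)) {
      ca <- (a - 1) * d + b; cb <- (b - 1) * d + a
      S[, ca] <- (G[, ca] + G[, cb]) / 2
    }
  list(S = S, ok = res$ok)
}

#' Wall shear stress vector from the strain rate
#'
#' Laminar mode: the tangential component of the viscous traction
#' `2 mu S . n`.  LES mode: the tangential component of
#' `(2 mu S + tau_sps) . n`, the laminar traction plus the Smagorinsky
#' sub-particle stress with eddy viscosity `mu_T = rho (C_s dl)^2
#' sqrt(2 S:S)` (isotropic SPS terms act along the normal and drop out of
#' the tangential projection).
#'
#' @param S n x (d*d) strain-rate tensors (1/s) or a single d x d matrix.
#' @param normal Unit normal(s): vector or n x d matrix.
#' @param mode `"laminar"` or `"les"`.
#' @param mu Dynamic viscosity (Pa s).
#' @param sps An [sps_config()] (LES mode).
#' @param rho Densities (kg/m^3) for the eddy viscosity (LES mode).
#' @return n x d matrix of wall shear stress vectors (Pa); a single vector
#'   when `S` was a single matrix.
#' @export
wall_shear_vector <- function(S, normal, mode = c("laminar", "les"), mu,
                              sps = NULL, rho = NULL) {
  mode <- match.arg(mode)
  single <- is.matrix(S) && nrow(S) == ncol(S) && nrow(S) %in% 2:3
  if (single) {
    d <- nrow(S)
    S <- matrix(as.numeric(t(S)), 1)
  } else {
    S <- as.matrix(S)
    d <- as.integer(sqrt(ncol(S)))
  }
  n <- nrow(S)
  if (is.null(dim(normal))) normal <- matrix(normal, n, d, byrow = TRUE)
  len <- sqrt(rowSums(normal^2))
  if (any(abs(len - 1) > 1e-8))
    stop("normal must be a unit vector", call. = FALSE)
  mu_eff <- rep(mu, n)
  if (mode == "les") {
    stopifnot(inherits(sps, "sps_config"), !is.null(rho))
    ss <- rowSums(S^2)
    mu_T <- rep_len(rho, n) * (sps$Cs * sps$dl)^2 * sqrt(2 * ss)
    mu_eff <- mu_eff + mu_T
  }
  # traction t_a = 2 mu_eff S[a,b] n_b, then remove the normal component
  tr <- matrix(0, n, d)
  for (a in seq_len(d)) {
    acc <- 0
    for (b in seq_len(d)) acc <- acc + S[, (a - 1) * d + b] * normal[, b]
    tr[, a] <- 2 * mu_eff * acc
  }
  tn <- rowSums(tr * normal)
  tau <- tr - tn * normal
  if (single) drop(tau) else tau
}

#' Project last-layer shear to the wall samples
#'
#' Kernel-weighted average of the last-fluid-layer shear vectors over each
#' wall sample's association set (fluid particles within the kernel
#' support).  Samples with an empty association set are flagged missing
#' (`NA`), never zero-filled.
#'
#' @param tau m x d matrix of shear vectors at last-layer fluid particles
#'   (Pa).
#' @param fluid_pos m x d matrix of those particles' positions (m).
#' @param samples A [wall_samples()] tibble.
#' @param kernel A [kernel_spec()].
#' @param method `"kernel"`: kernel-weighted average over the association
#'   set; `"linear"`: kernel-weighted linear fit in the wall-normal
#'   distance, evaluated at the wall (removes the O(dp/H) bias of plain
#'   averaging, exact for shear profiles linear in the normal coordinate).
#' @return Tibble: `sample`, shear components `taux`, `tauy` (, `tauz`),
#'   magnitude `wss` and logical `missing`.
#' @export
project_to_wall <- function(tau, fluid_pos, samples, kernel,
                            method = c("kernel", "linear")) {
  method <- match.arg(method)
  tau <- as.matrix(tau)
  fluid_pos <- as.matrix(fluid_pos)
  sp <- .sample_pos(samples)
  nrm <- .sample_normal(samples)
  d <- ncol(sp)
  ns <- nrow(sp)
  out <- matrix(NA_real_, ns, d)
  miss <- logical(ns)
  for (s in seq_len(ns)) {
    dx <- sweep(fluid_pos, 2, sp[s, ], "-")
    r <- sqrt(rowSums(dx^2))
    w <- wendland_value(r, kernel)
    wsum <- sum(w)
    if (wsum > 0) {
      if (method == "linear") {
        # weighted least squares of tau ~ a + b s, report a = tau at wall
        sdist <- drop(dx %*% nrm[s, ])
        sw <- sum(w); sx <- sum(w * sdist); sxx <- sum(w * sdist^2)
        det <- sw * sxx - sx^2
        if (det > 1e-12 * sw * max(sxx, kernel$h^2)) {
          for (a in seq_len(d)) {
            sy <- sum(w * tau[, a]); sxy <- sum(w * sdist * tau[, a])
            out[s, a] <- (sxx * sy - sx * sxy) / det
          }
        } else {
          out[s, ] <- colSums(tau * w) / wsum
        }
      } else {
        out[s, ] <- colSums(tau * w) / wsum
      }
    } else {
      miss[s] <- TRUE
    }
  }
  if (all(miss))
    stop("empty field: no wall sample has an associated fluid particle",
         call. = FALSE)
  axes <- c("x", "y", "z")[seq_len(d)]
  res <- tibble::as_tibble(c(
    list(sample = samples$sample),
    stats::setNames(lapply(seq_len(d), function(a) out[, a]),
                    paste0("tau", axes)),
    list(wss = sqrt(rowSums(out^2)), missing = miss)))
  res
}

#' One-call wall shear stress estimate for a case
#'
#' Finds the last fluid layer, evaluates the corrected strain rate there,
#' forms the shear vectors and projects them to the wall samples.
#'
#' @param case An [sph_case()].
#' @param samples A [wall_samples()] tibble.
#' @param mode `"laminar"` or `"les"`.
#' @param method Wall-transfer method, see [project_to_wall()]; the default
#'   `"linear"` extrapolates the near-wall shear profile to the wall.
#' @param cutoff Association distance for the near-wall fluid band (m);
#'   default `2 h` so the linear fit sees two to three particle rows.
#' @return The [project_to_wall()] tibble, with the current time attached as
#'   column `t`.
#' @export
compute_wall_shear <- function(case, samples, mode = c("laminar", "les"),
                               method = "linear",
                               cutoff = case$kernel$support_radius) {
  mode <- match.arg(mode)
  sys <- case$system
  ids <- last_fluid_layer(sys, samples, sys$dp, cutoff = cutoff)
  if (!length(ids)) stop("no last-layer fluid particles found", call. = FALSE)
  pairs <- build_neighbor_list(sys, case$kernel$support_radius, case$domain)
  sr <- strain_rate_tensor(sys, ids, pairs, case$kernel)
  # shear vector per last-layer particle, using the nearest sample's normal
  sp <- .sample_pos(samples)
  nrm <- .sample_normal(samples)
  nearest <- vapply(ids, function(i) {
    which.min(colSums((t(sp) - sys$pos[i, ])^2))
  }, integer(1))
  tau <- wall_shear_vector(sr$S[ids, , drop = FALSE], nrm[nearest, , drop = FALSE],
                           mode = mode, mu = sys$mu,
                           sps = case$sps, rho = sys$rho[ids])
  res <- project_to_wall(tau, sys$pos[ids, , drop = FALSE], samples,
                         case$kernel, method = method)
  res$t <- case$t
  res
}

#' Build a wall-shear time series
#'
#' Stacks per-time [compute_wall_shear()] (or equivalent) tibbles into a
#' `shear_series` spanning at least one cardiac cycle.
#'
#' @param records A tibble with columns `sample`, `t` and shear components
#'   `taux`, `tauy` (, `tauz`).
#' @param period Cardiac period T (s).
#' @return The tibble with class `shear_series` and attribute `period`.
#' @export
shear_series <- function(records, period) {
  stopifnot(all(c("sample", "t", "taux") %in% names(records)), period > 0)
  out <- tibble::as_tibble(records)
  attr(out, "period") <- period
  class(out) <- c("shear_series", class(out))
  out
}

.tau_cols <- function(df) intersect(c("taux", "tauy", "tauz"), names(df))

.trapz <- function(t, y) {
  k <- length(t)
  if (k < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-k]) / 2)
}

# restrict one sample's records to the last full cycle
.last_cycle <- function(t, period) {
  span <- max(t) - min(t)
  if (span < period - 1e-9)
    stop("insufficient coverage: series spans ", signif(span, 4),
         " s < period ", period, " s", call. = FALSE)
  t >= max(t) - period - 1e-12
}

.per_sample <- function(series, period, fn) {
  tc <- .tau_cols(series)
  parts <- split(series[c("t", tc)], series$sample)
  vals <- vapply(parts, function(df) {
    df <- df[order(df$t), ]
    keep <- .last_cycle(df$t, period)
    fn(df$t[keep], as.matrix(df[keep, tc]))
  }, numeric(1))
  tibble::tibble(sample = as.integer(names(parts)), value = unname(vals))
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) integral_0^T |tau_wall| dt` by the trapezoidal rule over
#' the last full cardiac cycle of the series.
#'
#' @param series A [shear_series()], or a list `list(t =, tau =)` for a
#'   single sample.
#' @param period Cardiac period (s); defaults to the series attribute.
#' @return Tibble `sample`, `tawss` (Pa); or a scalar for single-sample
#'   input.
#' @export
tawss <- function(series, period = attr(series, "period")) {
  f <- function(t, tau) .trapz(t, sqrt(rowSums(tau^2))) / period
  if (is.list(series) && !is.data.frame(series)) {
    keep <- .last_cycle(series$t, period)
    return(f(series$t[keep], as.matrix(series$tau)[keep, , drop = FALSE]))
  }
  out <- .per_sample(series, period, f)
  names(out)[2] <- "tawss"
  out
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = (1 - |integral tau dt| / integral |tau| dt) / 2`, the vector
#' integral taken componentwise; 0 for unidirectional shear, 0.5 for shear
#' that fully reverses direction with equal magnitudes; defined as 0 when
#' the denominator vanishes.
#'
#' @inheritParams tawss
#' @return Tibble `sample`, `osi` (dimensionless in `[0, 0.5]`); or a
#'   scalar.
#' @export
osi <- function(series, period = attr(series, "period")) {
  f <- function(t, tau) {
    den <- .trapz(t, sqrt(rowSums(tau^2)))
    if (den <= 0) return(0)
    num <- sqrt(sum(vapply(seq_len(ncol(tau)),
                           function(a) .trapz(t, tau[, a]), numeric(1))^2))
    val <- 0.5 * (1 - num / den)
    min(max(val, 0), 0.5)
  }
  if (is.list(series) && !is.data.frame(series)) {
    keep <- .last_cycle(series$t, period)
    return(f(series$t[keep], as.matrix(series$tau)[keep, , drop = FALSE]))
  }
  out <- .per_sample(series, period, f)
  names(out)[2] <- "osi"
  out
}

#' Endothelial cell activation potential (ECAP)
#'
#' `ECAP = OSI / TAWSS` (1/Pa): high where oscillatory shear coincides with
#' low time-averaged shear, flagging thrombogenic-prone wall regions.
#' Undefined (`NA`, not infinite) where TAWSS is zero.
#'
#' @param osi_value OSI value(s).
#' @param tawss_value TAWSS value(s) (Pa).
#' @return ECAP value(s) (1/Pa).
#' @export
ecap <- function(osi_value, tawss_value) {
  out <- ifelse(tawss_value > 0, osi_value / tawss_value, NA_real_)
  out
}

#' Peak systolic wall shear stress (PSWSS)
#'
#' Maximum shear magnitude over the cycle per sample.
#'
#' @inheritParams tawss
#' @return Tibble `sample`, `pswss` (Pa); or a scalar.
#' @export
pswss <- function(series, period = attr(series, "period")) {
  f <- function(t, tau) max(sqrt(rowSums(tau^2)))
  if (is.list(series) && !is.data.frame(series)) {
    keep <- .last_cycle(series$t, period)
    return(f(series$t[keep], as.matrix(series$tau)[keep, , drop = FALSE]))
  }
  out <- .per_sample(series, period, f)
  names(out)[2] <- "pswss"
  out
}

#' Haemodynamic risk maps
#'
#' Per-wall-sample TAWSS, OSI, ECAP and PSWSS over the last full cardiac
#' cycle of the shear series.
#'
#' @param series A [shear_series()].
#' @param period Cardiac period (s); defaults to the series attribute.
#' @param samples Optional [wall_samples()] to join positions/normals onto
#'   the result.
#' @return A tibble of class `haemodynamic_maps`: `sample`, `tawss`, `osi`,
#'   `ecap`, `pswss` (plus coordinates when `samples` is given).
#' @export
haemodynamic_maps <- function(series, period = attr(series, "period"),
                              samples = NULL) {
  tw <- tawss(series, period)
  os <- osi(series, period)
  ps <- pswss(series, period)
  out <- dplyr::left_join(tw, os, by = "sample")
  out <- dplyr::left_join(out, ps, by = "sample")
  out$ecap <- ecap(out$osi, out$tawss)
  out <- out[c("sample", "tawss", "osi", "ecap", "pswss")]
  if (!is.null(samples))
    out <- dplyr::left_join(out, samples, by = "sample")
  attr(out, "period") <- period
  class(out) <- c("haemodynamic_maps", class(out))
  out
}

#' Effective orifice area (EOA)
#'
#' Planimetric open area of the valve plane: the lumen cross-section is
#' rasterised at `resolution` (default `dp/2`) and raster points within an
#' occlusion radius of any solid, rigid, flexible or wall particle inside
#' the plane slab are counted as blocked.  In 2D the "area" is the open gap
#' length across the channel (m); in 3D it is an area (m^2).
#'
#' @param system A [particle_system()].
#' @param plane_origin Point on the valve plane (m).
#' @param plane_normal Plane normal (flow direction).
#' @param lumen For 2D: `c(min, max)` transverse extent of the lumen; for
#'   3D: `list(center =, radius =)` circular lumen in the plane.
#' @param dp Particle spacing (m).
#' @param slab Slab thickness (m), default `2 * dp` (must be at least that).
#' @param resolution Raster spacing (m), default `dp / 2`.
#' @param occlusion_radius Blocking radius per particle (m), default
#'   `0.55 * dp`.
#' @return Open length (2D, m) or area (3D, m^2).
#' @export
effective_orifice_area <- function(system, plane_origin, plane_normal, lumen,
                                   dp, slab = 2 * dp, resolution = dp / 2,
                                   occlusion_radius = 0.55 * dp) {
  if (slab < 2 * dp)
    stop("valve-plane slab thickness must be >= 2 dp", call. = FALSE)
  d <- sys_dim(system)
  nrm <- plane_normal / sqrt(sum(plane_normal^2))
  s <- drop(sweep(system$pos, 2, plane_origin, "-") %*% nrm)
  solid <- .boundary_like(system$tag)
  inslab <- solid & abs(s) <= slab / 2
  if (d == 2L) {
    tang <- c(-nrm[2], nrm[1])
    yr <- seq(lumen[1], lumen[2], by = resolution)
    if (!length(yr)) stop("empty slab/lumen", call. = FALSE)
    occ <- logical(length(yr))
    if (any(inslab)) {
      yp <- drop(sweep(system$pos[inslab, , drop = FALSE], 2, plane_origin,
                       "-") %*% tang)
      for (k in seq_along(yr)) occ[k] <- any(abs(yp - yr[k]) <= occlusion_radius)
    }
    sum(!occ) * resolution
  } else {
    # circular lumen in the plane spanned by two tangents
    t1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * nrm) * nrm; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- .cross(nrm, t1)
    g <- seq(-lumen$radius, lumen$radius, by = resolution)
    gr <- expand.grid(a = g, b = g)
    gr <- gr[gr$a^2 + gr$b^2 <= lumen$radius^2, ]
    if (!nrow(gr)) stop("empty slab/lumen", call. = FALSE)
    occ <- logical(nrow(gr))
    if (any(inslab)) {
      rel <- sweep(system$pos[inslab, , drop = FALSE], 2, plane_origin, "-")
      pa <- drop(rel %*% t1); pb <- drop(rel %*% t2)
      for (k in seq_len(nrow(gr)))
        occ[k] <- any((pa - gr$a[k])^2 + (pb - gr$b[k])^2 <=
                        occlusion_radius^2)
    }
    sum(!occ) * resolution^2
  }
}
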