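#' Smoothing-kernel specification
#'
#' Builds the specification of the Wendland C2 smoothing kernel used
#' throughout the solver: smoothing length `h`, spatial dimension, the
#' dimension-dependent normalization constant `alpha_d` and the compact
#' support radius `2 h`.
#'
#' @param h Smoothing length (m).  Fixtures use `h = 1.4 * dp` where `dp` is
#'   the initial particle spacing.
#' @param dim Spatial dimension, one of 1, 2, 3.
#' @return An object of class `kernel_spec` with fields `h`, `dim`,
#'   `alpha_d` (1/m^dim) and `support_radius` (= `2 h`).
#' @examples
#' ks <- kernel_spec(h = 1.4 * 0.001, dim = 2)
#' wendland_value(0, ks) # kernel peak 7 / (4 pi h^2)
#' @export
kernel_spec <- function(h, dim) {
  stopifnot(is.numeric(h), length(h) == 1L, is.finite(h))
  if (h <= 0) stop("smoothing length `h` must be positive", call. = FALSE)
  structure(
    list(h = h, dim = as.integer(dim),
         alpha_d = normalization_constant(dim, h),
         support_radius = 2 * h),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("Wendland C2 kernel: h = %g m, dim = %d, alpha_d = %g, support = %g m\n",
              x$h, x$dim, x$alpha_d, x$support_radius))
  invisible(x)
}

#' Kernel normalization constant
#'
#' The Wendland C2 normalization constant `alpha_d`, equal to `3/(4h)`,
#' `7/(4 pi h^2)` and `21/(16 pi h^3)` in one, two and three dimensions.
#'
#' @param dim Spatial dimension in `{1, 2, 3}`.
#' @param h Smoothing length (m), positive.
#' @return `alpha_d` (units 1/m^dim).
#' @export
normalization_constant <- function(dim, h) {
  stopifnot(is.numeric(dim), length(dim) == 1L, is.numeric(h), length(h) == 1L)
  if (h <= 0) stop("smoothing length `h` must be positive", call. = FALSE)
  dim <- as.integer(dim)
  switch(as.character(dim),
    "1" = 3 / (4 * h),
    "2" = 7 / (4 * pi * h^2),
    "3" = 21 / (16 * pi * h^3),
    stop("unsupported dimension: ", dim, " (must be 1, 2 or 3)", call. = FALSE))
}

#' Wendland C2 kernel value
#'
#' Evaluates `W(r, h) = alpha_d (1 - q/2)^4 (2 q + 1)` for `q = r/h` in
#' `[0, 2]` and zero beyond the support radius `2 h`.  Vectorised over
#' `distance`.
#'
#' @param distance Non-negative distance(s) (m).
#' @param spec A [kernel_spec()].
#' @return Kernel value(s), units 1/m^dim.
#' @export
wendland_value <- function(distance, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (any(distance < 0)) stop("distance must be non-negative", call. = FALSE)
  q <- distance / spec$h
  w <- ifelse(q < 2, (1 - q / 2)^4 * (2 * q + 1), 0)
  spec$alpha_d * w
}

#' Wendland C2 kernel gradient
#'
#' Gradient of the kernel with respect to the first particle's position,
#' `grad_i W(r_i - r_j)`.  Radially symmetric, so it points along
#' `-offset` (the kernel decreases with distance), vanishes at the origin
#' and beyond the support radius.
#'
#' @param offset Displacement vector `r_i - r_j` (m), length `spec$dim`, or a
#'   matrix with `spec$dim` columns (one offset per row).
#' @param spec A [kernel_spec()].
#' @return Gradient vector (or matrix of row vectors), units 1/m^(dim+1).
#' @export
wendland_gradient <- function(offset, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  vec <- is.null(dim(offset))
  off <- if (vec) matrix(offset, nrow = 1L) else as.matrix(offset)
  stopifnot(ncol(off) == spec$dim)
  r <- sqrt(rowSums(off^2))
  q <- r / spec$h
  # dW/dq = -5 q (1 - q/2)^3 ; grad = alpha_d dW/dq / h * (offset / r)
  coef <- numeric(length(r))
  inside <- q > 0 & q < 2
  coef[inside] <- spec$alpha_d * (-5 * q[inside] * (1 - q[inside] / 2)^3) /
    (spec$h * r[inside])
  g <- off * coef
  if (vec) drop(g) else g
}
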