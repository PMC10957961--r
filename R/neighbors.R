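#' Simulation domain
#'
#' Axis-aligned bounding box used by the cell-linked-list neighbour search,
#' with optional periodic axes (minimum-image convention).
#'
#' @param lo,hi Numeric vectors of length `dim`: box corners (m).
#' @param periodic Logical vector of length `dim`; default all `FALSE`.
#' @return An object of class `sph_domain`.
#' @export
sph_domain <- function(lo, hi, periodic = rep(FALSE, length(lo))) {
  stopifnot(length(lo) == length(hi), all(hi > lo),
            length(periodic) == length(lo))
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi),
                 periodic = as.logical(periodic)),
            class = "sph_domain")
}

# default domain: particle bounding box padded by one support radius
default_domain <- function(system, support_radius) {
  lo <- apply(system$pos, 2, min) - support_radius
  hi <- apply(system$pos, 2, max) + support_radius
  sph_domain(lo, hi)
}

#' Build the neighbour pair list
#'
#' Cell-linked-list search returning exactly the unordered particle pairs
#' closer than `support_radius` (`= 2 h`), with deterministic ordering
#' (ascending `i`, then `j`).  On periodic axes distances use the
#' minimum-image convention and the stored offsets are wrapped.
#'
#' @param system A [particle_system()].
#' @param support_radius Cut-off distance (m), normally `2 * h`.
#' @param domain An [sph_domain()]; defaults to the padded particle bounding
#'   box (non-periodic).
#' @return An object of class `pair_list`: integer vectors `i`, `j` (1-based,
#'   `i < j`), matrix `dx` of offsets `x_i - x_j` (m) and vector `r = |dx|`.
#' @export
build_neighbor_list <- function(system, support_radius, domain = NULL) {
  if (any(!is.finite(system$pos)))
    stop("invalid state: non-finite particle positions", call. = FALSE)
  if (is.null(domain)) domain <- default_domain(system, support_radius)
  pl <- cpp_cell_pairs(system$pos, support_radius, domain$lo, domain$hi,
                       domain$periodic)
  structure(c(pl, list(support_radius = support_radius)), class = "pair_list")
}

#' @export
print.pair_list <- function(x, ...) {
  cat(sprintf("<pair_list> %d pairs within %g m\n", length(x$i),
              x$support_radius))
  invisible(x)
}
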