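#' Run a simulation
#'
#' Fixed-timestep driver over [advance_timestep()] with optional observation
#' hooks and snapshot output.  The timestep defaults to the stability bound
#' evaluated at entry (with a safety re-check every `recheck_every` steps:
#' the bound tightens as the flow accelerates).
#'
#' @param case An [sph_case()].
#' @param until Physical end time (s) relative to `case$t`.
#' @param dt Timestep (s); default [stable_dt()] at entry times 0.9.
#' @param observer Optional `function(case)` returning a tibble of
#'   observations; called every `observe_every` seconds of physical time.
#' @param observe_every Observation cadence (s), default 2 ms (the
#'   default output cadence for metric time series).
#' @param snapshot_dir Optional directory for CSV snapshots at the
#'   observation cadence.
#' @param verbose Print a progress line every `log_every` steps.
#' @param log_every Steps between log lines (default 500).
#' @param recheck_every Steps between stability-bound rechecks.
#' @return List with the final `case` and `observations` (row-bound tibble
#'   or `NULL`).
#' @export
run_simulation <- function(case, until, dt = NULL, observer = NULL,
                           observe_every = 0.002, snapshot_dir = NULL,
                           verbose = FALSE, log_every = 500L,
                           recheck_every = 200L) {
  if (is.null(dt)) dt <- 0.9 * stable_dt(case)
  t_end <- case$t + until
  obs <- list()
  next_obs <- case$t
  step <- 0L
  snap_id <- 0L
  while (case$t < t_end - 1e-12) {
    if (step %% recheck_every == 0L && step > 0L) {
      bound <- stable_dt(case)
      if (dt > bound) dt <- 0.9 * bound
    }
    case <- advance_timestep(case, min(dt, t_end - case$t), check_dt = FALSE)
    step <- step + 1L
    if (!is.null(observer) && case$t >= next_obs - 1e-12) {
      obs[[length(obs) + 1L]] <- observer(case)
      next_obs <- next_obs + observe_every
      if (!is.null(snapshot_dir)) {
        snap_id <- snap_id + 1L
        write_snapshot(case$system, case$t,
                       file.path(snapshot_dir,
                                 sprintf("snap_%05d.csv", snap_id)))
      }
    }
    if (verbose && step %% log_every == 0L) {
      sys <- case$system
      umax <- max(sqrt(rowSums(sys$vel^2)))
      drho <- max(abs(sys$rho[sys$tag == 0L] / sys$rho0 - 1))
      ang <- if (length(case$rigid_bodies))
        paste(sprintf(" theta%d=%.1f", seq_along(case$rigid_bodies),
                      vapply(case$rigid_bodies, `[[`, numeric(1), "theta")),
              collapse = "") else ""
      message(sprintf("step %d t=%.4f umax=%.3f drho=%.2e%s",
                      step, case$t, umax, drho, ang))
    }
  }
  list(case = case,
       observations = if (length(obs)) dplyr::bind_rows(obs) else NULL)
}

#' Record wall shear during a run
#'
#' Convenience observer factory for [run_simulation()]: evaluates
#' [compute_wall_shear()] against the case's wall samples at every
#' observation time.
#'
#' @param samples A [wall_samples()] tibble; defaults to `case$samples`.
#' @param mode `"laminar"` or `"les"`.
#' @return An observer function.
#' @export
wss_observer <- function(samples = NULL, mode = "laminar") {
  function(case) {
    sm <- if (is.null(samples)) case$samples else samples
    compute_wall_shear(case, sm, mode = mode)
  }
}
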