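#' Write a particle snapshot
#'
#' Native format is CSV with the fixed header
#' `t,x,y,z,vx,vy,vz,rho,p,tag,body` (2D states pad `z`/`vz` with zeros);
#' `format = "vtk"` writes a legacy ASCII VTK point cloud with the same
#' point-data fields for visualisation.
#'
#' @param system A [particle_system()].
#' @param t Simulation time (s).
#' @param path Output file path.
#' @param format `"csv"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(system, t, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  d <- sys_dim(system)
  n <- n_particles(system)
  pad <- function(m) if (d == 3L) m else cbind(m, matrix(0, n, 3L - d))
  pos <- pad(system$pos); vel <- pad(system$vel)
  df <- data.frame(t = rep(t, n),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
                   rho = system$rho, p = system$p,
                   tag = system$tag, body = system$body)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("haemosph snapshot t=%.9g", t),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", n)), con)
    if (n) write(t(pos), con, ncolumns = 3)
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS velocity double", con)
    if (n) write(t(vel), con, ncolumns = 3)
    for (f in c("rho", "p")) {
      writeLines(c(sprintf("SCALARS %s double 1", f), "LOOKUP_TABLE default"),
                 con)
      if (n) write(df[[f]], con, ncolumns = 9)
    }
    writeLines(c("SCALARS tag int 1", "LOOKUP_TABLE default"), con)
    if (n) write(df$tag, con, ncolumns = 9)
  }
  invisible(path)
}

#' Read a CSV particle snapshot
#'
#' Inverse of [write_snapshot()] (CSV format).  Trailing zero `z` columns
#' are dropped back to 2D when `dim = 2`.
#'
#' @param path Snapshot file.
#' @param dim Spatial dimension of the stored state (2 or 3).
#' @param rho0,mu,dp Material metadata to attach (not stored in the file).
#' @return A list with the [particle_system()] and the snapshot time `t`.
#' @export
read_snapshot <- function(path, dim = 2L, rho0 = 1060, mu = 0.003,
                          dp = NULL) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "z", "vx", "vy", "vz", "rho", "p", "tag", "body")
  if (!all(need %in% names(df)))
    stop("format error: snapshot lacks required columns", call. = FALSE)
  axes <- c("x", "y", "z")[seq_len(dim)]
  n <- nrow(df)
  sys <- particle_system(
    positions = as.matrix(df[axes]),
    velocities = as.matrix(df[paste0("v", axes)]),
    rho = df$rho, mass = if (is.null(dp)) 1 else rho0 * dp^dim,
    tag = df$tag, body = df$body, rho0 = rho0, mu = mu, dp = dp)
  sys$p <- df$p
  list(system = sys, t = if (n) df$t[1] else 0)
}

.default_config <- function() {
  list(
    case = list(name = NULL),
    fluid = list(rho0 = 1060, mu = 0.003, h_ratio = 1.4),
    inlet = list(period = 0.8, peak_time = 0.1, peak_speed = 0.79,
                 shape = list(systolic_fraction = 0.35,
                              diastolic_fraction = 0.05)),
    outlet = list(pressure = 0),
    buffer = list(layers = 5),
    solid = list(E = 1e6, nu = 0.49, rho0 = 1100, layers = 3),
    valve = list(theta_closed = 30, theta_open = 85, leaflet_density = 1100))
}

.check_keys <- function(given, defaults, path = "") {
  for (k in names(given)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("config error: unknown key `", full, "`", call. = FALSE)
    if (is.list(defaults[[k]]) && is.list(given[[k]]))
      .check_keys(given[[k]], defaults[[k]], full)
  }
}

#' Load a case configuration
#'
#' Reads a JSON configuration, validates every key against the known schema
#' (unknown keys are rejected by name), applies the physiological defaults
#' (`rho0 = 1060`, `mu = 0.003`, `h = 1.4 dp`, `E = 1e6`, `nu = 0.49`,
#' `rho_solid = 1100`, `T = 0.8` s, peak systole 0.1 s, 5 buffer layers,
#' hinge stops 30/85 degrees) and range-checks the physical bounds.
#'
#' @param path JSON configuration file.  Required keys: `case.name`,
#'   `case.dp` plus the geometry fields of the named fixture.
#' @return A validated nested configuration list (class `haemosph_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- .default_config()
  defaults$case <- c(defaults$case,
                     list(dp = NULL, height = NULL, length = NULL,
                          tube_width = NULL, thickness = NULL,
                          drive = NULL, leaflet = NULL, u_max = NULL,
                          tip_load = NULL, seed = 1))
  .check_keys(cfg, defaults)
  merged <- utils::modifyList(defaults, cfg)
  if (is.null(merged$case$name))
    stop("config error: missing required key `case.name`", call. = FALSE)
  if (merged$solid$nu >= 0.5)
    stop("config error: `solid.nu` must be < 0.5", call. = FALSE)
  if (merged$fluid$rho0 <= 0)
    stop("config error: `fluid.rho0` must be positive", call. = FALSE)
  if (merged$buffer$layers < 1)
    stop("config error: `buffer.layers` must be >= 1", call. = FALSE)
  structure(merged, class = c("haemosph_config", "list"))
}

#' Save a configuration
#'
#' @param config A configuration list (as from [load_config()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Build a case from a configuration
#'
#' Dispatches on `config$case$name` (`"channel"`, `"bileaflet_valve"`,
#' `"cantilever"`) to the fixture generators.
#'
#' @param config A `haemosph_config` (see [load_config()]).
#' @return An [sph_case()] (or the cantilever fixture list).
#' @export
case_from_config <- function(config) {
  cc <- config$case
  switch(cc$name,
    channel = make_channel_case(
      height = cc$height, length = cc$length, dp = cc$dp,
      drive = if (is.null(cc$drive)) "body-force" else cc$drive,
      u_max = if (is.null(cc$u_max)) 0.1 else cc$u_max,
      seed = cc$seed),
    bileaflet_valve = make_bileaflet_valve_case(
      tube_width = if (is.null(cc$tube_width)) 0.025 else cc$tube_width,
      dp = cc$dp,
      leaflet = if (is.null(cc$leaflet)) "rigid" else cc$leaflet,
      profile = inlet_profile(
        period = config$inlet$period, peak_time = config$inlet$peak_time,
        peak_speed = config$inlet$peak_speed,
        systolic_fraction = config$inlet$shape$systolic_fraction,
        diastolic_fraction = config$inlet$shape$diastolic_fraction),
      seed = cc$seed),
    cantilever = make_cantilever_case(
      length = cc$length, thickness = cc$thickness, dp = cc$dp,
      tip_load = if (is.null(cc$tip_load)) 0 else cc$tip_load,
      E = config$solid$E, nu = config$solid$nu, rho0 = config$solid$rho0),
    stop("config error: unknown case name `", cc$name, "`", call. = FALSE))
}

#' Write a run manifest
#'
#' Records the configuration echo, a content hash, the seed and the package
#' version so a run can be reproduced exactly.
#'
#' @param config Configuration list (or case `spec`).
#' @param seed Seed used.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small polynomial content hash mod 2^31 - 1 (no external digest
  # dependency; double arithmetic stays exact below 2^53)
  bytes <- utf8ToInt(as.character(txt))
  hash <- 0
  for (b in bytes) hash <- (hash * 131 + b) %% 2147483647
  jsonlite::write_json(
    list(config = unclass(config), config_hash = sprintf("%08x", hash),
         seed = seed, package = "haemosph",
         version = as.character(utils::packageVersion("haemosph"))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Export haemodynamic maps as CSV
#'
#' Columns `x,y,z,nx,ny,nz,TAWSS,OSI,ECAP,PSWSS` (2D states pad z).
#'
#' @param maps A [haemodynamic_maps()] tibble joined with wall samples.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_maps_csv <- function(maps, path) {
  get0c <- function(nm) if (nm %in% names(maps)) maps[[nm]] else 0
  df <- data.frame(x = get0c("x"), y = get0c("y"), z = get0c("z"),
                   nx = get0c("nx"), ny = get0c("ny"), nz = get0c("nz"),
                   TAWSS = maps$tawss, OSI = maps$osi, ECAP = maps$ecap,
                   PSWSS = maps$pswss)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
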