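# Surface generation, trajectory/mesh I/O, configuration and the CLI driver.
#
# A trajectory is rendered as a swept surface: one profile row per stored
# time, stacked along the growth direction. Geometries: "strip" (planar
# accretion, the shell-edge record), "disc" (arc coordinate mapped to the
# angle of an expanding circle — radial history, as in mushroom lamellae),
# "helicospiral" (profile painted as a normal displacement on a logarithmic
# helicospiral generating curve — a simplified dressed-shell mapping).

.profile_row <- function(trajectory, i, x) {
  lv <- trajectory$levels
  act <- which(lv$t_onset <= trajectory$time[i] + 1e-12 &
                 trajectory$a[i, ] > 0)
  y <- numeric(length(x))
  if (length(act) == 0L) return(y)
  levels <- data.frame(level = lv$level[act], N = lv$N[act], sigma = lv$sigma[act],
                       amplitude = trajectory$a[i, act])
  L <- trajectory$schedule$L(trajectory$time[i])
  seqs <- if (nrow(levels) == 1L) rep(1L, levels$N[1]) else
    intercalation_sequence(levels$N[1], nrow(levels))
  pat <- try(hierarchical_pattern(levels, L = L, sequence = seqs), silent = TRUE)
  if (inherits(pat, "try-error") || is.null(pat$bumps)) return(y)
  pattern_profile(pat)(x * L)
}

#' Sweep a trajectory into a surface
#'
#' @param trajectory A `pattern_trajectory`.
#' @param geometry `"strip"`, `"disc"` or `"helicospiral"`.
#' @param nx Number of arc samples per profile row.
#' @param nt Number of profile rows (subsampled uniformly from the stored
#'   times).
#' @param coil Helicospiral parameters (list with growth rate `c`, angular
#'   rate `omega`, drop rate `b`, aperture scale `rho`).
#' @return An object of class `pattern_surface`: `vertices` (V x 3 matrix),
#'   `faces` (F x 3, 1-based triangles), `dims = c(nt, nx)`, `geometry`.
#' @export
sweep_surface <- function(trajectory, geometry = c("strip", "disc", "helicospiral"),
                          nx = 201L, nt = 60L,
                          coil = list(c = 0.25, omega = 2 * pi, b = 0.4, rho = 0.35)) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(trajectory, "pattern_trajectory"))
  if (length(trajectory$time) < 2L) stop("trajectory has fewer than two time points")
  idx <- unique(round(seq(1, length(trajectory$time), length.out = nt)))
  nt <- length(idx)
  xs <- seq(-1, 1, length.out = nx)  # arc coordinate as fraction of L(t)
  verts <- matrix(0, nt * nx, 3)
  for (r in seq_len(nt)) {
    i <- idx[r]
    t <- trajectory$time[i]
    y <- .profile_row(trajectory, i, xs)
    L <- trajectory$schedule$L(t)
    rows <- (r - 1L) * nx + seq_len(nx)
    if (geometry == "strip") {
      verts[rows, ] <- cbind(xs * L, rep(t, nx), y)
    } else if (geometry == "disc") {
      theta <- pi * xs
      rad <- L / pi + y
      verts[rows, ] <- cbind(rad * cos(theta), rad * sin(theta), 0)
    } else {
      e <- exp(coil$c * t)
      centre <- c(e * cos(coil$omega * t), e * sin(coil$omega * t), -coil$b * e)
      e_r <- c(cos(coil$omega * t), sin(coil$omega * t), 0)
      e_z <- c(0, 0, 1)
      phi <- pi * xs
      rho <- coil$rho * e
      for (j in seq_len(nx)) {
        dirv <- cos(phi[j]) * e_r + sin(phi[j]) * e_z
        verts[rows[j], ] <- centre + (rho + y[j]) * dirv
      }
    }
  }
  faces <- matrix(0L, 2L * (nt - 1L) * (nx - 1L), 3L)
  f <- 1L
  for (r in seq_len(nt - 1L)) for (j in seq_len(nx - 1L)) {
    v00 <- (r - 1L) * nx + j; v01 <- v00 + 1L
    v10 <- r * nx + j; v11 <- v10 + 1L
    faces[f, ] <- c(v00, v10, v11); faces[f + 1L, ] <- c(v00, v11, v01)
    f <- f + 2L
  }
  storage.mode(faces) <- "integer"
  structure(list(vertices = verts, faces = faces, dims = c(nt, nx),
                 geometry = geometry), class = "pattern_surface")
}

#' @export
print.pattern_surface <- function(x, ...) {
  cat(sprintf("<pattern_surface> %s: %d vertices, %d triangles (%d x %d grid)\n",
              x$geometry, nrow(x$vertices), nrow(x$faces), x$dims[1], x$dims[2]))
  invisible(x)
}

#' Export a surface mesh to OBJ or PLY
#'
#' @param surface A [sweep_surface()] result.
#' @param path Output file path.
#' @param format `"obj"` or `"ply"` (ASCII); default inferred from the
#'   file extension.
#' @return The path, invisibly.
#' @export
export_mesh <- function(surface, path, format = NULL) {
  stopifnot(inherits(surface, "pattern_surface"))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply"))
  v <- surface$vertices; fc <- surface$faces
  con <- suppressWarnings(try(file(path, "w"), silent = TRUE))
  if (inherits(con, "try-error")) stop("cannot open '", path, "' for writing", call. = FALSE)
  on.exit(close(con))
  if (format == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", fc[, 1], fc[, 2], fc[, 3]), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(fc)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", fc[, 1] - 1L, fc[, 2] - 1L, fc[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read a mesh written by [export_mesh()]
#'
#' @param path OBJ or PLY file path.
#' @return List with `vertices` and `faces` (1-based).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, " +"), function(p) as.numeric(p[2:4])))
    fc <- do.call(rbind, lapply(strsplit(fl, " +"), function(p) as.integer(p[2:4])))
  } else if (ext == "ply") {
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    hdr <- which(lines == "end_header")
    v <- do.call(rbind, lapply(strsplit(lines[hdr + seq_len(nv)], " +"),
                               function(p) as.numeric(p[1:3])))
    fc <- do.call(rbind, lapply(strsplit(lines[hdr + nv + seq_len(nf)], " +"),
                                function(p) as.integer(p[2:4]) + 1L))
  } else stop("unsupported mesh format: ", ext, call. = FALSE)
  list(vertices = v, faces = fc)
}

# ---- trajectory I/O ---------------------------------------------------------

#' Write a trajectory to CSV or JSON
#'
#' CSV stores the long format (`t, level, a, ahat, sigma, N`); JSON
#' additionally records the level table and the schedule/material metadata
#' needed to reconstruct a `pattern_trajectory` with [read_trajectory()].
#'
#' @param trajectory A `pattern_trajectory`.
#' @param path Output path; format inferred from the `.csv`/`.json`
#'   extension unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = NULL) {
  stopifnot(inherits(trajectory, "pattern_trajectory"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  } else {
    sch <- trajectory$schedule
    obj <- list(time = trajectory$time, a = trajectory$a, ahat = trajectory$ahat,
                levels = trajectory$levels, max_level = trajectory$max_level,
                params = unclass(trajectory$params)[c("m", "mu", "Eb", "K", "eta")],
                schedule = list(L0 = sch$L0, g = sch$g, delta0 = sch$delta0,
                                type = sch$type, rate = sch$rate))
    writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()] (JSON format)
#'
#' @param path JSON file path.
#' @return A reconstructed `pattern_trajectory`.
#' @export
read_trajectory <- function(path) {
  obj <- jsonlite::fromJSON(path)
  params <- material_params(m = obj$params$m, mu = obj$params$mu, Eb = obj$params$Eb,
                            K = obj$params$K, eta = obj$params$eta)
  gb <- if (obj$schedule$type == "burst") obj$schedule$rate else NULL
  sched <- growth_schedule(L0 = obj$schedule$L0, g = obj$schedule$g,
                           delta0 = obj$schedule$delta0, type = obj$schedule$type,
                           g_burst = gb)
  .new_trajectory(as.numeric(obj$time), as.matrix(obj$a), as.matrix(obj$ahat),
                  as.data.frame(obj$levels), params, sched, obj$max_level)
}

# ---- configuration ----------------------------------------------------------

#' Default run configuration
#'
#' All tunables of a simulation run with explicit defaults: material
#' parameters (`m`, `mu`, `eta`), growth schedule (`L0`, `g`, `delta0`,
#' `type`), solver settings (`t_max`, `dt`, `max_level`, optional `N1`),
#' rendering (`geometry`, `nx`, `nt_rows`) and output paths.
#'
#' @return A named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    m = 4L, mu = 30, eta = 0,
    L0 = 6, g = 0.1, delta0 = 0.04, type = "linear",
    t_max = 3, dt = 1e-3, max_level = 5L, N1 = NULL,
    geometry = "strip", nx = 201L, nt_rows = 60L,
    out_dir = ".", seed = 1L
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A list (e.g. from [load_config()]); unknown fields are
#'   rejected, missing fields filled from [default_config()].
#' @return The completed config (class `run_config`), or an error describing
#'   the offending field.
#' @export
validate_config <- function(config) {
  base <- default_config()
  extra <- setdiff(names(config), names(base))
  if (length(extra)) stop("unknown config field(s): ", paste(extra, collapse = ", "),
                          call. = FALSE)
  cfg <- modifyList(unclass(base), config)
  chk <- function(cond, msg) if (!cond) stop("config: ", msg, call. = FALSE)
  chk(cfg$m %in% 2:4, "'m' must be 2, 3 or 4")
  chk(is.numeric(cfg$mu) && cfg$mu >= 0, "'mu' must be >= 0")
  chk(is.numeric(cfg$eta) && cfg$eta >= 0, "'eta' must be >= 0")
  chk(is.numeric(cfg$L0) && cfg$L0 > 0, "'L0' must be > 0")
  chk(is.numeric(cfg$g) && cfg$g >= 0, "'g' must be >= 0")
  chk(is.numeric(cfg$delta0) && cfg$delta0 >= 0, "'delta0' must be >= 0")
  chk(cfg$type %in% c("linear", "burst"), "'type' must be linear or burst")
  chk(is.numeric(cfg$t_max) && cfg$t_max > 0, "'t_max' must be > 0")
  chk(is.numeric(cfg$dt) && cfg$dt > 0 && cfg$dt < cfg$t_max, "'dt' must be in (0, t_max)")
  chk(cfg$max_level >= 1, "'max_level' must be >= 1")
  chk(cfg$geometry %in% c("strip", "disc", "helicospiral"), "unknown 'geometry'")
  class(cfg) <- "run_config"
  cfg
}

#' Load and validate a JSON run configuration
#'
#' @param path JSON file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_config(jsonlite::fromJSON(path))
}

.cfg_objects <- function(cfg) {
  list(params = material_params(m = cfg$m, mu = cfg$mu, eta = cfg$eta),
       schedule = growth_schedule(L0 = cfg$L0, g = cfg$g, delta0 = cfg$delta0,
                                  type = cfg$type))
}

# ---- morphospace ------------------------------------------------------------

#' Morphospace sweep over stiffness ratio and growth rate
#'
#' Runs the hierarchy solver over a grid of `(mu, g)` and reports the
#' level-1 mode and the level-2 onset time for each cell. A stiffer
#' foundation (larger `mu`) selects narrower bumps and hence a denser
#' level-1 pattern; faster excess growth (larger `g`) brings the level-2
#' bifurcation earlier.
#'
#' @param mu_values,g_values Grid values.
#' @param config Base configuration (defaults from [default_config()]).
#' @return Data frame with columns `mu`, `g`, `N1`, `t2`, `levels`.
#' @export
morphospace <- function(mu_values, g_values, config = default_config()) {
  cfg <- validate_config(unclass(config))
  out <- expand.grid(mu = mu_values, g = g_values, KEEP.OUT.ATTRS = FALSE)
  out$N1 <- NA_integer_; out$t2 <- NA_real_; out$levels <- NA_integer_
  for (i in seq_len(nrow(out))) {
    cfg_i <- cfg; cfg_i$mu <- out$mu[i]; cfg_i$g <- out$g[i]
    ob <- .cfg_objects(cfg_i)
    tr <- solve_hierarchy(ob$params, ob$schedule, t_max = cfg$t_max,
                          max_level = min(cfg$max_level, 3L), dt = cfg$dt)
    out$N1[i] <- tr$levels$N[1]
    out$t2[i] <- if (nrow(tr$levels) >= 2) tr$levels$t_onset[2] else NA_real_
    out$levels[i] <- nrow(tr$levels)
  }
  out
}

# ---- CLI --------------------------------------------------------------------

.cli_msg <- function(...) cat(sprintf(...), "\n", sep = "")

#' Command-line driver
#'
#' Subcommands:
#' * `simulate [--config f.json] [--out dir]` — hierarchy run (memory-aware
#'   when `eta > 0`), writes `trajectory.csv` / `trajectory.json`.
#' * `dilate [--config f.json] [--out dir]` — linear vs fractal dilation of
#'   the default ridge fixture on the configured domain, writes energy CSV.
#' * `morphospace [--config f.json] [--out dir] [--mu a,b,...] [--g a,b,...]`
#'   — grid sweep, writes `morphospace.csv`.
#' * `render [--config f.json] [--out dir] [--format obj|ply]` — simulate and
#'   export the swept surface mesh.
#' * `validate [--config f.json] [--out dir]` — ansatz-versus-oracle energy
#'   comparison record (JSON).
#'
#' @param argv Character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code: 0 on success, 2 on usage/config errors.
#' @export
run_cli <- function(argv = character()) {
  usage <- function() {
    .cli_msg("usage: morphoridge <simulate|dilate|morphospace|render|validate> [--config file] [--out dir] ...")
    2L
  }
  if (length(argv) < 1L) return(usage())
  cmd <- argv[1]
  if (!cmd %in% c("simulate", "dilate", "morphospace", "render", "validate"))
    return(usage())
  opts <- list(config = NULL, out = ".", format = "obj", mu = NULL, g = NULL)
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) return(usage())
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  cfg <- tryCatch(
    if (is.null(opts$config)) default_config() else load_config(opts$config),
    error = function(e) { .cli_msg("config error: %s", conditionMessage(e)); NULL })
  if (is.null(cfg)) return(2L)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  ob <- .cfg_objects(cfg)
  .cli_msg("morphoridge %s: m=%d mu=%g g=%g eta=%g L0=%g", cmd, cfg$m, cfg$mu,
           cfg$g, cfg$eta, cfg$L0)
  if (cmd == "simulate" || cmd == "render") {
    tr <- if (cfg$eta > 0)
      evolve_with_memory(ob$params, ob$schedule, t_max = cfg$t_max,
                         max_level = cfg$max_level, dt = cfg$dt, N1 = cfg$N1)
    else solve_hierarchy(ob$params, ob$schedule, t_max = cfg$t_max,
                         max_level = cfg$max_level, dt = cfg$dt, N1 = cfg$N1)
    write_trajectory(tr, file.path(opts$out, "trajectory.csv"))
    write_trajectory(tr, file.path(opts$out, "trajectory.json"))
    .cli_msg("levels attained: %d (onsets: %s)", nrow(tr$levels),
             paste(signif(tr$levels$t_onset, 4), collapse = ", "))
    if (cmd == "render") {
      surf <- sweep_surface(tr, geometry = cfg$geometry, nx = cfg$nx, nt = cfg$nt_rows)
      mesh_path <- file.path(opts$out, paste0("surface.", opts$format))
      export_mesh(surf, mesh_path, format = opts$format)
      .cli_msg("mesh written: %s", mesh_path)
    }
  } else if (cmd == "dilate") {
    params <- ob$params
    ridges <- ridge_pattern(c(3, 2, 3, 1, 3, 2, 3), L = cfg$L0, params = params,
                            delta = cfg$delta0)
    res <- compare_dilation(ridges, params = params, t_max = cfg$t_max / 3)
    write.csv(res$energy, file.path(opts$out, "dilation_energy.csv"), row.names = FALSE)
    .cli_msg("winner: %s", res$winner)
  } else if (cmd == "morphospace") {
    mu_v <- if (is.null(opts$mu)) c(3, 30, 100, 300) else as.numeric(strsplit(opts$mu, ",")[[1]])
    g_v <- if (is.null(opts$g)) c(0.05, 0.1, 0.15, 0.2) else as.numeric(strsplit(opts$g, ",")[[1]])
    ms <- morphospace(mu_v, g_v, cfg)
    write.csv(ms, file.path(opts$out, "morphospace.csv"), row.names = FALSE)
    .cli_msg("%d cells written", nrow(ms))
  } else if (cmd == "validate") {
    params <- ob$params
    tr <- solve_hierarchy(params, ob$schedule, t_max = cfg$t_max, max_level = 1L,
                          dt = cfg$dt)
    pat <- pattern_at(tr, max(tr$time))
    rep <- oracle_report(pat, params, n = 201L)
    writeLines(jsonlite::toJSON(rep, digits = NA, auto_unbox = TRUE),
               file.path(opts$out, "oracle_report.json"))
    .cli_msg("E_sep=%.5g E_overlap=%.5g E_full=%.5g", rep$separated, rep$overlap, rep$full)
  }
  0L
}
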