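# Configuration files, run outputs and the command-line interface.

#' @noRd
default_raw_config <- function() {
  list(
    seed = 1L,
    units = list(length = "pixels"),
    grid = list(pixel_size = 10),
    phantom = list(kind = "straight_tract", shape = c(320L, 224L),
                   tract_width = 2, contrast = 1, band_period = 6),
    input = NULL,
    smoothing_sigma = 2,
    tumors = list(),
    injection = list(center = NULL, radius = 5),
    params = list(
      # midpoints of the published parameter ranges
      d_w = 2.75, d_g = 2.55, lambda_c = 6.5, beta_w = 2.5, alpha_c = 3,
      epsilon_M = 0.4, epsilon_c = 0.05, dt = 1 / 1000, n_days = 30,
      n_agents = 1000, chemotaxis_absorb = TRUE, wm_noise_sd = 0
    )
  )
}

#' @noRd
merge_defaults <- function(raw, def) {
  for (k in names(def)) {
    if (is.null(raw[[k]])) {
      raw[k] <- def[k]
    } else if (is.list(def[[k]]) && is.list(raw[[k]]) &&
               !is.null(names(def[[k]]))) {
      raw[[k]] <- merge_defaults(raw[[k]], def[[k]])
    }
  }
  raw
}

#' @noRd
cfg_check <- function(ok, key, what) {
  if (!ok) stop(sprintf("config key '%s' %s", key, what), call. = FALSE)
}

#' Resolve and validate a raw configuration
#'
#' Fills unset keys with the package defaults (midpoints of the published
#' parameter ranges, `epsilon_M = 0.4`), validates every constraint naming
#' the offending key, and converts all lengths to pixels (the `units:` block
#' declares whether tumor centres and the injection site were given in
#' `pixels` or `um`). The resolved configuration is the canonical form:
#' resolving it again is a no-op.
#'
#' @param raw a plain (possibly partial) configuration list, e.g. from
#'   [yaml::read_yaml()].
#' @return The resolved configuration list (class `nsc_config`).
#' @export
resolve_config <- function(raw) {
  cfg <- merge_defaults(raw, default_raw_config())
  unit <- cfg$units$length %||% "pixels"
  cfg_check(unit %in% c("pixels", "um"), "units.length",
            "must be 'pixels' or 'um'")
  ps <- cfg$grid$pixel_size
  cfg_check(is.numeric(ps) && ps > 0, "grid.pixel_size", "must be > 0")
  to_px <- function(v) if (unit == "um") v / ps else v

  p <- cfg$params
  cfg_check(p$d_w >= 0, "params.d_w", "must be >= 0")
  cfg_check(p$d_g >= 0, "params.d_g", "must be >= 0")
  cfg_check(p$lambda_c >= 0, "params.lambda_c", "must be >= 0")
  cfg_check(p$beta_w >= 1, "params.beta_w", "must be >= 1")
  cfg_check(p$alpha_c >= 1, "params.alpha_c", "must be >= 1")
  cfg_check(p$epsilon_M >= 0 && p$epsilon_M <= 1, "params.epsilon_M",
            "must be in [0, 1]")
  cfg_check(p$epsilon_c > 0 && p$epsilon_c < 1, "params.epsilon_c",
            "must be in (0, 1)")
  cfg_check(p$dt > 0, "params.dt", "must be > 0")
  cfg_check(p$n_days > 0, "params.n_days", "must be > 0")
  cfg_check(p$n_agents >= 1, "params.n_agents", "must be >= 1")

  if (!is.null(cfg$injection$center)) {
    cfg$injection$center <- to_px(as.numeric(cfg$injection$center))
    cfg$injection$radius <- to_px(cfg$injection$radius)
  }
  cfg_check(is.numeric(cfg$injection$radius) && cfg$injection$radius >= 0,
            "injection.radius", "must be >= 0")
  cfg$tumors <- lapply(seq_along(cfg$tumors), function(i) {
    tm <- cfg$tumors[[i]]
    key <- sprintf("tumors[%d]", i)
    cfg_check(!is.null(tm$center), paste0(key, ".center"), "is required")
    tm$center <- to_px(as.numeric(tm$center))
    if (!is.null(tm$sigma)) {
      tm$sigma <- to_px(as.numeric(tm$sigma))
      cfg_check(all(tm$sigma > 0), paste0(key, ".sigma"), "must be > 0")
    }
    tm$p <- tm$p %||% 1
    cfg_check(tm$p > 0, paste0(key, ".p"), "must be > 0")
    if (!is.null(tm$extent_um)) {
      cfg_check(all(tm$extent_um > 0), paste0(key, ".extent_um"), "must be > 0")
    }
    tm
  })
  if (!is.null(cfg$input)) cfg$phantom <- NULL
  cfg$units$length <- "pixels"
  structure(cfg, class = "nsc_config")
}

#' Load a scenario configuration from YAML
#'
#' @param path YAML file.
#' @return The resolved configuration (see [resolve_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  resolve_config(yaml::read_yaml(path))
}

#' Write a configuration to YAML
#'
#' @param cfg a configuration list (raw or resolved).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build scenario objects from a configuration
#'
#' Renders the phantom (or reads the input volume), computes the tissue
#' field, assembles the chemoattractant field and the
#' [simulation_config()].
#'
#' @param cfg a resolved configuration from [resolve_config()] /
#'   [load_config()].
#' @return A list with `image`, `tissue`, `chemo` (`NULL` when no tumors)
#'   and `config`.
#' @export
build_scenario <- function(cfg) {
  if (!inherits(cfg, "nsc_config")) cfg <- resolve_config(cfg)
  ps <- cfg$grid$pixel_size
  if (!is.null(cfg$input)) {
    img <- read_volume(cfg$input$path %||% cfg$input, pixel_size = ps,
                       brain_mask = cfg$input$brain_mask)
  } else {
    ph <- cfg$phantom
    spec <- phantom_spec(ph$shape, ph$kind, tract_width = ph$tract_width,
                         contrast = ph$contrast, noise_sd = ph$noise_sd,
                         band_period = ph$band_period,
                         gap_period = ph$gap_period %||% 60,
                         gap_width = ph$gap_width %||% 18,
                         pixel_size = ps)
    set.seed(cfg$seed)  # phantom texture noise is part of the scenario seed
    img <- make_phantom(spec, epsilon_M = cfg$params$epsilon_M,
                        smoothing_sigma = cfg$smoothing_sigma)
  }
  tissue <- classify_tissue(structure_tensor(img, cfg$smoothing_sigma),
                            epsilon_M = cfg$params$epsilon_M)
  chemo <- if (length(cfg$tumors)) {
    chemo_field(
      lapply(cfg$tumors, function(tm) {
        tumor_site(tm$center, half_decay = tm$sigma, decay_power = tm$p,
                   extent_um = tm$extent_um)
      }),
      epsilon_c = cfg$params$epsilon_c, pixel_size = ps
    )
  } else {
    NULL
  }
  p <- cfg$params
  config <- simulation_config(
    d_w = p$d_w, d_g = p$d_g, lambda_c = p$lambda_c, beta_w = p$beta_w,
    alpha_c = p$alpha_c, epsilon_M = p$epsilon_M, epsilon_c = p$epsilon_c,
    dt = p$dt, n_steps = round(p$n_days / p$dt), n_agents = p$n_agents,
    injection_center = cfg$injection$center,
    injection_radius = cfg$injection$radius,
    seed = cfg$seed,
    chemotaxis_absorb = isTRUE(p$chemotaxis_absorb),
    wm_noise_sd = p$wm_noise_sd
  )
  list(image = img, tissue = tissue, chemo = chemo, config = config)
}

#' Write trajectory snapshots to CSV
#'
#' Long format, one row per snapshot step and agent: `step`, `agent`,
#' `x`, `y` (,`z`), `on_wm`, `arrived_site` (0 while not arrived).
#'
#' @param record a `sim_record`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(record, path) {
  stopifnot(inherits(record, "sim_record"))
  ns <- length(record$snapshot_steps)
  n <- record$n_agents
  d <- record$dim
  flat <- matrix(aperm(record$snapshots, c(2, 1, 3)), ns * n, d)
  step <- rep(record$snapshot_steps, each = n)
  agent <- rep(seq_len(n), ns)
  arr <- ifelse(!is.na(record$arrival_step[agent]) &
                  record$arrival_step[agent] <= step,
                record$arrival_site[agent], 0L)
  # coordinates are printed with 17 significant digits so that reading the
  # file back reproduces the doubles bit-exactly (metric recomputation from
  # a saved record must match the original run byte for byte)
  fmt <- function(v) sprintf("%.17g", v)
  df <- data.table::data.table(step = step, agent = agent,
                               x = fmt(flat[, 1]), y = fmt(flat[, 2]))
  if (d == 3L) df$z <- fmt(flat[, 3])
  df$on_wm <- as.vector(t(record$snapshot_wm))
  df$arrived_site <- arr
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @noRd
write_arrivals <- function(record, path) {
  ids <- which(record$arrival_site > 0L)
  df <- data.table::data.table(
    agent = ids,
    site = record$arrival_site[ids],
    step = record$arrival_step[ids],
    path_um = sprintf("%.17g", record$arrival_path_um[ids])
  )
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Write the tidy metric table
#'
#' @param record a `sim_record`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(record, path) {
  data.table::fwrite(data.table::as.data.table(metric_table(record)), path,
                     na = "NA")
  invisible(path)
}

#' Reconstruct a minimal record from a run output directory
#'
#' Reads `trajectories.csv`, `arrivals.csv` and `manifest.json` (as written
#' by the CLI `run` subcommand) back into a `sim_record` sufficient for all
#' metric functions; [metric_table()] on the reconstruction reproduces the
#' run's `metrics.csv` exactly.
#'
#' @param dir run output directory.
#' @return A `sim_record`.
#' @export
read_record <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tr <- data.table::fread(file.path(dir, "trajectories.csv"))
  ar <- data.table::fread(file.path(dir, "arrivals.csv"))
  steps <- sort(unique(tr$step))
  n <- man$n_agents
  d <- if ("z" %in% names(tr)) 3L else 2L
  data.table::setorderv(tr, c("step", "agent"))
  ns <- length(steps)
  coords <- as.matrix(tr[, c("x", "y", if (d == 3L) "z"), with = FALSE])
  snaps <- aperm(array(coords, c(n, ns, d)), c(2, 1, 3))
  snap_wm <- t(matrix(tr$on_wm, n, ns))
  arrival_site <- integer(n)
  arrival_step <- rep(NA_integer_, n)
  arrival_path <- rep(NA_real_, n)
  if (nrow(ar)) {
    arrival_site[ar$agent] <- ar$site
    arrival_step[ar$agent] <- ar$step
    arrival_path[ar$agent] <- ar$path_um
  }
  structure(
    list(
      config = list(dt = man$dt, n_steps = man$n_steps),
      seed = man$seed,
      pixel_size = man$pixel_size,
      injection_center = man$injection_center,
      dim = d,
      n_agents = n,
      n_sites = man$n_sites,
      snapshots = snaps,
      snapshot_steps = steps,
      snapshot_wm = snap_wm,
      arrival_step = arrival_step,
      arrival_site = arrival_site,
      arrival_path_um = arrival_path,
      final_pos = matrix(snaps[ns, , ], n, d)
    ),
    class = "sim_record"
  )
}

#' @noRd
write_manifest <- function(record, dir, config_path = NULL, wall_time = NA,
                           outputs = character()) {
  man <- list(
    tool = "nscmigrate",
    version = as.character(utils::packageVersion("nscmigrate")),
    config_path = config_path,
    config_hash = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    },
    seed = record$seed,
    n_agents = record$n_agents,
    n_steps = record$config$n_steps,
    n_sites = record$n_sites,
    dt = record$config$dt,
    pixel_size = record$pixel_size,
    injection_center = record$injection_center,
    outputs = outputs,
    wall_time_s = wall_time,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' @noRd
write_run_outputs <- function(record, dir, config_path = NULL, cfg = NULL,
                              wall_time = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(record, file.path(dir, "trajectories.csv"))
  write_arrivals(record, file.path(dir, "arrivals.csv"))
  write_metrics(record, file.path(dir, "metrics.csv"))
  last <- record$series[nrow(record$series), ]
  summary <- list(
    n_agents = record$n_agents,
    simulated_days = max(record$series$time_days),
    final_wm_pct = last$wm_pct,
    final_median_distance_um = last$dist_median_um
  )
  if (record$n_sites > 0) {
    summary$final_arrival_pct <- as.numeric(
      last[paste0("arrival_pct_site", seq_len(record$n_sites))]
    )
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(cfg)) write_config(cfg, file.path(dir, "config.yaml"))
  write_manifest(record, dir, config_path, wall_time,
                 outputs = c("trajectories.csv", "arrivals.csv", "metrics.csv",
                             "summary.json", "config.yaml"))
  invisible(dir)
}
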