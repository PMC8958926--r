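# Small hand-built fixtures shared across tests.

# Uniform grey tissue: zero anisotropy everywhere, direction placeholder.
grey_tissue <- function(shape = c(40, 40), pixel_size = 1) {
  d <- length(shape)
  dir <- array(0, c(shape, d))
  if (d == 2L) dir[, , 1] <- 1 else dir[, , , 1][] <- 1
  tissue_field(array(0, shape), dir, epsilon_M = 0.4, pixel_size = pixel_size)
}

# A horizontal white-matter strip with direction (1, 0): anisotropy 0.9 on
# rows y0..y1, 0 elsewhere.
strip_tissue <- function(shape = c(60, 40), y0 = 18, y1 = 22, pixel_size = 1) {
  anis <- array(0, shape)
  anis[, y0:y1] <- 0.9
  dir <- array(0, c(shape, 2))
  dir[, , 1] <- 1
  tissue_field(anis, dir, epsilon_M = 0.4, pixel_size = pixel_size)
}

# Minimal hand-built record for the metric functions.
fake_record <- function(snaps, snapshot_steps, snap_wm = NULL,
                        arrival_site = NULL, arrival_step = NULL,
                        arrival_path_um = NULL, n_sites = 1L,
                        pixel_size = 1, injection_center = NULL, dt = 1e-3) {
  ns <- dim(snaps)[1]
  n <- dim(snaps)[2]
  d <- dim(snaps)[3]
  structure(
    list(
      config = list(dt = dt, n_steps = max(snapshot_steps)),
      seed = 1L,
      pixel_size = pixel_size,
      injection_center = injection_center %||% rep(0, d),
      dim = d,
      n_agents = n,
      n_sites = n_sites,
      snapshots = snaps,
      snapshot_steps = snapshot_steps,
      snapshot_wm = snap_wm %||% matrix(FALSE, ns, n),
      arrival_step = arrival_step %||% rep(NA_integer_, n),
      arrival_site = arrival_site %||% integer(n),
      arrival_path_um = arrival_path_um %||% rep(NA_real_, n),
      final_pos = matrix(snaps[ns, , ], n, d)
    ),
    class = "sim_record"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
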