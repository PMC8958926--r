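#' Simulation configuration
#'
#' Bundles the migration parameters and run settings. Step sizes `d_w`
#' (white matter), `d_g` (grey matter) and the chemosensitivity `lambda_c`
#' are in pixels per time step; one step is `dt` days, and conversion to
#' um/day happens only at reporting time (multiply by
#' `pixel_size / dt`). Defaults are the midpoints of the published ranges:
#' `d_w` in `[0.5, 5]`, `d_g` in `[0.1, 5]`, `lambda_c` in `[3, 10]`,
#' `beta_w` in `[1, 4]`, `alpha_c` in `[1, 5]`, with `epsilon_M = 0.4`.
#'
#' @param d_w maximum white-matter step size (pixels/step), `>= 0`.
#' @param d_g grey-matter step size (pixels/step), `>= 0`.
#' @param lambda_c chemosensitivity (pixels/step), `>= 0`.
#' @param beta_w shape of the speed-trait beta law `B[1, beta_w]`, `>= 1`;
#'   larger values skew speeds toward zero.
#' @param alpha_c shape of the sensitivity-trait beta law `B[alpha_c, 1]`,
#'   `>= 1`; large values approach deterministic sensitivity.
#' @param epsilon_M white-matter anisotropy threshold in `[0, 1]`.
#' @param epsilon_c chemoattractant detection threshold in `(0, 1)`.
#' @param dt time step in days; default 1/1000.
#' @param n_steps number of steps; default 30 simulated days (`30 / dt`).
#' @param n_agents number of cells; default 1000.
#' @param injection_center injection site (pixels), length 2 or 3.
#' @param injection_radius radius (pixels) of the uniform injection ball.
#' @param seed RNG seed; every random draw of a run flows from it.
#' @param chemotaxis_absorb if `TRUE` (default), agents halt on first arrival
#'   at a tumor site.
#' @param wm_noise_sd optional isotropic Gaussian perturbation (pixels) added
#'   to white-matter steps; default 0 (off).
#' @param snapshot_stride record positions every this many steps; default
#'   `max(1, floor(n_steps / 100))`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(d_w = 2.75, d_g = 2.55, lambda_c = 6.5,
                              beta_w = 2.5, alpha_c = 3,
                              epsilon_M = 0.4, epsilon_c = 0.05,
                              dt = 1 / 1000, n_steps = NULL, n_agents = 1000,
                              injection_center = NULL, injection_radius = 5,
                              seed = 1L, chemotaxis_absorb = TRUE,
                              wm_noise_sd = 0, snapshot_stride = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(n_steps)) n_steps <- as.integer(round(30 / dt))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(d_w >= 0, "d_w must be >= 0")
  chk(d_g >= 0, "d_g must be >= 0")
  chk(lambda_c >= 0, "lambda_c must be >= 0")
  chk(beta_w >= 1, "beta_w must be >= 1")
  chk(alpha_c >= 1, "alpha_c must be >= 1")
  chk(epsilon_M >= 0 && epsilon_M <= 1, "epsilon_M must be in [0, 1]")
  chk(epsilon_c > 0 && epsilon_c < 1, "epsilon_c must be in (0, 1)")
  chk(n_steps >= 1, "n_steps must be >= 1")
  chk(n_agents >= 1, "n_agents must be >= 1")
  chk(injection_radius >= 0, "injection_radius must be >= 0")
  chk(wm_noise_sd >= 0, "wm_noise_sd must be >= 0")
  structure(
    list(
      d_w = d_w, d_g = d_g, lambda_c = lambda_c, beta_w = beta_w,
      alpha_c = alpha_c, epsilon_M = epsilon_M, epsilon_c = epsilon_c,
      dt = dt, n_steps = as.integer(n_steps), n_agents = as.integer(n_agents),
      injection_center = injection_center,
      injection_radius = injection_radius, seed = as.integer(seed),
      chemotaxis_absorb = isTRUE(chemotaxis_absorb),
      wm_noise_sd = wm_noise_sd,
      snapshot_stride = snapshot_stride
    ),
    class = "simulation_config"
  )
}

#' Per-cell migration speed factors
#'
#' Draws speed traits \eqn{\psi \sim B[1, \beta_w]} and rescales them by
#' \eqn{(1 + \beta_w) / 2} so the population mean is 1/2 for every
#' \eqn{\beta_w}. At \eqn{\beta_w = 1} the factors are exactly uniform on
#' `[0, 1]` (agent speeds uniform on `[0, d_w]`); larger \eqn{\beta_w} skews
#' the distribution toward zero (smaller median) while the rescaling creates
#' a heavier right tail of fast outliers.
#'
#' @param beta_w beta-law shape, `>= 1`.
#' @param n number of draws.
#' @return Numeric vector of `n` nonnegative factors with mean 1/2 and
#'   maximum possible value `(1 + beta_w) / 2`.
#' @export
sample_speed_factor <- function(beta_w, n) {
  if (beta_w < 1) stop("beta_w must be >= 1")
  stats::rbeta(n, 1, beta_w) * (1 + beta_w) / 2
}

#' Per-cell chemosensitivity factors
#'
#' Draws sensitivity traits \eqn{\eta \sim B[\alpha_c, 1]} in `[0, 1]`. At
#' \eqn{\alpha_c = 1} the chemosensitivity \eqn{\lambda_c \eta} is uniform on
#' `[0, lambda_c]`; as \eqn{\alpha_c} grows the distribution concentrates at
#' 1 and the response becomes effectively deterministic.
#'
#' @param alpha_c beta-law shape, `>= 1`.
#' @param n number of draws.
#' @return Numeric vector of `n` factors in `[0, 1]` with mean
#'   `alpha_c / (alpha_c + 1)`.
#' @export
sample_sensitivity_factor <- function(alpha_c, n) {
  if (alpha_c < 1) stop("alpha_c must be >= 1")
  stats::rbeta(n, alpha_c, 1)
}

#' Random unit vectors
#'
#' Directions uniform on the unit circle (2-D) or unit sphere surface (3-D),
#' by normalising standard Gaussian draws.
#'
#' @param n number of vectors.
#' @param dim 2 or 3.
#' @return `n x dim` matrix of unit vectors.
#' @export
random_unit_vector <- function(n, dim) {
  if (!dim %in% 2:3) stop("dim must be 2 or 3")
  v <- matrix(stats::rnorm(n * dim), n, dim)
  nn <- row_norms(v)
  while (any(nn < 1e-300)) {  # essentially impossible, but stay safe
    bad <- nn < 1e-300
    v[bad, ] <- stats::rnorm(sum(bad) * dim)
    nn <- row_norms(v)
  }
  v / nn
}

#' Initialize the agent population
#'
#' Places `n_agents` cells uniformly in the ball of `injection_radius` around
#' `injection_center`, intersected with the brain mask (out-of-brain proposals
#' are rejected and redrawn). Each cell receives fixed traits: a speed factor
#' \eqn{\psi_i} from [sample_speed_factor()] and a sensitivity factor
#' \eqn{\eta_i} from [sample_sensitivity_factor()]. Previous positions start
#' equal to the positions, so the first white-matter step direction is a
#' random sign.
#'
#' @param config a [simulation_config()] with `injection_center` set.
#' @param tissue a `tissue_field`.
#' @return An object of class `agent_population` with `pos`, `prev_pos`
#'   (`n x d` matrices), `speed_factor`, `sens_factor`, `arrived`
#'   (site index, 0 = not arrived) and `path_length_um`.
#' @export
initialize_population <- function(config, tissue) {
  stopifnot(inherits(config, "simulation_config"), inherits(tissue, "tissue_field"))
  d <- tissue$dim
  center <- config$injection_center
  if (is.null(center)) stop("config$injection_center must be set")
  if (length(center) != d) stop("injection_center dimensionality mismatch")
  sf <- sample_field_at(tissue, center)
  if (!sf$in_brain) stop("injection_center lies outside the brain mask")
  n <- config$n_agents
  r <- config$injection_radius
  pos <- matrix(rep(as.numeric(center), each = n), n, d)
  if (r > 0) {
    need <- seq_len(n)
    for (round in 1:200) {
      m <- length(need)
      if (!m) break
      u <- stats::runif(m)^(1 / d) * r
      prop <- matrix(center, m, d, byrow = TRUE) + u * random_unit_vector(m, d)
      ok <- sample_field_at(tissue, prop)$in_brain
      pos[need[ok], ] <- prop[ok, , drop = FALSE]
      need <- need[!ok]
    }
    if (length(need)) {
      stop("injection region is (almost) entirely outside the brain mask")
    }
  }
  structure(
    list(
      pos = pos,
      prev_pos = pos,
      speed_factor = sample_speed_factor(config$beta_w, n),
      sens_factor = sample_sensitivity_factor(config$alpha_c, n),
      arrived = integer(n),
      path_length_um = numeric(n)
    ),
    class = "agent_population"
  )
}

# Proposal step shared by migration_step() and run_simulation(): returns the
# tract-following / random-walk base displacement and the chemotaxis term
# separately (boundary handling recombines them).
#' @noRd
propose_displacement <- function(pos, prev, psi, eta, white, direction,
                                 chemo, config) {
  n <- nrow(pos)
  d <- ncol(pos)
  base <- matrix(0, n, d)
  if (any(white)) {
    ev <- direction[white, , drop = FALSE]
    ip <- rowSums((pos[white, , drop = FALSE] - prev[white, , drop = FALSE]) * ev)
    s <- sign(ip)
    tie <- s == 0
    if (any(tie)) s[tie] <- sample(c(-1, 1), sum(tie), replace = TRUE)
    base[white, ] <- (s * config$d_w * psi[white]) * ev
    if (config$wm_noise_sd > 0) {
      base[white, ] <- base[white, ] +
        matrix(stats::rnorm(sum(white) * d, sd = config$wm_noise_sd), ncol = d)
    }
  }
  grey <- !white
  if (any(grey)) {
    base[grey, ] <- config$d_g * random_unit_vector(sum(grey), d)
  }
  chem <- matrix(0, n, d)
  if (!is.null(chemo) && length(chemo$sites) && config$lambda_c > 0) {
    C <- concentration(chemo, pos)
    gate <- C >= config$epsilon_c
    if (any(gate)) {
      chem[gate, ] <- (config$lambda_c * eta[gate]) *
        chemo_gradient(chemo, pos[gate, , drop = FALSE])
    }
  }
  list(base = base, chem = chem)
}

#' One migration step (displacement proposal)
#'
#' The per-step update rule for one or more agents. On white matter the step
#' is \eqn{\pm d_w \psi_i M_{ev}(x)} with the sign chosen to be consistent
#' with the previous displacement (inertia: the sign of
#' \eqn{(x_i - x_{i-1}) \cdot M_{ev}}; an exactly-zero inner product draws a
#' random sign). On grey matter the step is \eqn{d_g \xi} with \eqn{\xi}
#' uniform on the unit circle/sphere. Wherever the chemoattractant
#' concentration satisfies \eqn{C(x) \ge \epsilon_c}, the chemotaxis term
#' \eqn{\lambda_c \eta_i \nabla C(x)} is added. Boundary handling is applied
#' by [run_simulation()], not here.
#'
#' @param pos,prev_pos current and previous positions (`n x d` or length-`d`).
#' @param psi,eta per-agent speed and sensitivity factors (recycled).
#' @param tissue a `tissue_field`.
#' @param chemo a [chemo_field()] or `NULL`.
#' @param config a [simulation_config()].
#' @return `n x d` matrix of displacements (pixels). Consumes RNG draws for
#'   grey-matter directions and sign ties.
#' @export
migration_step <- function(pos, prev_pos, psi, eta, tissue, chemo = NULL,
                           config = simulation_config()) {
  pos <- as_position_matrix(pos, tissue$dim)
  prev_pos <- as_position_matrix(prev_pos, tissue$dim)
  n <- nrow(pos)
  psi <- rep_len(psi, n)
  eta <- rep_len(eta, n)
  sf <- sample_field_at(tissue, pos)
  pr <- propose_displacement(pos, prev_pos, psi, eta, sf$is_white,
                             sf$direction, chemo, config)
  pr$base + pr$chem
}

#' Run the migration simulation
#'
#' Seeds the RNG from `config$seed`, initialises the population and performs
#' `n_steps` synchronous updates of all agents (fixed index order). Proposed
#' positions leaving the brain mask are rejected: grey-matter steps redraw
#' their random direction up to 10 times, white-matter steps flip their sign
#' once, and an agent whose retries are exhausted stays in place for that
#' step. Agents entering a tumor arrival region are recorded on first entry
#' and, when `chemotaxis_absorb` is on, halt there. Identical
#' `(config, seed)` inputs give bit-identical records.
#'
#' @param config a [simulation_config()].
#' @param tissue a `tissue_field`.
#' @param chemo a [chemo_field()] or `NULL` for tumor-free runs.
#' @param verbose print progress every ~10% of steps.
#' @return An object of class `sim_record`: the `config` echo, position
#'   `snapshots` (array `n_snap x n_agents x d`) with `snapshot_steps` and
#'   per-snapshot white-matter flags `snapshot_wm`, a per-step metric
#'   `series` data frame (time, white-matter %, distance quartiles in um,
#'   cumulative arrivals per site), per-agent `arrival_step`, `arrival_site`,
#'   `arrival_path_um`, final `path_um`, the traits `psi` and `eta`, and
#'   geometry metadata (`injection_center`, `pixel_size`, `n_sites`).
#' @export
run_simulation <- function(config, tissue, chemo = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"), inherits(tissue, "tissue_field"))
  d <- tissue$dim
  if (!is.null(chemo)) {
    stopifnot(inherits(chemo, "chemo_field"))
    for (s in chemo$sites) {
      if (length(s$center) != d) stop("tumor site dimensionality mismatch")
    }
  }
  if (!is.null(config$injection_center) && length(config$injection_center) != d) {
    stop("injection_center dimensionality mismatch")
  }

  set.seed(config$seed)
  pop <- initialize_population(config, tissue)
  n <- config$n_agents
  ps <- tissue$pixel_size
  shape <- tissue$shape
  wm <- as.vector(tissue$wm_mask)
  brain <- as.vector(tissue$brain_mask)
  dirm <- matrix(tissue$direction, ncol = d)
  nst <- config$n_steps
  nsites <- if (is.null(chemo)) 0L else length(chemo$sites)

  stride <- config$snapshot_stride %||% max(1L, nst %/% 100L)
  snap_steps <- unique(c(0L, seq.int(stride, nst, by = stride), nst))
  nsnap <- length(snap_steps)
  snaps <- array(NA_real_, c(nsnap, n, d))
  snap_wm <- matrix(FALSE, nsnap, n)

  pos <- pop$pos
  prev <- pop$prev_pos
  psi <- pop$speed_factor
  eta <- pop$sens_factor
  path <- numeric(n)
  arrived_site <- integer(n)
  arrival_step <- rep(NA_integer_, n)
  arrival_path <- rep(NA_real_, n)
  frozen <- logical(n)

  wm_pct <- numeric(nst + 1L)
  dmed <- numeric(nst + 1L)
  dq1 <- numeric(nst + 1L)
  dq3 <- numeric(nst + 1L)
  arr_counts <- matrix(0L, nst + 1L, max(nsites, 1L))

  inj <- as.numeric(config$injection_center)

  lookup <- function(p) {
    vox <- nearest_voxel(p)
    ok <- voxel_in_bounds(vox, shape)
    fl <- rep(NA_real_, nrow(p))
    fl[ok] <- flat_index(vox[ok, , drop = FALSE], shape)
    list(ok = ok, fl = fl)
  }
  in_brain_at <- function(p) {
    lk <- lookup(p)
    inb <- lk$ok
    inb[lk$ok] <- brain[lk$fl[lk$ok]]
    inb
  }
  record_arrivals <- function(step) {
    if (!nsites) return(invisible())
    cand <- which(arrived_site == 0L)
    if (!length(cand)) return(invisible())
    ht <- in_tumor(chemo, pos[cand, , drop = FALSE], ps)
    hit <- which(rowSums(ht) > 0)
    if (length(hit)) {
      ids <- cand[hit]
      arrived_site[ids] <<- max.col(ht[hit, , drop = FALSE], ties.method = "first")
      arrival_step[ids] <<- step
      arrival_path[ids] <<- path[ids]
      if (config$chemotaxis_absorb) frozen[ids] <<- TRUE
    }
    invisible()
  }
  record_series <- function(step) {
    i <- step + 1L
    fl <- flat_index(nearest_voxel(pos), shape)
    wm_pct[i] <<- 100 * mean(wm[fl])
    dum <- row_norms(pos - matrix(inj, n, d, byrow = TRUE)) * ps
    qs <- stats::quantile(dum, c(0.25, 0.5, 0.75), names = FALSE)
    dq1[i] <<- qs[1]; dmed[i] <<- qs[2]; dq3[i] <<- qs[3]
    if (nsites) arr_counts[i, ] <<- tabulate(arrived_site, nsites)
    invisible(fl)
  }

  record_arrivals(0L)
  fl0 <- record_series(0L)
  snaps[1L, , ] <- pos
  snap_wm[1L, ] <- wm[fl0]
  snap_i <- 2L

  progress_every <- max(1L, nst %/% 10L)
  for (st in seq_len(nst)) {
    act <- which(!frozen)
    if (length(act)) {
      pa <- pos[act, , drop = FALSE]
      pv <- prev[act, , drop = FALSE]
      fl <- flat_index(nearest_voxel(pa), shape)
      white <- wm[fl]
      pr <- propose_displacement(pa, pv, psi[act], eta[act], white,
                                 dirm[fl, , drop = FALSE], chemo, config)
      disp <- pr$base + pr$chem
      newp <- pa + disp
      ok <- in_brain_at(newp)
      if (!all(ok)) {
        badw <- which(!ok & white)
        if (length(badw)) {
          alt <- -pr$base[badw, , drop = FALSE] + pr$chem[badw, , drop = FALSE]
          np2 <- pa[badw, , drop = FALSE] + alt
          ok2 <- in_brain_at(np2)
          fix <- badw[ok2]
          disp[fix, ] <- alt[ok2, , drop = FALSE]
          newp[fix, ] <- np2[ok2, , drop = FALSE]
          stay <- badw[!ok2]
          disp[stay, ] <- 0
          newp[stay, ] <- pa[stay, , drop = FALSE]
        }
        rem <- which(!ok & !white)
        tries <- 0L
        while (length(rem) && tries < 10L) {
          tries <- tries + 1L
          dd <- config$d_g * random_unit_vector(length(rem), d) +
            pr$chem[rem, , drop = FALSE]
          np2 <- pa[rem, , drop = FALSE] + dd
          ok2 <- in_brain_at(np2)
          fix <- rem[ok2]
          disp[fix, ] <- dd[ok2, , drop = FALSE]
          newp[fix, ] <- np2[ok2, , drop = FALSE]
          rem <- rem[!ok2]
        }
        if (length(rem)) {
          disp[rem, ] <- 0
          newp[rem, ] <- pa[rem, , drop = FALSE]
        }
      }
      prev[act, ] <- pa
      pos[act, ] <- newp
      path[act] <- path[act] + row_norms(disp) * ps
    }
    record_arrivals(st)
    fl <- record_series(st)
    if (snap_i <= nsnap && st == snap_steps[snap_i]) {
      snaps[snap_i, , ] <- pos
      snap_wm[snap_i, ] <- wm[fl]
      snap_i <- snap_i + 1L
    }
    if (verbose && st %% progress_every == 0L) {
      message(sprintf("step %d/%d: %.1f%% on white matter, %d arrived",
                      st, nst, wm_pct[st + 1L], sum(arrived_site > 0L)))
    }
  }

  series <- data.frame(
    step = 0:nst,
    time_days = (0:nst) * config$dt,
    wm_pct = wm_pct,
    dist_q1_um = dq1,
    dist_median_um = dmed,
    dist_q3_um = dq3
  )
  if (nsites) {
    for (i in seq_len(nsites)) {
      series[[paste0("arrival_pct_site", i)]] <- 100 * arr_counts[, i] / n
    }
  }

  structure(
    list(
      config = config,
      seed = config$seed,
      pixel_size = ps,
      injection_center = inj,
      dim = d,
      n_agents = n,
      n_sites = nsites,
      snapshots = snaps,
      snapshot_steps = snap_steps,
      snapshot_wm = snap_wm,
      series = series,
      arrival_step = arrival_step,
      arrival_site = arrived_site,
      arrival_path_um = arrival_path,
      path_um = path,
      psi = psi,
      eta = eta,
      final_pos = pos
    ),
    class = "sim_record"
  )
}

#' @export
print.sim_record <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf(
    "<sim_record> %d agents, %d steps (%.3g days), %d tumor site(s)\n",
    x$n_agents, x$config$n_steps, max(x$series$time_days), x$n_sites
  ))
  cat(sprintf("  final: %.1f%% on white matter, median distance %.1f um\n",
              last$wm_pct, last$dist_median_um))
  if (x$n_sites > 0) {
    for (i in seq_len(x$n_sites)) {
      cat(sprintf("  arrival at site %d: %.1f%%\n", i,
                  last[[paste0("arrival_pct_site", i)]]))
    }
  }
  invisible(x)
}
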