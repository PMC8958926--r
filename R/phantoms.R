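# Synthetic tissue phantoms: intensity images whose structure-tensor
# analysis yields a connected high-anisotropy tract inside a low-anisotropy
# elliptical brain mask. Tracts are rendered as tubes carrying fine intensity
# banding ALONG the tract axis, so the smoothed gradient outer-products have
# their principal eigenvector parallel to the tract — the synthetic stand-in
# for a fiber direction field that real data would provide via DTI.

#' Phantom specification
#'
#' @param shape grid dimensions (length 2 or 3); tract kinds require at least
#'   32 pixels per axis.
#' @param kind one of `"uniform_grey"`, `"straight_tract"`, `"curved_tract"`,
#'   `"two_tract_cross"`.
#' @param tract_width Gaussian half-width (sd, pixels) of the tract tube;
#'   default 2, giving a classified white-matter band a few pixels wide —
#'   the scale of fiber bundles at the resolution of the published atlases.
#' @param contrast amplitude of the tract banding relative to the constant
#'   background intensity 0.5.
#' @param noise_sd sd of additive Gaussian intensity noise. Tract phantoms
#'   default to 0.02: coherence is scale-invariant, so a perfectly flat
#'   background would let arbitrarily faint smoothing leakage from the tract
#'   classify as white matter, whereas a weak isotropic texture (as any real
#'   image has) keeps the background below threshold. `uniform_grey`
#'   defaults to 0 (exactly zero anisotropy).
#' @param band_period spatial period (pixels) of the along-tract banding.
#' @param gap_period,gap_width straight tracts are interrupted by grey gaps
#'   of `gap_width` pixels every `gap_period` pixels (defaults 60 and 18),
#'   emulating tracts that pass through grey structures; on a gap-free
#'   straight tract an agent that reaches it can never leave, which no real
#'   anisotropy map produces. The gap must be wider than the tensor-smoothing
#'   kernel, or coherent signal smears across it and the gap still classifies
#'   as white matter. `gap_period = Inf` renders a solid tract. Ignored by
#'   `curved_tract` (curvature provides turnover).
#' @param brain_axes semi-axes of the elliptical/ellipsoidal brain mask;
#'   default `0.45 * shape`.
#' @param pixel_size um per pixel; default 10 (2-D) or 13.5 (3-D).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape,
                         kind = c("straight_tract", "uniform_grey",
                                  "curved_tract", "two_tract_cross"),
                         tract_width = 2, contrast = 1, noise_sd = NULL,
                         band_period = 6, gap_period = 60, gap_width = 18,
                         brain_axes = NULL, pixel_size = NULL) {
  kind <- match.arg(kind)
  if (is.null(noise_sd)) noise_sd <- if (kind == "uniform_grey") 0 else 0.02
  d <- length(shape)
  if (!d %in% 2:3) stop("shape must have 2 or 3 dimensions")
  if (kind != "uniform_grey" && any(shape < 32)) {
    stop("tract phantoms require shape >= 32 per axis")
  }
  if (is.null(brain_axes)) brain_axes <- 0.45 * shape
  if (2 * tract_width > min(brain_axes)) {
    stop("tract is wider than the brain mask")
  }
  if (is.null(pixel_size)) pixel_size <- if (d == 2L) 10 else 13.5
  structure(
    list(shape = as.integer(shape), kind = kind, tract_width = tract_width,
         contrast = contrast, noise_sd = noise_sd, band_period = band_period,
         gap_period = gap_period, gap_width = gap_width,
         brain_axes = brain_axes, pixel_size = pixel_size),
    class = "phantom_spec"
  )
}

#' @noRd
coord_grids <- function(shape) {
  d <- length(shape)
  if (d == 2L) {
    list(
      x = matrix(seq_len(shape[1]), shape[1], shape[2]),
      y = matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    )
  } else {
    x <- array(seq_len(shape[1]), shape)
    y <- array(rep(seq_len(shape[2]), each = shape[1]), shape)
    z <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
    list(x = x, y = y, z = z)
  }
}

#' @noRd
ellipse_mask <- function(shape, axes) {
  g <- coord_grids(shape)
  ctr <- (shape + 1) / 2
  r2 <- ((g$x - ctr[1]) / axes[1])^2 + ((g$y - ctr[2]) / axes[2])^2
  if (length(shape) == 3L) r2 <- r2 + ((g$z - ctr[3]) / axes[3])^2
  r2 <= 1
}

# Geometry shared by the phantoms and the packaged scenarios.
#' @noRd
phantom_geometry <- function(spec) {
  shape <- spec$shape
  ctr <- (shape + 1) / 2
  axes <- spec$brain_axes
  list(
    ctr = ctr, axes = axes,
    # straight tracts span the whole mask (as major tracts span the brain),
    # so agents reflect off the brain boundary instead of spilling out of
    # free tract ends; the end taper falls outside the mask
    half_length = axes[1],
    arc_radius = 0.45 * min(axes[1:2]),
    arc_center = ctr - c(0, 0.25 * axes[2], if (length(shape) == 3L) 0),
    arc_half_angle = 70 * pi / 180
  )
}

# Gap envelope along a straight tract: exactly zero within half a gap width
# of each gap centre (gap centres at ctr + (k + 1/2) * gap_period), ramping
# quadratically back to 1 over 3 px. Inside a gap the image is pure
# background texture, so the voxels classify as grey matter.
#' @noRd
gap_envelope <- function(axis_coord, ctr, gap_period, gap_width) {
  if (!is.finite(gap_period)) return(1)
  u <- (axis_coord - ctr) / gap_period - 0.5
  dgap <- abs(u - round(u)) * gap_period
  pmin(pmax((dgap - gap_width / 2) / 3, 0), 1)^2
}

# Along-tract end taper, shifted and truncated to exactly zero (see
# tube_profile for why the tails must vanish identically).
#' @noRd
tract_window <- function(excess, taper = 3) {
  cut <- 3 * taper
  floorv <- exp(-cut^2 / (2 * taper^2))
  pmax(exp(-pmin(pmax(excess, 0), cut)^2 / (2 * taper^2)) - floorv, 0) /
    (1 - floorv)
}

# Cross-tract profile: Gaussian shifted and truncated to reach exactly zero
# at 4 half-widths. Coherence is scale-invariant, so an untruncated Gaussian
# tail would classify as white matter arbitrarily far from the tract; the
# shifted truncation makes the background tensor exactly zero while keeping
# the profile (and hence the banding gradient) continuous at the cutoff.
#' @noRd
tube_profile <- function(perp2, width) {
  cut2 <- (4 * width)^2
  floorv <- exp(-cut2 / (2 * width^2))
  pmax(exp(-pmin(perp2, cut2) / (2 * width^2)) - floorv, 0) / (1 - floorv)
}

#' @noRd
render_straight <- function(spec, g, geo, along = 1L, center_perp = NULL,
                            half_length = NULL) {
  shape <- spec$shape
  ctr <- geo$ctr
  axis_coord <- if (along == 1L) g$x else g$y
  cp <- center_perp %||% ctr[if (along == 1L) 2L else 1L]
  perp2 <- if (along == 1L) (g$y - cp)^2 else (g$x - cp)^2
  if (length(shape) == 3L) perp2 <- perp2 + (g$z - ctr[3])^2
  hl <- half_length %||% if (along == 1L) geo$half_length else 0.38 * geo$axes[2]
  prof <- tube_profile(perp2, spec$tract_width)
  win <- tract_window(abs(axis_coord - ctr[along]) - hl)
  env <- gap_envelope(axis_coord, ctr[along], spec$gap_period, spec$gap_width)
  spec$contrast * prof * win * env * sin(2 * pi * axis_coord / spec$band_period)
}


#' @noRd
render_curved <- function(spec, g, geo) {
  shape <- spec$shape
  o <- geo$arc_center
  R <- geo$arc_radius
  dx <- g$x - o[1]
  dy <- g$y - o[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dx, dy)                 # 0 at the top of the arc
  tube2 <- (r - R)^2
  if (length(shape) == 3L) tube2 <- tube2 + (g$z - o[3])^2
  prof <- tube_profile(tube2, spec$tract_width)
  win <- tract_window((abs(theta) - geo$arc_half_angle) * R)
  spec$contrast * prof * win * sin(2 * pi * R * theta / spec$band_period)
}

# Centerline sample points for verification / tests (interior, tapers excluded).
#' @noRd
phantom_centerline <- function(spec, n = 40) {
  geo <- phantom_geometry(spec)
  d <- length(spec$shape)
  zc <- if (d == 3L) geo$ctr[3] else NULL
  if (spec$kind == "straight_tract") {
    hl <- 0.85 * geo$half_length  # stay inside the mask
    xs <- seq(geo$ctr[1] - hl, geo$ctr[1] + hl, length.out = n)
    xs <- xs[gap_envelope(xs, geo$ctr[1], spec$gap_period,
                          spec$gap_width + 4) >= 1]  # skip gap zones
    pts <- cbind(xs, geo$ctr[2], zc)
    tang <- matrix(rep(c(1, 0, if (d == 3L) 0), each = length(xs)),
                   length(xs), d)
  } else if (spec$kind == "curved_tract") {
    th <- seq(-geo$arc_half_angle + 0.15, geo$arc_half_angle - 0.15,
              length.out = n)
    pts <- cbind(geo$arc_center[1] + geo$arc_radius * sin(th),
                 geo$arc_center[2] + geo$arc_radius * cos(th), zc)
    tang <- cbind(cos(th), -sin(th), if (d == 3L) rep(0, n))
  } else if (spec$kind == "two_tract_cross") {
    hl <- 0.85 * geo$half_length
    xs <- seq(geo$ctr[1] - hl, geo$ctr[1] + hl, length.out = n)
    keep <- abs(xs - geo$ctr[1]) > 3 * spec$tract_width &  # skip the crossing
      gap_envelope(xs, geo$ctr[1], spec$gap_period, spec$gap_width + 4) >= 1
    pts <- cbind(xs[keep], geo$ctr[2], zc)
    tang <- matrix(rep(c(1, 0, if (d == 3L) 0), each = sum(keep)), sum(keep), d)
  } else {
    return(NULL)
  }
  list(points = pts, tangent = tang)
}

#' Generate a synthetic tissue phantom
#'
#' Renders the phantom described by `spec` as an intensity image (constant
#' background 0.5 inside an elliptical brain mask; tract tubes carry
#' sinusoidal banding along their axis) and verifies post-generation that
#' structure-tensor analysis classifies the tract centerline as white matter
#' (anisotropy `>= epsilon_M`) and the background as grey matter. If the
#' check fails the phantom is regenerated with doubled contrast, up to three
#' times.
#'
#' @param spec a [phantom_spec()].
#' @param epsilon_M,smoothing_sigma classification settings used for the
#'   verification pass (defaults 0.4 and 2).
#' @param verify set `FALSE` to skip the verification pass.
#' @return An [image_volume()] with the ellipsoidal brain mask attached.
#' @export
make_phantom <- function(spec, epsilon_M = 0.4, smoothing_sigma = 2,
                         verify = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  for (attempt in 1:3) {
    img <- render_phantom(spec)
    if (!verify || spec$kind == "uniform_grey") return(img)
    tis <- classify_tissue(structure_tensor(img, smoothing_sigma), epsilon_M)
    cl <- phantom_centerline(spec)
    on_line <- sample_field_at(tis, cl$points)$is_white
    anis <- as.vector(tis$anisotropy)
    # background: in-mask voxels below threshold must dominate heavily
    bg_ok <- mean(anis[as.vector(img$brain_mask)] >= epsilon_M) < 0.25
    if (mean(on_line) >= 0.9 && bg_ok) return(img)
    spec$contrast <- spec$contrast * 2
  }
  stop("phantom verification failed: tract not separable from background")
}

#' @noRd
render_phantom <- function(spec) {
  shape <- spec$shape
  g <- coord_grids(shape)
  geo <- phantom_geometry(spec)
  img <- array(0.5, shape)
  img <- img + switch(spec$kind,
    uniform_grey = 0,
    straight_tract = render_straight(spec, g, geo, along = 1L),
    curved_tract = render_curved(spec, g, geo),
    two_tract_cross = render_straight(spec, g, geo, along = 1L) +
      render_straight(spec, g, geo, along = 2L)
  )
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd), shape)
  }
  image_volume(img, pixel_size = spec$pixel_size,
               brain_mask = ellipse_mask(shape, spec$brain_axes))
}

#' Direct-tensor phantom
#'
#' Builds the tensor field of a phantom analytically instead of going through
#' an intensity image: inside the tract tube the tensor is
#' \eqn{(1 - b)\,\hat t \hat t^T + b I} with tangent \eqn{\hat t} and
#' baseline `b = 0.05` (strongly anisotropic), elsewhere \eqn{b I}
#' (isotropic). Exercises the precomputed-tensor path of [tensor_field()].
#'
#' @param spec a [phantom_spec()] (tract kinds only).
#' @param baseline isotropic eigenvalue `b`; default 0.05.
#' @return A `tensor_field`.
#' @export
make_tensor_phantom <- function(spec, baseline = 0.05) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind == "uniform_grey") {
    stop("uniform_grey has no tract; use make_phantom()")
  }
  shape <- spec$shape
  d <- length(shape)
  g <- coord_grids(shape)
  geo <- phantom_geometry(spec)
  nvox <- prod(shape)
  tang <- matrix(0, nvox, d)
  inside <- rep(FALSE, nvox)

  add_straight <- function(along) {
    ctr <- geo$ctr
    axis_coord <- as.vector(if (along == 1L) g$x else g$y)
    perp2 <- as.vector(if (along == 1L) (g$y - ctr[2])^2 else (g$x - ctr[1])^2)
    if (d == 3L) perp2 <- perp2 + as.vector((g$z - ctr[3])^2)
    hl <- if (along == 1L) geo$half_length else 0.38 * geo$axes[2]
    sel <- perp2 <= (2 * spec$tract_width)^2 &
      abs(axis_coord - ctr[along]) <= hl & !inside
    tang[sel, along] <<- 1
    inside[sel] <<- TRUE
  }
  if (spec$kind %in% c("straight_tract", "two_tract_cross")) {
    add_straight(1L)
    if (spec$kind == "two_tract_cross") add_straight(2L)
  } else {
    o <- geo$arc_center
    R <- geo$arc_radius
    dx <- as.vector(g$x) - o[1]
    dy <- as.vector(g$y) - o[2]
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dx, dy)
    tube2 <- (r - R)^2
    if (d == 3L) tube2 <- tube2 + as.vector((g$z - o[3])^2)
    sel <- tube2 <= (2 * spec$tract_width)^2 & abs(theta) <= geo$arc_half_angle
    tang[sel, 1] <- cos(theta[sel])
    tang[sel, 2] <- -sin(theta[sel])
    inside <- sel
  }

  ncomp <- if (d == 2L) 3L else 6L
  comp <- matrix(0, nvox, ncomp)
  iso_idx <- if (d == 2L) c(1L, 3L) else c(1L, 4L, 6L)
  comp[, iso_idx] <- baseline
  w <- 1 - baseline
  if (d == 2L) {
    comp[inside, 1] <- comp[inside, 1] + w * tang[inside, 1]^2
    comp[inside, 2] <- w * tang[inside, 1] * tang[inside, 2]
    comp[inside, 3] <- comp[inside, 3] + w * tang[inside, 2]^2
  } else {
    comp[inside, 1] <- comp[inside, 1] + w * tang[inside, 1]^2
    comp[inside, 2] <- w * tang[inside, 1] * tang[inside, 2]
    comp[inside, 3] <- w * tang[inside, 1] * tang[inside, 3]
    comp[inside, 4] <- comp[inside, 4] + w * tang[inside, 2]^2
    comp[inside, 5] <- w * tang[inside, 2] * tang[inside, 3]
    comp[inside, 6] <- comp[inside, 6] + w * tang[inside, 3]^2
  }
  tensor_field(array(comp, c(shape, ncomp)),
               pixel_size = spec$pixel_size,
               brain_mask = ellipse_mask(shape, spec$brain_axes))
}

#' Packaged test scenarios
#'
#' Assembles a complete, reproducible scenario on a straight-tract phantom:
#' tissue field, chemoattractant field and simulation configuration. The
#' scenarios mirror the structure of the published three cases on a phantom:
#' `near_tumor` places one tumor just off the tract close to the injection
#' site, `far_tumor` places it off-tract far from the injection,
#' `bilateral_tumors` places two tumors on opposite sides of the tract, and
#' `no_tumor` is the tumor-free control. Two injection presets are provided:
#' `"on_tract"` (the intracerebral analogue, on the tract) and `"off_tract"`
#' (the intranasal analogue, in grey matter near the mask periphery).
#'
#' @param name scenario name.
#' @param dim 2 (default) or 3.
#' @param seed RNG seed stored in the configuration.
#' @param n_days simulated days (default 30; one step is 1/1000 day).
#' @param injection `"on_tract"` or `"off_tract"`.
#' @param n_agents number of cells; default 1000.
#' @param params named list of [simulation_config()] overrides.
#' @param shape grid dimensions; defaults to `c(320, 224)` in 2-D and
#'   `c(96, 72, 48)` in 3-D.
#' @return A list with elements `image` ([image_volume()]), `tissue`
#'   (`tissue_field`), `chemo` ([chemo_field()] or `NULL`), `config`
#'   ([simulation_config()]) and `config_raw` (the plain-list configuration,
#'   writable with [write_config()]).
#' @export
make_scenario <- function(name = c("near_tumor", "far_tumor",
                                   "bilateral_tumors", "no_tumor"),
                          dim = 2, seed = 1L, n_days = 30,
                          injection = c("on_tract", "off_tract"),
                          n_agents = 1000, params = list(), shape = NULL) {
  name <- match.arg(name)
  injection <- match.arg(injection)
  if (!dim %in% 2:3) stop("dim must be 2 or 3")
  if (is.null(shape)) shape <- if (dim == 2L) c(320L, 224L) else c(96L, 72L, 48L)
  pixel_size <- if (dim == 2L) 10 else 13.5
  spec <- phantom_spec(shape, "straight_tract", pixel_size = pixel_size)
  geo <- phantom_geometry(spec)
  ctr <- geo$ctr
  axes <- geo$axes
  ext_px <- 100 / pixel_size      # tumor half-width, px
  zpad <- function(v) c(v, if (dim == 3L) ctr[3])

  inj_center <- switch(injection,
    on_tract = zpad(c(ctr[1] - 0.28 * axes[1], ctr[2])),
    off_tract = zpad(c(ctr[1] - 0.56 * axes[1], ctr[2] - 0.42 * axes[2]))
  )
  tumor_centers <- switch(name,
    no_tumor = list(),
    near_tumor = list(zpad(c(ctr[1] - 0.28 * axes[1] + 2 * ext_px,
                             ctr[2] + 1.8 * ext_px))),
    far_tumor = list(zpad(c(ctr[1] + 0.55 * axes[1], ctr[2] - 0.52 * axes[2]))),
    bilateral_tumors = list(zpad(c(ctr[1], ctr[2] + 0.5 * axes[2])),
                            zpad(c(ctr[1], ctr[2] - 0.5 * axes[2])))
  )

  base_params <- list(
    d_w = 5, d_g = 0.5, lambda_c = 6, beta_w = 1, alpha_c = 1,
    epsilon_M = 0.4, epsilon_c = 0.05, dt = 1 / 1000,
    n_agents = n_agents, injection_radius = 5
  )
  base_params[names(params)] <- params

  raw <- list(
    seed = as.integer(seed),
    units = list(length = "pixels"),
    grid = list(pixel_size = pixel_size),
    phantom = list(kind = "straight_tract", shape = as.integer(shape),
                   tract_width = spec$tract_width, contrast = spec$contrast,
                   noise_sd = spec$noise_sd, band_period = spec$band_period,
                   gap_period = spec$gap_period, gap_width = spec$gap_width),
    smoothing_sigma = 2,
    tumors = lapply(tumor_centers, function(ct) {
      list(center = as.numeric(ct), p = 1,
           extent_um = c(100, 100, 400)[seq_len(dim)])
    }),
    injection = list(center = as.numeric(inj_center), radius = base_params$injection_radius),
    params = c(base_params[setdiff(names(base_params), c("n_agents", "injection_radius"))],
               list(n_days = n_days, n_agents = n_agents))
  )
  cfg <- resolve_config(raw)
  out <- build_scenario(cfg)
  out$config_raw <- cfg
  out
}
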