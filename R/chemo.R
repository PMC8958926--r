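#' Tumor site for the chemoattractant field
#'
#' A tumor secretes urokinase plasminogen activator (uPA) whose concentration
#' decays from the tumor centre as
#' \deqn{C(x) = \left(1 + \frac{(x-x_c)^2}{\sigma_x^2} +
#'   \frac{(y-y_c)^2}{\sigma_y^2} + \frac{(z-z_c)^2}{\sigma_z^2}\right)^{-p},}
#' so \eqn{C = 1} at the centre. \eqn{\sigma} is the per-axis decay length
#' (at \eqn{p = 1} it is the distance at which the concentration halves) and
#' `p` sets how gradually the concentration decays. The arrival region is an
#' axis-aligned box of half-widths `extent_um` around the centre (a disc of
#' radius `extent_um[1]` in 2-D).
#'
#' @param center tumor centre, length 2 or 3, in pixels.
#' @param half_decay per-axis decay lengths \eqn{\sigma} in pixels (recycled
#'   to the dimensionality). Default: twice the extent, in pixels, resolved
#'   by [chemo_field()] when left `NULL`.
#' @param decay_power decay exponent `p > 0`; default 1.
#' @param extent_um arrival-region half-widths in micrometres; default
#'   `c(100, 100, 400)` (a 200 x 200 x 800 um box).
#' @return An object of class `tumor_site`.
#' @export
tumor_site <- function(center, half_decay = NULL, decay_power = 1,
                       extent_um = NULL) {
  d <- length(center)
  if (!d %in% 2:3) stop("tumor center must have 2 or 3 coordinates")
  if (is.null(extent_um)) extent_um <- c(100, 100, 400)[seq_len(d)]
  extent_um <- rep_len(extent_um, d)
  if (any(extent_um <= 0)) stop("tumor extents must be positive")
  if (decay_power <= 0) stop("decay_power must be positive")
  if (!is.null(half_decay)) {
    half_decay <- rep_len(half_decay, d)
    if (any(half_decay <= 0)) stop("half_decay lengths must be positive")
  }
  structure(
    list(center = as.numeric(center), half_decay = half_decay,
         decay_power = decay_power, extent_um = extent_um),
    class = "tumor_site"
  )
}

#' Chemoattractant field over one or more tumor sites
#'
#' Concentrations (and gradients) of multiple sites are summed — secretion is
#' treated as additive; `combine = "max"` takes the per-site maximum instead.
#' The field is static in time: uPA diffusion is assumed much slower than NSC
#' migration. Agents sense the field only where `C >= epsilon_c`.
#'
#' @param sites list of [tumor_site()] objects (possibly empty).
#' @param epsilon_c detection threshold on the concentration, in `(0, 1)`.
#' @param pixel_size um per pixel, used to resolve default decay lengths
#'   (`2 * extent_um / pixel_size`) and arrival boxes.
#' @param combine `"sum"` (default) or `"max"`.
#' @return An object of class `chemo_field`.
#' @export
chemo_field <- function(sites = list(), epsilon_c = 0.05, pixel_size = 1,
                        combine = c("sum", "max")) {
  combine <- match.arg(combine)
  if (inherits(sites, "tumor_site")) sites <- list(sites)
  if (!all(vapply(sites, inherits, TRUE, "tumor_site"))) {
    stop("sites must be a list of tumor_site objects")
  }
  if (epsilon_c <= 0 || epsilon_c >= 1) stop("epsilon_c must be in (0, 1)")
  sites <- lapply(sites, function(s) {
    if (is.null(s$half_decay)) {
      s$half_decay <- 2 * s$extent_um[seq_along(s$center)] / pixel_size
    }
    s
  })
  structure(
    list(sites = sites, epsilon_c = epsilon_c, pixel_size = pixel_size,
         combine = combine),
    class = "chemo_field"
  )
}

#' @export
print.chemo_field <- function(x, ...) {
  cat(sprintf("<chemo_field> %d site(s), epsilon_c = %.3g, combine = %s\n",
              length(x$sites), x$epsilon_c, x$combine))
  invisible(x)
}

#' @noRd
site_u <- function(site, pos) {
  u <- rep(1, nrow(pos))
  for (k in seq_along(site$center)) {
    u <- u + ((pos[, k] - site$center[k]) / site$half_decay[k])^2
  }
  u
}

#' uPA concentration at positions
#'
#' @param cf a [chemo_field()].
#' @param pos length-`d` position or `n x d` matrix, in pixels.
#' @return Numeric vector of concentrations (0 when the field has no sites).
#' @export
concentration <- function(cf, pos) {
  stopifnot(inherits(cf, "chemo_field"))
  pos <- as_position_matrix(pos)
  if (!length(cf$sites)) return(numeric(nrow(pos)))
  per <- vapply(cf$sites, function(s) site_u(s, pos)^(-s$decay_power),
                numeric(nrow(pos)))
  per <- matrix(per, nrow = nrow(pos))
  if (cf$combine == "sum") rowSums(per) else apply(per, 1L, max)
}

#' Analytic gradient of the uPA concentration
#'
#' \eqn{\partial C / \partial x_k = -2 p\, u^{-p-1} (x_k - c_k) / \sigma_k^2}
#' per site, combined like the concentrations. The gradient always points
#' toward the (nearest) tumor centre.
#'
#' @inheritParams concentration
#' @return `n x d` matrix of gradient vectors.
#' @export
chemo_gradient <- function(cf, pos) {
  stopifnot(inherits(cf, "chemo_field"))
  pos <- as_position_matrix(pos)
  d <- ncol(pos)
  g <- matrix(0, nrow(pos), d)
  if (!length(cf$sites)) return(g)
  if (cf$combine == "max") {
    per <- vapply(cf$sites, function(s) site_u(s, pos)^(-s$decay_power),
                  numeric(nrow(pos)))
    per <- matrix(per, nrow = nrow(pos))
    which_site <- max.col(per, ties.method = "first")
  }
  for (i in seq_along(cf$sites)) {
    s <- cf$sites[[i]]
    u <- site_u(s, pos)
    fac <- -2 * s$decay_power * u^(-s$decay_power - 1)
    gi <- matrix(0, nrow(pos), d)
    for (k in seq_len(d)) {
      gi[, k] <- fac * (pos[, k] - s$center[k]) / s$half_decay[k]^2
    }
    if (cf$combine == "sum") {
      g <- g + gi
    } else {
      sel <- which_site == i
      g[sel, ] <- gi[sel, , drop = FALSE]
    }
  }
  g
}

#' Arrival test: is a position inside a tumor region?
#'
#' In 3-D the arrival region of a site is the closed axis-aligned box of
#' half-widths `extent_um` (in micrometres) around its centre; in 2-D it is
#' the closed disc of radius `extent_um[1]`.
#'
#' @inheritParams concentration
#' @param pixel_size um per pixel, to convert pixel offsets to micrometres.
#' @return `n x n_sites` logical matrix (zero columns when there are no sites).
#' @export
in_tumor <- function(cf, pos, pixel_size = cf$pixel_size) {
  stopifnot(inherits(cf, "chemo_field"))
  pos <- as_position_matrix(pos)
  d <- ncol(pos)
  out <- matrix(FALSE, nrow(pos), length(cf$sites))
  for (i in seq_along(cf$sites)) {
    s <- cf$sites[[i]]
    off <- sweep(pos, 2L, s$center[seq_len(d)]) * pixel_size
    if (d == 2L) {
      out[, i] <- row_norms(off) <= s$extent_um[1]
    } else {
      inside <- rep(TRUE, nrow(pos))
      for (k in seq_len(d)) inside <- inside & abs(off[, k]) <= s$extent_um[k]
      out[, i] <- inside
    }
  }
  out
}
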