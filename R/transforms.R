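#' 2D rigid transforms
#'
#' A rigid transform maps a point `p` (an `(x, y)` pair) to
#' `R(theta) %*% (p - center) + center + t`, i.e. rotation by `theta` degrees
#' about `center` followed by translation `t`. Units follow the coordinates
#' they are applied to (pixels or micrometres).
#'
#' @param theta_deg Rotation angle in degrees (counter-clockwise).
#' @param tx,ty Translation.
#' @param center Length-2 rotation center (default origin).
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(theta_deg = 0, tx = 0, ty = 0, center = c(0, 0)) {
  structure(list(theta_deg = theta_deg, t = c(tx, ty),
                 center = as.numeric(center)),
            class = "rigid2d")
}

rot2 <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param rt A `rigid2d`.
#' @param xy Numeric matrix (or length-2 vector) of `(x, y)` points, one row
#'   per point.
#' @return Transformed points, same shape as `xy`.
#' @export
rigid_apply <- function(rt, xy) {
  v <- is.null(dim(xy))
  xy <- matrix(as.numeric(xy), ncol = 2)
  R <- rot2(rt$theta_deg)
  out <- sweep(tcrossprod(sweep(xy, 2, rt$center), R), 2,
               rt$center + rt$t, "+")
  if (v) drop(out) else out
}

#' Invert a rigid transform
#' @param rt A `rigid2d`.
#' @return The inverse `rigid2d` (same rotation center).
#' @export
rigid_invert <- function(rt) {
  R <- rot2(-rt$theta_deg)
  # p = R'(q - c - t) + c  ->  rotation -theta about c, translation -R' t
  t_new <- drop(R %*% (-rt$t))
  rigid2d(-rt$theta_deg, t_new[1], t_new[2], center = rt$center)
}

#' Compose rigid transforms
#'
#' `rigid_compose(a, b)` returns the transform applying `b` first, then `a`.
#' The result is expressed about `a`'s rotation center.
#'
#' @param a,b `rigid2d` objects.
#' @return A `rigid2d` equal to `a %after% b`.
#' @export
rigid_compose <- function(a, b) {
  theta <- a$theta_deg + b$theta_deg
  c_a <- a$center
  # action on p: a(b(p)); express as rotation theta about c_a + translation t
  Rb <- rot2(b$theta_deg); Ra <- rot2(a$theta_deg); Rab <- rot2(theta)
  # b(p) = Rb (p - cb) + cb + tb ; a(q) = Ra (q - ca) + ca + ta
  # a(b(p)) = Ra Rb p + [Ra (cb - Rb cb + tb - ca) + ca + ta]
  const <- drop(Ra %*% (b$center - Rb %*% b$center + b$t - c_a)) + c_a + a$t
  # match constants of Rab(p - ca) + ca + t  ==  Rab p + const
  t_new <- const - c_a + drop(Rab %*% c_a)
  rigid2d(theta, t_new[1], t_new[2], center = c_a)
}

#' Smooth planar deformation fields
#'
#' A band-limited displacement field built from sinusoidal components,
#' used to emulate sectioning distortions with a known ground truth. The
#' displacement at `(x, y)` is
#' `amp * c(sin(2*pi*(x*kx1 + y*ky1) + phase1), sin(2*pi*(x*kx2 + y*ky2) + phase2))`.
#'
#' @param amplitude Peak displacement (same units as coordinates).
#' @param period Spatial period of the field.
#' @param seed Seed fixing directions and phases.
#' @return An object of class `smooth_field`.
#' @export
smooth_field <- function(amplitude = 5, period = 1500, seed = 1) {
  par <- with_seed(seed, {
    ang <- stats::runif(2, 0, 2 * pi)
    ph <- stats::runif(2, 0, 2 * pi)
    list(ang = ang, ph = ph)
  })
  structure(list(amplitude = amplitude, period = period,
                 ang = par$ang, phase = par$ph),
            class = "smooth_field")
}

#' Evaluate a smooth deformation field
#' @param field A `smooth_field`.
#' @param xy Points, one `(x, y)` row per point.
#' @return Matrix of displacements, same shape as `xy`.
#' @export
field_displacement <- function(field, xy) {
  v <- is.null(dim(xy))
  xy <- matrix(as.numeric(xy), ncol = 2)
  k <- 1 / field$period
  u <- field$amplitude *
    sin(2 * pi * k * (xy[, 1] * cos(field$ang[1]) + xy[, 2] * sin(field$ang[1])) +
          field$phase[1])
  w <- field$amplitude *
    sin(2 * pi * k * (xy[, 1] * cos(field$ang[2]) + xy[, 2] * sin(field$ang[2])) +
          field$phase[2])
  out <- cbind(u, w)
  if (v) drop(out) else out
}

#' Apply a known rigid-plus-smooth deformation to coordinates
#'
#' Models a sectioning distortion: points are first moved rigidly, then a
#' smooth residual displacement (evaluated in the deformed frame) is added:
#' `y = rigid(x) + disp(rigid(x))`. The returned object carries a numerically
#' exact inverse (fixed-point iteration), so ground-truth coordinates can be
#' recovered from deformed ones.
#'
#' @param xy Point coordinates, one `(x, y)` row per point.
#' @param rigid A `rigid2d` (identity if `NULL`).
#' @param field A `smooth_field` (zero field if `NULL`).
#' @param max_displacement Guard: error if any total displacement exceeds
#'   this value (`Inf` to disable).
#' @return A list with `deformed` coordinates, the `rigid` and `field` used,
#'   and functions `forward(xy)` / `inverse(xy)`.
#' @export
apply_known_deformation <- function(xy, rigid = NULL, field = NULL,
                                    max_displacement = Inf) {
  rigid <- rigid %||% rigid2d()
  forward <- function(p) {
    q <- rigid_apply(rigid, p)
    if (!is.null(field)) q <- q + field_displacement(field, q)
    q
  }
  inverse <- function(q) {
    qm <- matrix(as.numeric(q), ncol = 2)
    z <- qm
    if (!is.null(field)) {
      for (i in seq_len(200)) {
        z_new <- qm - field_displacement(field, z)
        if (max(abs(z_new - z)) < 1e-12) { z <- z_new; break }
        z <- z_new
      }
    }
    out <- rigid_apply(rigid_invert(rigid), z)
    if (is.null(dim(q))) drop(out) else out
  }
  deformed <- forward(xy)
  disp <- sqrt(rowSums((matrix(deformed, ncol = 2) - matrix(xy, ncol = 2))^2))
  if (any(disp > max_displacement))
    stop_orfish("deformation displacement exceeds allowed maximum",
                class = "orfish_config_error")
  list(deformed = deformed, rigid = rigid, field = field,
       forward = forward, inverse = inverse)
}
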