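#' Channel geometry and the inlet direction convention
#'
#' Image coordinates have `x` rightward (columns) and `y` downward (rows); the
#' perfusion channel runs along `x`. `channel_geometry()` fixes the unit
#' vector \eqn{\hat n} pointing toward the channel inlet (default: inlet at
#' \eqn{-x}) and the total field area \eqn{A_{Total}} used for coverage.
#' Trajectory angles are measured from \eqn{\hat n}: 0 deg is flow straight
#' toward the inlet, 180 deg toward the outlet, and the sign of +/-90 deg
#' follows the right-handed perpendicular \eqn{\hat p = (-n_y, n_x)}.
#'
#' @param field_size_um numeric pair, field-of-view extent (x, y) in um.
#' @param inlet `"-x"`, `"+x"`, or a length-2 numeric direction vector
#'   (normalized internally; must be parallel to an axis of the channel).
#' @return A `channel_geometry` list with `n_hat`, `p_hat`, `field_size_um`,
#'   `area_um2`.
#' @export
channel_geometry <- function(field_size_um, inlet = "-x") {
  n_hat <- if (is.character(inlet)) {
    switch(inlet, "-x" = c(-1, 0), "+x" = c(1, 0),
           stopf("`inlet` must be \"-x\", \"+x\", or a direction vector"))
  } else {
    v <- as.numeric(inlet)
    if (length(v) != 2 || all(v == 0)) stopf("inlet vector must be a nonzero 2-vector")
    v / sqrt(sum(v^2))
  }
  structure(list(n_hat = n_hat, p_hat = c(-n_hat[2], n_hat[1]),
                 field_size_um = as.numeric(field_size_um),
                 area_um2 = prod(as.numeric(field_size_um))),
            class = "channel_geometry")
}

# Signed angle (deg, in (-180, 180]) of displacement (dx, dy) measured from
# the inlet direction n_hat. Vectorized over dx/dy.
angle_from_displacement <- function(dx, dy, geom) {
  along <- dx * geom$n_hat[1] + dy * geom$n_hat[2]
  perp <- dx * geom$p_hat[1] + dy * geom$p_hat[2]
  wrap_angle_deg(rad2deg(atan2(perp, along)))
}

# Unit vector in image coordinates for an angle (deg) measured from n_hat.
direction_to_vector <- function(theta_deg, geom) {
  th <- deg2rad(theta_deg)
  cbind(cos(th) * geom$n_hat[1] + sin(th) * geom$p_hat[1],
        cos(th) * geom$n_hat[2] + sin(th) * geom$p_hat[2])
}
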