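#' Tumor radius update
#'
#' One explicit time step of the tumor radius dynamics
#' \deqn{R_{t+1} = R_t + (g - k L)\,\Delta t,}
#' where `g` is the innate linear growth rate of the radius, `k` the killing
#' rate per tumor-infiltrating lymphocyte (TIL), and `L` the current TIL
#' count.  Growth is linear in the absence of an immune response and the net
#' change per step is negative exactly when `L > g / k` (133.33 cells at the
#' default parameters).  The radius is clamped at zero: a fully regressed
#' tumor does not regrow a negative radius.
#'
#' @param radius Current radius (um), >= 0.  Vectorised.
#' @param til_count Current number of TILs `L`, >= 0.
#' @param g Innate growth rate (um/min), default 0.2.
#' @param k Killing rate per TIL (um/min/cell), default 0.0015.
#' @param dt Time step (min), default 1.
#' @return Updated radius (um), `max(0, radius + (g - k * til_count) * dt)`.
#' @examples
#' update_radius(200, 0)            # 200.2
#' update_radius(200, 0.2 / 0.0015) # unchanged: kL = g
#' @export
update_radius <- function(radius, til_count, g = 0.2, k = 0.0015, dt = 1) {
  if (any(radius < 0)) abort("`radius` must be >= 0")
  if (any(til_count < 0)) abort("`til_count` must be >= 0")
  if (any(g < 0) || any(k < 0)) abort("`g` and `k` must be >= 0")
  if (any(dt <= 0)) abort("`dt` must be positive")
  pmax(0, radius + (g - k * til_count) * dt)
}

#' Is a point inside the tumor?
#'
#' Boundary-inclusive disc membership: a point exactly on the boundary
#' (distance equal to the radius) counts as inside, which is the convention
#' used for TIL conversion when an activated T cell crosses the boundary.
#'
#' @param x,y Query coordinates (um), vectorised.
#' @param radius Tumor radius (um).
#' @param center Numeric length-2 tumor centre.
#' @return Logical vector.
#' @export
tumor_contains <- function(x, y, radius, center = c(0, 0)) {
  stopifnot(length(x) == length(y), radius >= 0, length(center) == 2)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}
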