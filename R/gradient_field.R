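#' Chemokine gradient field from activated stromal sources
#'
#' Builds the chemoattractant field emitted by activated reticular fibroblast
#' cells (RFC).  Each activated RFC contributes a two-dimensional Gaussian
#' centred at the cell,
#' \deqn{c_i(p) = A_i \exp(-\lVert p - c_i \rVert^2 / (2\sigma_i^2)),}
#' and the total field is the sum over sources, so the signal strengthens as
#' more RFC are activated.  The Gaussian is peak-height normalised (value
#' \eqn{A_i} at the source), not unit-mass normalised.  A second,
#' tumor-centred inflammatory field is represented purely by direction (see
#' [tumor_direction()]); the tumor centre and radius are carried here for
#' that purpose.
#'
#' @param sources A data frame with columns `x`, `y` (source positions, um)
#'   and optionally `amplitude` (default 1) and `sigma` (um, default 200).
#'   May have zero rows.
#' @param tumor_center Numeric length-2, tumor centre (um).
#' @param tumor_radius Tumor radius (um), used by downstream plotting.
#' @return A `gradient_field` object.
#' @examples
#' f <- gradient_field(tibble::tibble(x = 2000, y = 0))
#' eln_concentration(f, 2000, 0)     # 1 at the source
#' eln_concentration(f, 2200, 0)     # exp(-1/2) one sigma away
#' @export
gradient_field <- function(sources = tibble(x = numeric(), y = numeric()),
                           tumor_center = c(0, 0), tumor_radius = 200) {
  stopifnot(is.data.frame(sources))
  sources <- as_tibble(sources)
  if (!all(c("x", "y") %in% names(sources))) {
    abort("`sources` needs columns x and y")
  }
  if (!"amplitude" %in% names(sources)) sources$amplitude <- 1
  if (!"sigma" %in% names(sources)) sources$sigma <- 200
  if (nrow(sources) > 0) {
    if (any(!is.finite(sources$x) | !is.finite(sources$y))) {
      abort("source positions must be finite")
    }
    if (any(sources$sigma <= 0)) abort("`sigma` must be positive")
    if (any(sources$amplitude < 0)) abort("`amplitude` must be >= 0")
  }
  stopifnot(length(tumor_center) == 2, is.finite(tumor_center),
            tumor_radius >= 0)
  structure(
    list(sources = sources, tumor_center = as.numeric(tumor_center),
         tumor_radius = as.numeric(tumor_radius)),
    class = "gradient_field"
  )
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("<gradient_field> ", nrow(x$sources), " Gaussian source(s), tumor at (",
      x$tumor_center[1], ", ", x$tumor_center[2], "), R = ", x$tumor_radius,
      " um\n", sep = "")
  invisible(x)
}

#' Evaluate the chemokine concentration of a field
#'
#' @param field A [gradient_field()].
#' @param x,y Query coordinates (um), vectorised.
#' @return Numeric vector of concentrations (dimensionless, >= 0; 0 when the
#'   field has no sources).
#' @export
eln_concentration <- function(field, x, y) {
  stopifnot(inherits(field, "gradient_field"), length(x) == length(y))
  s <- field$sources
  out <- numeric(length(x))
  for (i in seq_len(nrow(s))) {
    d2 <- (x - s$x[i])^2 + (y - s$y[i])^2
    out <- out + s$amplitude[i] * exp(-d2 / (2 * s$sigma[i]^2))
  }
  out
}

#' Analytic gradient of the chemokine field
#'
#' The gradient of the Gaussian sum, evaluated analytically:
#' \deqn{\nabla c(p) = \sum_i -\frac{A_i}{\sigma_i^2}
#'   e^{-\lVert p-c_i\rVert^2/(2\sigma_i^2)} (p - c_i).}
#' It vanishes at an isolated source centre and at the midpoint between two
#' equal sources, and always points toward increasing concentration.
#'
#' @inheritParams eln_concentration
#' @return A tibble with columns `gx`, `gy` (concentration per um).
#' @export
eln_gradient <- function(field, x, y) {
  stopifnot(inherits(field, "gradient_field"), length(x) == length(y))
  s <- field$sources
  gx <- numeric(length(x))
  gy <- numeric(length(x))
  for (i in seq_len(nrow(s))) {
    dx <- x - s$x[i]
    dy <- y - s$y[i]
    e <- s$amplitude[i] * exp(-(dx^2 + dy^2) / (2 * s$sigma[i]^2)) /
      s$sigma[i]^2
    gx <- gx - e * dx
    gy <- gy - e * dy
  }
  tibble(gx = gx, gy = gy)
}

#' Unit direction of the tumor-centred inflammatory field
#'
#' The tumor produces inflammatory chemokines that bias resting APC and
#' activated T cells toward its centre.  No functional form is attached to
#' this field: it acts through its direction only, the unit vector from a
#' point toward the tumor centre.  Negating the result gives the
#' "away from the tumor" direction used by antigen-loaded APC.  At the
#' singular point (the centre itself) the zero vector is returned: there is
#' no bias there.
#'
#' @param x,y Query coordinates (um), vectorised.
#' @param tumor_center Numeric length-2 centre.
#' @return A tibble with columns `dx`, `dy`, each row of norm 1 (or 0 at the
#'   centre).
#' @export
tumor_direction <- function(x, y, tumor_center = c(0, 0)) {
  stopifnot(length(x) == length(y), length(tumor_center) == 2)
  vx <- tumor_center[1] - x
  vy <- tumor_center[2] - y
  nrm <- sqrt(vx^2 + vy^2)
  zero <- nrm == 0
  nrm[zero] <- 1
  tibble(dx = ifelse(zero, 0, vx / nrm), dy = ifelse(zero, 0, vy / nrm))
}

#' Rasterise a gradient field for plotting or export
#'
#' @param field A [gradient_field()].
#' @param xlim,ylim Numeric length-2 ranges (um).
#' @param n Grid resolution per axis.
#' @param normalize Divide values by the grid maximum (a display convention
#'   only, useful for overlaying on agent snapshots).
#' @return A tibble with columns `x`, `y`, `value`.
#' @export
field_raster <- function(field, xlim, ylim, n = 101, normalize = FALSE) {
  stopifnot(inherits(field, "gradient_field"), n >= 2)
  gr <- tidyr::expand_grid(
    x = seq(xlim[1], xlim[2], length.out = n),
    y = seq(ylim[1], ylim[2], length.out = n)
  )
  gr$value <- eln_concentration(field, gr$x, gr$y)
  if (normalize && max(gr$value) > 0) gr$value <- gr$value / max(gr$value)
  gr
}
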