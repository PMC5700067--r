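#' One unbiased random-walk step
#'
#' Off-lattice random motility: each cell draws a displacement length
#' uniformly on `[0, kinetic_speed * dt]` and a direction uniformly on the
#' circle, so the expected step length is `kinetic_speed * dt / 2`.  Uses
#' R's global RNG stream (`set.seed()` makes it reproducible); the compiled
#' simulation engine applies the identical rule with its own seeded
#' generator.
#'
#' @param cells A data frame with columns `x`, `y` (um).
#' @param kinetic_speed Maximum speed (um/min).
#' @param dt Time step (min).
#' @return The input with updated `x`, `y`.
#' @examples
#' set.seed(1)
#' random_walk_step(tibble::tibble(x = 0, y = 0), kinetic_speed = 12, dt = 1)
#' @export
random_walk_step <- function(cells, kinetic_speed, dt = 1) {
  stopifnot(is.data.frame(cells), all(c("x", "y") %in% names(cells)))
  if (kinetic_speed < 0) abort("`kinetic_speed` must be >= 0")
  if (dt <= 0) abort("`dt` must be positive")
  n <- nrow(cells)
  len <- runif(n, 0, kinetic_speed * dt)
  ang <- runif(n, 0, 2 * pi)
  cells$x <- cells$x + len * cos(ang)
  cells$y <- cells$y + len * sin(ang)
  cells
}

#' One chemotactic (directed) step
#'
#' The directed component of a biased random walk: a second displacement of
#' length uniform on `[0, bias_scale * tactic_speed * dt]` along a fixed
#' unit direction (toward the chemokine source, i.e. up the gradient).  A
#' zero direction or zero bias produces no displacement.
#'
#' @param cells A data frame with columns `x`, `y`.
#' @param direction A data frame or matrix with per-cell components
#'   (`dx`, `dy`), each row a unit vector or zero.
#' @param tactic_speed Maximum chemotactic speed (um/min).
#' @param bias_scale Gradient-strength scaling in `[0, 1]`, recycled.
#' @param dt Time step (min).
#' @return The input with updated `x`, `y`.
#' @export
tactic_step <- function(cells, direction, tactic_speed, bias_scale = 1,
                        dt = 1) {
  stopifnot(is.data.frame(cells), all(c("x", "y") %in% names(cells)))
  direction <- as.data.frame(direction)
  if (ncol(direction) < 2) abort("`direction` needs two columns (dx, dy)")
  names(direction)[1:2] <- c("dx", "dy")
  if (tactic_speed < 0) abort("`tactic_speed` must be >= 0")
  if (any(bias_scale < 0 | bias_scale > 1)) {
    abort("`bias_scale` must lie in [0, 1]")
  }
  if (dt <= 0) abort("`dt` must be positive")
  nrm <- sqrt(direction$dx^2 + direction$dy^2)
  if (any(nrm > 0 & abs(nrm - 1) > 1e-8)) {
    abort("`direction` rows must be unit vectors or zero")
  }
  n <- nrow(cells)
  len <- runif(n) * bias_scale * tactic_speed * dt
  cells$x <- cells$x + len * direction$dx
  cells$y <- cells$y + len * direction$dy
  cells
}

#' Saturating gradient-strength bias
#'
#' Maps the local gradient magnitude to the `[0, 1]` bias applied to the
#' chemotactic speed: `|g| / (|g| + k_half)`, a Michaelis-Menten saturation
#' so the bias "scales with the strength of the gradient" but can never
#' exceed the configured chemotactic speed.
#'
#' @param gradient_magnitude Non-negative gradient magnitudes.
#' @param k_half Half-saturation constant (same units); see [sim_config()].
#' @return Values in `[0, 1)`.
#' @export
bias_scale <- function(gradient_magnitude, k_half) {
  if (any(gradient_magnitude < 0)) abort("gradient magnitude must be >= 0")
  if (k_half <= 0) abort("`k_half` must be positive")
  gradient_magnitude / (gradient_magnitude + k_half)
}

#' Apply one step of cell state transitions
#'
#' Applies all contact- and position-driven transitions once, in the fixed
#' documented order:
#' (a) APC^OFF inside the tumor loads antigen and becomes APC^M;
#' (c) an APC^M within the activation distance of a resting RFC activates
#' it; (b) each inactive T cell, in id order, is activated by the nearest
#' APC^M within range that still has capacity (ties to the lower id; one
#' activation per T cell per step; an APC^M is removed when its capacity is
#' exhausted); (d) activated T cells on or inside the tumor boundary become
#' TIL; (e) all ages advance by `dt`, and TILs older than the lifespan are
#' removed.  Cells have no spatial exclusion and may approach arbitrarily
#' closely; proximity is plain Euclidean distance.
#'
#' @param cells A tibble with columns `id`, `kind` (values among
#'   `r paste(elnsim:::.kind_levels, collapse = ", ")`), `x`, `y`, `age`
#'   (min), `activations` (APC^M bookkeeping; 0 elsewhere).
#' @param tumor_radius Current tumor radius `R` (um); `R <= 0` means no
#'   interior, so no conversions occur.
#' @param config A [sim_config()] (supplies the activation distance, APC^M
#'   capacity, TIL lifespan and `dt`).
#' @return A list with `cells` (updated tibble, removed cells dropped) and
#'   `events` (tibble with columns `event`, `id`).
#' @export
transition_cells <- function(cells, tumor_radius, config = sim_config()) {
  stopifnot(is.data.frame(cells))
  need <- c("id", "kind", "x", "y", "age", "activations")
  if (!all(need %in% names(cells))) {
    abort(paste0("`cells` needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cells$id)) abort("cell ids must be unique")
  is_rfc <- cells$kind %in% c("RFC_OFF", "RFC_ON")
  mot <- cells[!is_rfc, ]
  rfc <- cells[is_rfc, ]
  res <- cpp_transition_cells(
    as.integer(mot$id), kind_to_code(mot$kind),
    as.numeric(mot$x), as.numeric(mot$y), as.numeric(mot$age),
    as.integer(mot$activations),
    as.numeric(rfc$x), as.numeric(rfc$y), rfc$kind == "RFC_ON",
    as.numeric(tumor_radius), unclass(config)
  )
  out_mot <- as_tibble(res$agents) %>%
    mutate(kind = code_to_kind(.data$kind))
  out_rfc <- rfc %>%
    mutate(kind = dplyr::if_else(as.logical(res$rfc_on), "RFC_ON", "RFC_OFF"),
           age = .data$age + config$dt)
  ev <- res$events
  events <- bind_rows(
    tibble(event = "apc_antigen_loaded", id = as.integer(ev$apc_loaded)),
    tibble(event = "rfc_activated",
           id = as.integer(rfc$id[ev$rfc_activated])),
    tibble(event = "t_activated", id = as.integer(ev$t_activated)),
    tibble(event = "til_entered", id = as.integer(ev$til_entered)),
    tibble(event = "til_expired", id = as.integer(ev$til_expired)),
    tibble(event = "apc_m_removed", id = as.integer(ev$apc_m_removed))
  )
  list(
    cells = bind_rows(out_mot, out_rfc[names(out_mot)]),
    events = events
  )
}

#' Neighbour pairs within a radius
#'
#' All unordered pairs of points within `radius` of each other (boundary
#' inclusive), by a uniform spatial hash with cell size equal to the query
#' radius, or by brute-force all-pairs comparison.  The two methods return
#' identical pair sets; the brute-force route exists as the reference
#' implementation for verifying the hash.
#'
#' @param x,y Point coordinates.
#' @param radius Query radius (um), > 0.
#' @param method `"hash"` (default) or `"brute"`.
#' @return A tibble with columns `i`, `j` (1-based indices, `i < j`), sorted.
#' @export
neighbor_pairs <- function(x, y, radius, method = c("hash", "brute")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), radius > 0)
  m <- cpp_neighbor_pairs(as.numeric(x), as.numeric(y), radius, method)
  out <- tibble(i = m[, 1], j = m[, 2])
  arrange(out, .data$i, .data$j)
}
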