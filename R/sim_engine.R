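#' Initialise a simulation state
#'
#' Builds the time-zero state for a configuration: the tumor at the origin
#' with the initial radius; `rfc_count` resting RFC placed uniformly at
#' random in a disc of radius `rfc_patch_radius` centred
#' `tumor_eln_distance` um from the tumor centre (along the positive x
#' axis); and the initial APC^OFF and inactive T cells positioned by the
#' influx-annulus rule.  Deterministic given `config$seed`.  If the ELN
#' patch overlaps the initial tumor a warning (not an error) is issued.
#'
#' @param config A [sim_config()].
#' @return A list with `cells` (tibble: `id`, `kind`, `x`, `y`, `age`,
#'   `activations`; RFC rows carry ids after the motile cells), `radius`,
#'   and `config`.
#' @examples
#' st <- init_simulation(sim_config(rfc_count = 10, seed = 42))
#' table(st$cells$kind)
#' @export
init_simulation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tumor_eln_distance <
        config$initial_radius + config$rfc_patch_radius &&
        config$rfc_count > 0) {
    warn("ELN patch overlaps the initial tumor")
  }
  res <- cpp_init_simulation(unclass(config))
  agents <- as_tibble(res$agents) %>%
    mutate(kind = code_to_kind(.data$kind))
  rfc <- as_tibble(res$rfc)
  rfc_cells <- tibble(
    id = max(c(0L, agents$id)) + seq_len(nrow(rfc)),
    kind = dplyr::if_else(rfc$active, "RFC_ON", "RFC_OFF"),
    x = rfc$x, y = rfc$y, age = 0, activations = 0L
  )
  cells <- bind_rows(agents, rfc_cells)
  list(cells = cells, radius = res$radius, config = config)
}

#' Sample one influx of cells into the annulus
#'
#' New cells enter in the annulus around the tumor spanning radii
#' `[max(0, R - inner), R + outer]`; the count is Poisson with mean
#' `rate * dt` and positions are uniform by area over the annulus.  This is
#' the R-level counterpart of the influx applied every step inside
#' [run_simulation()]; it uses R's global RNG stream.
#'
#' @param rate Influx rate (cells/min).
#' @param tumor_radius Current tumor radius `R` (um).
#' @param dt Time step (min).
#' @param inner_offset,outer_offset Annulus offsets (um).
#' @return A tibble with columns `x`, `y` (possibly zero rows).
#' @export
spawn_influx <- function(rate, tumor_radius, dt = 1, inner_offset = 500,
                         outer_offset = 1500) {
  if (rate < 0) abort("`rate` must be >= 0")
  n <- if (rate == 0) 0L else rpois(1, rate * dt)
  ri <- max(0, tumor_radius - inner_offset)
  ro <- tumor_radius + outer_offset
  r <- sqrt(ri^2 + runif(n) * (ro^2 - ri^2))
  th <- runif(n, 0, 2 * pi)
  tibble(x = r * cos(th), y = r * sin(th))
}

#' Run one seeded simulation
#'
#' Executes the full agent-based model for `total_time_days`: each step
#' applies influx, movement (one unbiased random-walk displacement plus one
#' directed displacement along the summed bias vector for every motile
#' cell), the state transitions of [transition_cells()], and the tumor
#' radius update, then records the state every `record_every` minutes.
#' The trajectory is bit-reproducible for a fixed `(config, seed)`; it runs
#' to the full horizon even if the tumor regresses to radius zero.
#'
#' @param config A [sim_config()].
#' @param verbose Print a one-line run summary (seed, peak and final radius).
#' @return An `eln_sim` tibble with one row per recorded time: `time_min`,
#'   `radius_um`, per-kind counts (`n_apc_off`, `n_apc_m`, `n_t_inactive`,
#'   `n_t_active`, `n_til`, `n_rfc_on`) and cumulative bookkeeping columns
#'   (`cum_influx_apc`, `cum_influx_t`, `cum_til_expired`,
#'   `cum_apc_m_removed`).  The configuration, the final agent table and the
#'   RFC table are attached as attributes `config`, `final_agents`, `rfc`.
#' @examples
#' ts <- run_simulation(sim_config(total_time_days = 0.25, seed = 1))
#' tail(ts, 3)
#' @export
run_simulation <- function(config = sim_config(), verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  res <- cpp_run_simulation(unclass(config))
  ts <- as_tibble(res$timeseries)
  attr(ts, "config") <- config
  attr(ts, "final_agents") <- as_tibble(res$final_agents) %>%
    mutate(kind = code_to_kind(.data$kind))
  attr(ts, "rfc") <- as_tibble(res$rfc)
  class(ts) <- c("eln_sim", class(ts))
  if (verbose) {
    pk <- detect_peak(ts)
    message(sprintf(
      "run seed=%d config=%s peak_radius=%.1f um at day %.2f, final=%.1f um",
      as.integer(config$seed), config_hash(config),
      pk$peak_radius_um, pk$peak_day, ts$radius_um[nrow(ts)]))
  }
  ts
}

#' Short hash of a configuration
#'
#' A compact fingerprint of all configuration values, used in run summary
#' lines and sweep bookkeeping.
#'
#' @param config A [sim_config()].
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), ""),
    sep = "=", collapse = ";")
  # polynomial rolling hash over the serialised key=value string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Export a time series to CSV
#'
#' @param ts An `eln_sim` time series.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  readr::write_csv(as_tibble(ts), path)
  invisible(path)
}
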