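#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation time series
#'
#' Long-format view of an `eln_sim` run: one row per recorded time and cell
#' kind, convenient for ggplot2 faceting.
#'
#' @param x An `eln_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A tibble with columns `time_min`, `day`, `kind`, `count`, plus
#'   `radius_um` repeated per kind.
#' @export
tidy.eln_sim <- function(x, ...) {
  as_tibble(x) %>%
    select("time_min", "radius_um", dplyr::starts_with("n_")) %>%
    tidyr::pivot_longer(dplyr::starts_with("n_"), names_to = "kind",
                        names_prefix = "n_", values_to = "count") %>%
    mutate(day = .data$time_min / 1440, .after = "time_min")
}

#' One-row summary of a simulation run
#'
#' @param x An `eln_sim`.
#' @param ... Unused.
#' @return A tibble with `seed`, `config_hash`, `peak_day`,
#'   `peak_radius_um`, `final_radius_um`, `final_til`, `n_rfc_on`.
#' @export
glance.eln_sim <- function(x, ...) {
  cfg <- attr(x, "config")
  pk <- detect_peak(x)
  tibble(
    seed = as.integer(cfg$seed),
    config_hash = config_hash(cfg),
    peak_day = pk$peak_day,
    peak_radius_um = pk$peak_radius_um,
    final_radius_um = x$radius_um[nrow(x)],
    final_til = x$n_til[nrow(x)],
    n_rfc_on = x$n_rfc_on[nrow(x)]
  )
}

#' Tidy an RFC sweep
#'
#' @param x An [rfc_sweep()] result.
#' @param ... Unused.
#' @return The per-arm summary tibble.
#' @export
tidy.rfc_sweep <- function(x, ...) {
  x$summary
}

#' One-row summary of an RFC sweep
#'
#' @param x An [rfc_sweep()] result.
#' @param ... Unused.
#' @return A tibble with the arm count, replicate count, master seed and the
#'   strongest day-30 reduction observed.
#' @export
glance.rfc_sweep <- function(x, ...) {
  tibble(
    n_arms = nrow(x$summary),
    replicates = x$replicates,
    seed = x$seed,
    best_day30_reduction_pct = max(x$summary$pct_day30_vs_zero, na.rm = TRUE)
  )
}
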